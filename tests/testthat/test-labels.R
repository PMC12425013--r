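# label extraction: superposition, empirical joint, marginals, coupling, RMSF

test_that("kabsch_superpose recovers exact rigid copies and excludes reflections", {
  set.seed(3)
  X <- matrix(stats::rnorm(15, sd = 4), 5, 3)
  Q <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3)   # 90 degrees about z
  Y <- X %*% t(Q) + matrix(c(1, 2, 3), 5, 3, byrow = TRUE)
  fit <- kabsch_superpose(Y, X)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_lt(max(abs(fit$fitted - X)), 1e-8)

  # mirror image of a chiral 4-point set: rotation stays proper, rmsd > 0
  chiral <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1.3, 0), c(0.2, 0.4, 1.7))
  mirror <- chiral %*% diag(c(-1, 1, 1))
  fit2 <- kabsch_superpose(mirror, chiral)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-9)
  expect_gt(fit2$rmsd, 0.1)

  expect_error(kabsch_superpose(chiral[1:2, ], chiral[1:2, ]), "at least 3")
})

test_that("kabsch rmsd matches brute-force quaternion minimization and bio3d", {
  set.seed(21)
  for (rep in 1:3) {
    A <- matrix(stats::rnorm(30, sd = 3), 10, 3)
    B <- matrix(stats::rnorm(30, sd = 3), 10, 3)
    r_pkg <- kabsch_superpose(A, B)$rmsd
    expect_equal(r_pkg, brute_force_rmsd(A, B), tolerance = 1e-6)
    r_bio3d <- bio3d::rmsd(as.vector(t(B)), as.vector(t(A)), fit = TRUE)
    expect_equal(r_pkg, r_bio3d, tolerance = 1e-3)  # bio3d rounds to 3 decimals
  }
})

test_that("align_ensemble collapses rigid copies, is idempotent, never increases RMSD", {
  ch <- make_chain(12, seed = 7)
  set.seed(12)
  Tn <- 6
  coords <- array(NA_real_, c(Tn, 12, 3))
  for (t in seq_len(Tn)) {
    Q <- random_rotation(); b <- stats::rnorm(3, 0, 8)
    coords[t, , ] <- ch$ca %*% t(Q) + matrix(b, 12, 3, byrow = TRUE)
  }
  al <- align_ensemble(gd_ensemble(coords), ch)
  expect_true(al$aligned)
  expect_lt(max(abs(sweep(al$coords, c(2, 3), ch$ca))), 1e-6)

  # idempotence on an already aligned ensemble
  al2 <- align_ensemble(al, ch)
  expect_lt(max(abs(al2$coords - al$coords)), 1e-8)

  # generic ensembles: per-frame RMSD never increases
  noisy <- gd_ensemble(coords + array(stats::rnorm(length(coords)), dim(coords)))
  before <- ensemble_rmsd(noisy, ch)
  after <- ensemble_rmsd(align_ensemble(noisy, ch), ch)
  expect_true(all(after <= before + 1e-10))

  expect_error(align_ensemble(noisy, make_chain(10, seed = 1)), "match")
})

test_that("empirical_joint computes the unbiased sample covariance", {
  # all frames identical -> zero covariance
  ch <- make_chain(5, seed = 1)
  same <- gd_ensemble(array(rep(ch$ca, each = 3), c(3, 5, 3)), aligned = TRUE)
  j <- empirical_joint(same)
  expect_equal(max(abs(j$cov)), 0)
  expect_equal(matrix(j$mean, ncol = 3, byrow = TRUE), ch$ca, ignore_attr = TRUE)

  # 1 residue, two frames at (0,0,0) and (2,0,0): var_x = 2 with T-1 denominator
  e2 <- gd_ensemble(array(c(0, 2, 0, 0, 0, 0), c(2, 1, 3)), aligned = TRUE)
  j2 <- empirical_joint(e2)
  expect_equal(j2$mean, c(1, 0, 0))
  expect_equal(j2$cov[1, 1], 2)
  expect_equal(sum(abs(j2$cov)) - abs(j2$cov[1, 1]), 0)

  expect_error(empirical_joint(gd_ensemble(array(0, c(1, 2, 3)), aligned = TRUE)),
               "at least 2")
  expect_error(empirical_joint(gd_ensemble(array(0, c(3, 2, 3)))), "aligned")
})

test_that("empirical joint converges to the generating covariance (Monte Carlo)", {
  set.seed(99)
  n <- 2
  S <- random_spd(6, 0.5, 2)
  L <- t(chol(S))
  ens <- sample_conformations(numeric(6), L, 1e5, seed = 5)
  j <- empirical_joint(ens)
  rel_err <- norm(j$cov - S, "2") / norm(S, "2")
  expect_lt(rel_err, 0.05)
})

test_that("marginals_from_joint extracts diagonal blocks exactly", {
  # identity joint -> identity marginals
  j <- gd_joint(numeric(9), diag(9))
  m <- marginals_from_joint(j)
  for (i in 1:3) expect_equal(matrix(m[i, , ], 3, 3), diag(3))

  # block-diagonal joint from known blocks
  set.seed(2)
  blocks <- lapply(1:3, function(i) random_spd(3))
  J <- matrix(0, 9, 9)
  for (i in 1:3) J[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)] <- blocks[[i]]
  m2 <- marginals_from_joint(gd_joint(numeric(9), J))
  for (i in 1:3) expect_equal(matrix(m2[i, , ], 3, 3), blocks[[i]])
})

test_that("marginals match a Monte-Carlo marginalization oracle", {
  skip_if_not_installed("MASS")
  set.seed(31)
  S <- random_spd(6, 0.5, 2)
  j <- gd_joint(numeric(6), S)
  m <- marginals_from_joint(j)
  X <- MASS::mvrnorm(2e5, numeric(6), S)
  emp1 <- stats::cov(X[, 1:3])
  expect_lt(max(abs(emp1 - matrix(m[1, , ], 3, 3))), 0.1)
})

test_that("coupling_from_joint mean-pools blocks and matches the naive loop", {
  # a block of all twos pools to 2; identity diagonal block pools to 1/3
  J <- diag(6)
  J[1:3, 4:6] <- 2; J[4:6, 1:3] <- 2
  C <- coupling_from_joint(gd_joint(numeric(6), J))
  expect_equal(C[1, 2], 2)
  expect_equal(C[1, 1], 1 / 3)

  set.seed(17)
  S <- random_spd(12, 0.2, 2)
  j <- gd_joint(numeric(12), S)
  C2 <- coupling_from_joint(j)
  naive <- matrix(0, 4, 4)
  for (i in 1:4) for (k in 1:4)
    naive[i, k] <- mean(S[(3 * i - 2):(3 * i), (3 * k - 2):(3 * k)])
  expect_lt(max(abs(C2 - naive)), 1e-12)
  expect_equal(C2, t(C2))

  # trace pooling variant
  Ct <- coupling_from_joint(j, pooling = "trace")
  naive_t <- matrix(0, 4, 4)
  for (i in 1:4) for (k in 1:4)
    naive_t[i, k] <- sum(diag(S[(3 * i - 2):(3 * i), (3 * k - 2):(3 * k)])) / 3
  expect_lt(max(abs(Ct - naive_t)), 1e-12)
})

test_that("rmsf_from_marginals follows sqrt(trace)", {
  m <- array(0, c(3, 3, 3))
  m[1, , ] <- diag(3)
  m[2, , ] <- diag(c(1, 4, 9))
  m[3, , ] <- 0
  expect_equal(rmsf_from_marginals(m), c(sqrt(3), sqrt(14), 0))
  m[3, , ] <- -diag(3)
  expect_error(rmsf_from_marginals(m), "negative")
})

test_that("RMSF from marginals equals direct coordinate RMSF", {
  set.seed(44)
  fam <- kronecker_family(8)
  L <- joint_factor(fam$marginals, fam$ctilde)
  ens <- sample_conformations(numeric(24), L, 4000, seed = 3)
  labs <- extract_labels(ens, gd_structure(rep("A", 8), matrix(stats::rnorm(24), 8, 3)))
  mu <- apply(ens$coords, c(2, 3), mean)
  Tn <- dim(ens$coords)[1]
  # same T - 1 denominator as the unbiased covariance
  direct <- sqrt(rowSums(apply(ens$coords, 1, function(x)
    rowSums((x - mu)^2))) / (Tn - 1))
  expect_equal(labs$rmsf, direct, tolerance = 1e-10)
  # and both approach the generating RMSF at the Monte-Carlo rate
  expect_equal(labs$rmsf, rmsf_from_marginals(fam$marginals), tolerance = 0.1)
})

test_that("correlation_standardize matches the closed form and Cauchy-Schwarz", {
  # already unit-diagonal input is unchanged under scaling
  Ct <- random_correlation(6)
  expect_equal(correlation_standardize(4 * Ct), Ct, tolerance = 1e-12)

  C <- matrix(c(4, 2, 2, 1), 2, 2)
  expect_equal(correlation_standardize(C), matrix(1, 2, 2))

  set.seed(6)
  for (rep in 1:20) {
    S <- random_spd(7, 0.1, 3)
    Cs <- correlation_standardize(S)
    d <- diag(1 / sqrt(diag(S)))
    raw <- d %*% S %*% d
    expect_true(max(abs(raw)) <= 1 + 1e-12)      # Cauchy-Schwarz: clipping no-op
    expect_lt(max(abs(Cs - raw)), 1e-12)
  }
  expect_error(correlation_standardize(matrix(c(0, 0, 0, 1), 2, 2)), "positive")
})

test_that("replicate ensembles concatenate along T", {
  ch <- make_chain(6, seed = 3)
  fam <- kronecker_family(6)
  L <- joint_factor(fam$marginals, fam$ctilde)
  e1 <- sample_conformations(ch$ca, L, 50, seed = 1)
  e2 <- sample_conformations(ch$ca, L, 70, seed = 2)
  labs <- extract_labels(list(e1, e2), ch)
  expect_equal(labs$n_frames, 120)
})
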