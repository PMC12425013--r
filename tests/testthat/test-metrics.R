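# evaluation metrics

test_that("rmsf_pearson handles trivial and degenerate cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(rmsf_pearson(x, x), 1)
  expect_equal(rmsf_pearson(2.5 * x + 1, x), 1)
  expect_equal(rmsf_pearson(x, rev(x)), -1)
  expect_true(is.na(rmsf_pearson(rep(1, 4), x)))
  expect_error(rmsf_pearson(x, x[1:3]), "equal length")
})

test_that("rmwd matches closed forms and decomposes mean/variance terms", {
  m1 <- array(0, c(1, 3, 3)); m1[1, , ] <- diag(3)
  m2 <- array(0, c(1, 3, 3)); m2[1, , ] <- 4 * diag(3)
  mu <- matrix(0, 1, 3)
  expect_equal(rmwd(m1, m1, mu, mu), 0, tolerance = 1e-8)
  expect_equal(rmwd(m1, m2, variance_only = TRUE), sqrt(3), tolerance = 1e-10)

  # equal covariances, constant mean offset v: full = |v|, variance-only = 0
  set.seed(2)
  n <- 6
  m <- array(NA_real_, c(n, 3, 3))
  for (i in seq_len(n)) m[i, , ] <- random_spd(3)
  v <- c(0.3, -0.4, 1.2)
  mu1 <- matrix(stats::rnorm(n * 3), n, 3)
  mu2 <- mu1 + matrix(v, n, 3, byrow = TRUE)
  expect_equal(rmwd(m, m, mu1, mu2), sqrt(sum(v^2)), tolerance = 1e-7)
  expect_equal(rmwd(m, m, variance_only = TRUE), 0, tolerance = 1e-7)
  expect_error(rmwd(m, m), "means")
})

test_that("symmetric KL variance term matches the Gaussian closed form", {
  m1 <- array(0, c(1, 3, 3)); m1[1, , ] <- diag(3)
  expect_equal(symmetric_kl_var(m1, m1)$mean, 0, tolerance = 1e-12)
  m2 <- array(0, c(1, 3, 3)); m2[1, , ] <- 2 * diag(3)
  expect_equal(symmetric_kl_var(m1, m2)$mean, 0.75, tolerance = 1e-12)

  # symmetry in arguments and invariance under joint rotation
  set.seed(3)
  a <- array(0, c(2, 3, 3)); b <- array(0, c(2, 3, 3))
  for (i in 1:2) { a[i, , ] <- random_spd(3); b[i, , ] <- random_spd(3) }
  expect_equal(symmetric_kl_var(a, b)$mean, symmetric_kl_var(b, a)$mean,
               tolerance = 1e-10)
  Q <- random_rotation()
  ar <- a; br <- b
  for (i in 1:2) {
    ar[i, , ] <- Q %*% matrix(a[i, , ], 3, 3) %*% t(Q)
    br[i, , ] <- Q %*% matrix(b[i, , ], 3, 3) %*% t(Q)
  }
  expect_equal(symmetric_kl_var(ar, br)$mean, symmetric_kl_var(a, b)$mean,
               tolerance = 1e-8)
})

test_that("bandwise_pearson matches a brute-force band extraction", {
  set.seed(4)
  A <- random_correlation(30)
  expect_true(all(abs(bandwise_pearson(A, A, 20) - 1) < 1e-12, na.rm = TRUE))
  Aneg <- -A; diag(Aneg) <- 1
  expect_true(all(abs(bandwise_pearson(A, Aneg, 20) + 1) < 1e-12, na.rm = TRUE))

  B <- random_correlation(30, decay = 2)
  r_pkg <- bandwise_pearson(A, B, 25)
  for (k in c(1, 3, 10, 25)) {
    xs <- c(); ys <- c()
    for (i in 1:30) for (j in 1:30)
      if (j - i >= 1 && j - i <= k) { xs <- c(xs, A[i, j]); ys <- c(ys, B[i, j]) }
    expect_equal(r_pkg[[paste0("k", k)]], stats::cor(xs, ys), tolerance = 1e-12)
  }
  # a band with fewer than 3 entries is missing, not zero; wider bands
  # saturate at the full upper triangle
  r_small <- bandwise_pearson(A[1:3, 1:3], B[1:3, 1:3], 4)
  expect_true(is.na(r_small[1]))          # 2 entries only
  expect_false(is.na(r_small[2]))
  expect_equal(r_small[[2]], r_small[[4]])
})

test_that("ensemble self-comparison hits the trivial fixed points", {
  ch <- make_chain(15, seed = 6)
  fam <- kronecker_family(15)
  ens <- predict_to_ensemble(ch, fam$marginals, fam$ctilde,
                             n_samples = 60, seed = 2)
  rep <- ensemble_metrics(ens, ens, ch)
  expect_equal(rep$rmsf_r, 1, tolerance = 1e-12)
  expect_equal(rep$pca_w2_md, 0, tolerance = 1e-6)
  expect_equal(rep$pca_w2_joint, 0, tolerance = 1e-6)
  expect_equal(rep$weak_contacts_j, 1)
  expect_equal(rep$transient_contacts_j, 1)
  expect_equal(rep$pairwise_rmsd_pred, rep$pairwise_rmsd_ref)

  # frame-order invariance
  perm <- sample(60)
  ens_p <- gd_ensemble(ens$coords[perm, , ], aligned = TRUE)
  rep2 <- ensemble_metrics(ens_p, ens, ch)
  expect_equal(rep2$rmsf_r, 1, tolerance = 1e-12)
  expect_equal(rep2$weak_contacts_j, 1)
  expect_equal(rep2$pairwise_rmsd_pred, rep$pairwise_rmsd_pred, tolerance = 1e-9)
})

test_that("pairwise RMSD of a 2-frame ensemble equals the Kabsch RMSD", {
  ch <- make_chain(10, seed = 7)
  set.seed(8)
  x2 <- ch$ca + matrix(stats::rnorm(30, 0, 0.8), 10, 3)
  ens <- gd_ensemble(gaussdyn:::abind1(array(ch$ca, c(1, 10, 3)),
                                       array(x2, c(1, 10, 3))), aligned = TRUE)
  rep <- ensemble_metrics(ens, ens, ch)
  expect_equal(rep$pairwise_rmsd_pred, kabsch_superpose(ch$ca, x2)$rmsd,
               tolerance = 1e-12)
})

test_that("metrics are invariant under a consistent global rigid motion", {
  ch <- make_chain(12, seed = 9)
  fam <- kronecker_family(12)
  e1 <- predict_to_ensemble(ch, fam$marginals, fam$ctilde, n_samples = 40, seed = 3)
  e2 <- predict_to_ensemble(ch, fam$marginals, fam$ctilde, n_samples = 40, seed = 4)
  rep <- ensemble_metrics(e1, e2, ch)
  set.seed(10)
  Q <- random_rotation(); b <- stats::rnorm(3, 0, 6)
  rot_ens <- function(e) {
    out <- e$coords
    for (t in seq_len(dim(out)[1]))
      out[t, , ] <- e$coords[t, , ] %*% t(Q) + matrix(b, 12, 3, byrow = TRUE)
    gd_ensemble(out, aligned = TRUE)
  }
  rep_rot <- ensemble_metrics(rot_ens(e1), rot_ens(e2), transform_structure(ch, Q, b))
  expect_equal(rep_rot$rmsf_r, rep$rmsf_r, tolerance = 1e-8)
  expect_equal(rep_rot$pairwise_rmsd_pred, rep$pairwise_rmsd_pred, tolerance = 1e-8)
  expect_equal(rep_rot$weak_contacts_j, rep$weak_contacts_j, tolerance = 1e-12)
  expect_equal(rep_rot$pca_w2_md, rep$pca_w2_md, tolerance = 1e-6)

  # rmwd/symmetric KL: zero iff identical Gaussian sets, positive otherwise
  m <- fam$marginals
  expect_gt(rmwd(m, as_marginal_array(lapply(1:12, function(i) random_spd(3))),
                 variance_only = TRUE), 0)
  expect_gt(symmetric_kl_var(m, as_marginal_array(
    lapply(1:12, function(i) random_spd(3))))$mean, 0)
})

test_that("summarize_metrics reports percentiles over finite values", {
  df <- data.frame(a = c(1, 2, 3, NA), b = c(0.5, Inf, 1.5, 2.5))
  s <- summarize_metrics(df)
  expect_equal(s$n, c(3, 3))
  expect_equal(s$median[1], 2)
  expect_equal(s$p25[2], 1.0)
})
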