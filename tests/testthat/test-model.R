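# dynamics predictor: embedding, IPA invariance, SPD heads, training

cfg_small <- gd_config(hidden_dim = 16, num_ipa_blocks = 2, num_pair_blocks = 1,
                       pair_dim = 12, seed = 77, epochs = 5)
enc_small <- gd_encoder(cfg_small)

test_that("sequence embedding is deterministic, local, and shape-correct", {
  s <- "ACDEFGHIKLMNPQRSTVWY"
  e1 <- embed_sequence(s, enc_small)
  e2 <- embed_sequence(s, enc_small)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(20L, cfg_small$hidden_dim))

  s2 <- "ACDEFGHIKLMNPQRSTVWA"   # differs at the last position only
  e3 <- embed_sequence(s2, enc_small)
  expect_equal(e1[1:19, ], e3[1:19, ])
  expect_gt(max(abs(e1[20, ] - e3[20, ])), 1e-6)

  expect_warning(eu <- embed_sequence("ACZ", enc_small), "unknown")
  expect_equal(eu[3, ], embed_sequence("ACX", enc_small)[3, ])
})

test_that("the IPA representation is invariant to global rigid motions", {
  ch <- make_chain(18, seed = 31)
  e1 <- encode_structure(ch, enc_small)
  set.seed(13)
  for (rep in 1:3) {
    Q <- random_rotation(); b <- stats::rnorm(3, 0, 20)
    e2 <- encode_structure(transform_structure(ch, Q, b), enc_small)
    expect_lt(max(abs(e1$h - e2$h)), 1e-5)
  }
  # geometry sensitivity: same sequence, different fold -> different h
  ch2 <- make_chain(18, seed = 32)
  ch2 <- gd_structure(ch$sequence, ch2$ca, ch2$n_coords, ch2$c_coords)
  e3 <- encode_structure(ch2, enc_small)
  expect_gt(max(abs(e1$h - e3$h)), 1e-3)
})

test_that("permutation behavior follows the positional-feature configuration", {
  ch <- make_chain(12, seed = 41)
  perm <- sample(12)
  permute <- function(st) gd_structure(st$sequence[perm], st$ca[perm, ],
                                       st$n_coords[perm, ], st$c_coords[perm, ])
  # without positional features the encoder is permutation-equivariant
  cfg_np <- gd_config(hidden_dim = 16, num_ipa_blocks = 2, seed = 77,
                      use_position = FALSE)
  enc_np <- gd_encoder(cfg_np)
  h <- encode_structure(ch, enc_np)$h
  hp <- encode_structure(permute(ch), enc_np)$h
  expect_lt(max(abs(h[perm, ] - hp)), 1e-5)
  # with positional features enabled (default) it is not
  h2 <- encode_structure(ch, enc_small)$h
  hp2 <- encode_structure(permute(ch), enc_small)$h
  expect_gt(max(abs(h2[perm, ] - hp2)), 1e-3)
})

test_that("marginal head emits SPD, rotation-equivariant covariances", {
  ch <- make_chain(14, seed = 51)
  e <- encode_structure(ch, enc_small)
  q <- ncol(e$h_aug)
  set.seed(15)
  params <- list(W = matrix(stats::rnorm(q * 6, 0, 0.3), q, 6),
                 b = stats::rnorm(6))
  mh <- marginal_head(e$h_aug, e$frames, params)
  for (i in 1:14) expect_true(is_spd(matrix(mh$marginals[i, , ], 3, 3)))

  Q <- random_rotation(); b <- stats::rnorm(3, 0, 5)
  e2 <- encode_structure(transform_structure(ch, Q, b), enc_small)
  mh2 <- marginal_head(e2$h_aug, e2$frames, params)
  for (i in 1:14)
    expect_lt(max(abs(Q %*% matrix(mh$marginals[i, , ], 3, 3) %*% t(Q) -
                        matrix(mh2$marginals[i, , ], 3, 3))), 1e-5)
  # RMSF (trace) is rotation-invariant
  expect_equal(rmsf_from_marginals(mh$marginals),
               rmsf_from_marginals(mh2$marginals), tolerance = 1e-6)
})

test_that("pairwise head emits an SPD, rotation-invariant coupling", {
  ch <- make_chain(10, seed = 61)
  e <- encode_structure(ch, enc_small)
  pf <- pair_features(e, enc_small)
  set.seed(16)
  params <- list(w = stats::rnorm(dim(pf)[3], 0, 0.3), b = stats::rnorm(1))
  ph <- pairwise_head(pf, params)
  expect_true(is_spd(ph$coupling))

  Q <- random_rotation(); b <- stats::rnorm(3, 0, 5)
  e2 <- encode_structure(transform_structure(ch, Q, b), enc_small)
  ph2 <- pairwise_head(pair_features(e2, enc_small), params)
  expect_lt(max(abs(ph$coupling - ph2$coupling)), 1e-5)
})

test_that("pairwise composition matches the hand-built Cholesky on N = 2", {
  ch <- make_chain(5, seed = 71)
  st <- gd_structure(ch$sequence[1:5], ch$ca, ch$n_coords, ch$c_coords)
  e <- encode_structure(st, enc_small)
  pf <- pair_features(e, enc_small)[1:2, 1:2, , drop = FALSE]
  set.seed(17)
  params <- list(w = stats::rnorm(dim(pf)[3], 0, 0.5), b = 0.3)
  ph <- pairwise_head(pf, params)
  z <- ph$z
  L <- matrix(c(softplus(z[1, 1]), z[2, 1], 0, softplus(z[2, 2])), 2, 2)
  expect_equal(ph$coupling, L %*% t(L), tolerance = 1e-12)
})

test_that("SPD-by-construction holds across random weight draws", {
  ch <- make_chain(9, seed = 81)
  e <- encode_structure(ch, enc_small)
  pf <- pair_features(e, enc_small)
  q <- ncol(e$h_aug)
  set.seed(18)
  for (rep in 1:200) {
    mh <- marginal_head(e$h_aug, e$frames,
                        list(W = matrix(stats::rnorm(q * 6, 0, 2), q, 6),
                             b = stats::rnorm(6, 0, 2)))
    for (i in c(1, 5, 9))
      expect_true(is_spd(matrix(mh$marginals[i, , ], 3, 3),
                         tol_eig = -1e-9, relative = TRUE))
    ph <- pairwise_head(pf, list(w = stats::rnorm(dim(pf)[3], 0, 2),
                                 b = stats::rnorm(1, 0, 2)))
    expect_true(is_spd(ph$coupling, tol_eig = -1e-9, relative = TRUE))
  }
})

test_that("loss gradients are finite at the softplus origin", {
  ch <- make_chain(8, seed = 91)
  e <- encode_structure(ch, enc_small)
  q <- ncol(e$h_aug)
  params <- list(W = matrix(0, q, 6), b = rep(0, 6))   # raw a = 0 exactly
  mh <- marginal_head(e$h_aug, e$frames, params)
  mlog <- gaussdyn:::.local_label_logs(
    as_marginal_array(lapply(1:8, function(i) random_spd(3))), e$frames)
  g <- gaussdyn:::.marginal_loss_grad(e$h_aug, mh$raw, mh$local, mlog)
  expect_true(all(is.finite(g$dW)))
  expect_true(all(is.finite(g$db)))
  expect_true(is.finite(g$loss))
})

test_that("training reduces the loss and is exactly reproducible", {
  ds <- tiny_dataset()
  cfg <- gd_config(hidden_dim = 16, num_ipa_blocks = 1, num_pair_blocks = 1,
                   pair_dim = 12, seed = 5, epochs = 40, heads = "both")
  fit1 <- dynfit(ds, cfg)
  expect_lt(fit1$log$train_marginal[nrow(fit1$log)] + fit1$log$train_pairwise[nrow(fit1$log)],
            fit1$log$train_marginal[1] + fit1$log$train_pairwise[1])
  fit2 <- dynfit(ds, cfg)
  expect_identical(fit1$log, fit2$log)
  expect_identical(fit1$params, fit2$params)

  expect_error(dynfit(list(), cfg), "empty")
})

test_that("prediction is deterministic, symmetric, and type-compatible", {
  ds <- tiny_dataset()
  cfg <- gd_config(hidden_dim = 16, num_ipa_blocks = 1, num_pair_blocks = 1,
                   pair_dim = 12, seed = 5, epochs = 60, heads = "both")
  fit <- dynfit(ds, cfg)
  it <- dataset_split(ds, "train")[[1]]
  p1 <- predict(fit, it$structure)
  p2 <- predict(fit, it$structure)
  expect_identical(p1$marginals, p2$marginals)

  # rotated input: RMSF identical, marginals co-rotated, coupling identical
  set.seed(19)
  Q <- random_rotation(); b <- stats::rnorm(3, 0, 10)
  p3 <- predict(fit, transform_structure(it$structure, Q, b))
  expect_equal(p1$rmsf, p3$rmsf, tolerance = 1e-6)
  expect_lt(max(abs(p1$coupling - p3$coupling)), 1e-5)
  n <- n_residues(it$structure)
  for (i in seq_len(n))
    expect_lt(max(abs(Q %*% matrix(p1$marginals[i, , ], 3, 3) %*% t(Q) -
                        matrix(p3$marginals[i, , ], 3, 3))), 1e-5)
  # outputs feed the label machinery directly
  expect_silent(rmsf_from_marginals(p1$marginals))
  expect_silent(correlation_standardize(p1$coupling))

  # memorization sanity: training-item loss is near the final training mean
  losses <- dynfit_losses(fit, dataset_split(ds, "train")[1])
  expect_lt(losses$marginal[1],
            2 * fit$log$train_marginal[fit$best_epoch] + 0.1)
})

test_that("training labels must match the selected heads", {
  ds <- tiny_dataset()
  items <- dataset_split(ds, "train")
  broken <- lapply(items, function(it) {
    it$labels$marginals <- NULL
    it
  })
  expect_error(dynfit(broken, gd_config(heads = "marginal", epochs = 2)),
               "marginals")
})
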