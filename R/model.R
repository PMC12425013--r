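#' SE(3)-invariant dynamics predictor
#'
#' The predictor maps a structure (sequence + residue frames) to the
#' multiscale Gaussian descriptors.  Architecture:
#'
#' * a per-residue sequence embedding plus invariant geometric descriptors
#'   (contact counts at several radii, optional chain-position feature);
#' * a stack of invariant point attention (IPA) blocks over the residue
#'   frames — attention logits combine scalar query/key products with
#'   distances between frame-anchored query/key points, and point outputs are
#'   mapped back into each local frame, so the residue representation `h` is
#'   invariant to any global rigid motion of the input;
#' * a *marginal head* emitting 6 raw numbers per residue, mapped through the
#'   softplus-Cholesky parameterization to a local SPD covariance and rotated
#'   to global coordinates as `Sigma_i = R_i L_i L_i' R_i'` (equivariant);
#' * a *pairwise head* building pair features (including triangle
#'   multiplicative update blocks), reading out one scalar `z_ij` per pair
#'   `i >= j`, and composing the SPD coupling `C = L L'` with softplus on the
#'   diagonal of `L`.
#'
#' The encoder and pair blocks are a fixed random-feature map: their weights
#' are drawn once from the model seed and never updated.  Only the two
#' readout heads are trained (Adam on the analytic gradient of the
#' log-Frobenius loss through the Cholesky composition and the matrix
#' logarithm).  This keeps training on a single CPU fast and exactly
#' reproducible while preserving every structural guarantee: outputs are SPD
#' by construction at any weight setting, and the SE(3) symmetry properties
#' hold for trained and untrained weights alike.
#'
#' @name dynamics_model
NULL

#' Model configuration
#'
#' @param hidden_dim width D of the residue representation (default 32).
#' @param num_ipa_blocks IPA blocks in the encoder (default 2 at desk scale).
#' @param num_pair_blocks triangle-update blocks in the pairwise stack.
#' @param pair_dim pair feature width d' (default 32).
#' @param n_points query/key/value points per residue in IPA (default 4).
#' @param use_position include the chain-position feature i/N (default TRUE;
#'   with FALSE the encoder is exactly permutation-equivariant).
#' @param lr Adam learning rate for the readout heads.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on validation loss.
#' @param seed integer seed controlling the random-feature weights.
#' @param heads `"marginal"`, `"pairwise"` or `"both"`.
#' @return list of class `gd_config`.
#' @export
gd_config <- function(hidden_dim = 32, num_ipa_blocks = 2, num_pair_blocks = 2,
                      pair_dim = 32, n_points = 4, use_position = TRUE,
                      lr = 0.01, epochs = 400, patience = 60, seed = 1,
                      heads = c("both", "marginal", "pairwise")) {
  heads <- match.arg(heads)
  stopifnot(hidden_dim > 0, num_ipa_blocks >= 0, num_pair_blocks >= 0,
            pair_dim > 0, n_points > 0, lr > 0, epochs >= 1)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 num_ipa_blocks = as.integer(num_ipa_blocks),
                 num_pair_blocks = as.integer(num_pair_blocks),
                 pair_dim = as.integer(pair_dim),
                 n_points = as.integer(n_points),
                 use_position = isTRUE(use_position),
                 lr = lr, epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed), heads = heads),
            class = "gd_config")
}

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y","X")

.geo_radii <- c(6, 8, 10, 12, 14)
.rbf_seq_centers <- c(0, 1, 2, 3, 5, 8, 13, 21, 34)
.rbf_dist_centers <- c(4, 6, 8, 10, 14, 18, 24)

.n_geo <- function(config) length(.geo_radii) + as.integer(config$use_position)

.rnorm_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

#' Build the fixed random-feature encoder for a configuration
#'
#' All weights are drawn from `config$seed`; two encoders with the same
#' config are identical.
#'
#' @param config a [gd_config()].
#' @return list of class `gd_encoder` holding the (frozen) weights.
#' @export
gd_encoder <- function(config) {
  D <- config$hidden_dim; P <- config$n_points; dp <- config$pair_dim
  ng <- .n_geo(config)
  set.seed(config$seed)
  blocks <- lapply(seq_len(config$num_ipa_blocks), function(b) list(
    Wq = .rnorm_mat(D, D, 1 / sqrt(D)),
    Wk = .rnorm_mat(D, D, 1 / sqrt(D)),
    Wv = .rnorm_mat(D, D, 1 / sqrt(D)),
    Wqp = .rnorm_mat(D, 3 * P, 0.5 / sqrt(D)),
    Wkp = .rnorm_mat(D, 3 * P, 0.5 / sqrt(D)),
    Wvp = .rnorm_mat(D, 3 * P, 1 / sqrt(D)),
    Wo = .rnorm_mat(D + 4 * P, D, 1 / sqrt(D + 4 * P)),
    bo = stats::rnorm(D, 0, 0.1),
    gamma_pt = 0.5))
  pair_blocks <- lapply(seq_len(config$num_pair_blocks), function(b) list(
    Wa = .rnorm_mat(dp, dp, 1 / sqrt(dp)),
    Wb = .rnorm_mat(dp, dp, 1 / sqrt(dp)),
    Wg = .rnorm_mat(dp, dp, 1 / sqrt(dp))))
  enc <- list(
    We = .rnorm_mat(length(AA_ALPHABET), D, 1),
    Wg = .rnorm_mat(ng, D, 1),
    blocks = blocks,
    Wpp = .rnorm_mat(2 * D + ng * 2, dp, 1 / sqrt(2 * D)),
    Wpr = .rnorm_mat(length(.rbf_seq_centers), dp, 1),
    Wpd = .rnorm_mat(length(.rbf_dist_centers), dp, 1),
    bpp = stats::rnorm(dp, 0, 0.1),
    pair_blocks = pair_blocks,
    config = config)
  class(enc) <- "gd_encoder"
  enc
}

# row-wise layer normalization (no learned gain/shift)
.ln_rows <- function(M) {
  mu <- rowMeans(M)
  s <- sqrt(rowMeans((M - mu)^2) + 1e-8)
  (M - mu) / s
}

#' Embed an amino-acid sequence
#'
#' Pure per-residue lookup: row i depends only on residue i.  Unknown letters
#' map to the 'X' token with a warning.
#'
#' @param sequence character vector (or single string) of one-letter codes.
#' @param encoder a [gd_encoder()].
#' @return `N x D` matrix.
#' @export
embed_sequence <- function(sequence, encoder) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  sequence <- toupper(sequence)
  idx <- match(sequence, AA_ALPHABET)
  if (anyNA(idx)) {
    warning("unknown residue letter(s) ",
            paste(unique(sequence[is.na(idx)]), collapse = ", "),
            " mapped to 'X'")
    idx[is.na(idx)] <- length(AA_ALPHABET)
  }
  encoder$We[idx, , drop = FALSE]
}

#' Invariant per-residue geometric descriptors
#'
#' Contact counts within 6/8/10/12/14 Angstrom (scaled by 1/10) and, if
#' configured, the normalized chain position `i/N`.  With positional features
#' enabled, near-sequence neighbours (`|i - j| < 2`) are excluded from the
#' counts; without them, only the residue itself is excluded, so the
#' descriptors are exactly permutation-covariant.
#'
#' @param ca `N x 3` Calpha coordinates.
#' @param config a [gd_config()].
#' @return `N x n_geo` matrix; invariant under rigid motions.
#' @export
geo_features <- function(ca, config) {
  n <- nrow(ca)
  D <- as.matrix(stats::dist(ca))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  min_sep <- if (config$use_position) 2 else 1
  G <- sapply(.geo_radii, function(r) colSums(D < r & sep >= min_sep) / 10)
  if (config$use_position) G <- cbind(G, seq_len(n) / n)
  G
}

.rbf <- function(x, centers) {
  w <- pmax(centers / 2, 1)
  exp(-sweep(outer(x, centers, "-"), 2, w, "/")^2)
}

#' Run the IPA encoder
#'
#' @param seq_repr `N x D` sequence representation from [embed_sequence()].
#' @param frames a `gd_frames` from [frames_from_backbone()].
#' @param encoder a [gd_encoder()].
#' @return `N x D` residue representation `h`, invariant to global rigid
#'   motions of the frames.
#' @export
ipa_encode <- function(seq_repr, frames, encoder) {
  cfg <- encoder$config
  n <- dim(frames$rotations)[1]
  if (nrow(seq_repr) != n) stop("sequence representation / frame count mismatch")
  D <- cfg$hidden_dim; P <- cfg$n_points
  G <- geo_features(frames$translations, cfg)
  h <- tanh(seq_repr + G %*% encoder$Wg)
  Rm <- frames$rotations; tv <- frames$translations
  to_global <- function(Pl) {
    # Pl: N x 3P local points -> global
    out <- Pl
    for (i in seq_len(n)) {
      M <- matrix(Pl[i, ], nrow = 3)               # 3 x P
      out[i, ] <- as.vector(matrix(Rm[i, , ], 3, 3) %*% M + tv[i, ])
    }
    out
  }
  for (blk in encoder$blocks) {
    q <- h %*% blk$Wq; k <- h %*% blk$Wk; v <- h %*% blk$Wv
    QPg <- to_global(h %*% blk$Wqp)
    KPg <- to_global(h %*% blk$Wkp)
    VPg <- to_global(h %*% blk$Wvp)
    # squared distances between query points of i and key points of j
    d2 <- outer(rowSums(QPg^2), rep(1, n)) + outer(rep(1, n), rowSums(KPg^2)) -
      2 * tcrossprod(QPg, KPg)
    logits <- tcrossprod(q, k) / sqrt(D) - blk$gamma_pt * d2 / (2 * P)
    logits <- sweep(logits, 1, apply(logits, 1, max))
    A <- exp(logits)
    A <- A / rowSums(A)
    o_sc <- A %*% v
    M <- A %*% VPg                                  # N x 3P attended global points
    o_pt <- M
    for (i in seq_len(n)) {
      X <- matrix(M[i, ], nrow = 3) - tv[i, ]
      o_pt[i, ] <- as.vector(t(matrix(Rm[i, , ], 3, 3)) %*% X)  # back to local frame
    }
    norms <- sqrt(t(apply(o_pt, 1, function(r) colSums(matrix(r, nrow = 3)^2))) + 1e-8)
    upd <- cbind(o_sc, o_pt, norms) %*% blk$Wo
    h <- .ln_rows(h + tanh(sweep(upd, 2, blk$bo, "+")))
  }
  h
}

#' Encode a structure end to end
#'
#' Convenience wrapper: frames, geometric descriptors, sequence embedding and
#' IPA encoder.  The head input `h_aug` is `cbind(h, geo)` — the invariant
#' descriptors are skip-connected past the encoder to the readouts.
#'
#' @param structure a [gd_structure()].
#' @param encoder a [gd_encoder()].
#' @return list with `h`, `h_aug`, `frames`, `geo`.
#' @export
encode_structure <- function(structure, encoder) {
  frames <- frames_from_backbone(structure)
  s <- embed_sequence(structure$sequence, encoder)
  h <- ipa_encode(s, frames, encoder)
  geo <- geo_features(structure$ca, encoder$config)
  list(h = h, h_aug = cbind(h, geo), frames = frames, geo = geo)
}

#' Pair features for the pairwise head
#'
#' `f0_ij = tanh(Wpp [h_i || h_j || g_i || g_j] + Wpr rbf(|i-j|) +
#' Wpd rbf(d_ij) + b)`, followed by triangle multiplicative-update blocks
#' `F <- LN(F + tanh(G W_g))` with `G_ij = (1/N) sum_k a_ik * b_jk`.
#' The returned readout input appends the sequence-separation radial basis to
#' the pair features.
#'
#' @param enc_out output of [encode_structure()].
#' @param encoder a [gd_encoder()].
#' @return `N x N x (d' + n_rbf)` array of pair readout features.
#' @export
pair_features <- function(enc_out, encoder) {
  cfg <- encoder$config
  h <- enc_out$h_aug
  n <- nrow(h)
  if (n > 512) stop("pairwise head capped at N = 512 residues (O(N^2) memory)")
  ca <- enc_out$frames$translations
  dp <- cfg$pair_dim
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  Dm <- as.matrix(stats::dist(ca))
  Rseq <- .rbf(as.vector(sep), .rbf_seq_centers)    # n^2 x n_rbf
  Rdist <- .rbf(as.vector(Dm), .rbf_dist_centers)
  Hi <- h[rep(seq_len(n), times = n), , drop = FALSE]
  Hj <- h[rep(seq_len(n), each = n), , drop = FALSE]
  # column-major vec: entry (i, j) is row i + (j-1)*n
  f <- tanh(cbind(Hi, Hj) %*% encoder$Wpp + Rseq %*% encoder$Wpr +
              Rdist %*% encoder$Wpd +
              matrix(encoder$bpp, n * n, dp, byrow = TRUE))
  F3 <- array(f, c(n, n, dp))
  for (blk in encoder$pair_blocks) {
    Af <- tanh(array(matrix(F3, n * n, dp) %*% blk$Wa, c(n, n, dp)))
    Bf <- tanh(array(matrix(F3, n * n, dp) %*% blk$Wb, c(n, n, dp)))
    G <- array(0, c(n, n, dp))
    for (c in seq_len(dp)) G[, , c] <- tcrossprod(Af[, , c], Bf[, , c]) / n
    upd <- tanh(matrix(G, n * n, dp) %*% blk$Wg)
    F3 <- array(.ln_rows(matrix(F3, n * n, dp) + upd), c(n, n, dp))
  }
  out <- array(NA_real_, c(n, n, dp + ncol(Rseq) + 1L))
  out[, , seq_len(dp)] <- F3
  out[, , dp + seq_len(ncol(Rseq))] <- array(Rseq, c(n, n, ncol(Rseq)))
  out[, , dp + ncol(Rseq) + 1L] <- diag(n)    # diagonal indicator channel
  out
}

#' Marginal readout: SPD 3x3 covariances per residue
#'
#' `a_i = W' h_i + b` (6 raw numbers), `L_i` = softplus-Cholesky factor,
#' local covariance `L_i L_i'` rotated to global coordinates by the residue
#' frame: `Sigma_i = R_i L_i L_i' R_i'`.  SPD by construction at any weights;
#' rotation-equivariant because `h` is invariant and the frames co-rotate.
#'
#' @param h_aug `N x q` head input from [encode_structure()].
#' @param frames residue frames.
#' @param params list with `W` (`q x 6`) and `b` (length 6).
#' @return list: `marginals` (`N x 3 x 3` global), `local` (`N x 3 x 3`),
#'   `raw` (`N x 6`).
#' @export
marginal_head <- function(h_aug, frames, params) {
  n <- nrow(h_aug)
  a <- h_aug %*% params$W + matrix(params$b, n, 6, byrow = TRUE)
  marg <- array(NA_real_, c(n, 3, 3)); loc <- array(NA_real_, c(n, 3, 3))
  for (i in seq_len(n)) {
    L <- cholesky_from_raw(a[i, ])
    S <- tcrossprod(L)
    loc[i, , ] <- S
    R <- matrix(frames$rotations[i, , ], 3, 3)
    marg[i, , ] <- R %*% S %*% t(R)
  }
  list(marginals = marg, local = loc, raw = a)
}

#' Pairwise readout: SPD NxN coupling matrix
#'
#' One scalar per pair `i >= j`: `z_ij = w . f_ij + b`; the lower triangle of
#' `L` is filled with `z_ij`, the diagonal passes through softplus, and
#' `C = L L'` — SPD by construction.
#'
#' @param pf `N x N x q` pair readout features from [pair_features()].
#' @param params list with `w` (length q) and `b` (scalar).
#' @return list: `coupling` (`N x N` SPD), `L`, `z` (lower-triangular raw).
#' @export
pairwise_head <- function(pf, params) {
  n <- dim(pf)[1]
  Z <- matrix(as.vector(matrix(pf, n * n, dim(pf)[3]) %*% params$w) + params$b, n, n)
  L <- matrix(0, n, n)
  low <- lower.tri(L)
  L[low] <- Z[low]
  diag(L) <- softplus(diag(Z))
  list(coupling = tcrossprod(L), L = L, z = Z)
}

# ---------------------------------------------------------------------------
# training

# Adam update; state carries first/second moments per parameter array
.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

.adam_init <- function(params)
  list(t = 0,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))

# marginal loss + gradient for one protein (everything in local frames;
# conjugation by a rotation leaves the log-Frobenius distance unchanged)
.marginal_loss_grad <- function(h_aug, a, local_spd, label_logs, want_grad = TRUE) {
  n <- nrow(a)
  loss <- 0
  dA <- if (want_grad) matrix(0, n, 6) else NULL
  for (i in seq_len(n)) {
    S <- add_jitter(matrix(local_spd[i, , ], 3, 3), 1e-10)
    Mlog <- matrix(label_logs[i, , ], 3, 3)
    lg <- matrix_log(S) - Mlog
    loss <- loss + sum(lg * lg)
    if (want_grad) {
      G <- grad_logfrob_sq(S, Mlog)
      dL <- 2 * (G %*% cholesky_from_raw(a[i, ]))
      # map lower-triangular gradient back to the raw 6-vector
      dA[i, ] <- c(dL[1, 1] * sigmoid(a[i, 1]), dL[2, 1],
                   dL[2, 2] * sigmoid(a[i, 3]), dL[3, 1], dL[3, 2],
                   dL[3, 3] * sigmoid(a[i, 6]))
    }
  }
  loss <- loss / n
  out <- list(loss = loss)
  if (want_grad) {
    dA <- dA / n
    out$dW <- crossprod(h_aug, dA)
    out$db <- colSums(dA)
  }
  out
}

# pairwise loss + gradient for one protein; loss is logfrob^2 / N
.pairwise_loss_grad <- function(pf, head, label_log, want_grad = TRUE) {
  n <- nrow(head$coupling)
  Cj <- add_jitter(head$coupling, 1e-10)   # guard against roundoff at the floor
  lg <- matrix_log(Cj) - label_log
  loss <- sum(lg * lg) / n
  out <- list(loss = loss)
  if (want_grad) {
    G <- grad_logfrob_sq(Cj, label_log) / n
    dL <- 2 * (G %*% head$L)
    dZ <- matrix(0, n, n)
    low <- lower.tri(dZ)
    dZ[low] <- dL[low]
    diag(dZ) <- diag(dL) * sigmoid(diag(head$z))
    Fm <- matrix(pf, n * n, dim(pf)[3])
    out$dw <- as.vector(crossprod(Fm, as.vector(dZ)))
    out$db <- sum(dZ)
  }
  out
}

# log of the label marginals in the local residue frames
.local_label_logs <- function(marginals, frames) {
  m <- as_marginal_array(marginals)
  n <- dim(m)[1]
  out <- array(NA_real_, c(n, 3, 3))
  for (i in seq_len(n)) {
    R <- matrix(frames$rotations[i, , ], 3, 3)
    out[i, , ] <- matrix_log(add_jitter(t(R) %*% matrix(m[i, , ], 3, 3) %*% R))
  }
  out
}

#' Fit the dynamics predictor
#'
#' Trains the SPD readout heads on (structure, label) pairs under the squared
#' log-Frobenius loss: the per-residue 3x3 loss (averaged over residues) for
#' the marginal head and the `N x N` loss (scaled by `1/N`) for the pairwise
#' head.  The two heads are independent models sharing the frozen encoder.
#' Full-batch Adam with early stopping on validation loss; fully
#' deterministic given `config$seed`.
#'
#' @param data list of training items, each a list with `structure`
#'   (a [gd_structure()]) and `labels` (a `gd_labels`, needing `marginals`
#'   and/or `coupling` according to `config$heads`).  A `gd_dataset` from
#'   [make_dataset()] is also accepted (its train/val splits are used).
#' @param config a [gd_config()].
#' @param val_data optional validation items (same shape as `data`); when
#'   omitted and `data` is a plain list, the last ~15% of `data` is held out.
#' @return an object of class `dynfit` with the trained head parameters, the
#'   frozen encoder, per-epoch train/validation loss curves and the
#'   best-validation checkpoint.  Methods: [predict.dynfit()],
#'   `print`, `summary`, `coef`, `plot`, `residuals`, [simulate.dynfit()].
#' @examples
#' \donttest{
#' ds <- make_dataset(synthetic_spec(n_train = 4, n_val = 1, n_test = 1,
#'                                   n_frames = 100, seed = 7))
#' fit <- dynfit(ds, gd_config(epochs = 30, heads = "marginal"))
#' pred <- predict(fit, ds$items[[1]]$structure)
#' }
#' @export
dynfit <- function(data, config = gd_config(), val_data = NULL) {
  if (inherits(data, "gd_dataset")) {
    if (is.null(val_data)) val_data <- dataset_split(data, "val")
    data <- dataset_split(data, "train")
  }
  if (length(data) == 0L) stop("empty training set")
  if (is.null(val_data) || length(val_data) == 0L) {
    n_val <- max(1L, round(0.15 * length(data)))
    if (length(data) <= n_val) stop("too few items to carve out validation data")
    val_data <- data[(length(data) - n_val + 1L):length(data)]
    data <- data[seq_len(length(data) - n_val)]
  }
  enc <- gd_encoder(config)
  prep <- function(items) lapply(items, function(it) {
    e <- encode_structure(it$structure, enc)
    p <- list(h_aug = e$h_aug, frames = e$frames, n = nrow(e$h_aug))
    if (config$heads %in% c("both", "marginal")) {
      if (is.null(it$labels$marginals)) stop("labels lack marginals")
      p$mlog <- .local_label_logs(it$labels$marginals, e$frames)
    }
    if (config$heads %in% c("both", "pairwise")) {
      if (is.null(it$labels$coupling)) stop("labels lack coupling")
      p$pf <- pair_features(e, enc)
      p$clog <- matrix_log(add_jitter(it$labels$coupling))
    }
    p
  })
  tr <- prep(data); va <- prep(val_data)
  q <- ncol(tr[[1]]$h_aug)
  npf <- if (!is.null(tr[[1]]$pf)) dim(tr[[1]]$pf)[3] else 0L

  # data-driven head initialization: mean local label covariance / coupling scale
  params <- list()
  if (config$heads %in% c("both", "marginal")) {
    Sbar <- matrix(0, 3, 3)
    for (p in tr) for (i in seq_len(p$n))
      Sbar <- Sbar + matrix_exp(matrix(p$mlog[i, , ], 3, 3))
    Sbar <- Sbar / sum(vapply(tr, `[[`, 1L, "n"))
    params$mW <- matrix(0, q, 6)
    params$mb <- raw_from_cholesky(t(chol(Sbar)))
  }
  if (config$heads %in% c("both", "pairwise")) {
    dbar <- mean(unlist(lapply(tr, function(p) mean(diag(matrix_exp(p$clog))))))
    # start from a diagonal coupling: zero off-diagonal Cholesky entries,
    # diagonal sqrt(mean label variance) via the indicator channel
    params$pw <- numeric(npf)
    params$pw[npf] <- softplus_inv(sqrt(max(dbar, 1e-6)))
    params$pb <- 0
  }

  eval_items <- function(items, prm, want_grad = FALSE) {
    tot <- list(loss_m = 0, loss_p = 0,
                dmW = if (want_grad) params$mW * 0, dmb = if (want_grad) numeric(6),
                dpw = if (want_grad) numeric(npf), dpb = if (want_grad) 0)
    for (p in items) {
      if (!is.null(p$mlog)) {
        mh <- marginal_head(p$h_aug, p$frames, list(W = prm$mW, b = prm$mb))
        r <- .marginal_loss_grad(p$h_aug, mh$raw, mh$local, p$mlog, want_grad)
        tot$loss_m <- tot$loss_m + r$loss
        if (want_grad) { tot$dmW <- tot$dmW + r$dW; tot$dmb <- tot$dmb + r$db }
      }
      if (!is.null(p$clog)) {
        ph <- pairwise_head(p$pf, list(w = prm$pw, b = prm$pb))
        r <- .pairwise_loss_grad(p$pf, ph, p$clog, want_grad)
        tot$loss_p <- tot$loss_p + r$loss
        if (want_grad) { tot$dpw <- tot$dpw + r$dw; tot$dpb <- tot$dpb + r$db }
      }
    }
    m <- length(items)
    tot$loss_m <- tot$loss_m / m; tot$loss_p <- tot$loss_p / m
    if (want_grad) {
      tot$dmW <- tot$dmW / m; tot$dmb <- tot$dmb / m
      tot$dpw <- tot$dpw / m; tot$dpb <- tot$dpb / m
    }
    tot
  }

  grads_of <- function(tot) {
    g <- list()
    if (!is.null(params$mW)) { g$mW <- tot$dmW; g$mb <- tot$dmb }
    if (!is.null(params$pw)) { g$pw <- tot$dpw; g$pb <- tot$dpb }
    g
  }
  state <- .adam_init(params)
  log_df <- data.frame(epoch = integer(), train_marginal = numeric(),
                       train_pairwise = numeric(), val_marginal = numeric(),
                       val_pairwise = numeric(), val_total = numeric())
  best <- list(val = Inf, params = params, epoch = 0L)
  for (ep in seq_len(config$epochs)) {
    tot <- eval_items(tr, params, want_grad = TRUE)
    if (!is.finite(tot$loss_m + tot$loss_p))
      stop("non-finite training loss at epoch ", ep,
           " (marginal = ", tot$loss_m, ", pairwise = ", tot$loss_p, ")")
    upd <- .adam_step(params, grads_of(tot), state, lr = config$lr)
    params <- upd$params; state <- upd$state
    vtot <- eval_items(va, params, want_grad = FALSE)
    vloss <- vtot$loss_m + vtot$loss_p
    log_df[nrow(log_df) + 1L, ] <- list(ep, tot$loss_m, tot$loss_p,
                                        vtot$loss_m, vtot$loss_p, vloss)
    if (vloss < best$val - 1e-10) best <- list(val = vloss, params = params, epoch = ep)
    if (ep - best$epoch >= config$patience) break
  }
  structure(list(encoder = enc, config = config, params = best$params,
                 final_params = params, log = log_df,
                 best_epoch = best$epoch, best_val = best$val,
                 n_train = length(data), n_val = length(val_data)),
            class = "dynfit")
}

#' Predict dynamics descriptors for a structure
#'
#' @param object a fitted [dynfit()] model.
#' @param structure a [gd_structure()].
#' @param ... unused.
#' @return list of class `gd_prediction`: `marginals` (`N x 3 x 3`, SPD),
#'   `coupling` (`N x N`, SPD; `NULL` if only the marginal head was
#'   trained), `correlation`, `rmsf`, and `mean` (the input Calpha
#'   coordinates, the fixed-mean convention).
#' @export
predict.dynfit <- function(object, structure, ...) {
  e <- encode_structure(structure, object$encoder)
  out <- list(mean = structure$ca)
  if (!is.null(object$params$mW)) {
    mh <- marginal_head(e$h_aug, e$frames,
                        list(W = object$params$mW, b = object$params$mb))
    out$marginals <- mh$marginals
    out$rmsf <- rmsf_from_marginals(mh$marginals)
  }
  if (!is.null(object$params$pw)) {
    pf <- pair_features(e, object$encoder)
    ph <- pairwise_head(pf, list(w = object$params$pw, b = object$params$pb))
    out$coupling <- ph$coupling
    out$correlation <- correlation_standardize(ph$coupling)
  }
  structure(out, class = "gd_prediction")
}

#' @export
print.gd_prediction <- function(x, ...) {
  cat(sprintf("<gd_prediction> N = %d%s%s\n", nrow(x$mean),
              if (!is.null(x$marginals)) sprintf(", RMSF %.2f-%.2f A",
                                                 min(x$rmsf), max(x$rmsf)) else "",
              if (!is.null(x$coupling)) ", with coupling" else ""))
  invisible(x)
}

#' @export
print.dynfit <- function(x, ...) {
  cat(sprintf("<dynfit> heads: %s | D = %d, %d IPA block(s) | %d train / %d val proteins\n",
              x$config$heads, x$config$hidden_dim, x$config$num_ipa_blocks,
              x$n_train, x$n_val))
  cat(sprintf(" best validation loss %.4f at epoch %d (of %d run)\n",
              x$best_val, x$best_epoch, nrow(x$log)))
  invisible(x)
}

#' @export
summary.dynfit <- function(object, ...) {
  cat("Dynamics predictor fit\n")
  print(object)
  cat("\nLoss curve (first/last epochs):\n")
  n <- nrow(object$log)
  print(object$log[unique(c(1, 2, 3, n - 1, n)), ], row.names = FALSE)
  invisible(object$log)
}

#' @export
coef.dynfit <- function(object, ...) object$params

#' @export
residuals.dynfit <- function(object, ...) {
  # per-epoch decrease of training loss; useful as a convergence residual
  with(object$log, train_marginal + train_pairwise)
}

#' @export
plot.dynfit <- function(x, ...) {
  with(x$log, {
    tr <- train_marginal + train_pairwise
    va <- val_total
    graphics::matplot(epoch, cbind(tr, va), type = "l", lty = 1,
                      col = c("black", "firebrick"),
                      xlab = "epoch", ylab = "log-Frobenius loss", ...)
    graphics::legend("topright", c("train", "validation"), lty = 1,
                     col = c("black", "firebrick"), bty = "n")
  })
  invisible(x)
}

#' Sample a conformational ensemble from a fitted model
#'
#' Predicts marginals and coupling for `structure`, standardizes the coupling
#' and draws `nsim` conformations around the input coordinates via the
#' closed-form joint factor.
#'
#' @param object a [dynfit()] with both heads.
#' @param nsim ensemble size (default 250).
#' @param seed integer seed (required).
#' @param structure a [gd_structure()].
#' @param repair project a non-PD predicted correlation onto the nearest
#'   correlation matrix (default FALSE: fail loudly instead).
#' @param ... unused.
#' @return a [gd_ensemble()].
#' @export
simulate.dynfit <- function(object, nsim = 250, seed, structure,
                            repair = FALSE, ...) {
  pred <- predict(object, structure)
  if (is.null(pred$marginals) || is.null(pred$coupling))
    stop("simulate needs a model trained with heads = 'both'")
  predict_to_ensemble(structure, pred$marginals, pred$correlation,
                      n_samples = nsim, seed = seed, repair = repair)
}

#' Evaluate the mean prediction losses of a fitted model on items
#'
#' @param object a `dynfit`.
#' @param items list of items with `structure` and `labels`.
#' @return data.frame with one row per item: marginal and pairwise losses.
#' @export
dynfit_losses <- function(object, items) {
  out <- data.frame(item = seq_along(items), marginal = NA_real_,
                    pairwise = NA_real_)
  for (k in seq_along(items)) {
    it <- items[[k]]
    pred <- predict(object, it$structure)
    if (!is.null(pred$marginals) && !is.null(it$labels$marginals)) {
      m <- as_marginal_array(it$labels$marginals)
      l <- 0
      for (i in seq_len(dim(m)[1]))
        l <- l + log_frobenius_sq(matrix(pred$marginals[i, , ], 3, 3),
                                  add_jitter(matrix(m[i, , ], 3, 3)))
      out$marginal[k] <- l / dim(m)[1]
    }
    if (!is.null(pred$coupling) && !is.null(it$labels$coupling))
      out$pairwise[k] <- log_frobenius_sq(pred$coupling,
                                          add_jitter(it$labels$coupling)) /
        nrow(pred$coupling)
  }
  out
}
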