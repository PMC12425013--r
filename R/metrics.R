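#' Evaluation metrics for predicted dynamics
#'
#' Statistics for comparing predicted Gaussian descriptors and sampled
#' ensembles against reference (e.g. MD-derived) ones: RMSF Pearson
#' correlation, root mean 2-Wasserstein distance over per-residue Gaussians
#' (with a variance-only mode), the variance contribution of the symmetric
#' KL divergence, band-wise Pearson correlation of coupling matrices as a
#' function of sequence separation, and ensemble-level comparisons
#' (pairwise RMSD, RMSF correlation, PCA-projected 2-Wasserstein distances,
#' contact-set Jaccard similarities).
#'
#' @name eval_metrics
NULL

#' Pearson correlation between two RMSF profiles
#'
#' Returns `NA` (missing, not zero) when either profile has zero variance.
#'
#' @param pred_rmsf,true_rmsf numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
rmsf_pearson <- function(pred_rmsf, true_rmsf) {
  if (length(pred_rmsf) != length(true_rmsf) || length(pred_rmsf) < 3)
    stop("profiles must have equal length >= 3")
  if (stats::sd(pred_rmsf) == 0 || stats::sd(true_rmsf) == 0) return(NA_real_)
  stats::cor(pred_rmsf, true_rmsf)
}

#' Root mean 2-Wasserstein distance between per-residue Gaussians
#'
#' `sqrt(mean_i W2^2(N(mu_i^pred, S_i^pred), N(mu_i^true, S_i^true)))` in
#' Angstrom; with `variance_only = TRUE` the squared mean-difference term of
#' each `W2^2` is dropped, leaving the Bures (covariance) contribution.
#'
#' @param pred_marginals,true_marginals `N x 3 x 3` arrays of SPD matrices.
#' @param pred_means,true_means optional `N x 3` mean matrices (required
#'   unless `variance_only = TRUE`).
#' @param variance_only drop the mean term.
#' @return nonnegative scalar (Angstrom).
#' @export
rmwd <- function(pred_marginals, true_marginals, pred_means = NULL,
                 true_means = NULL, variance_only = FALSE) {
  P <- as_marginal_array(pred_marginals); Tm <- as_marginal_array(true_marginals)
  n <- dim(P)[1]
  if (dim(Tm)[1] != n) stop("marginal counts differ")
  if (!variance_only && (is.null(pred_means) || is.null(true_means)))
    stop("means are required unless variance_only = TRUE")
  tot <- 0
  for (i in seq_len(n)) {
    w2 <- bures_w2(NULL, matrix(P[i, , ], 3, 3), NULL, matrix(Tm[i, , ], 3, 3))^2
    if (!variance_only) w2 <- w2 + sum((pred_means[i, ] - true_means[i, ])^2)
    tot <- tot + w2
  }
  sqrt(tot / n)
}

#' Variance contribution of the symmetric KL divergence
#'
#' Zero-mean Gaussian symmetric KL per residue:
#' `KL(p||q) + KL(q||p) = 0.5 * (Tr(Sq^-1 Sp) + Tr(Sp^-1 Sq)) - 3`.
#'
#' @inheritParams rmwd
#' @return list with `per_residue` (length N) and `mean`.
#' @export
symmetric_kl_var <- function(pred_marginals, true_marginals) {
  P <- as_marginal_array(pred_marginals); Tm <- as_marginal_array(true_marginals)
  n <- dim(P)[1]
  if (dim(Tm)[1] != n) stop("marginal counts differ")
  vals <- numeric(n)
  for (i in seq_len(n)) {
    Sp <- matrix(P[i, , ], 3, 3); Sq <- matrix(Tm[i, , ], 3, 3)
    iq <- tryCatch(solve(Sq), error = function(e)
      stop("singular covariance at residue ", i, "; add jitter"))
    ip <- tryCatch(solve(Sp), error = function(e)
      stop("singular covariance at residue ", i, "; add jitter"))
    vals[i] <- 0.5 * (sum(diag(iq %*% Sp)) + sum(diag(ip %*% Sq))) - 3
  }
  list(per_residue = vals, mean = mean(vals))
}

#' Band-wise Pearson correlation of coupling/correlation matrices
#'
#' For each band width `k = 1..k_max`, the Pearson correlation over the
#' upper-triangle entries with sequence separation `1 <= j - i <= k`
#' (cumulative bands; the unit diagonal is excluded).  Bands with fewer than
#' 3 entries, or zero variance, are reported as `NA`.
#'
#' @param pred,true `N x N` matrices.
#' @param k_max maximum band width (default 50).
#' @return numeric vector of length `k_max` (named `k1..k`), entries in
#'   `[-1, 1]` or `NA`.
#' @export
bandwise_pearson <- function(pred, true, k_max = 50) {
  pred <- as.matrix(pred); true <- as.matrix(true)
  n <- nrow(pred)
  if (!all(dim(pred) == dim(true))) stop("matrix dimensions differ")
  sep <- outer(seq_len(n), seq_len(n), function(i, j) j - i)
  out <- rep(NA_real_, k_max)
  for (k in seq_len(k_max)) {
    sel <- sep >= 1 & sep <= k
    if (sum(sel) < 3) next
    x <- pred[sel]; y <- true[sel]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    out[k] <- stats::cor(x, y)
  }
  names(out) <- paste0("k", seq_len(k_max))
  out
}

# mean pairwise Calpha RMSD within an ensemble (Kabsch-refit per pair);
# deterministic subsample of pairs when there are more than max_pairs
.mean_pairwise_rmsd <- function(ens, max_pairs = 2000) {
  Tn <- dim(ens$coords)[1]
  if (Tn < 2) stop("need at least 2 conformations")
  pairs <- utils::combn(Tn, 2)
  if (ncol(pairs) > max_pairs)
    pairs <- pairs[, round(seq(1, ncol(pairs), length.out = max_pairs)), drop = FALSE]
  mean(apply(pairs, 2, function(p)
    kabsch_superpose(ens$coords[p[1], , ], ens$coords[p[2], , ])$rmsd))
}

# per-residue RMSF of an aligned ensemble about its own mean
.ensemble_rmsf <- function(ens) {
  mu <- apply(ens$coords, c(2, 3), mean)
  sqrt(apply(ens$coords, 1, function(x) rowSums((x - mu)^2)) |>
         rowMeans())
}

# contact occupancy: fraction of frames with Calpha distance < cutoff
.contact_occupancy <- function(ens, cutoff = 8) {
  Tn <- dim(ens$coords)[1]; n <- dim(ens$coords)[2]
  occ <- matrix(0, n, n)
  for (t in seq_len(Tn))
    occ <- occ + (as.matrix(stats::dist(ens$coords[t, , ])) < cutoff)
  occ / Tn
}

.jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)        # both sets empty: identical
  sum(a & b) / u
}

# 2-Wasserstein between two point clouds under a Gaussian approximation
.gauss_w2_clouds <- function(X, Y) {
  cx <- stats::cov(X); cy <- stats::cov(Y)
  bures_w2(colMeans(X), add_jitter(cx, 1e-10), colMeans(Y), add_jitter(cy, 1e-10))
}

#' Ensemble-level comparison metrics
#'
#' Compares a sampled ensemble against a reference ensemble of the same
#' protein (both aligned to the input structure):
#'
#' * mean pairwise Calpha RMSD within each ensemble (flexibility magnitude);
#' * Pearson correlation of per-residue RMSF profiles;
#' * 2-Wasserstein distance between the ensembles projected on the top-2
#'   principal components of the reference ensemble (`pca_w2_md`) or of the
#'   pooled ensembles (`pca_w2_joint`), under a Gaussian approximation of the
#'   projected clouds;
#' * Jaccard similarity of *weak* contacts (reference occupancy strictly
#'   between `weak_range`) and of *transient* contacts (not in contact in the
#'   input structure, occupancy above `transient_min`), with the same rules
#'   applied to each ensemble.  Contact: Calpha distance < `contact_cutoff`.
#'
#' @param pred,reference [gd_ensemble()] objects with matching N, aligned.
#' @param input a [gd_structure()] (the prediction input / contact baseline).
#' @param contact_cutoff Angstrom (default 8).
#' @param weak_range occupancy band defining weak contacts (default 0.1-0.9).
#' @param transient_min occupancy threshold for transient contacts.
#' @param max_pairs cap on Kabsch pairs for the pairwise RMSD.
#' @return list of class `gd_metric_report`.
#' @export
ensemble_metrics <- function(pred, reference, input, contact_cutoff = 8,
                             weak_range = c(0.1, 0.9), transient_min = 0.1,
                             max_pairs = 2000) {
  n <- dim(pred$coords)[2]
  if (dim(reference$coords)[2] != n || n_residues(input) != n)
    stop("residue counts differ between ensembles/input")
  if (dim(pred$coords)[1] < 2 || dim(reference$coords)[1] < 2)
    stop("both ensembles need at least 2 conformations")
  rmsf_p <- .ensemble_rmsf(pred); rmsf_r <- .ensemble_rmsf(reference)

  flat <- function(e) {
    X <- matrix(NA_real_, dim(e$coords)[1], 3 * n)
    for (t in seq_len(nrow(X))) X[t, ] <- as.vector(t(e$coords[t, , ]))
    X
  }
  Xp <- flat(pred); Xr <- flat(reference)
  pc_md <- stats::prcomp(Xr, center = TRUE, rank. = 2)
  proj <- function(X, pc) sweep(X, 2, pc$center) %*% pc$rotation[, 1:2]
  pc_joint <- stats::prcomp(rbind(Xr, Xp), center = TRUE, rank. = 2)

  occ_p <- .contact_occupancy(pred, contact_cutoff)
  occ_r <- .contact_occupancy(reference, contact_cutoff)
  d0 <- as.matrix(stats::dist(input$ca))
  up <- upper.tri(d0)
  weak_set <- function(occ) occ[up] > weak_range[1] & occ[up] < weak_range[2]
  trans_set <- function(occ) d0[up] >= contact_cutoff & occ[up] > transient_min

  structure(list(
    pairwise_rmsd_pred = .mean_pairwise_rmsd(pred, max_pairs),
    pairwise_rmsd_ref = .mean_pairwise_rmsd(reference, max_pairs),
    rmsf_r = rmsf_pearson(rmsf_p, rmsf_r),
    pca_w2_md = .gauss_w2_clouds(proj(Xp, pc_md), proj(Xr, pc_md)),
    pca_w2_joint = .gauss_w2_clouds(proj(Xp, pc_joint), proj(Xr, pc_joint)),
    weak_contacts_j = .jaccard(weak_set(occ_p), weak_set(occ_r)),
    transient_contacts_j = .jaccard(trans_set(occ_p), trans_set(occ_r)),
    n_residues = n,
    n_pred = dim(pred$coords)[1], n_ref = dim(reference$coords)[1]),
    class = "gd_metric_report")
}

#' @export
print.gd_metric_report <- function(x, ...) {
  cat("<gd_metric_report>\n")
  cat(sprintf("  pairwise RMSD (pred/ref): %.3f / %.3f A\n",
              x$pairwise_rmsd_pred, x$pairwise_rmsd_ref))
  cat(sprintf("  RMSF r: %.3f | PCA W2 (MD/joint): %.3f / %.3f\n",
              x$rmsf_r, x$pca_w2_md, x$pca_w2_joint))
  cat(sprintf("  Jaccard weak / transient contacts: %.3f / %.3f\n",
              x$weak_contacts_j, x$transient_contacts_j))
  invisible(x)
}

#' Summarize per-protein metric values by percentiles
#'
#' @param df data.frame of per-protein metric values (one column per metric).
#' @return data.frame with 25th, median and 75th percentile per metric,
#'   computed over finite values only, plus the count used.
#' @export
summarize_metrics <- function(df) {
  do.call(rbind, lapply(names(df), function(nm) {
    v <- df[[nm]]
    v <- v[is.finite(v)]
    data.frame(metric = nm, n = length(v),
               p25 = if (length(v)) stats::quantile(v, 0.25, names = FALSE) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_,
               p75 = if (length(v)) stats::quantile(v, 0.75, names = FALSE) else NA_real_)
  }))
}
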