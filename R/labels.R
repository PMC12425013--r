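#' Gaussian dynamics labels from conformational ensembles
#'
#' An aligned ensemble of `T` conformations defines an empirical Gaussian
#' over the flattened `3N` Calpha coordinates.  From the joint covariance we
#' extract the multiscale labels: per-residue 3x3 marginal covariances (its
#' diagonal blocks), an `N x N` scalar coupling matrix (mean pooling of each
#' 3x3 block), per-residue RMSF (`sqrt` of each marginal trace) and the
#' unit-diagonal standardization of the coupling.
#'
#' @name labels
NULL

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (det = +1, reflections excluded) and translation
#' minimizing the RMSD of `mobile` onto `reference`.
#'
#' @param mobile,reference `N x 3` coordinate matrices, `N >= 3`.
#' @return list with `rotation` (3x3), `translation` (length 3; the fit is
#'   `mobile %*% t(rotation) + translation`), `rmsd` (Angstrom) and
#'   `fitted` coordinates.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    stop("coordinate sets must be equal-size N x 3 matrices")
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)            # 3x3 covariance of the point sets
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("degenerate (collinear) geometry; rotation not determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)     # proper rotation: R %*% a ~ b
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = as.numeric(cr - R %*% cm), rmsd = rmsd,
       fitted = sweep(fitted, 2, cr, "+"))
}

#' Superpose every conformation of an ensemble onto a reference structure
#'
#' Each frame is independently Kabsch-fitted onto the reference Calpha
#' coordinates; the returned ensemble carries `aligned = TRUE`.
#'
#' @param ensemble a [gd_ensemble()].
#' @param reference a [gd_structure()] or `N x 3` matrix.
#' @return an aligned [gd_ensemble()].
#' @export
align_ensemble <- function(ensemble, reference) {
  ref <- if (inherits(reference, "gd_structure")) reference$ca else as.matrix(reference)
  d <- dim(ensemble$coords)
  if (d[2] != nrow(ref))
    stop("ensemble (", d[2], " residues) does not match reference (",
         nrow(ref), ")")
  out <- ensemble$coords
  for (t in seq_len(d[1]))
    out[t, , ] <- kabsch_superpose(ensemble$coords[t, , ], ref)$fitted
  gd_ensemble(out, aligned = TRUE)
}

#' Per-frame RMSD of an ensemble to a reference
#' @inheritParams align_ensemble
#' @return numeric vector of length `T` (Angstrom), without refitting.
#' @export
ensemble_rmsd <- function(ensemble, reference) {
  ref <- if (inherits(reference, "gd_structure")) reference$ca else as.matrix(reference)
  apply(ensemble$coords, 1, function(x) sqrt(mean(rowSums((x - ref)^2))))
}

#' Empirical joint Gaussian of an aligned ensemble
#'
#' Mean and unbiased (`T - 1` denominator) covariance of the flattened
#' `3N`-vectors.  Coordinates are flattened residue-major:
#' `(x1, y1, z1, x2, ...)`.
#'
#' @param aligned an aligned [gd_ensemble()] with `T >= 2`.
#' @return list of class `gd_joint` with `mean` (length `3N`) and `cov`
#'   (`3N x 3N`, symmetric PSD).
#' @export
empirical_joint <- function(aligned) {
  if (!inherits(aligned, "gd_ensemble")) stop("need a gd_ensemble")
  if (!aligned$aligned)
    stop("ensemble must be aligned first (see align_ensemble)")
  d <- dim(aligned$coords)
  if (d[1] < 2L) stop("need at least 2 conformations for a covariance")
  X <- matrix(NA_real_, d[1], 3L * d[2])
  for (t in seq_len(d[1])) X[t, ] <- as.vector(t(aligned$coords[t, , ]))
  mu <- colMeans(X)
  S <- stats::cov(X)              # unbiased, T - 1 denominator
  gd_joint(mu, (S + t(S)) / 2)
}

#' Construct a joint Gaussian object
#' @param mean numeric vector of length `3N`.
#' @param cov `3N x 3N` symmetric PSD matrix.
#' @return object of class `gd_joint`.
#' @export
gd_joint <- function(mean, cov) {
  cov <- as.matrix(cov)
  if (length(mean) != nrow(cov) || nrow(cov) != ncol(cov))
    stop("mean/cov dimension mismatch")
  if (nrow(cov) %% 3L != 0L) stop("joint dimension must be a multiple of 3")
  if (max(abs(cov - t(cov))) > 1e-6) stop("joint covariance must be symmetric")
  structure(list(mean = as.numeric(mean), cov = cov,
                 n = nrow(cov) %/% 3L), class = "gd_joint")
}

#' @export
print.gd_joint <- function(x, ...) {
  cat(sprintf("<gd_joint> 3N = %d (N = %d residues)\n", 3 * x$n, x$n))
  invisible(x)
}

#' Extract the 3x3 diagonal blocks (marginal covariances) of a joint
#' @param joint a [gd_joint()].
#' @return `N x 3 x 3` array of marginal covariances.
#' @export
marginals_from_joint <- function(joint) {
  n <- joint$n
  covs <- array(NA_real_, c(n, 3, 3))
  for (i in seq_len(n)) {
    idx <- (3 * (i - 1) + 1):(3 * i)
    B <- joint$cov[idx, idx]
    covs[i, , ] <- (B + t(B)) / 2
  }
  covs
}

#' Mean-pooled scalar coupling matrix of a joint
#'
#' `C[i, j]` is the arithmetic mean of the 9 entries of the `(i, j)` 3x3
#' block of the joint covariance (so `C[i, i] = trace/3` only when the block
#' is diagonal).  `pooling = "trace"` uses `trace/3` of each block instead.
#'
#' @param joint a [gd_joint()].
#' @param pooling `"mean"` (default, mean of all 9 entries) or `"trace"`.
#' @return `N x N` symmetric matrix.
#' @export
coupling_from_joint <- function(joint, pooling = c("mean", "trace")) {
  pooling <- match.arg(pooling)
  n <- joint$n
  # average the 9 entries of every block at once via index folding
  S <- joint$cov
  if (pooling == "mean") {
    E <- matrix(1, 3, 1)
    P <- diag(n) %x% E              # 3N x N block-sum operator
    C <- crossprod(P, S %*% P) / 9
  } else {
    C <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      B <- S[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)]
      C[i, j] <- sum(diag(B)) / 3
    }
  }
  (C + t(C)) / 2
}

#' RMSF from marginal covariances
#'
#' `RMSF_i = sqrt(trace(Sigma_marginal(i)))` in Angstrom.
#'
#' @param marginals `N x 3 x 3` array (or list) of marginal covariances.
#' @return numeric vector of length N.
#' @export
rmsf_from_marginals <- function(marginals) {
  marginals <- as_marginal_array(marginals)
  tr <- apply(marginals, 1, function(S) sum(diag(matrix(S, 3, 3))))
  if (any(tr < -1e-8)) stop("negative marginal trace; invalid covariance")
  sqrt(pmax(tr, 0))
}

#' Coerce marginals to a canonical `N x 3 x 3` array
#' @param m list of 3x3 matrices or an `N x 3 x 3` array.
#' @return `N x 3 x 3` array.
#' @export
as_marginal_array <- function(m) {
  if (is.list(m)) {
    out <- array(NA_real_, c(length(m), 3, 3))
    for (i in seq_along(m)) out[i, , ] <- as.matrix(m[[i]])
    out
  } else {
    stopifnot(length(dim(m)) == 3L, dim(m)[2] == 3L, dim(m)[3] == 3L)
    m
  }
}

#' Standardize a coupling matrix to a correlation matrix
#'
#' `Ctilde[i, j] = C[i, j] / sqrt(C[i, i] C[j, j])`, then clipped to
#' `[-1, 1]`; the diagonal is exactly 1.  For an exactly SPD `C` the clipping
#' is a no-op (Cauchy-Schwarz).
#'
#' @param C `N x N` symmetric coupling matrix with positive diagonal.
#' @return `N x N` correlation matrix.
#' @export
correlation_standardize <- function(C) {
  C <- as.matrix(C)
  d <- diag(C)
  if (any(d <= 0)) stop("coupling diagonal must be positive to standardize")
  s <- 1 / sqrt(d)
  Ct <- C * tcrossprod(s)
  Ct <- pmin(pmax(Ct, -1), 1)
  Ct <- (Ct + t(Ct)) / 2
  diag(Ct) <- 1
  Ct
}

#' Extract the full label set from an ensemble
#'
#' Convenience wrapper: align onto the reference, form the empirical joint,
#' and derive marginals, coupling, correlation and RMSF.
#'
#' @param ensemble a [gd_ensemble()] (or list of ensembles, concatenated
#'   along `T` as with replicate simulations).
#' @param reference a [gd_structure()].
#' @param keep_joint keep the dense `3N x 3N` joint in the result?
#' @param align superpose each frame onto the reference first.  The default
#'   (`NULL`) aligns only ensembles not flagged as aligned: re-superposing an
#'   ensemble that is already expressed in the reference frame (e.g. drawn
#'   from a Gaussian around the reference) removes the rigid-body component
#'   of its collective motions and deterministically distorts the extracted
#'   covariance.
#' @return list of class `gd_labels`: `mean` (`N x 3`), `marginals`
#'   (`N x 3 x 3`), `coupling` (`N x N`), `correlation`, `rmsf`, `n_frames`,
#'   optionally `joint`.
#' @export
extract_labels <- function(ensemble, reference, keep_joint = FALSE,
                           align = NULL) {
  if (inherits(ensemble, "gd_ensemble")) ensemble <- list(ensemble)
  if (is.null(align)) align <- !all(vapply(ensemble, `[[`, TRUE, "aligned"))
  coords <- do.call(abind1, lapply(ensemble, function(e) e$coords))
  aligned <- if (align) align_ensemble(gd_ensemble(coords), reference)
             else gd_ensemble(coords, aligned = TRUE)
  joint <- empirical_joint(aligned)
  labels_from_joint(joint, n_frames = dim(coords)[1], keep_joint = keep_joint)
}

#' Derive the label set from a joint Gaussian
#' @param joint a [gd_joint()].
#' @param n_frames frame count to record (if known).
#' @param keep_joint keep the dense joint in the result?
#' @return a `gd_labels` list (see [extract_labels()]).
#' @export
labels_from_joint <- function(joint, n_frames = NA_integer_, keep_joint = FALSE) {
  marg <- marginals_from_joint(joint)
  C <- coupling_from_joint(joint)
  out <- list(mean = matrix(joint$mean, ncol = 3, byrow = TRUE),
              marginals = marg,
              coupling = C,
              correlation = correlation_standardize(
                if (min(diag(C)) > 1e-10) C else add_jitter(C)),
              rmsf = rmsf_from_marginals(marg),
              n_frames = n_frames)
  if (keep_joint) out$joint <- joint
  structure(out, class = "gd_labels")
}

#' @export
print.gd_labels <- function(x, ...) {
  cat(sprintf("<gd_labels> N = %d residues, RMSF %.2f-%.2f A%s\n",
              nrow(x$mean), min(x$rmsf), max(x$rmsf),
              if (is.na(x$n_frames)) "" else sprintf(" (from %d frames)", x$n_frames)))
  invisible(x)
}

# concatenate along first dimension
abind1 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  out <- array(NA_real_, c(sum(vapply(xs, function(x) dim(x)[1], 1L)), d[2], d[3]))
  at <- 1L
  for (x in xs) {
    out[at:(at + dim(x)[1] - 1L), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

# ---------------------------------------------------------------------------
# label container (JSON)

#' Write / read a label set as a JSON container
#'
#' Datasets: `mean` (N x 3), `marginals` (N x 3 x 3), `coupling` (N x N),
#' `rmsf` (N), optional `joint` (3N x 3N), plus `n_frames` and free-form
#' `meta`.  Full double precision is preserved.
#'
#' @param labels a `gd_labels` list.
#' @param path output `.json` path.
#' @param meta optional named list stored alongside.
#' @return `path` invisibly.
#' @export
write_labels <- function(labels, path, meta = NULL) {
  obj <- list(mean = labels$mean, marginals = labels$marginals,
              coupling = labels$coupling, rmsf = labels$rmsf,
              n_frames = labels$n_frames)
  if (!is.null(labels$joint))
    obj$joint <- list(mean = labels$joint$mean, cov = labels$joint$cov)
  if (!is.null(meta)) obj$meta <- meta
  obj <- Filter(Negate(is.null), obj)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(mean = as.matrix(obj$mean),
              marginals = obj$marginals,
              coupling = if (!is.null(obj$coupling)) as.matrix(obj$coupling),
              rmsf = as.numeric(obj$rmsf),
              n_frames = if (is.null(obj$n_frames)) NA_integer_ else obj$n_frames)
  if (!is.null(out$coupling))
    out$correlation <- correlation_standardize(
      if (min(diag(out$coupling)) > 1e-10) out$coupling else add_jitter(out$coupling))
  if (!is.null(obj$joint))
    out$joint <- gd_joint(obj$joint$mean, obj$joint$cov)
  out$meta <- obj$meta
  structure(out, class = "gd_labels")
}
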