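#' Anisotropic network model (ANM) baseline
#'
#' Elastic-network model over Calpha atoms: residues closer than a cutoff are
#' joined by identical Hookean springs.  The Hessian has 3x3 off-diagonal
#' blocks `H_ij = -(gamma / |r_ij|^2) r_ij r_ij'` for contacts and diagonal
#' blocks `H_ii = -sum_j H_ij`.  The positional covariance is the
#' Moore-Penrose pseudo-inverse of `H` over the non-rigid modes (the six
#' zero-frequency translations/rotations are skipped), from which the same
#' Gaussian labels (marginals, coupling, RMSF) are extracted as from an MD
#' ensemble.  Defaults follow the common ANM convention: 15 Angstrom cutoff,
#' spring constant `gamma = 1` in arbitrary units (RMSF shape is
#' gamma-independent; absolute scale is 1/gamma).
#'
#' @param structure a [gd_structure()] (or `N x 3` Calpha matrix), `N >= 3`.
#' @param cutoff contact cutoff in Angstrom (default 15).
#' @param gamma spring constant (default 1).
#' @return object of class `gd_anm` with elements `hessian` (`3N x 3N`),
#'   `cutoff`, `gamma`, `n_skipped_modes` (6), `ca`.
#' @examples
#' ch <- make_chain(20, seed = 1)
#' m <- anm(ch)
#' labs <- labels_from_joint(anm_covariance(m))
#' @export
anm <- function(structure, cutoff = 15, gamma = 1) {
  ca <- if (inherits(structure, "gd_structure")) structure$ca else as.matrix(structure)
  n <- nrow(ca)
  if (n < 3L) stop("ANM needs at least 3 residues")
  D <- as.matrix(stats::dist(ca))
  if (min(D[upper.tri(D)]) < 1e-6) stop("duplicate coordinates in input")
  H <- matrix(0, 3 * n, 3 * n)
  contact <- D < cutoff & upper.tri(D)
  for (i in seq_len(n - 1)) for (j in seq_len(n)[-seq_len(i)]) {
    if (!contact[i, j]) next
    r <- ca[j, ] - ca[i, ]
    B <- -(gamma / sum(r^2)) * tcrossprod(r)
    ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
    H[ri, rj] <- B
    H[rj, ri] <- B
    H[ri, ri] <- H[ri, ri] - B
    H[rj, rj] <- H[rj, rj] - B
  }
  # connectivity check: contact graph must be connected for exactly 6 zero modes
  adj <- (D < cutoff); diag(adj) <- FALSE
  comp <- .graph_components(adj)
  if (max(comp) > 1L)
    stop("contact graph is disconnected at cutoff ", cutoff,
         " Angstrom; increase the cutoff")
  structure(list(hessian = (H + t(H)) / 2, cutoff = cutoff, gamma = gamma,
                 n_skipped_modes = 6L, ca = ca), class = "gd_anm")
}

.graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n); k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v] > 0L) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' @export
print.gd_anm <- function(x, ...) {
  cat(sprintf("<gd_anm> %d residues, cutoff %.1f A, gamma %g\n",
              nrow(x$ca), x$cutoff, x$gamma))
  invisible(x)
}

#' Pseudo-inverse covariance of an ANM
#'
#' Eigendecomposes the Hessian, drops the `n_skipped_modes` smallest-|lambda|
#' modes (rigid-body translations and rotations) and inverts the rest:
#' `Sigma = sum_k v_k v_k' / lambda_k`.  A sanity check requires the first
#' kept eigenvalue to exceed `1e-6` times the largest (i.e. exactly six
#' near-zero modes).
#'
#' @param model a `gd_anm` from [anm()].
#' @param scale optional multiplicative scale applied to the covariance
#'   (e.g. a least-squares fit against reference marginals); default 1.
#' @return a [gd_joint()] with mean equal to the input Calpha coordinates.
#' @export
anm_covariance <- function(model, scale = 1) {
  H <- model$hessian
  d <- nrow(H)
  if (d < 3 * 3 || d - model$n_skipped_modes < 1)
    stop("too few residues for non-rigid modes")
  e <- eigen(H, symmetric = TRUE)        # eigenvalues descending
  lam <- e$values
  keep <- seq_len(d - model$n_skipped_modes)
  if (lam[max(keep)] <= 1e-6 * lam[1])
    stop("7th-smallest eigenvalue is numerically zero: more than 6 rigid modes ",
         "(disconnected or degenerate network)")
  V <- e$vectors[, keep, drop = FALSE]
  S <- V %*% (t(V) / lam[keep]) * scale
  gd_joint(as.vector(t(model$ca)), (S + t(S)) / 2)
}

#' Least-squares scale matching ANM marginals to reference marginals
#'
#' ANM covariances carry an arbitrary 1/gamma scale; for magnitude-sensitive
#' comparisons (RMWD) this fits `s >= 0` minimizing
#' `|| s * diag_blocks(ANM) - reference ||_F^2`.
#'
#' @param model a `gd_anm`.
#' @param ref_marginals reference `N x 3 x 3` marginal covariances.
#' @return scalar scale factor.
#' @export
anm_scale_fit <- function(model, ref_marginals) {
  m_anm <- marginals_from_joint(anm_covariance(model))
  ref <- as_marginal_array(ref_marginals)
  s <- sum(m_anm * ref) / sum(m_anm * m_anm)
  max(s, 0)
}

#' Gaussian dynamics labels from an ANM
#'
#' @inheritParams anm_covariance
#' @param ref_marginals optional reference marginals; when given, the
#'   covariance is scale-fitted to them first (see [anm_scale_fit()]).
#' @return a `gd_labels` list, as from [extract_labels()].
#' @export
anm_labels <- function(model, ref_marginals = NULL, scale = NULL) {
  if (is.null(scale))
    scale <- if (is.null(ref_marginals)) 1 else anm_scale_fit(model, ref_marginals)
  labels_from_joint(anm_covariance(model, scale = scale))
}
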