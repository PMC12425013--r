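#' Joint covariance reconstruction and Gaussian ensemble sampling
#'
#' Given per-residue marginal covariances `Sigma_i = L_i L_i'` and a
#' unit-diagonal correlation matrix `Ctilde`, the approximate joint is
#'
#'   `Sigma_joint = L_marginal (Ctilde (x) I_3) L_marginal'`,
#'
#' with `L_marginal = blockdiag(L_1, ..., L_N)`.  The cross block `(i, j)`
#' is `L_i Ctilde[i, j] L_j'`, a multivariate analogue of
#' `Cov = Corr * sd_i * sd_j`.  If the marginals and `Ctilde` are SPD the
#' result is SPD (SPD closure), and its diagonal blocks equal the input
#' marginals exactly because `Ctilde` has unit diagonal.  Sampling uses the
#' closed-form Cholesky factor `L_marginal (chol(Ctilde) (x) I_3)` and the
#' reparameterization `x = mu + L eps`, never a dense `3N x 3N`
#' factorization.
#'
#' @name joint_reconstruct
NULL

# lower Cholesky of Ctilde with jitter escalation 1e-10 -> 1e-6
.chol_correlation <- function(Ct, repair = FALSE) {
  Ct <- as.matrix(Ct)
  ev_min <- min(eigen((Ct + t(Ct)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-10) {
    if (!repair)
      stop("correlation matrix is not positive definite (min eigenvalue ",
           format(ev_min, digits = 3),
           "); pass repair = TRUE to project onto the nearest correlation matrix")
    Ct <- nearest_correlation(Ct)
  }
  for (eps in c(0, 1e-10, 1e-8, 1e-6)) {
    ch <- tryCatch(t(chol(Ct + diag(eps, nrow(Ct)))), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
  }
  stop("Cholesky of the correlation matrix failed even with jitter 1e-6")
}

#' Nearest correlation matrix (alternating projections)
#'
#' Higham-style alternation between the PSD cone and the unit-diagonal
#' affine set; used to repair predicted correlation matrices that lost
#' positive definiteness to clipping or estimation noise.
#'
#' @param C symmetric matrix with unit diagonal (approximately).
#' @param maxit,tol iteration controls.
#' @return a unit-diagonal positive semidefinite matrix.
#' @export
nearest_correlation <- function(C, maxit = 200, tol = 1e-10) {
  X <- (C + t(C)) / 2
  dS <- matrix(0, nrow(X), ncol(X))
  for (it in seq_len(maxit)) {
    R <- X - dS
    e <- eigen((R + t(R)) / 2, symmetric = TRUE)
    Xp <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))  # PSD projection
    dS <- Xp - R
    Xn <- Xp
    diag(Xn) <- 1                                           # unit-diagonal projection
    if (max(abs(Xn - X)) < tol) { X <- Xn; break }
    X <- Xn
  }
  (X + t(X)) / 2 + diag(1e-10, nrow(X))
}

# Cholesky factors of the marginals, block stacked: N x 3 x 3
.marginal_factors <- function(marginals) {
  m <- as_marginal_array(marginals)
  n <- dim(m)[1]
  Ls <- array(0, c(n, 3, 3))
  for (i in seq_len(n)) {
    S <- matrix(m[i, , ], 3, 3)
    ch <- tryCatch(t(chol((S + t(S)) / 2)), error = function(e) NULL)
    if (is.null(ch)) ch <- t(chol(add_jitter((S + t(S)) / 2)))
    Ls[i, , ] <- ch
  }
  Ls
}

#' Reconstruct an approximate joint covariance from marginals and correlation
#'
#' @param marginals `N x 3 x 3` array (or list) of SPD marginal covariances.
#' @param ctilde `N x N` unit-diagonal correlation matrix; must be positive
#'   definite unless `repair = TRUE`.
#' @param mean optional mean (`N x 3` matrix or `3N` vector; default zero).
#' @param repair project a non-PD `ctilde` onto the nearest correlation
#'   matrix instead of erroring (default `FALSE`: silent repair would mask
#'   model failure).
#' @return a [gd_joint()] whose diagonal 3x3 blocks equal `marginals`.
#' @export
reconstruct_joint <- function(marginals, ctilde, mean = NULL, repair = FALSE) {
  L <- joint_factor(marginals, ctilde, repair = repair)
  n <- dim(as_marginal_array(marginals))[1]
  if (is.null(mean)) mean <- numeric(3 * n)
  if (is.matrix(mean)) mean <- as.vector(t(mean))
  gd_joint(mean, tcrossprod(L))
}

#' Closed-form Cholesky factor of the reconstructed joint
#'
#' `L = L_marginal (chol(Ctilde) (x) I_3)`: lower-triangular with positive
#' diagonal, and `L L' = reconstruct_joint(...)` exactly — no dense `3N x 3N`
#' factorization is ever performed.
#'
#' @inheritParams reconstruct_joint
#' @return `3N x 3N` lower-triangular matrix.
#' @export
joint_factor <- function(marginals, ctilde, repair = FALSE) {
  m <- as_marginal_array(marginals)
  n <- dim(m)[1]
  ctilde <- as.matrix(ctilde)
  if (!all(dim(ctilde) == c(n, n)))
    stop("ctilde must be ", n, " x ", n, " to match the marginals")
  if (max(abs(diag(ctilde) - 1)) > 1e-8)
    stop("ctilde must have unit diagonal")
  Ls <- .marginal_factors(m)
  G <- .chol_correlation(ctilde, repair = repair)   # N x N lower
  L <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    Li <- matrix(Ls[i, , ], 3, 3)
    ri <- (3 * i - 2):(3 * i)
    for (j in seq_len(i)) {
      if (G[i, j] != 0)
        L[ri, (3 * j - 2):(3 * j)] <- Li * G[i, j]
    }
  }
  L
}

#' Sample conformations from a Gaussian joint
#'
#' Reparameterization sampling `x = mu + L eps`, `eps ~ N(0, I)`.
#' Deterministic given `seed`.
#'
#' @param mu mean, length `3N` (or `N x 3` matrix).
#' @param factor lower-triangular `3N x 3N` factor from [joint_factor()]
#'   (any matrix square root works).
#' @param n_samples number of conformations `T >= 1`.
#' @param seed integer seed (required: sampling must be reproducible).
#' @return a [gd_ensemble()] with `T x N x 3` coordinates, `aligned = TRUE`.
#' @export
sample_conformations <- function(mu, factor, n_samples = 250, seed) {
  if (missing(seed) || is.null(seed)) stop("an explicit integer `seed` is required")
  if (is.matrix(mu)) mu <- as.vector(t(mu))
  d <- length(mu)
  stopifnot(nrow(factor) == d, ncol(factor) == d, n_samples >= 1)
  set.seed(as.integer(seed))
  eps <- matrix(stats::rnorm(n_samples * d), nrow = d)
  X <- mu + factor %*% eps                 # d x T
  coords <- array(NA_real_, c(n_samples, d %/% 3L, 3L))
  for (t in seq_len(n_samples)) coords[t, , ] <- matrix(X[, t], ncol = 3, byrow = TRUE)
  gd_ensemble(coords, aligned = TRUE)
}

#' Predict-and-sample: Gaussian ensemble around an input structure
#'
#' Applies the fixed-mean convention (`mu` = the input structure's Calpha
#' coordinates), builds the closed-form joint factor from predicted
#' marginals and correlation, and samples `T` conformations.
#'
#' @param structure a [gd_structure()] giving the mean.
#' @param marginals `N x 3 x 3` marginal covariances.
#' @param ctilde `N x N` correlation matrix.
#' @param n_samples conformations to draw (default 250).
#' @param seed integer seed (required).
#' @param repair see [reconstruct_joint()].
#' @return a [gd_ensemble()].
#' @export
predict_to_ensemble <- function(structure, marginals, ctilde,
                                n_samples = 250, seed, repair = FALSE) {
  n <- n_residues(structure)
  m <- as_marginal_array(marginals)
  if (dim(m)[1] != n) stop("marginal count does not match structure length")
  L <- joint_factor(m, ctilde, repair = repair)
  sample_conformations(structure$ca, L, n_samples = n_samples, seed = seed)
}
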