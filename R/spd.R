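#' SPD matrix machinery
#'
#' Covariance matrices live on the manifold of symmetric positive definite
#' (SPD) matrices.  The package never predicts a covariance directly: it
#' predicts the entries of a lower-triangular Cholesky factor, maps the
#' diagonal through softplus so it stays positive, and composes `L %*% t(L)`.
#' Distances between covariances are measured with the log-Euclidean
#' (log-Frobenius) metric, which applies the matrix logarithm and compares in
#' the flat tangent space, or with the Bures-Wasserstein (Gaussian
#' 2-Wasserstein) distance.
#'
#' @name spd
#' @keywords internal
NULL

#' Numerically stable softplus and its inverse/derivative
#'
#' `softplus(x) = log(1 + exp(x))`, computed with the large-argument branch
#' `x + log1p(exp(-x))` so it never overflows.
#'
#' @param x numeric vector.
#' @return numeric vector, strictly positive.
#' @export
softplus <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
}

#' @rdname softplus
#' @export
softplus_inv <- function(x) {
  stopifnot(all(x > 0))
  # inverse of log(1+e^a): a = log(e^x - 1), stable for large x
  ifelse(x > 30, x, log(expm1(x)))
}

# d softplus / dx = sigmoid(x)
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Build a 3x3 Cholesky factor from 6 unconstrained parameters
#'
#' The lower triangle is filled row-wise as
#' `L = [softplus(a1) 0 0; a2 softplus(a3) 0; a4 a5 softplus(a6)]`,
#' so the diagonal is positive for any real input and `L %*% t(L)` is SPD by
#' construction.
#'
#' @param a numeric vector of length 6, finite.
#' @return 3x3 lower-triangular matrix with positive diagonal.
#' @seealso [compose_spd()], [raw_from_cholesky()]
#' @export
cholesky_from_raw <- function(a) {
  if (length(a) != 6L || !all(is.finite(a)))
    stop("`a` must be 6 finite reals")
  L <- matrix(0, 3, 3)
  d <- softplus(a[c(1, 3, 6)])
  L[1, 1] <- d[1]
  L[2, 1] <- a[2]; L[2, 2] <- d[2]
  L[3, 1] <- a[4]; L[3, 2] <- a[5]; L[3, 3] <- d[3]
  L
}

#' Invert [cholesky_from_raw()]: raw 6-vector from a Cholesky factor
#' @param L 3x3 lower-triangular matrix with positive diagonal.
#' @return numeric vector of length 6.
#' @export
raw_from_cholesky <- function(L) {
  c(softplus_inv(L[1, 1]), L[2, 1], softplus_inv(L[2, 2]),
    L[3, 1], L[3, 2], softplus_inv(L[3, 3]))
}

#' Compose an SPD matrix from its Cholesky factor
#' @param L lower-triangular matrix with positive diagonal.
#' @return SPD matrix `L %*% t(L)`.
#' @export
compose_spd <- function(L) {
  L <- as.matrix(L)
  tcrossprod(L)
}

#' Check that a matrix is symmetric positive definite
#'
#' @param S square matrix.
#' @param tol_sym symmetry tolerance on `max|S - t(S)|`.
#' @param tol_eig absolute eigenvalue floor.
#' @param relative floor the smallest eigenvalue at `tol_eig * max(|eigen|)`
#'   instead; use a small negative `tol_eig` to accept matrices that are PD
#'   up to floating-point roundoff.
#' @return `TRUE`/`FALSE`.
#' @export
is_spd <- function(S, tol_sym = 1e-8, tol_eig = 0, relative = FALSE) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) return(FALSE)
  if (max(abs(S - t(S))) > tol_sym) return(FALSE)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  floor_val <- if (relative) tol_eig * max(abs(ev), .Machine$double.xmin) else tol_eig
  min(ev) > floor_val
}

# symmetrize and eigendecompose, with a floor check on eigenvalues
.sym_eigen <- function(S, floor = 1e-12, what = "matrix_log") {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < floor)
    stop(sprintf("%s: eigenvalue %.3e below floor %.1e; add jitter to the input",
                 what, min(e$values), floor))
  e
}

#' Principal matrix logarithm of an SPD matrix
#'
#' Computed by symmetric eigendecomposition: `log(S) = Q log(Lambda) Q'`.
#' Inputs are symmetrized as `(S + t(S))/2` first; eigenvalues below `1e-12`
#' raise an error advising jitter.
#'
#' @param S SPD matrix.
#' @return symmetric matrix, the same shape as `S`.
#' @export
matrix_log <- function(S) {
  e <- .sym_eigen(S)
  e$vectors %*% (log(e$values) * t(e$vectors))
}

#' Matrix exponential of a symmetric matrix
#' @param M symmetric matrix.
#' @return SPD matrix `exp(M)`.
#' @export
matrix_exp <- function(M) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% (exp(e$values) * t(e$vectors))
}

#' Symmetric square root of an SPD matrix
#' @param S SPD matrix.
#' @return SPD matrix `S^(1/2)`.
#' @export
matrix_sqrt <- function(S) {
  e <- .sym_eigen(S, floor = -1e-10, what = "matrix_sqrt")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Squared log-Frobenius (log-Euclidean) distance between SPD matrices
#'
#' `||log(Sa) - log(Sb)||_F^2`, the training loss for both covariance
#' readouts.  The (unsquared) metric is [log_frobenius()].
#'
#' @param Sa,Sb SPD matrices of equal dimension.
#' @return nonnegative scalar; zero iff `Sa == Sb`.
#' @export
log_frobenius_sq <- function(Sa, Sb) {
  Sa <- as.matrix(Sa); Sb <- as.matrix(Sb)
  if (!all(dim(Sa) == dim(Sb))) stop("dimension mismatch")
  D <- matrix_log(Sa) - matrix_log(Sb)
  sum(D * D)
}

#' @rdname log_frobenius_sq
#' @export
log_frobenius <- function(Sa, Sb) sqrt(log_frobenius_sq(Sa, Sb))

#' Bures-Wasserstein (Gaussian 2-Wasserstein) distance
#'
#' For Gaussians `N(mu1, S1)` and `N(mu2, S2)`:
#' `W2^2 = ||mu1 - mu2||^2 + Tr(S1 + S2 - 2 (S1^{1/2} S2 S1^{1/2})^{1/2})`.
#' Matrix square roots are taken by eigendecomposition.
#'
#' @param mu1,mu2 mean vectors (may be `NULL`/zero for variance-only use).
#' @param S1,S2 SPD covariance matrices.
#' @return the distance `W2 >= 0` (not squared).
#' @export
bures_w2 <- function(mu1, S1, mu2, S2) {
  S1 <- as.matrix(S1); S2 <- as.matrix(S2)
  if (is.null(mu1)) mu1 <- numeric(nrow(S1))
  if (is.null(mu2)) mu2 <- numeric(nrow(S2))
  if (length(mu1) != nrow(S1) || length(mu2) != nrow(S2) ||
      !all(dim(S1) == dim(S2)) || length(mu1) != length(mu2))
    stop("dimension mismatch between means and covariances")
  if (!is_spd(S1, tol_eig = -1e-10) || !is_spd(S2, tol_eig = -1e-10))
    stop("bures_w2 requires SPD covariance inputs")
  r1 <- matrix_sqrt(S1)
  cross <- matrix_sqrt(r1 %*% S2 %*% r1)
  w2sq <- sum((mu1 - mu2)^2) + sum(diag(S1)) + sum(diag(S2)) - 2 * sum(diag(cross))
  sqrt(max(w2sq, 0))
}

#' Gradient of the squared log-Frobenius loss in the covariance
#'
#' For `f(S) = ||log S - M||_F^2` with `M` fixed symmetric, returns `df/dS`
#' using the Daleckii-Krein derivative of the matrix logarithm: with
#' `S = Q diag(lambda) Q'` and `A = 2 (log S - M)`,
#' `df/dS = Q (K * (Q' A Q)) Q'` where `K_kl = (log l_k - log l_l)/(l_k - l_l)`
#' (and `1/l_k` on the diagonal / for equal eigenvalues).
#'
#' Used by the trainer; exposed for gradient checking.
#'
#' @param S SPD matrix (the prediction).
#' @param M symmetric matrix (`log` of the label).
#' @return symmetric gradient matrix, same shape as `S`.
#' @keywords internal
grad_logfrob_sq <- function(S, M) {
  e <- .sym_eigen(S)
  Q <- e$vectors; lam <- e$values
  A <- 2 * (Q %*% (log(lam) * t(Q)) - (M + t(M)) / 2)
  d <- length(lam)
  K <- matrix(0, d, d)
  for (k in seq_len(d)) for (l in seq_len(d)) {
    K[k, l] <- if (abs(lam[k] - lam[l]) < 1e-12 * max(lam)) 1 / lam[k]
               else (log(lam[k]) - log(lam[l])) / (lam[k] - lam[l])
  }
  G <- Q %*% (K * (t(Q) %*% A %*% Q)) %*% t(Q)
  (G + t(G)) / 2
}

# add eps*I jitter (used before Cholesky/eigen on empirical covariances)
add_jitter <- function(S, eps = 1e-8) S + diag(eps, nrow(S))
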