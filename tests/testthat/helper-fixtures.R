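# shared fixtures and small independent oracles

# random proper rotation from a seeded stream
random_rotation <- function() {
  repeat {
    ax <- stats::rnorm(3)
    n <- sqrt(sum(ax^2))
    if (n > 1e-8) { ax <- ax / n; break }
  }
  th <- stats::runif(1, 0.1, pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# random SPD matrix with eigenvalues in [lo, hi]
random_spd <- function(d = 3, lo = 0.3, hi = 3) {
  Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d)))
  ev <- stats::runif(d, lo, hi)
  Q %*% (ev * t(Q))
}

# apply a rigid motion (Q, b) to a structure
transform_structure <- function(st, Q, b) {
  tr <- function(M) if (is.null(M)) NULL else
    M %*% t(Q) + matrix(b, nrow(M), 3, byrow = TRUE)
  gd_structure(st$sequence, tr(st$ca), n_coords = tr(st$n_coords),
               c_coords = tr(st$c_coords), chain_id = st$chain_id,
               resno = st$resno)
}

# random unit-diagonal PD correlation matrix (exponential-decay base + noise)
random_correlation <- function(n, decay = 4) {
  base <- exp(-abs(outer(seq_len(n), seq_len(n), "-")) / decay)
  W <- matrix(stats::rnorm(n * n, 0, 0.2), n)
  S <- base + crossprod(W) / n
  correlation_standardize(S)
}

# exact-reconstruction family: marginals sigma_i^2 * B (common SPD base),
# for which label extraction + reconstruction is an exact round trip
kronecker_family <- function(n, decay = 4) {
  B <- random_spd(3, 0.5, 2)
  sig2 <- stats::runif(n, 0.3, 2)
  marg <- array(NA_real_, c(n, 3, 3))
  for (i in seq_len(n)) marg[i, , ] <- sig2[i] * B
  ct <- exp(-abs(outer(seq_len(n), seq_len(n), "-")) / decay)
  list(marginals = marg, ctilde = ct)
}

# hand-written 3-residue PDB fixture (two chains, one altloc pair on A/2)
write_fixture_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   1.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   2.500   3.000  1.00  0.00           C",
    "ATOM      4  N   GLY A   2       3.000   3.200   3.100  1.00  0.00           N",
    "ATOM      5  CA AGLY A   2       4.000   5.000   6.000  0.60  0.00           C",
    "ATOM      6  CA BGLY A   2       4.500   5.500   6.500  0.40  0.00           C",
    "ATOM      7  C   GLY A   2       5.000   5.500   6.000  1.00  0.00           C",
    "ATOM      8  N   SER A   3       6.000   6.100   6.100  1.00  0.00           N",
    "ATOM      9  CA  SER A   3       7.000   8.000   9.000  1.00  0.00           C",
    "ATOM     10  C   SER A   3       8.000   8.500   9.000  1.00  0.00           C",
    "ATOM     11  CA  LEU B   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM     12  CA  LEU B   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM     13  CA  LEU B   3       7.600   0.000   0.000  1.00  0.00           C",
    "END")
  writeLines(lines, path)
  path
}

# brute-force minimal RMSD over rotations parameterized by quaternions
brute_force_rmsd <- function(mobile, reference, n_starts = 12) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  quat_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  obj <- function(q) sqrt(mean(rowSums((A %*% t(quat_rot(q)) - B)^2)))
  best <- Inf
  for (s in seq_len(n_starts)) {
    q0 <- stats::rnorm(4)
    r <- stats::optim(q0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, r$value)
  }
  best
}

# Rscript invocation of the installed CLI with the current library path
run_cli <- function(args, error_on_status = TRUE) {
  cli <- system.file("cli", "gaussdyn.R", package = "gaussdyn")
  rscript <- file.path(R.home("bin"), "Rscript")
  withr::with_envvar(c(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep),
                       R_LIBS_USER = paste(.libPaths(), collapse = .Platform$path.sep)), {
    out <- suppressWarnings(system2(rscript, c(shQuote(cli), args),
                                    stdout = TRUE, stderr = TRUE))
  })
  status <- attr(out, "status")
  if (is.null(status)) status <- 0L
  if (error_on_status && status != 0L)
    stop("CLI failed (status ", status, "):\n", paste(out, collapse = "\n"))
  list(status = status, output = out)
}

# one small shared dataset for model tests (built once per test run)
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_dataset(synthetic_spec(n_train = 5, n_val = 1, n_test = 2,
                                            length_range = c(18, 28),
                                            n_frames = 200, seed = 404))
    cache
  }
})
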