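#' Synthetic chains, ground-truth covariances and labeled datasets
#'
#' Desk-scale stand-in for an MD training corpus: self-avoiding Calpha
#' chains with ideal backbone geometry, ground-truth joint covariances with
#' known structure (either the exact Kronecker family the reconstruction
#' heuristic spans, or an elastic-network covariance), ensembles sampled
#' from those joints, and labels re-extracted from the sampled ensembles so
#' they carry realistic finite-sampling noise.
#'
#' In the `kronecker` family the per-residue fluctuation scale is a smooth
#' decreasing function of local contact density (buried residues move less,
#' chain termini more — the dominant pattern in real MD RMSF profiles) with
#' 10% lognormal noise, and the marginal principal axes follow the residue
#' frame perturbed by a small random rotation.  This makes the labels a
#' learnable function of structure while keeping eigenvalues inside the
#' requested scale range.
#'
#' @name synthetic_data
NULL

#' Specification for a synthetic dataset
#'
#' @param n_train,n_val,n_test protein counts per split.
#' @param length_range inclusive residue-count range to draw chain lengths from.
#' @param n_frames ensemble size T sampled per protein.
#' @param family `"kronecker"` (exact reconstruction family) or `"anm"`.
#' @param scale_range marginal eigenvalue scale range in Angstrom^2.
#' @param decay correlation decay length in residues:
#'   `Ctilde[i, j] = exp(-|i - j| / decay)`.
#' @param seed integer master seed (mandatory).
#' @return list of class `gd_synth_spec`.
#' @export
synthetic_spec <- function(n_train = 20, n_val = 3, n_test = 5,
                           length_range = c(20, 40), n_frames = 500,
                           family = c("kronecker", "anm"),
                           scale_range = c(0.15, 2.0), decay = 5, seed) {
  if (missing(seed)) stop("`seed` is mandatory for a synthetic spec")
  family <- match.arg(family)
  stopifnot(n_train >= 1, n_val >= 0, n_test >= 0,
            length_range[1] >= 5, n_frames >= 2,
            all(scale_range > 0), decay > 0)
  structure(list(n_train = n_train, n_val = n_val, n_test = n_test,
                 length_range = as.integer(length_range),
                 n_frames = as.integer(n_frames), family = family,
                 scale_range = scale_range, decay = decay,
                 seed = as.integer(seed)),
            class = "gd_synth_spec")
}

#' Generate a self-avoiding Calpha chain with ideal backbone geometry
#'
#' Consecutive Calpha distance is 3.8 Angstrom; non-adjacent residues keep at
#' least 3.0 Angstrom separation.  A weak bias toward the running centroid
#' yields compact, globule-like chains so contact density varies along the
#' chain.  Synthetic backbone N and C atoms are placed at ideal local
#' geometry so residue frames are well defined; the sequence is uniform
#' random over the 20 amino acids.
#'
#' @param n chain length (>= 5).
#' @param seed integer seed.
#' @param bond Calpha-Calpha distance (3.8 A).
#' @param min_sep minimum non-bonded separation (3.0 A).
#' @return a [gd_structure()].
#' @export
make_chain <- function(n, seed, bond = 3.8, min_sep = 3.0) {
  if (n < 5L) stop("chains shorter than 5 residues are not supported")
  set.seed(as.integer(seed))
  for (attempt in 1:50) {
    ca <- matrix(NA_real_, n, 3)
    ca[1, ] <- c(0, 0, 0)
    dir <- .runif_sphere()
    ca[2, ] <- ca[1, ] + bond * dir
    ok <- TRUE
    for (i in 3:n) {
      placed <- FALSE
      for (try in 1:200) {
        # persistent direction + compaction bias toward the centroid
        cen <- colMeans(ca[1:(i - 1), , drop = FALSE])
        pull <- cen - ca[i - 1, ]
        np <- sqrt(sum(pull^2))
        if (np > 0) pull <- pull / np
        d <- dir + 0.9 * .runif_sphere() + 0.25 * pull
        d <- d / sqrt(sum(d^2))
        cand <- ca[i - 1, ] + bond * d
        prev <- ca[1:(i - 2), , drop = FALSE]
        if (min(sqrt(rowSums((prev - matrix(cand, nrow(prev), 3, byrow = TRUE))^2))) >= min_sep) {
          ca[i, ] <- cand
          dir <- d
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      bb <- .ideal_backbone(ca)
      seq1 <- sample(c("A","C","D","E","F","G","H","I","K","L",
                       "M","N","P","Q","R","S","T","V","W","Y"), n, replace = TRUE)
      return(gd_structure(seq1, ca, n_coords = bb$n, c_coords = bb$c))
    }
  }
  stop("chain placement failed after 50 restarts (n = ", n, ")")
}

.runif_sphere <- function() {
  repeat {
    v <- stats::rnorm(3)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) return(v / nv)
  }
}

# place N and C at ideal local geometry around each Calpha
.ideal_backbone <- function(ca) {
  n <- nrow(ca)
  nn <- matrix(NA_real_, n, 3); cc <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    a <- if (i < n) ca[i + 1, ] - ca[i, ] else ca[i, ] - ca[i - 1, ]
    a <- a / sqrt(sum(a^2))
    # deterministic perpendicular
    ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    p <- ref - sum(ref * a) * a
    p <- p / sqrt(sum(p^2))
    dc <- cos(0.62) * a + sin(0.62) * p      # ~35.5 deg off the chain axis
    dn <- cos(2.00) * a + sin(2.00) * p      # ~114.6 deg: never collinear with dc
    cc[i, ] <- ca[i, ] + 1.52 * dc
    nn[i, ] <- ca[i, ] + 1.46 * dn
  }
  list(n = nn, c = cc)
}

#' Contact counts within a radius (excluding sequence neighbours)
#' @param ca `N x 3` Calpha coordinates.
#' @param radius cutoff in Angstrom.
#' @param min_seq_sep exclude pairs with `|i - j|` below this (default 2).
#' @return integer vector of length N.
#' @export
contact_number <- function(ca, radius = 10, min_seq_sep = 2) {
  D <- as.matrix(stats::dist(ca))
  n <- nrow(D)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  colSums(D < radius & sep >= min_seq_sep)
}

# small random rotation: Rodrigues about a random axis, angle ~ N(0, sd_deg)
.small_rotation <- function(sd_deg = 10) {
  ax <- .runif_sphere()
  th <- stats::rnorm(1, 0, sd_deg * pi / 180)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Ground-truth Gaussian for a synthetic chain
#'
#' `kronecker` family: marginal eigenvalues are
#' `s_i * (1.5, 1.0, 0.5) * lognormal(sd 0.1)` where
#' `s_i = lo + (hi - lo) * exp(-cn_i / 6)` decreases with the contact number
#' `cn_i` (10 A radius); principal axes are the residue frame perturbed by a
#' ~10 degree random rotation; the correlation is the exponential-decay
#' (AR(1)) matrix `exp(-|i-j|/decay)`, positive definite by construction;
#' the joint is assembled with [reconstruct_joint()] so it lies exactly in
#' the reconstruction family.  `anm` family: the elastic-network covariance
#' of the chain (plus `1e-6` jitter), rescaled so the median RMSF is 1
#' Angstrom, with labels extracted from it.
#'
#' @param chain a [gd_structure()].
#' @param spec a [synthetic_spec()].
#' @param seed integer seed for the marginal noise draws.
#' @return list with `marginals` (`N x 3 x 3`), `ctilde` (`N x N`),
#'   `joint` ([gd_joint()] with mean = the chain), and `labels`
#'   (clean `gd_labels` derived from the joint).
#' @export
make_ground_truth <- function(chain, spec, seed) {
  n <- n_residues(chain)
  set.seed(as.integer(seed))
  if (spec$family == "kronecker") {
    fr <- frames_from_backbone(chain)
    cn <- contact_number(chain$ca, radius = 10)
    lo <- spec$scale_range[1]; hi <- spec$scale_range[2]
    s <- lo + (hi - lo) * exp(-cn / 6)
    g <- c(1.5, 1.0, 0.5)
    marg <- array(NA_real_, c(n, 3, 3))
    for (i in seq_len(n)) {
      ev <- s[i] * g * exp(stats::rnorm(3, 0, 0.1))
      U <- matrix(fr$rotations[i, , ], 3, 3) %*% .small_rotation(10)
      marg[i, , ] <- U %*% (ev * t(U))
    }
    idx <- seq_len(n)
    ctilde <- exp(-abs(outer(idx, idx, "-")) / spec$decay)
    joint <- reconstruct_joint(marg, ctilde, mean = chain$ca)
  } else {
    model <- anm(chain, cutoff = 15, gamma = 1)
    raw <- anm_covariance(model)
    sc <- 1 / stats::median(rmsf_from_marginals(marginals_from_joint(raw)))^2
    joint <- gd_joint(raw$mean, add_jitter(raw$cov * sc, 1e-6))
    marg <- marginals_from_joint(joint)
    ctilde <- correlation_standardize(coupling_from_joint(joint))
  }
  labels <- labels_from_joint(joint)
  list(marginals = marg, ctilde = ctilde, joint = joint, labels = labels)
}

#' Generate a labeled synthetic dataset
#'
#' For each protein: build a chain, build its ground-truth joint, sample an
#' ensemble of `n_frames` conformations from the closed-form factor, and
#' re-extract "empirical" labels from the sampled ensemble (training uses
#' these, mirroring labels derived from finite MD).  Clean generator labels
#' are kept alongside.  Fully deterministic given the spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir optional directory; when given, per-protein structure PDB,
#'   ensemble PDB, empirical and clean label JSON files plus a
#'   `manifest.json` are written.
#' @return list of class `gd_dataset`: `items` (each with `name`, `split`,
#'   `structure`, `ensemble`, `labels` (empirical), `clean` (generator
#'   truth), `seed`), `spec`, and `manifest`.
#' @export
make_dataset <- function(spec, out_dir = NULL) {
  n_items <- spec$n_train + spec$n_val + spec$n_test
  set.seed(spec$seed)
  item_seeds <- sample.int(2^30, n_items * 3)
  lens <- sample(seq(spec$length_range[1], spec$length_range[2]), n_items,
                 replace = TRUE)
  split <- rep(c("train", "val", "test"), c(spec$n_train, spec$n_val, spec$n_test))
  items <- vector("list", n_items)
  for (k in seq_len(n_items)) {
    s_chain <- item_seeds[3 * k - 2]
    s_gt <- item_seeds[3 * k - 1]
    s_ens <- item_seeds[3 * k]
    chain <- make_chain(lens[k], seed = s_chain)
    gt <- make_ground_truth(chain, spec, seed = s_gt)
    L <- joint_factor(gt$marginals, gt$ctilde)
    ens <- sample_conformations(chain$ca, L, n_samples = spec$n_frames,
                                seed = s_ens)
    emp <- extract_labels(ens, chain)
    items[[k]] <- list(name = sprintf("synth_%03d", k), split = split[k],
                       structure = chain, ensemble = ens,
                       labels = emp, clean = gt$labels, ctilde = gt$ctilde,
                       seed = c(chain = s_chain, truth = s_gt, ensemble = s_ens))
  }
  manifest <- list(
    spec = unclass(spec),
    items = lapply(items, function(it)
      list(name = it$name, split = it$split,
           n_residues = n_residues(it$structure),
           seeds = as.list(it$seed),
           files = list(structure = paste0(it$name, "_structure.pdb"),
                        ensemble = paste0(it$name, "_ensemble.pdb"),
                        labels = paste0(it$name, "_labels.json"),
                        clean_labels = paste0(it$name, "_labels_clean.json")))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (it in items) {
      write_structure(it$structure, file.path(out_dir, paste0(it$name, "_structure.pdb")))
      write_ensemble(it$ensemble, it$structure,
                     file.path(out_dir, paste0(it$name, "_ensemble.pdb")),
                     bfactor = it$labels$rmsf)
      write_labels(it$labels, file.path(out_dir, paste0(it$name, "_labels.json")),
                   meta = list(kind = "empirical", seeds = as.list(it$seed)))
      write_labels(it$clean, file.path(out_dir, paste0(it$name, "_labels_clean.json")),
                   meta = list(kind = "clean", seeds = as.list(it$seed)))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  structure(list(items = items, spec = spec, manifest = manifest),
            class = "gd_dataset")
}

#' @export
print.gd_dataset <- function(x, ...) {
  tab <- table(vapply(x$items, `[[`, "", "split"))
  cat(sprintf("<gd_dataset> %d proteins (%s), family %s, T = %d\n",
              length(x$items),
              paste(names(tab), tab, sep = ": ", collapse = ", "),
              x$spec$family, x$spec$n_frames))
  invisible(x)
}

#' Subset a dataset by split
#' @param dataset a `gd_dataset`.
#' @param split one of `"train"`, `"val"`, `"test"`.
#' @return list of items.
#' @export
dataset_split <- function(dataset, split) {
  Filter(function(it) it$split == split, dataset$items)
}
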