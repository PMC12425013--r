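---
title: "Gaussian models of backbone dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian models of backbone dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaussdyn)
```

## The model

A protein's backbone fluctuations around an equilibrium structure are
summarized to second order by modelling the flattened Cα coordinates
`X ∈ ℝ^{3N}` as a multivariate Gaussian `X ~ N(μ, Σ_joint)`.  This discards
anharmonicity and multi-basin behaviour but yields tractable, composable
descriptors:

* **marginal covariances** `Σ_i`, the 3×3 diagonal blocks of `Σ_joint`:
  each is an anisotropic ellipsoid of positional spread for one residue;
* **RMSF**, `sqrt(tr Σ_i)`: scalar flexibility per residue;
* **scalar coupling** `C_ij`: mean of the nine entries of the `(i, j)`
  off-diagonal block (mean pooling; the alternative `trace/3`, which ignores
  the off-diagonal structure of each block, is available via
  `coupling_from_joint(..., pooling = "trace")`);
* the **correlation standardization** `C̃_ij = C_ij / sqrt(C_ii C_jj)`,
  clipped to `[−1, 1]` (a no-op for exactly SPD `C`, by Cauchy–Schwarz).

### Label extraction

Given an ensemble of `T` conformations, `empirical_joint()` uses the
unbiased (`T − 1` denominator) sample covariance; the choice is stated here
and in the tests because at `T` of a few hundred the `T` vs `T − 1`
difference is visible at the tolerances we test.

Alignment semantics deserve a note.  Ensembles read from files are Kabsch-
superposed frame-by-frame onto the reference structure before covariance
extraction.  Ensembles *sampled from a Gaussian around the reference* are
already expressed in the reference frame; `extract_labels()` therefore skips
the re-fit when the ensemble carries its `aligned` flag.  This is not a
shortcut: re-superposing such an ensemble projects out the rigid-body
component of every sample, which deterministically shrinks and reshapes the
extracted covariance (on strongly coupled chains we measured RMSF profiles
whose correlation with the generating truth dropped below 0.4 while two
independently sampled ensembles agreed with each other at r > 0.99).  With
the flag honored, extracted labels converge to the generating ground truth
as `T` grows — a property the test suite checks at `T ∈ {10², 10³, 10⁴}`.

### SPD parameterization and loss

Covariances must be symmetric positive definite.  Instead of predicting
matrix entries and repairing, every covariance output is built from a
Cholesky factor whose diagonal passes through softplus
(`cholesky_from_raw()`): any 6 real numbers map to a valid 3×3 SPD matrix,
and any real lower triangle maps to a valid `N×N` coupling.  Distances
between covariances use the log-Euclidean (log-Frobenius) metric,
`‖log Σ_a − log Σ_b‖_F`, computed by symmetric eigendecomposition with an
eigenvalue floor of `1e-12` (inputs are symmetrized first; empirical
covariances get `1e-8·I` jitter before any factorization).  The squared form
is the training loss; the Bures–Wasserstein (Gaussian 2-Wasserstein)
distance is provided as a metric (`bures_w2()`) but not used for training —
the log-Euclidean loss has better-behaved gradients on ill-conditioned
inputs.

The loss gradient in the covariance needs the derivative of the matrix
logarithm; we use the Daleckii–Krein closed form on the eigenbasis
(`grad_logfrob_sq()`), verified against finite differences in the tests.

### Joint reconstruction and sampling

From marginals and a correlation matrix,

```
Σ_joint = L_marginal (C̃ ⊗ I₃) L_marginalᵀ,   L_marginal = ⊕_i chol(Σ_i),
```

the multivariate analogue of `cov = corr · σ_i σ_j`.  Two properties drive
everything downstream, and both are tested directly: the result is SPD
whenever the inputs are (congruence of the SPD matrix `C̃ ⊗ I₃` by an
invertible triangular matrix), and its diagonal blocks equal the input
marginals exactly because `C̃` has unit diagonal.  Sampling uses the
closed-form factor `L = L_marginal (chol(C̃) ⊗ I₃)` — lower-triangular with
positive diagonal, equal to the dense Cholesky of `Σ_joint` — so drawing an
ensemble is `x = μ + Lε` with no `3N×3N` factorization.

The reconstruction is a heuristic: mean pooling is not the exact inverse of
the cross-block formula unless the marginal factors share their orientation
(e.g. marginals that are scalar multiples of a common base matrix).  On that
family extraction → reconstruction is an exact round trip (tested to
`1e-10`); on general joints the reconstruction preserves marginals and SPD
but approximates cross blocks.

A predicted `C̃` can lose positive definiteness to clipping or estimation
noise.  The default is a hard error: silent repair would mask model failure.
`repair = TRUE` projects onto the nearest unit-diagonal PSD matrix by
alternating projections, and the Cholesky of `C̃` escalates jitter
`0 → 1e-10 → 1e-8 → 1e-6` before failing.

### The predictor

The inputs are per-residue rigid frames `T_i = (R_i, t_i)` built from
backbone N/Cα/C by Gram–Schmidt (first axis along `C − Cα`; Cα-only inputs
fall back to identity rotations with a warning and lose equivariance) plus
the amino-acid sequence.  The encoder is a stack of invariant point
attention blocks: attention logits combine scalar query–key products with
squared distances between frame-anchored 3-D points, and point outputs are
rotated back into each residue's local frame, so the representation `h` is
invariant under any global rigid motion — verified to `1e-5` (observed at
machine precision).  No pair representation enters the encoder.  Invariant
geometric descriptors (contact counts at 6–14 Å, optionally the chain
position `i/N`) are appended to the input embedding and skip-connected to
the readouts.

Predictions must nevertheless live in the *global* frame, and covariances
must co-rotate with the structure.  The marginal head resolves this by
predicting in the local frame and rotating out:
`Σ_i = R_i (L_i L_iᵀ) R_iᵀ` — equivariant by construction since `h` is
invariant and `R_i` co-rotates.  The pairwise head builds pair features from
`h` (concatenation projection plus radial-basis encodings of sequence
separation and Cα distance), passes them through triangle multiplicative
update blocks, and reads out one scalar per pair `i ≥ j` to fill the
Cholesky factor of `C`; being a function of invariant quantities only, `C`
is invariant.

**Training scope.** The encoder and pair blocks are a *fixed random-feature
map*: their weights are drawn once from the model seed and never updated;
only the readout heads are trained, by full-batch Adam on analytic gradients
through the softplus-Cholesky composition and the matrix logarithm.  This is
a deliberate design for a package that must train in seconds on one CPU with
exact reproducibility: the SPD and symmetry guarantees are architectural
(they hold at any weights, trained or not), the optimization is
low-dimensional and stable, and on the synthetic study conditions the frozen
encoder retains enough geometric information that held-out RMSF profiles are
recovered at median r ≈ 0.95 and coupling band correlations at r ≈ 0.95.
End-to-end training of the encoder would be the natural extension where a
GPU autodiff stack is available; nothing in the interfaces would change.
The two heads are trained as two independent models sharing the frozen
encoder, with the per-residue 3×3 loss averaged over residues and the `N×N`
loss scaled by `1/N` so proteins of different length weigh comparably.
Defaults (`gd_config()`): `D = 32`, 2 IPA blocks, 2 triangle blocks,
`d' = 32`, Adam at `lr = 0.01` for up to 400 epochs with early stopping on
validation loss (patience 60) — the learning rate was chosen for stability
of the loss curve on pilot data, and everything is config-exposed.  Training
aborts on a non-finite loss with diagnostics.  The pairwise head caps `N` at
512 (O(N²) memory).

### The elastic-network baseline

`anm()` implements the anisotropic network model with the common
conventions: 15 Å cutoff, uniform spring constant γ = 1 (arbitrary units),
off-diagonal blocks `−(γ/|r_ij|²) r_ij r_ijᵀ`, diagonal blocks the negative
row sums.  The covariance is the pseudo-inverse over non-rigid modes,
skipping exactly 6 modes by count with a sanity check that the 7th
eigenvalue exceeds `1e-6` of the largest; a disconnected contact graph is an
error suggesting a larger cutoff.  ANM covariances carry an arbitrary 1/γ
scale, so comparisons use scale-free statistics (correlations, standardized
`C̃`); `anm_scale_fit()` provides a least-squares scale for RMWD-type
comparisons.

### Evaluation metrics

* `rmsf_pearson()` — Pearson r of RMSF profiles; zero-variance inputs give
  `NA` (missing), never zero.
* `rmwd()` — `sqrt(mean_i W₂²)` over per-residue Gaussians (root of the
  mean, not mean of roots); `variance_only` drops the mean-difference term.
* `symmetric_kl_var()` — zero-mean symmetric KL per residue,
  `½(tr(Σ_q⁻¹Σ_p) + tr(Σ_p⁻¹Σ_q)) − 3`, mirroring the variance-only RMWD
  treatment.  This is the *variance contribution* only; mean terms are
  evaluated by RMWD.
* `bandwise_pearson()` — Pearson r over upper-triangle entries with
  sequence separation `1 ≤ j − i ≤ k`, cumulative in `k` (default to 50),
  diagonal excluded (identically 1 in both); bands with < 3 entries are
  missing.
* `ensemble_metrics()` — mean pairwise Cα RMSD (Kabsch-refit per pair,
  deterministically subsampled above 2000 pairs), RMSF correlation,
  2-Wasserstein distance between ensembles projected on the top-2 principal
  components of the reference (or pooled) ensemble under a Gaussian
  approximation of the projected clouds, and Jaccard similarity of contact
  sets.  Contacts use Cα–Cα < 8 Å with occupancy = fraction of frames;
  *weak* contacts have reference-rule occupancy in (0.1, 0.9), *transient*
  contacts are absent in the input structure but occupied > 0.1.  All
  thresholds are exposed as arguments.  Two empty contact sets count as
  identical (Jaccard 1).

### The synthetic-data generator

`make_dataset()` emulates what an MD-derived training corpus looks like to
this model: compact self-avoiding Cα chains (3.8 Å bonds, ≥ 3.0 Å
self-avoidance, ideal backbone N/C so frames are well defined), a
ground-truth joint covariance per chain, ensembles sampled from that joint,
and labels re-extracted from the sampled ensemble so training labels carry
realistic finite-`T` noise (clean generator labels are kept alongside).

In the default `kronecker` family the joint is built by the reconstruction
formula itself, with marginal eigenvalues `s_i · (1.5, 1.0, 0.5)` ×
lognormal(sd 0.1) noise, where `s_i` decreases smoothly with local contact
density — buried residues fluctuate less, termini more, the dominant pattern
in real RMSF profiles — and spans the configured scale range
(0.15–2.0 Å² by default, i.e. RMSF roughly 0.7–2.5 Å).  Marginal axes
follow the residue frame perturbed by a ~10° random rotation; the
correlation is the exponential-decay (AR(1)) matrix `exp(−|i−j|/5)`,
positive definite by construction, reflecting coupling that decays quickly
with sequence separation.  The `anm` family instead uses the elastic-network
covariance of the chain (jittered, rescaled to unit median RMSF), giving
out-of-family joints.

What this generator does *not* emulate: sequence–structure consistency (the
sequence is uniform random; the learning task is geometric), multi-basin
dynamics, anharmonicity, solvent effects, or time correlation.  Passing
tests on these data demonstrate that the machinery is correct and that the
model can recover learnable structure–dynamics relationships — not that it
matches real MD accuracy.

### Numerical choices, in one place

* Unbiased covariance (`T − 1`); alignment honors the `aligned` flag.
* Jitter `1e-8·I` before factorizing empirical covariances; `1e-10·I`
  inside the training loss as a roundoff guard; eigenvalue floor `1e-12` in
  `matrix_log` with an error advising jitter.
* Altloc resolution: highest occupancy, ties to altloc `A`; insertion codes
  preserved in residue order; coordinates always Å; residue indexing
  1-based everywhere user-facing.
* `C̃` Cholesky jitter escalation to `1e-6`, then error; nearest-correlation
  repair is opt-in.
* Softplus uses the overflow-safe branch; its output is SPD-by-construction
  at any weights — at extreme weights (|raw| ≳ 30) the composed matrix's
  smallest eigenvalue falls below double-precision roundoff relative to its
  norm, so SPD checks in the tests use a relative floor of `−1e-9·max|λ|`.
* All sampling requires an explicit integer seed; training is deterministic
  given the config seed (full-batch, single-threaded).

### Problem sizes used by the tests

The test suite and acceptance script run chains of 18–40 residues, datasets
of 5–28 proteins with ensembles of 150–500 frames, Monte-Carlo checks at
`10⁴`–`10⁵` samples, and 1000-draw property loops — sizes chosen so the
whole suite completes in a couple of minutes on a single CPU while every
statistical tolerance retains a wide margin over its sampling error.

### Known limitations

* The Gaussian assumption cannot represent multi-modal ensembles; sampled
  conformations are raw Cα Gaussians with no bond-length or stereochemistry
  constraints.
* The frozen-encoder design trades representational adaptivity for speed
  and determinism; on complex real data it will underfit relative to an
  end-to-end trained encoder.
* The reconstruction is exact only on its own family; on general joints the
  cross blocks are approximations.
* Single chains only; no mmCIF or trajectory formats; no side chains.
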