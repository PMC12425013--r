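# gaussdyn — multiscale Gaussian models of protein backbone dynamics

Proteins are not static: around an experimental structure, the backbone
fluctuates, and those fluctuations — which residues move, how far, in which
directions, and which residues move *together* — carry functional
information.  Molecular dynamics (MD) can measure them, but at a cost of
hours per protein.  `gaussdyn` is for structural bioinformaticians who want
cheap, explicit second-order descriptors of backbone dynamics: it models the
Cα coordinates of an `N`-residue protein as a multivariate Gaussian
`X ~ N(μ, Σ_joint)`, `X ∈ ℝ^{3N}`, and works with a hierarchy of views of
`Σ_joint`:

| level | object | meaning |
|---|---|---|
| RMSF | `rmsf[i] = sqrt(tr Σ_i)` | scalar per-residue flexibility |
| marginals | `Σ_i ∈ ℝ^{3×3}` (SPD) | anisotropic "Gaussian blob" per residue |
| coupling | `C ∈ ℝ^{N×N}`, `C_ij = mean` of the `(i,j)` 3×3 block | scalar residue–residue co-motion |
| joint | `Σ_joint ∈ ℝ^{3N×3N}` | everything, reconstructed approximately |

The package provides:

* **Label extraction** from conformational ensembles (multi-model PDB):
  Kabsch superposition, empirical joint covariance (unbiased, `T−1`),
  marginals, mean-pooled coupling, RMSF, and correlation standardization
  `C̃_ij = C_ij / sqrt(C_ii C_jj)`.
* **A learnable predictor** (`dynfit()`): sequence embedding + invariant
  point attention over residue frames gives an SE(3)-invariant
  representation; SPD-constrained readouts emit per-residue covariances via
  the softplus-Cholesky map `Σ = L Lᵀ` (and an `N×N` coupling the same way),
  trained under the log-Euclidean loss
  `L = ‖log Σ_pred − log Σ_true‖_F²`.
* **Joint reconstruction** (`reconstruct_joint()`): with `L_i = chol(Σ_i)`
  and `L_marginal = ⊕_i L_i`,
  `Σ_joint = L_marginal (C̃ ⊗ I₃) L_marginalᵀ` — symmetric positive definite
  whenever the marginals and `C̃` are (SPD closure), with diagonal blocks
  exactly equal to the marginals.
* **Fast ensemble sampling** (`sample_conformations()`, `simulate()`):
  `x = μ + L ε` with the closed-form factor
  `L = L_marginal (chol(C̃) ⊗ I₃)` — no dense `3N×3N` factorization.
* **An elastic-network baseline** (`anm()`): anisotropic network model
  Hessian and its pseudo-inverse covariance (6 rigid modes skipped).
* **Evaluation metrics**: RMSF Pearson correlation, root mean 2-Wasserstein
  distance (RMWD) over per-residue Gaussians, symmetric-KL variance terms,
  band-wise coupling correlation vs sequence separation, and ensemble-level
  comparisons (pairwise RMSD, PCA-projected 2-Wasserstein, contact Jaccard).
* **A synthetic-data generator** (`make_dataset()`) producing chains with
  *known* ground-truth joint covariances, so the whole pipeline is testable
  without any external dataset.

## Worked example

Train on a small synthetic dataset, predict dynamics for a held-out protein,
sample an ensemble, and score it against the reference ensemble:

```r
library(gaussdyn)

ds  <- make_dataset(synthetic_spec(n_train = 6, n_val = 1, n_test = 1, seed = 42))
fit <- dynfit(ds, gd_config(heads = "both", epochs = 150, seed = 7))
fit
#> <dynfit> heads: both | D = 32, 2 IPA block(s) | 6 train / 1 val proteins
#>  best validation loss 0.4818 at epoch 150 (of 150 run)

it   <- dataset_split(ds, "test")[[1]]
pred <- predict(fit, it$structure)
pred
#> <gd_prediction> N = 36, RMSF 0.73-1.90 A, with coupling
rmsf_pearson(pred$rmsf, it$labels$rmsf)
#> [1] 0.953

ens <- simulate(fit, nsim = 250, seed = 11, structure = it$structure, repair = TRUE)
ensemble_metrics(ens, it$ensemble, it$structure)
#> <gd_metric_report>
#>   pairwise RMSD (pred/ref): 1.618 / 1.663 A
#>   RMSF r: 0.949 | PCA W2 (MD/joint): 0.615 / 0.522
#>   Jaccard weak / transient contacts: 0.929 / 0.931
```

Reading the output: the model never saw the test protein, yet its predicted
per-residue flexibility profile correlates at `r = 0.95` with the profile
extracted from the reference ensemble; the sampled 250-conformation ensemble
has the same overall spread as the reference (mean pairwise Cα RMSD 1.62 vs
1.66 Å), overlaps it in the dominant-motion subspace (2-Wasserstein distance
0.6 Å after projecting both ensembles on the reference's top two principal
components), and recovers ~93% of its fluctuating contacts.

A command-line interface over the same functions ships in
`inst/cli/gaussdyn.R` with subcommands `simulate`, `extract-labels`,
`train`, `predict`, `anm`, `sample`, and `evaluate`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "gaussdyn.R", package = "gaussdyn"))')
Rscript $CLI simulate --spec spec.yaml --out data/
Rscript $CLI train    --data data/ --out run/
Rscript $CLI predict  --structure data/synth_006_structure.pdb \
                      --weights run/model.rds --out pred.json
Rscript $CLI sample   --structure data/synth_006_structure.pdb \
                      --labels pred.json --num 250 --seed 17 --out ens.pdb
```

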