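# mlaprbfn

Multi-view Laplacian-regularized RBF network regression for clinical
dry-weight prediction, in R.

## The problem

Dry weight (DW) — the target post-dialysis body weight of a patient with
end-stage renal disease — is routinely set by labor-intensive clinical
assessment (natriuretic peptides, chest CT, ultrasound, bioimpedance).
This package implements a machine-learning alternative: a radial basis
function (RBF) network that predicts DW (kg) from seven readily available
predictors (gender, age, BMI, heart rate, diastolic and systolic blood
pressure, years of dialysis), regularized so that predictions vary
smoothly over the patient-similarity graph.

## The model

Stage one is the classic self-organized RBF network: `p` centers `c_j`
are placed by k-means on the standardized predictors, all Gaussian basis
functions share the width `σ = σ_max / √(2p)` (`σ_max` the maximum
pairwise center distance), and the design matrix is
`Φ_ij = exp(−‖x_i − c_j‖² / 2σ²)`.

Stage two replaces the plain least-squares readout
`W* = (ΦᵀΦ)⁻¹ΦᵀY` with the penalized objective

    min_{W, η}  ½‖ΦW − Y‖²_F
              + (λ₁/2) Tr( (ΦW)ᵀ Σ_v η_v^ρ L_v (ΦW) )
              + (λ₂/2) ‖W‖₂,₁          s.t.  Σ_v η_v = 1, 0 < η_v < 1

where `L_v` are normalized graph Laplacians of four patient-similarity
views (Gaussian heat kernel, cosine, shifted polynomial, sigmoid), `η`
are learned view weights on the probability simplex with exponent
`ρ > 1`, and the L2,1 norm prunes whole basis functions. The alternating
solver cycles three closed-form updates — the IRLS diagonal
`G_jj = 1/(2‖W_j‖₂)`, the readout solve
`(ΦᵀΦ + λ₁ΦᵀL*Φ + λ₂G) W = ΦᵀY`, and the simplex weights
`η_v ∝ h_v^{−1/(ρ−1)}` with `h_v = Tr((ΦW)ᵀL_v(ΦW))` — and each cycle
provably never increases the objective.

Evaluation follows the usual clinical method-comparison battery:
pooled 10-fold cross-validation, RMSE / Pearson R / R², signed-error
summaries, and Bland–Altman agreement with the 95%-limits rule (fewer
than 5% of patients outside the limits — fewer than 24 of 476).

## Worked example

```r
library(mlaprbfn)

co  <- generate_multiview_fixture(n = 60, d = 3, noise_sd = 0.3, seed = 2)
ctl <- mlap_control(p = 20)          # lambda1 = lambda2 = 2^-3, rho = 2
fit <- mlaprbfn(co, ctl)
print(fit)
#> Multi-view Laplacian-regularized RBF network
#>   hidden nodes: 20  sigma: 0.6943763
#>   views (kernels): 1, 2, 3, 4
#>   eta: 0.67958, 0.06333, 0.19200, 0.06510
#>   objective: 3.317576 -> 3.176184 over 10 iterations

kfold_cv(co, k = 10, seed = 2, model = "mlaprbfn", control = ctl)
#> 10-fold CV of mlaprbfn (seed 2):
#> n = 60  RMSE = 0.4132  R = 0.2436  R^2 = -0.0811
#> signed errors: min -0.9087, median -0.0601, max 1.0816
#> mean difference -0.0513 (95% CI -0.1559 to 0.0533), sd 0.4134
#> limits of agreement -0.8616 to 0.7590
#> outside limits: 2/60 (3.33%), threshold 3 -> acceptable
```

The learned view weights concentrate on the Gaussian heat-kernel graph
(`η₁ ≈ 0.68`), the objective decreases monotonically over the 10
alternating iterations, and on the same folds the plain RBF network
(`model = "rbfn"`) gives RMSE 0.4190 — the graph smoother and row
sparsity buy a small but consistent gain in this noisy setting.

The clinical schema runs the same way from a synthetic cohort that
mirrors the published 476-patient summary statistics (the real data are
not public):

```r
cohort <- generate_cohort(cohort_spec(n = 476, seed = 1))
cv <- kfold_cv(cohort, k = 10, seed = 1, model = "mlaprbfn",
               control = mlap_control(p = 60))
cv$agreement
#> mean difference -34.2689 (95% CI -36.8588 to -31.6789), sd 28.8297
#> limits of agreement -90.7751 to 22.2373
#> outside limits: 20/476 (4.20%), threshold 24 -> acceptable
```

Note the synthetic cohort reproduces the published cohort's *structure*
(marginal moments, feature–DW correlation pattern), not its predictive
accuracy; see the methods vignette for why absolute errors on this
generator are large and not comparable to results on real clinical data.

A thin command-line front end in `exec/mlaprbfn` wraps the same
functions (`simulate`, `fit`, `predict`, `cv`, `tune` subcommands).

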