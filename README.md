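# naivedyn

Naive CD4 and CD8 T cells must be built up rapidly after birth and then
maintained for the lifetime of the animal. Whether that maintenance relies on
homeostatic feedback, on distinct recent-thymic-emigrant (RTE) biology, or on
cell-intrinsic adaptation with post-thymic age is a long-standing question in
quantitative immunology. `naivedyn` implements, in one tested R package, the
modelling toolkit needed to ask it in mice:

* **Candidate kinetic models** of the naive compartment with binary Ki67
  structure and thymic influx: homogeneous ("neutral"), density-dependent
  loss or division, an RTE/mature-naive two-compartment model, and
  cell-age-structured models in which the loss rate `delta(a)` or the
  division rate `rho(a)` varies exponentially with post-thymic age `a`,

  `delta(a) = delta0 e^(-r_delta a)`, `rho(a) = rho0 e^(r_rho a)`.

  The age-structured transport equations

  `du+/ds = 2 rho u- + rho u+ - (beta + delta) u+`,
  `du-/ds = beta u+ - (rho + delta) u-`

  are solved exactly along characteristics (cohorts), with thymic export
  `theta(t) = psi S(t)` split into Ki67+/Ki67- streams by the SP thymocyte
  Ki67 fraction `kappa(t)`.
* **Bayesian fitting** of busulfan-chimera timecourses — total naive
  numbers, normalised donor fraction `fd`, and Ki67+ fractions within host
  and donor cells — via an adaptive Metropolis sampler, with PSIS-LOO
  cross-validation and pseudo-BMA(+) model weights for ranking the
  candidates.
* **Hierarchical cohort analysis** of tamoxifen time-stamped naive CD8
  cohorts: net loss `lambda(a) = lambda0 e^(-r_lambda a)`, with `N0` and
  `lambda0` varying by mouse or by age group, and a Hill description of how
  the baseline loss rate `lambda0(t)` declines with mouse age.
* **Out-of-sample prediction engines**: RTE/MN co-transfer ratios, Rag-GFP
  reporter fractions (GFP+ probability `e^(-a/T_gfp)`), extrapolation of
  adult-fitted models back to age 1 day with an optional neonatal
  baseline-loss modifier for CD8, thymic-lobe graft simulations, and derived
  mean residence times of mature naive cells.
* **Seeded synthetic-data generators** for all four dataset schemas
  (SP thymocyte timecourses, chimera observations, labelled cohorts,
  reporter fractions), so the entire pipeline runs and is tested without any
  external data.

## Worked example

Generate a synthetic chimera cohort under the age-dependent loss model with
the published CD4 point estimates, fit three candidate models, and rank them:

```r
library(naivedyn)

influx <- default_influx("CD4")          # SP counts S(t), Ki67 kappa(t)
truth  <- reference_params("CD4")        # age_loss: 1/22 d, halving 92 d
design <- chimera_design(n_mice = 60, seed = 1)
data   <- generate_chimera_dataset(truth, influx, design, seed = 2)

cmp <- compare_model_variants(data, c("age_loss", "neutral", "age_division"),
                              influx, seed = 3, chains = 2,
                              iter_warmup = 300, iter_sampling = 400)
cmp[, c("model", "n_unknowns", "elpd_loo", "weight_pct")]
#>          model n_unknowns elpd_loo weight_pct
#> 1     age_loss          7   -17.01  1.000e+02
#> 2      neutral          6   -95.25  1.791e-21
#> 3 age_division          7   -96.25  7.489e-22
```

The generating variant takes essentially all of the pseudo-BMA weight: the
incomplete saturation of the donor fraction and the host/donor Ki67 split
carry a strong signature of cell-age-dependent loss. Posterior summaries of
the winning fit recover the generating rates:

```r
summary(attr(cmp, "fits")$age_loss)[1:3, 1:4]
#>   parameter  median    q2.5   q97.5
#> 1    delta0 0.04401 0.03983 0.04854     # truth 1/22   = 0.04545
#> 2   r_delta 0.00726 0.00648 0.00802     # truth ln2/92 = 0.00753
#> 3      rho0 0.00189 0.00166 0.00208     # truth 1/548  = 0.00182
```

Derived residence times of mature naive (MN) cells aged over 3 weeks in a
12-week-old mouse, under the published point estimates:

```r
mean_mn_residence_time(reference_params("CD4"), default_influx("CD4"),
                       t = 84, a_min = 21)
#> [1] 52.2      # days; CD4 MN cells
mean_mn_residence_time(reference_params("CD8"), default_influx("CD8"),
                       t = 84, a_min = 21)
#> [1] 78.8      # days; CD8 MN cells
```

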