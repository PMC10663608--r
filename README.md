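# vesiclebias

Quantification of ligand- and mutation-induced signaling bias in receptor
phosphorylation from single-vesicle fluorescence dose-response data.

## The problem

Receptor tyrosine kinases such as EGFR respond to ligand binding by
phosphorylating specific tyrosines (e.g. Y1068, Y1173) on their
intracellular tails, and different ligands — or oncogenic mutations like
L834R/L858R — can prefer one phosphosite over another. Measured in
plasma-membrane-derived vesicles, which keep the receptor but lose all
cytoplasmic signaling proteins, this preference is *intrinsic* bias:
a property of the ligand/receptor pair, free of cellular feedback. The
observable is a per-vesicle fluorescence ratio (phospho-antibody channel /
receptor channel) across a ligand titration.

`vesiclebias` is for analysts of such single-particle dose-response data.
It implements, as a tested pipeline:

* fixed-slope Hill fitting with constitutive-signal correction:
  `E(L) = E0 + E_top·L / (L + EC50)`;
* bias plots (response vs response at matched doses) and relative bias
  coefficients

  `β = log10[ (E_top,A·EC50,B / EC50,A·E_top,B)_test ·
  (E_top,B·EC50,A / EC50,B·E_top,A)_ref ]`

  for ligand-vs-ligand (`beta_lig`) and mutant-vs-WT (`beta_mut`)
  comparisons (positive β ⇒ response A preferred);
* transducer-function fitting in the Black–Leff operational-model
  framework, `R = f_bound·R_max / (f_bound + K_resp)`, from three-channel
  (ligand / antibody / receptor) data, with the phosphorylation efficiency
  `1/(1 + K_resp)`;
* absolute bias coefficients `β′* = log10(K_resp,B / K_resp,A)` and their
  transfer to further ligands via `β′*_test = β_rel + β′*_ref`;
* Monte-Carlo error propagation (10⁶ Gaussian draws per parameter),
  one-way ANOVA + Tukey HSD, and pairwise t-tests with Holm–Šidák
  adjustment;
* a synthetic single-vesicle generator with the statistical structure the
  analysis assumes, so everything is testable without microscopy data.

## Worked example

Simulate a three-channel rho-mEGF-style titration (~2000 vesicles per
phosphosite) with the published Y1068/Y1173 transducer parameters as
ground truth, then run the full pipeline:

```r
library(vesiclebias)

cfg <- run_config(
  seed = 1,
  mc = list(n_draws = 1e5),
  simulate = list(
    list(ligand = "rho-mEGF", py_site = "Y1068", three_channel = TRUE),
    list(ligand = "rho-mEGF", py_site = "Y1173", three_channel = TRUE,
         K_resp = 0.86, R_max = 0.39)
  )
)
bundle <- run_pipeline(cfg)

bundle$transducer[["WT|rho-mEGF"]]$Y1068$fit
#> Transducer function fit: R = f_bound * R_max / (f_bound + K_resp)
#>   K_resp = 0.38 +/- 0.02
#>   R_max  = 0.931 +/- 0.018
#>   phosphorylation efficiency = 0.725 +/- 0.01
#>   n = 2000 vesicles; converged: TRUE

bundle$bias_coefficients[["beta_star|WT|rho-mEGF"]]
#> absolute bias (beta'*): rho-mEGF vs absolute-scale [Y1068 / Y1173]
#>   value = 0.390 +/- 0.059 (log10 units)
#>   sign: Y1068 preferred
```

The fitted `K_resp = 0.38 ± 0.02` recovers the generating value 0.40
within error; the efficiency says ~72% of the full-agonist maximum is
reached at complete occupancy (a partial agonist); the positive absolute
coefficient says Y1068 phosphorylation is intrinsically preferred over
Y1173 (truth: log10(0.86/0.40) = 0.33, within 1 SE of the estimate).
And directly from the published best-fit constants:

```r
round(phospho_efficiency(c(0.40, 0.86)), 2)
#> [1] 0.71 0.54
round(beta_star_from_kresp(0.40, 0.86)$value, 2)
#> [1] 0.33
```

A command-line interface is available via `vesiclebias_cli()` (launcher in
`inst/scripts/vesiclebias`): subcommands `simulate`, `fit-dose`, `bias`,
`transducer`, `test`, `report` with flags `--config --seed --out --strict
--format`.

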