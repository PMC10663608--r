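---
title: "Quantifying phosphorylation signaling bias from single-vesicle dose-response data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phosphorylation signaling bias from single-vesicle dose-response data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The measurement and the model

A receptor tyrosine kinase (RTK) such as EGFR converts ligand binding at
the cell surface into phosphorylation of specific tyrosines on its
intracellular tail. Different ligands — or oncogenic receptor mutations —
can favour one phosphosite over another. Measured in plasma-membrane-derived
vesicles, which retain the receptor but lose all cytoplasmic signaling
proteins, this preference is *intrinsic* bias: a property of the
ligand/receptor pair, uncontaminated by feedback loops or effector
abundances.

The observable for one vesicle is a fluorescence ratio: phospho-antibody
channel over receptor channel, i.e. phosphorylation per receptor. Across a
ligand titration this follows a Hill curve with unit slope,

$$E(L) = E_0 + \frac{E_\mathrm{top}\, L}{L + \mathrm{EC}_{50}},$$

where $E_0$ is the constitutive (ligand-independent) signal from
unliganded receptor dimers. The Black–Leff operational model underlies the
whole analysis: ligand-bound receptors form the stimulus, and the response
follows the hyperbolic transducer function

$$R_\mathrm{phospho} = \frac{f_\mathrm{bound}\, R_\mathrm{max}}{f_\mathrm{bound} + K_\mathrm{resp}},
\qquad f_\mathrm{bound} = \frac{L}{L + K_L},$$

with $R_\mathrm{max}$ the maximal response a full agonist could elicit
(a property of the detection channel) and $K_\mathrm{resp}$ the bound
fraction that half-saturates the response. The *phosphorylation
efficiency* $1/(1+K_\mathrm{resp})$ is the response, relative to
$R_\mathrm{max}$, at full occupancy; efficiency $\to 1$ marks a full
agonist. The transducer coefficient $\tau$ links the two pictures:
$E_\mathrm{top} = \tau R_\mathrm{max}/(\tau+1)$,
$\mathrm{EC}_{50} = K_L/(\tau+1)$, and $K_\mathrm{resp} = 1/\tau$ on the
bound-fraction scale.

Bias coefficients compare two phosphosite responses A and B (by
convention A = Y1068, B = Y1173, both carried as metadata on every
coefficient):

* **relative**, between a ligand and a reference ligand
  ($\beta_\mathrm{lig}$) or between a mutant and the wild-type receptor
  ($\beta_\mathrm{mut}$):
  $\beta = \log_{10}\left[
  \left(\tfrac{E_\mathrm{top,A}\,\mathrm{EC}_{50,B}}{\mathrm{EC}_{50,A}\,E_\mathrm{top,B}}\right)_\mathrm{test}
  \left(\tfrac{E_\mathrm{top,B}\,\mathrm{EC}_{50,A}}{\mathrm{EC}_{50,B}\,E_\mathrm{top,A}}\right)_\mathrm{ref}
  \right]$;
* **absolute** ($\beta'^*$), free of detection gain, from the transducer
  constants of the two responses:
  $\beta'^* = \log_{10}(K_\mathrm{resp,B}/K_\mathrm{resp,A})$.

Positive values mean response A is preferred. Base-10 logarithms are used
throughout; with the published transducer constants (0.40 for Y1068, 0.86
for Y1173) this gives $\beta'^* = 0.33$, which fixes the convention
unambiguously.

## Sign of the absolute-bias transfer

With a shared ligand dissociation constant across the two antibody
channels, the operational model gives
$\beta_\mathrm{rel} = \beta'^*_\mathrm{test} - \beta'^*_\mathrm{ref}$.
The package therefore computes
$\beta'^*_\mathrm{test} = \beta_\mathrm{rel} + \beta'^*_\mathrm{ref}$
(`beta_star_transfer()`). The addition — rather than subtraction — is
forced by the internal consistency of the model: an unbiased test ligand
($\beta_\mathrm{rel} = 0$) must inherit the reference's absolute
coefficient. The rule is recorded in every result bundle
(`beta_star_rule` in the provenance and coefficient records).

## What the synthetic generator emulates

`generative_config()` / `simulate_dose_response()` /
`simulate_three_channel()` produce per-vesicle tables with the structure
the analysis assumes:

| parameter | default | meaning |
|---|---|---|
| `ligand_concentrations` | 0–1000 nM, 8 doses | titration from zero to saturation |
| `vesicles_per_concentration` | 250 | ~2000 vesicles per condition, matching the scale of a real titration |
| `K_L` | 10 nM | effective ligand-receptor dissociation constant (low-nM EGF-class affinity) |
| `K_resp`, `R_max` | 0.40, 0.95 | published Y1068 best-fit transducer parameters |
| `E0` | 0.2 | constitutive offset, visibly nonzero as in the measured zero-dose ratios |
| `receptor_log_mean/sd` | log(1000), 0.5 | log-normal receptor expression across vesicles |
| `cv_antibody` | 0.2 | per-vesicle multiplicative response noise (a placeholder; not a published value) |
| `cv_ligand` | 0.05 | ligand-channel ratio noise (see below) |

The generator reproduces: the fan-shaped scatter of per-vesicle ratios
(multiplicative noise), the nonzero zero-dose baseline, equilibrium Hill
binding without ligand depletion, a single $K_L$ shared by both
phosphosite responses, and a ligand channel proportional to
occupancy times receptor level. It does **not** emulate: images or
segmentation errors, antibody binding kinetics, day-to-day experiment
effects, receptor-density-dependent responses, or ligand depletion at
high vesicle density. A green recovery test therefore establishes
correctness of the estimators under the stated noise model, not
robustness to every artefact of real microscopy.

**Stimulus-axis noise and attenuation.** The transducer fit regresses
response on the *measured* per-vesicle bound fraction. Noise on that axis
is an errors-in-variables problem: ordinary least squares then attenuates
$K_\mathrm{resp}$ and $R_\mathrm{max}$ (at `cv_ligand = 0.2` the fitted
$K_\mathrm{resp}$ under-shoots the generating 0.40 by roughly 20%, several
reported SEs at $n = 2000$). The published procedure — and this package —
uses plain least squares, so the parameter-recovery guarantees are
meaningful only when the ligand channel is well measured; the default
`cv_ligand = 0.05` encodes that regime, and the residual attenuation
(≈1%) is second-order. This is a known limitation, not a corrected one:
no deattenuation is attempted.

## Numerical choices

* **Fitting.** Both the Hill and the transducer model are linear in their
  amplitude parameter given the half-saturation parameter. The amplitude
  (and, with `e0_mode = "free"`, the offset) is profiled out by QR least
  squares and the half-saturation parameter is minimised on the log scale
  (coarse 80-point bracket, then `optimize()` to tolerance `1e-12`). This
  recovers zero-noise data to machine precision, where Gauss–Newton
  (`nls`) fails on the zero-residual surface, and cannot step to negative
  parameter values.
* **Standard errors** are Jacobian-based least-squares covariances,
  $\hat\sigma^2 (J^\top J)^{-1}$. A fit whose half-saturation parameter
  lands on the search boundary is flagged `converged = FALSE`; an exactly
  flat response returns `E_top = 0` with `ec50_identifiable = FALSE`
  rather than an arbitrary EC50.
* **Constitutive correction** defaults to subtracting the mean zero-dose
  ratio (`e0_mode = "subtract"`); the offset may instead be co-fit
  (`"free"`). The exact published correction procedure is not recoverable
  from the main text, so both are exposed and neither is asserted as
  "the" procedure. Zero-dose points stay in the fit with model value 0.
* **Initialisation / tie-breaks.** The profiled search needs no starting
  values; the coarse bracket spans two decades beyond the observed dose
  (or bound-fraction) range, and ties in the bracket resolve to the
  lowest value by `which.min`.
* **Bound-fraction scaling** divides by the maximum over
  ligand-concentration groups of the group-mean ligand/receptor ratio
  (vesicle-level maxima would be noise-dominated). Scaled values above 1
  are retained, as are negative corrected responses — the noise is
  symmetric about the model and clipping would bias the fit.
* **Monte-Carlo propagation** uses $10^6$ Gaussian draws per parameter by
  default, seeded and reproducible. Draws outside a function's domain
  (e.g. a negative EC50 draw) are rejected and counted; more than 1%
  rejections aborts with a diagnostic rather than silently truncating the
  distribution.
* **Hypothesis tests.** One-way ANOVA + Tukey HSD and pairwise two-tailed
  t-tests with the Holm–Šidák step-down adjustment
  ($p_{(i)} \mapsto 1-(1-p_{(i)})^{m-i+1}$, monotonised, capped at 1).
  What constituted a "replicate" for the published figure-level tests is
  not stated; `coefficient_groups_from_mc()` bridges the gap by drawing
  labelled Gaussian pseudo-replicates from each coefficient's (value, SE)
  — a reconstruction, clearly flagged as such.

## Known limitations

* The published experimental coefficient values and p-values (shown only
  in figures, from raw data not shipped here) are not reproduced; the
  algebraic property suite (antisymmetry, reference chaining,
  detection-gain and unit invariance, Hill-route ≡ τ-route identity)
  covers the coefficient machinery instead.
* The reported $\beta'^*= 0.33 \pm 0.5$ uncertainty is inconsistent with
  propagating the printed $K_\mathrm{resp}$ SEs (which gives ≈0.05); the
  package follows the stated Monte-Carlo procedure and reports what it
  computes.
* Binned transducer means equal the model at the bin's mean bound
  fraction only for noiseless data concentrated within bins; for spread
  data the hyperbola's curvature contributes an $O(\mathrm{width}^2)$
  discrepancy. Binning is for display; fits always use the single-vesicle
  points.

## A worked run

```{r, eval = FALSE}
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
bundle$bias_coefficients[["beta_star|WT|rho-mEGF"]]
```

The README shows this run with its actual printed output.
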