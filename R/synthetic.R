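#' Generative configuration for synthetic single-vesicle data
#'
#' Bundles the "true" parameters of the generative model used by
#' [simulate_dose_response()] and [simulate_three_channel()]. The model is
#' Hill ligand binding, `f_bound = L / (L + K_L)`, composed with the
#' hyperbolic transducer `R = f_bound * R_max / (f_bound + K_resp)` plus an
#' additive constitutive offset `E0`, observed through per-vesicle
#' multiplicative Gaussian noise.
#'
#' Defaults describe a saturating rho-mEGF-style titration of roughly 2000
#' vesicles with the published Y1068 transducer parameters
#' (`K_resp = 0.40`, `R_max = 0.95`) and a per-vesicle response noise CV
#' of 0.2. The ligand-channel CV defaults to 0.05 (a well-measured
#' stimulus axis): because the transducer fit regresses response on the
#' *measured* per-vesicle bound fraction, noise on that axis attenuates
#' the fitted `K_resp` and `R_max` (errors-in-variables), and the
#' parameter-recovery guarantees hold only when the stimulus-axis noise is
#' second-order.
#'
#' @param ligand_concentrations numeric vector of ligand doses in nM,
#'   all `>= 0`. Include 0 so the constitutive signal can be estimated.
#' @param vesicles_per_concentration number of vesicles simulated at each
#'   dose (`>= 1`).
#' @param K_L effective ligand-receptor dissociation constant, nM (`> 0`).
#' @param K_resp dimensionless transducer constant: the bound fraction
#'   giving half of `R_max` (`> 0`).
#' @param R_max maximal response, in antibody/receptor ratio units (`>= 0`).
#' @param E0 constitutive (ligand-independent) response offset, ratio
#'   units (`>= 0`).
#' @param receptor_log_mean,receptor_log_sd mean and sd of log receptor
#'   fluorescence; per-vesicle receptor intensity is log-normal.
#' @param cv_antibody coefficient of variation of the multiplicative noise
#'   on the per-vesicle response ratio (`>= 0`).
#' @param cv_ligand CV of the noise on the ligand-channel ratio (`>= 0`).
#' @param ligand_gain ligand-channel fluorescence per unit bound fraction
#'   per unit receptor fluorescence (dimensionless, `> 0`).
#' @param seed integer RNG seed; identical config and seed give a
#'   byte-identical table.
#'
#' @return An object of class `generative_config` (a validated list).
#' @seealso [simulate_dose_response()], [simulate_three_channel()]
#' @export
generative_config <- function(ligand_concentrations = c(0, 0.3, 1, 3, 10, 30, 100, 1000),
                              vesicles_per_concentration = 250,
                              K_L = 10,
                              K_resp = 0.40,
                              R_max = 0.95,
                              E0 = 0.2,
                              receptor_log_mean = log(1000),
                              receptor_log_sd = 0.5,
                              cv_antibody = 0.2,
                              cv_ligand = 0.05,
                              ligand_gain = 1,
                              seed = 1L) {
  cfg <- list(
    ligand_concentrations = as.numeric(ligand_concentrations),
    vesicles_per_concentration = as.integer(vesicles_per_concentration),
    K_L = as.numeric(K_L),
    K_resp = as.numeric(K_resp),
    R_max = as.numeric(R_max),
    E0 = as.numeric(E0),
    receptor_log_mean = as.numeric(receptor_log_mean),
    receptor_log_sd = as.numeric(receptor_log_sd),
    cv_antibody = as.numeric(cv_antibody),
    cv_ligand = as.numeric(cv_ligand),
    ligand_gain = as.numeric(ligand_gain),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "generative_config"
  validate_generative_config(cfg)
  cfg
}

validate_generative_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid generative_config field '%s': %s", field, why),
         call. = FALSE)
  }
  if (length(cfg$ligand_concentrations) < 1 ||
      any(!is.finite(cfg$ligand_concentrations)) ||
      any(cfg$ligand_concentrations < 0)) {
    fail("ligand_concentrations", "must be finite and >= 0")
  }
  if (is.na(cfg$vesicles_per_concentration) || cfg$vesicles_per_concentration < 1L) {
    fail("vesicles_per_concentration", "must be >= 1")
  }
  if (!is.finite(cfg$K_L) || cfg$K_L <= 0) fail("K_L", "must be > 0")
  if (!is.finite(cfg$K_resp) || cfg$K_resp <= 0) fail("K_resp", "must be > 0")
  if (!is.finite(cfg$R_max) || cfg$R_max < 0) fail("R_max", "must be >= 0")
  if (!is.finite(cfg$E0) || cfg$E0 < 0) fail("E0", "must be >= 0")
  if (!is.finite(cfg$receptor_log_sd) || cfg$receptor_log_sd < 0) {
    fail("receptor_log_sd", "must be >= 0")
  }
  if (!is.finite(cfg$cv_antibody) || cfg$cv_antibody < 0) fail("cv_antibody", "must be >= 0")
  if (!is.finite(cfg$cv_ligand) || cfg$cv_ligand < 0) fail("cv_ligand", "must be >= 0")
  if (!is.finite(cfg$ligand_gain) || cfg$ligand_gain <= 0) fail("ligand_gain", "must be > 0")
  invisible(cfg)
}

#' @export
print.generative_config <- function(x, ...) {
  cat("Generative config for synthetic single-vesicle data\n")
  cat(sprintf("  doses (nM):   %s\n", paste(signif(x$ligand_concentrations, 4), collapse = ", ")))
  cat(sprintf("  n/dose:       %d\n", x$vesicles_per_concentration))
  cat(sprintf("  K_L = %g nM, K_resp = %g, R_max = %g, E0 = %g\n",
              x$K_L, x$K_resp, x$R_max, x$E0))
  cat(sprintf("  noise CVs: antibody %g, ligand %g; seed %s\n",
              x$cv_antibody, x$cv_ligand,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Noise-free response ratio of the generative model
#'
#' Evaluates `E0 + f_bound * R_max / (f_bound + K_resp)` with
#' `f_bound = L / (L + K_L)` at the doses `L`.
#'
#' @param config a [generative_config()].
#' @param L numeric vector of ligand doses (nM).
#' @return numeric vector of true response ratios.
#' @export
true_ratio <- function(config, L) {
  stopifnot(inherits(config, "generative_config"))
  f <- ifelse(L == 0, 0, L / (L + config$K_L))
  config$E0 + transducer_response(f, config$K_resp, config$R_max)
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a two-channel single-vesicle dose-response table
#'
#' For each dose `L` and vesicle: the bound fraction is
#' `f_bound = L / (L + K_L)`; the noise-free response ratio is
#' `r = E0 + f_bound * R_max / (f_bound + K_resp)`; receptor fluorescence is
#' drawn log-normal; the antibody channel is
#' `receptor_fluor * r * (1 + eps)` with `eps ~ N(0, cv_antibody)`,
#' truncated so the antibody fluorescence is never negative.
#'
#' @param config a [generative_config()].
#' @param receptor_variant condition label, `"WT"` or `"L834R"`.
#' @param ligand ligand name label.
#' @param py_site phosphosite label (`"Y1068"`, `"Y1173"` or `"panY"`).
#' @param experiment_id experiment label stored on every record.
#' @return A `data.frame` of vesicle records with columns `vesicle_id`,
#'   `experiment_id`, `receptor_variant`, `ligand`, `ligand_conc_nM`,
#'   `py_site`, `receptor_fluor`, `antibody_fluor` (and `ligand_fluor`, all
#'   `NA`, for format compatibility). The seed used is recorded in the
#'   `"seed"` attribute.
#' @export
simulate_dose_response <- function(config,
                                   receptor_variant = "WT",
                                   ligand = "EGF",
                                   py_site = "Y1068",
                                   experiment_id = "sim") {
  validate_generative_config(config)
  tab <- with_seed(config$seed, simulate_vesicles_impl(config, three_channel = FALSE))
  finish_vesicle_table(tab, config, receptor_variant, ligand, py_site, experiment_id)
}

#' Simulate a three-channel single-vesicle table (ligand channel included)
#'
#' As [simulate_dose_response()], plus a ligand channel
#' `ligand_fluor = ligand_gain * receptor_fluor * f_bound * (1 + eps')`
#' with `eps' ~ N(0, cv_ligand)`, truncated at zero. This is the input for
#' transducer-function analysis, where the per-vesicle bound fraction is
#' read off the ligand/receptor ratio.
#'
#' @inheritParams simulate_dose_response
#' @return A vesicle-record `data.frame` with a populated `ligand_fluor`
#'   column.
#' @export
simulate_three_channel <- function(config,
                                   receptor_variant = "WT",
                                   ligand = "rho-mEGF",
                                   py_site = "Y1068",
                                   experiment_id = "sim") {
  validate_generative_config(config)
  tab <- with_seed(config$seed, simulate_vesicles_impl(config, three_channel = TRUE))
  finish_vesicle_table(tab, config, receptor_variant, ligand, py_site, experiment_id)
}

simulate_vesicles_impl <- function(config, three_channel) {
  n_per <- config$vesicles_per_concentration
  L <- rep(config$ligand_concentrations, each = n_per)
  n <- length(L)
  f_bound <- ifelse(L == 0, 0, L / (L + config$K_L))
  r_true <- config$E0 + transducer_response(f_bound, config$K_resp, config$R_max)

  receptor <- exp(rnorm(n, config$receptor_log_mean, config$receptor_log_sd))
  eps_ab <- rnorm(n, 0, config$cv_antibody)
  antibody <- pmax(receptor * r_true * (1 + eps_ab), 0)

  out <- data.frame(
    ligand_conc_nM = L,
    receptor_fluor = receptor,
    antibody_fluor = antibody,
    ligand_fluor = NA_real_
  )
  if (three_channel) {
    eps_lig <- rnorm(n, 0, config$cv_ligand)
    out$ligand_fluor <- pmax(config$ligand_gain * receptor * f_bound * (1 + eps_lig), 0)
  }
  out
}

finish_vesicle_table <- function(tab, config, receptor_variant, ligand,
                                 py_site, experiment_id) {
  receptor_variant <- match.arg(receptor_variant, c("WT", "L834R"))
  py_site <- match.arg(py_site, c("Y1068", "Y1173", "panY"))
  n <- nrow(tab)
  out <- data.frame(
    vesicle_id = sprintf("v%06d", seq_len(n)),
    experiment_id = rep(experiment_id, n),
    receptor_variant = rep(receptor_variant, n),
    ligand = rep(ligand, n),
    ligand_conc_nM = tab$ligand_conc_nM,
    py_site = rep(py_site, n),
    receptor_fluor = tab$receptor_fluor,
    antibody_fluor = tab$antibody_fluor,
    ligand_fluor = tab$ligand_fluor,
    stringsAsFactors = FALSE
  )
  attr(out, "seed") <- config$seed
  out
}
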