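#' Construct a bias coefficient record
#'
#' Internal constructor carrying the comparison metadata alongside the
#' log10 value and its Monte-Carlo SE.
#'
#' @param value log10 bias value.
#' @param se standard error (log10 units, `>= 0`).
#' @param kind one of `"ligand"`, `"mutation"`, `"absolute"`.
#' @param response_A,response_B phosphosite labels (must differ).
#' @param test_entity ligand or variant being tested.
#' @param reference_entity reference ligand/variant, or
#'   `"absolute-scale"`.
#' @param mc list of MC settings used for the SE (may be `NULL`).
#' @return object of class `bias_coefficient`.
#' @export
bias_coefficient <- function(value, se, kind, response_A, response_B,
                             test_entity, reference_entity, mc = NULL) {
  kind <- match.arg(kind, c("ligand", "mutation", "absolute"))
  value <- as.numeric(value)
  se <- as.numeric(se)
  if (!is.finite(se) || se < 0) stop("se must be finite and >= 0", call. = FALSE)
  if (identical(response_A, response_B)) {
    stop("response_A and response_B must differ", call. = FALSE)
  }
  structure(list(value = value, se = se, kind = kind,
                 response_A = response_A, response_B = response_B,
                 test_entity = test_entity,
                 reference_entity = reference_entity,
                 mc = mc),
            class = "bias_coefficient")
}

#' @export
print.bias_coefficient <- function(x, ...) {
  lab <- switch(x$kind,
                ligand = "ligand bias (beta_lig)",
                mutation = "mutation-induced bias (beta_mut)",
                absolute = "absolute bias (beta'*)")
  cat(sprintf("%s: %s vs %s [%s / %s]\n", lab, x$test_entity,
              x$reference_entity, x$response_A, x$response_B))
  cat(sprintf("  value = %.3f +/- %.3f (log10 units)\n", x$value, x$se))
  if (x$value > 0) cat(sprintf("  sign: %s preferred\n", x$response_A))
  if (x$value < 0) cat(sprintf("  sign: %s preferred\n", x$response_B))
  invisible(x)
}

check_hill_fit_usable <- function(fit, what) {
  if (!inherits(fit, "hill_fit")) stop(sprintf("%s must be a hill_fit", what), call. = FALSE)
  if (!isTRUE(fit$converged)) stop(sprintf("%s did not converge", what), call. = FALSE)
  if (!isTRUE(fit$ec50_identifiable) || !is.finite(fit$EC50) ||
      fit$EC50 <= 0 || fit$E_top <= 0) {
    stop(sprintf("%s has nonpositive or unidentifiable E_top/EC50; bias undefined",
                 what), call. = FALSE)
  }
  invisible(fit)
}

# log10 of (E_top,A EC50,B / EC50,A E_top,B)_test * (E_top,B EC50,A / EC50,B E_top,A)_ref,
# the shared core of the relative bias coefficients.
log_bias_ratio <- function(EtA_t, ECA_t, EtB_t, ECB_t,
                           EtA_r, ECA_r, EtB_r, ECB_r) {
  ok <- EtA_t > 0 & ECA_t > 0 & EtB_t > 0 & ECB_t > 0 &
        EtA_r > 0 & ECA_r > 0 & EtB_r > 0 & ECB_r > 0
  out <- rep(NA_real_, length(ok))
  out[ok] <- (log10(EtA_t[ok]) - log10(ECA_t[ok]) - log10(EtB_t[ok]) + log10(ECB_t[ok])) -
             (log10(EtA_r[ok]) - log10(ECA_r[ok]) - log10(EtB_r[ok]) + log10(ECB_r[ok]))
  out
}

relative_bias <- function(fit_A_test, fit_B_test, fit_A_ref, fit_B_ref,
                          kind, response_A, response_B,
                          test_entity, reference_entity, settings) {
  check_hill_fit_usable(fit_A_test, "fit_A_test")
  check_hill_fit_usable(fit_B_test, "fit_B_test")
  check_hill_fit_usable(fit_A_ref, "fit_A_ref")
  check_hill_fit_usable(fit_B_ref, "fit_B_ref")

  means <- c(fit_A_test$E_top, fit_A_test$EC50, fit_B_test$E_top, fit_B_test$EC50,
             fit_A_ref$E_top, fit_A_ref$EC50, fit_B_ref$E_top, fit_B_ref$EC50)
  ses <- c(fit_A_test$E_top_se, fit_A_test$EC50_se, fit_B_test$E_top_se, fit_B_test$EC50_se,
           fit_A_ref$E_top_se, fit_A_ref$EC50_se, fit_B_ref$E_top_se, fit_B_ref$EC50_se)

  value <- log_bias_ratio(means[1], means[2], means[3], means[4],
                          means[5], means[6], means[7], means[8])
  se <- monte_carlo_se(
    function(a1, a2, a3, a4, a5, a6, a7, a8) {
      log_bias_ratio(a1, a2, a3, a4, a5, a6, a7, a8)
    },
    means = means, ses = ses, settings = settings
  )
  bias_coefficient(value, se, kind, response_A, response_B,
                   test_entity, reference_entity,
                   mc = list(n_draws = settings$n_draws, seed = settings$seed))
}

#' Ligand bias coefficient
#'
#' Relative bias of a test ligand against a reference ligand across two
#' phosphosite responses:
#' `beta_lig = log10( (E_top,A EC50,B / EC50,A E_top,B)_lig *
#' (E_top,B EC50,A / EC50,B E_top,A)_ref )`. Positive values mean the test
#' ligand prefers response A relative to the reference; detection gain on
#' each response cancels between the two factors.
#'
#' @param fit_A_lig,fit_B_lig [fit_hill()] results for the test ligand on
#'   responses A and B.
#' @param fit_A_ref,fit_B_ref Hill fits for the reference ligand.
#' @param ligand,reference names of the compared ligands.
#' @param response_A,response_B phosphosite labels; by convention A is
#'   Y1068 and B is Y1173.
#' @param settings [mc_settings()] used for the Monte-Carlo SE.
#' @return a [bias_coefficient()] of kind `"ligand"`.
#' @export
beta_lig <- function(fit_A_lig, fit_B_lig, fit_A_ref, fit_B_ref,
                     ligand = "ligand", reference = "reference",
                     response_A = "Y1068", response_B = "Y1173",
                     settings = mc_settings()) {
  relative_bias(fit_A_lig, fit_B_lig, fit_A_ref, fit_B_ref,
                kind = "ligand", response_A = response_A,
                response_B = response_B, test_entity = ligand,
                reference_entity = reference, settings = settings)
}

#' Mutation-induced bias coefficient
#'
#' As [beta_lig()], but comparing a receptor mutant to the wild-type under
#' the same ligand: the mutant takes the role of the test condition and WT
#' the reference.
#'
#' @param fit_A_mut,fit_B_mut Hill fits for the mutant on responses A, B.
#' @param fit_A_wt,fit_B_wt Hill fits for the wild-type receptor.
#' @param mutant,reference variant names.
#' @inheritParams beta_lig
#' @return a [bias_coefficient()] of kind `"mutation"`.
#' @export
beta_mut <- function(fit_A_mut, fit_B_mut, fit_A_wt, fit_B_wt,
                     mutant = "L834R", reference = "WT",
                     response_A = "Y1068", response_B = "Y1173",
                     settings = mc_settings()) {
  relative_bias(fit_A_mut, fit_B_mut, fit_A_wt, fit_B_wt,
                kind = "mutation", response_A = response_A,
                response_B = response_B, test_entity = mutant,
                reference_entity = reference, settings = settings)
}

#' Absolute bias coefficient from transducer constants
#'
#' `beta'* = log10(K_resp,B / K_resp,A)`: a detection-gain-free measure of
#' the preference between the two responses for one ligand. Positive means
#' response A is preferred (its transducer constant is smaller, i.e. its
#' phosphorylation is more efficient).
#'
#' @param K_resp_A,K_resp_B transducer constants for responses A and B
#'   (`> 0`).
#' @param se_A,se_B their standard errors (for the Monte-Carlo SE).
#' @param ligand ligand whose preference is being measured.
#' @param response_A,response_B phosphosite labels.
#' @param settings [mc_settings()].
#' @return a [bias_coefficient()] of kind `"absolute"` with
#'   `reference_entity = "absolute-scale"`.
#' @export
beta_star_from_kresp <- function(K_resp_A, K_resp_B, se_A = 0, se_B = 0,
                                 ligand = "ligand",
                                 response_A = "Y1068", response_B = "Y1173",
                                 settings = mc_settings()) {
  if (K_resp_A <= 0 || K_resp_B <= 0) {
    stop("K_resp values must be > 0", call. = FALSE)
  }
  value <- log10(K_resp_B / K_resp_A)
  se <- if (se_A == 0 && se_B == 0) 0 else {
    monte_carlo_se(function(a, b) ifelse(a > 0 & b > 0, log10(b / a), NA_real_),
                   means = c(K_resp_A, K_resp_B), ses = c(se_A, se_B),
                   settings = settings)
  }
  bias_coefficient(value, se, "absolute", response_A, response_B,
                   test_entity = ligand, reference_entity = "absolute-scale",
                   mc = list(n_draws = settings$n_draws, seed = settings$seed))
}

#' Transfer a relative bias onto the absolute scale
#'
#' Given the relative bias of a test condition against a reference, and
#' the reference's absolute coefficient, the test condition's absolute
#' coefficient is `beta'*_test = beta_rel + beta'*_ref`. (The operational
#' model gives `beta_rel = beta'*_test - beta'*_ref`; in particular an
#' unbiased ligand, `beta_rel = 0`, inherits the reference's absolute
#' coefficient.) The SE is propagated by Monte Carlo treating the two
#' inputs as independent.
#'
#' @param beta_rel a relative [bias_coefficient()] (`kind` `"ligand"` or
#'   `"mutation"`) computed against the reference below.
#' @param beta_star_ref the reference's absolute coefficient (kind
#'   `"absolute"`).
#' @param settings [mc_settings()].
#' @return a [bias_coefficient()] of kind `"absolute"` for the test
#'   entity.
#' @export
beta_star_transfer <- function(beta_rel, beta_star_ref,
                               settings = mc_settings()) {
  stopifnot(inherits(beta_rel, "bias_coefficient"),
            inherits(beta_star_ref, "bias_coefficient"))
  if (beta_star_ref$kind != "absolute") {
    stop("beta_star_ref must be an absolute coefficient", call. = FALSE)
  }
  if (beta_rel$kind == "absolute") {
    stop("beta_rel must be a relative (ligand or mutation) coefficient",
         call. = FALSE)
  }
  if (!identical(beta_rel$reference_entity, beta_star_ref$test_entity)) {
    stop(sprintf(
      "reference mismatch: beta_rel is relative to '%s' but beta_star_ref is for '%s'",
      beta_rel$reference_entity, beta_star_ref$test_entity), call. = FALSE)
  }
  if (!identical(beta_rel$response_A, beta_star_ref$response_A) ||
      !identical(beta_rel$response_B, beta_star_ref$response_B)) {
    stop("response labels differ between the two coefficients", call. = FALSE)
  }
  value <- beta_rel$value + beta_star_ref$value
  se <- monte_carlo_se(function(x, y) x + y,
                       means = c(beta_rel$value, beta_star_ref$value),
                       ses = c(beta_rel$se, beta_star_ref$se),
                       settings = settings)
  bias_coefficient(value, se, "absolute",
                   beta_rel$response_A, beta_rel$response_B,
                   test_entity = beta_rel$test_entity,
                   reference_entity = "absolute-scale",
                   mc = list(n_draws = settings$n_draws, seed = settings$seed,
                             transferred_from = beta_star_ref$test_entity))
}

#' Ligand bias from transducer coefficients
#'
#' The operational-model form of the relative bias:
#' `beta = log10( (tau_A / tau_B)_test * (tau_B / tau_A)_ref )`. With a
#' shared ligand dissociation constant this is algebraically identical to
#' the Hill-parameter form of [beta_lig()].
#'
#' @param tau_A_test,tau_B_test transducer coefficients of the test
#'   condition on responses A and B (`> 0`).
#' @param tau_A_ref,tau_B_ref transducer coefficients of the reference.
#' @return log10 bias value (numeric).
#' @export
beta_from_tau <- function(tau_A_test, tau_B_test, tau_A_ref, tau_B_ref) {
  if (any(c(tau_A_test, tau_B_test, tau_A_ref, tau_B_ref) <= 0)) {
    stop("all tau must be > 0", call. = FALSE)
  }
  log10(tau_A_test / tau_B_test) + log10(tau_B_ref / tau_A_ref)
}

#' Bias plot: one response against the other at matched doses
#'
#' Pairs the per-concentration summaries of two responses at their shared
#' ligand concentrations. Divergence of such curves between ligands
#' reveals bias directly from the measured data, with no model fitting.
#'
#' @param points_A,points_B per-concentration summaries from
#'   [aggregate_dose_response()] for responses A and B.
#' @return `data.frame` sorted by concentration with columns
#'   `ligand_conc_nM`, `mean_A`, `sem_A`, `n_A`, `mean_B`, `sem_B`, `n_B`.
#' @export
bias_plot <- function(points_A, points_B) {
  shared <- intersect(points_A$ligand_conc_nM, points_B$ligand_conc_nM)
  if (length(shared) < 2) {
    stop(sprintf(
      "need >= 2 shared concentrations; available A: {%s}, B: {%s}",
      paste(points_A$ligand_conc_nM, collapse = ", "),
      paste(points_B$ligand_conc_nM, collapse = ", ")), call. = FALSE)
  }
  shared <- sort(shared)
  ia <- match(shared, points_A$ligand_conc_nM)
  ib <- match(shared, points_B$ligand_conc_nM)
  data.frame(ligand_conc_nM = shared,
             mean_A = points_A$mean_ratio[ia],
             sem_A = points_A$sem_ratio[ia],
             n_A = points_A$n_vesicles[ia],
             mean_B = points_B$mean_ratio[ib],
             sem_B = points_B$sem_ratio[ib],
             n_B = points_B$n_vesicles[ib])
}
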