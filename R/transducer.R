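#' Hyperbolic transducer function
#'
#' The operational-model transducer maps the stimulus (fraction of
#' ligand-bound receptors) to the phosphorylation response:
#' `R = f_bound * R_max / (f_bound + K_resp)`.
#'
#' @param f_bound bound fraction (vectorised, `>= 0`).
#' @param K_resp transducer constant (`> 0`): the bound fraction at which
#'   the response is half of `R_max`.
#' @param R_max maximal response.
#' @return numeric responses.
#' @export
transducer_response <- function(f_bound, K_resp, R_max) {
  f_bound * R_max / (f_bound + K_resp)
}

#' Per-vesicle bound fraction from the ligand channel
#'
#' The raw per-vesicle stimulus is the ligand/receptor fluorescence ratio.
#' Because the ligand channel has arbitrary gain, the axis is scaled so
#' that the maximum over ligand-concentration groups of the group-mean
#' ratio equals 1 — i.e. the saturating dose defines full occupancy.
#' Individual vesicles may exceed 1 after scaling; they are not clipped.
#'
#' @param records vesicle records with a populated `ligand_fluor` column
#'   and at least 2 distinct concentrations.
#' @return numeric per-vesicle bound fractions, in input order, with the
#'   scale factor in attribute `"scale"`.
#' @export
scale_bound_fraction <- function(records) {
  if (any(is.na(records$ligand_fluor))) {
    stop("ligand_fluor is missing: three-channel data required", call. = FALSE)
  }
  if (any(records$receptor_fluor <= 0)) {
    stop("receptor_fluor must be > 0", call. = FALSE)
  }
  if (length(unique(records$ligand_conc_nM)) < 2) {
    stop("need >= 2 ligand concentrations to scale the bound fraction",
         call. = FALSE)
  }
  raw <- records$ligand_fluor / records$receptor_fluor
  group_means <- tapply(raw, records$ligand_conc_nM, mean)
  s <- max(group_means)
  if (s <= 0) {
    stop("no binding signal in any concentration group (all group means <= 0)",
         call. = FALSE)
  }
  f <- raw / s
  attr(f, "scale") <- s
  f
}

#' Fit the transducer function to single-vesicle data
#'
#' Unweighted least squares of
#' `R = f_bound * R_max / (f_bound + K_resp)` over all single-vesicle
#' points, responses having been corrected for the constitutive signal.
#' `R_max` is profiled out (the model is linear in it given `K_resp`) and
#' `K_resp` optimised on the log scale; SEs come from the Jacobian-based
#' covariance. The phosphorylation efficiency `1 / (1 + K_resp)` is
#' attached with a delta-method SE.
#'
#' @param f_bound per-vesicle bound fractions (see
#'   [scale_bound_fraction()]).
#' @param response constitutive-corrected response ratios.
#' @return An object of class `transducer_fit` with `K_resp`, `R_max`,
#'   `efficiency`, their SEs, the parameter covariance, `n_vesicles` and a
#'   `converged` flag.
#' @export
fit_transducer <- function(f_bound, response) {
  keep <- is.finite(f_bound) & is.finite(response)
  f <- as.numeric(f_bound)[keep]
  y <- as.numeric(response)[keep]
  if (length(unique(round(f, 12))) < 2) {
    stop("degenerate input: need >= 2 distinct bound-fraction levels",
         call. = FALSE)
  }
  fit <- fit_hyperbola(f, y, free_intercept = FALSE)
  eff <- 1 / (1 + fit$half)
  eff_se <- fit$half_se / (1 + fit$half)^2
  out <- list(
    K_resp = fit$half, K_resp_se = fit$half_se,
    R_max = fit$top, R_max_se = fit$top_se,
    efficiency = eff, efficiency_se = eff_se,
    cov = fit$cov,
    n_vesicles = length(y),
    sigma = fit$sigma,
    converged = fit$converged,
    identifiable = fit$identifiable
  )
  class(out) <- "transducer_fit"
  out
}

#' @export
print.transducer_fit <- function(x, ...) {
  cat("Transducer function fit: R = f_bound * R_max / (f_bound + K_resp)\n")
  cat(sprintf("  K_resp = %.3g +/- %.2g\n", x$K_resp, x$K_resp_se))
  cat(sprintf("  R_max  = %.3g +/- %.2g\n", x$R_max, x$R_max_se))
  cat(sprintf("  phosphorylation efficiency = %.3g +/- %.2g\n",
              x$efficiency, x$efficiency_se))
  cat(sprintf("  n = %d vesicles; converged: %s\n", x$n_vesicles, x$converged))
  invisible(x)
}

#' Phosphorylation efficiency
#'
#' The maximal response per receptor at full occupancy, relative to the
#' system maximum: `efficiency = 1 / (1 + K_resp)`. An efficiency of 1
#' (`K_resp -> 0`) marks a full agonist. When a standard error for
#' `K_resp` is supplied, the efficiency SE is propagated by Monte Carlo.
#'
#' @param K_resp transducer constant (`>= 0`).
#' @param se optional SE of `K_resp`.
#' @param settings [mc_settings()] for the propagation.
#' @return efficiency value, or a list `(value, se)` when `se` is given.
#' @export
phospho_efficiency <- function(K_resp, se = NULL, settings = mc_settings()) {
  if (any(K_resp < 0)) stop("K_resp must be >= 0", call. = FALSE)
  val <- 1 / (1 + K_resp)
  if (is.null(se)) return(val)
  mc_se <- monte_carlo_se(function(k) ifelse(k < 0, NA_real_, 1 / (1 + k)),
                          means = K_resp, ses = se, settings = settings)
  list(value = val, se = as.numeric(mc_se))
}

#' Bin the transducer curve for display
#'
#' Half-open bins `[k * width, (k + 1) * width)` on the bound-fraction
#' axis; bins holding fewer than `min_n` vesicles are dropped, so only
#' well-populated parts of the curve are shown.
#'
#' @param f_bound per-vesicle bound fractions.
#' @param response per-vesicle (corrected) responses.
#' @param width bin width on the bound-fraction axis (default 0.1).
#' @param min_n minimum vesicles per retained bin (default 50).
#' @return `data.frame` with `bin_center`, `mean_f_bound`,
#'   `mean_response`, `sem_response`, `n`.
#' @export
bin_transducer <- function(f_bound, response, width = 0.1, min_n = 50) {
  if (width <= 0) stop("bin width must be > 0", call. = FALSE)
  keep <- is.finite(f_bound) & is.finite(response)
  f <- f_bound[keep]; y <- response[keep]
  if (!length(f)) stop("no data to bin", call. = FALSE)
  k <- floor(f / width)
  out <- do.call(rbind, lapply(sort(unique(k)), function(kk) {
    i <- k == kk
    n <- sum(i)
    data.frame(bin_center = (kk + 0.5) * width,
               mean_f_bound = mean(f[i]),
               mean_response = mean(y[i]),
               sem_response = if (n > 1) stats::sd(y[i]) / sqrt(n) else 0,
               n = n)
  }))
  out <- out[out$n >= min_n, , drop = FALSE]
  rownames(out) <- NULL
  out
}
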