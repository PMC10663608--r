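#' Per-vesicle response ratios
#'
#' The phosphorylation response of one vesicle is the ratio of the
#' phospho-antibody channel to the receptor channel, so the value is a
#' degree of phosphorylation per receptor and is independent of vesicle
#' size and receptor expression.
#'
#' @param records a vesicle-record `data.frame` (see [read_vesicle_table()]
#'   or [simulate_dose_response()]).
#' @return numeric vector of `antibody_fluor / receptor_fluor`, in input
#'   order.
#' @export
compute_ratios <- function(records) {
  stopifnot(is.data.frame(records))
  bad <- which(!is.finite(records$receptor_fluor) | records$receptor_fluor <= 0)
  if (length(bad)) {
    ids <- records$vesicle_id[bad]
    stop(sprintf("nonpositive receptor_fluor for vesicle(s): %s",
                 paste(utils::head(ids, 5), collapse = ", ")), call. = FALSE)
  }
  records$antibody_fluor / records$receptor_fluor
}

#' Estimate the constitutive (ligand-independent) response
#'
#' Receptors in unliganded dimers are phosphorylated even at zero ligand,
#' so the zero-dose ratios carry a constitutive offset that must be
#' subtracted before Hill fitting. The estimate is the mean zero-ligand
#' ratio; its uncertainty is the standard error of that mean.
#'
#' @param records vesicle records containing zero-ligand rows.
#' @return list with `E0`, `se` and `n` (number of zero-ligand vesicles).
#' @export
estimate_constitutive <- function(records) {
  ratios <- compute_ratios(records)
  z <- ratios[records$ligand_conc_nM == 0]
  if (length(z) < 2) {
    stop(paste("need >= 2 zero-ligand vesicles to estimate the constitutive",
               "response; supply E0 explicitly or fit with e0_mode = 'free'"),
         call. = FALSE)
  }
  list(E0 = mean(z), se = stats::sd(z) / sqrt(length(z)), n = length(z))
}

#' Fit the fixed-slope Hill equation to dose-response data
#'
#' Fits `E(L) = E_top * L / (L + EC50)` (Hill slope fixed at 1) to
#' constitutive-corrected responses by unweighted least squares over all
#' single-vesicle points. `E_top` is profiled out analytically (the model
#' is linear in it given `EC50`), leaving a one-dimensional minimisation
#' over `log(EC50)`; this is robust for noiseless data where conventional
#' Gauss-Newton stalls on a zero-residual surface. Parameter standard
#' errors come from the Jacobian-based least-squares covariance.
#'
#' Zero-dose points participate with model value 0 after correction.
#'
#' @param x either a vesicle-record `data.frame`, or a numeric vector of
#'   ligand concentrations (nM) accompanied by `response`.
#' @param response numeric responses (ratio units) when `x` is a vector.
#' @param e0_mode how the constitutive offset is handled: `"subtract"`
#'   (default) subtracts the zero-ligand mean (or `E0` if supplied) before
#'   fitting; `"free"` co-fits `E0` as a third parameter; `"none"` assumes
#'   responses are already corrected.
#' @param E0 optional known constitutive offset used with
#'   `e0_mode = "subtract"`.
#' @param target `"vesicles"` fits all single points (default);
#'   `"means"` fits per-concentration means.
#' @return An object of class `hill_fit`: estimates and SEs for `EC50`,
#'   `E_top` and `E0`, the `(E_top, EC50)` covariance, `hill_slope = 1`,
#'   counts, and `converged` / `ec50_identifiable` flags.
#' @export
fit_hill <- function(x, response = NULL,
                     e0_mode = c("subtract", "free", "none"),
                     E0 = NULL,
                     target = c("vesicles", "means")) {
  e0_mode <- match.arg(e0_mode)
  target <- match.arg(target)

  if (is.data.frame(x)) {
    conc <- x$ligand_conc_nM
    response <- compute_ratios(x)
  } else {
    conc <- as.numeric(x)
    if (is.null(response)) stop("supply `response` when x is a vector")
  }
  keep <- is.finite(conc) & is.finite(response)
  conc <- conc[keep]; response <- response[keep]
  if (length(unique(conc[conc > 0])) < 3) {
    stop("need >= 3 distinct positive concentrations to fit the Hill equation",
         call. = FALSE)
  }

  e0_est <- list(E0 = 0, se = 0)
  if (e0_mode == "subtract") {
    if (!is.null(E0)) {
      e0_est <- list(E0 = E0, se = 0)
    } else {
      z <- response[conc == 0]
      if (length(z) < 2) {
        stop("e0_mode = 'subtract' needs >= 2 zero-ligand points or an explicit E0",
             call. = FALSE)
      }
      e0_est <- list(E0 = mean(z), se = stats::sd(z) / sqrt(length(z)))
    }
    response <- response - e0_est$E0
  }

  if (target == "means") {
    m <- tapply(response, conc, mean)
    conc <- as.numeric(names(m))
    response <- as.numeric(m)
  }

  fit <- fit_hyperbola(conc, response, free_intercept = (e0_mode == "free"))

  if (e0_mode == "free") {
    e0_est <- list(E0 = fit$intercept, se = fit$intercept_se)
  }

  out <- list(
    EC50 = fit$half, EC50_se = fit$half_se,
    E_top = fit$top, E_top_se = fit$top_se,
    E0 = e0_est$E0, E0_se = e0_est$se,
    hill_slope = 1,
    cov = fit$cov,
    n_points = length(conc),
    sigma = fit$sigma,
    converged = fit$converged,
    ec50_identifiable = fit$identifiable,
    e0_mode = e0_mode
  )
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill fit (slope fixed at 1)\n")
  cat(sprintf("  E_top = %.4g +/- %.3g\n", x$E_top, x$E_top_se))
  if (x$ec50_identifiable) {
    cat(sprintf("  EC50  = %.4g +/- %.3g nM\n", x$EC50, x$EC50_se))
  } else {
    cat("  EC50  : unidentifiable (flat response)\n")
  }
  cat(sprintf("  E0    = %.4g +/- %.3g (%s)\n", x$E0, x$E0_se, x$e0_mode))
  cat(sprintf("  n = %d points; converged: %s\n", x$n_points, x$converged))
  invisible(x)
}

# Shared engine for the Hill (slope 1) and transducer fits: least squares
# for y = [b0] + top * x / (x + half), with the linear parameters profiled
# out and `half` optimised on the log scale. Returns estimates, SEs and the
# (top, half) covariance block.
fit_hyperbola <- function(x, y, free_intercept = FALSE) {
  stopifnot(length(x) == length(y))
  xp <- x[x > 0]
  n <- length(x)

  design <- function(half) {
    g <- x / (x + half)
    if (free_intercept) cbind(1, g) else cbind(g)
  }
  sse_at <- function(loghalf) {
    X <- design(exp(loghalf))
    cf <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
    if (is.null(cf) || any(!is.finite(cf))) return(Inf)
    sum((y - X %*% cf)^2)
  }

  # Degenerate flat response: top = 0, half unidentifiable.
  if (all(abs(y - if (free_intercept) mean(y) else 0) < 1e-300)) {
    p <- if (free_intercept) 2L else 1L
    return(list(top = 0, top_se = 0, half = NA_real_, half_se = NA_real_,
                intercept = if (free_intercept) mean(y) else 0, intercept_se = 0,
                cov = matrix(0, 2, 2,
                             dimnames = list(c("top", "half"), c("top", "half"))),
                sigma = 0, converged = TRUE, identifiable = FALSE))
  }

  lo <- log(min(xp)) - log(100)
  hi <- log(max(xp)) + log(100)
  # Coarse bracket then refine: the profiled SSE can be multimodal when the
  # response barely rises, so seed optimize() near the grid minimum.
  grid <- seq(lo, hi, length.out = 80)
  sgrid <- vapply(grid, sse_at, numeric(1))
  i0 <- which.min(sgrid)
  bl <- grid[max(1, i0 - 1)]
  bu <- grid[min(length(grid), i0 + 1)]
  opt <- stats::optimize(sse_at, c(bl, bu), tol = 1e-12)
  loghalf <- opt$minimum
  half <- exp(loghalf)

  X <- design(half)
  cf <- qr.coef(qr(X), y)
  top <- unname(cf[ncol(X)])
  b0 <- if (free_intercept) unname(cf[1]) else 0
  resid <- y - X %*% cf
  sse <- sum(resid^2)

  at_boundary <- loghalf < lo + 1e-6 || loghalf > hi - 1e-6
  converged <- is.finite(sse) && !at_boundary

  # Jacobian of the mean function wrt (b0?, top, half)
  g <- x / (x + half)
  d_half <- -top * x / (x + half)^2
  J <- if (free_intercept) cbind(1, g, d_half) else cbind(g, d_half)
  p <- ncol(J)
  sigma2 <- if (n > p) sse / (n - p) else 0
  covfull <- tryCatch(sigma2 * solve(crossprod(J)),
                      error = function(e) matrix(NA_real_, p, p))
  idx <- if (free_intercept) c(2L, 3L) else c(1L, 2L)
  cov <- covfull[idx, idx, drop = FALSE]
  dimnames(cov) <- list(c("top", "half"), c("top", "half"))

  list(top = top,
       top_se = sqrt(max(cov["top", "top"], 0)),
       half = half,
       half_se = sqrt(max(cov["half", "half"], 0)),
       intercept = b0,
       intercept_se = if (free_intercept) sqrt(max(covfull[1, 1], 0)) else 0,
       cov = cov,
       sigma = sqrt(sigma2),
       converged = converged,
       identifiable = TRUE)
}

#' Per-concentration dose-response summaries
#'
#' @param records vesicle records.
#' @return `data.frame` with one row per unique concentration:
#'   `ligand_conc_nM`, `mean_ratio`, `sem_ratio` (0 by convention when
#'   `n_vesicles = 1`), `n_vesicles`; sorted by concentration.
#' @export
aggregate_dose_response <- function(records) {
  if (!nrow(records)) stop("no records to aggregate", call. = FALSE)
  ratios <- compute_ratios(records)
  conc <- records$ligand_conc_nM
  grp <- sort(unique(conc))
  out <- do.call(rbind, lapply(grp, function(L) {
    r <- ratios[conc == L]
    n <- length(r)
    data.frame(ligand_conc_nM = L,
               mean_ratio = mean(r),
               sem_ratio = if (n > 1) stats::sd(r) / sqrt(n) else 0,
               n_vesicles = n)
  }))
  rownames(out) <- NULL
  out
}

#' Hill parameters from the operational-model transducer coefficient
#'
#' In the operational model the observable Hill parameters are determined
#' by the transducer coefficient tau, the ligand dissociation constant and
#' the system maximum: `E_top = tau * R_max / (tau + 1)` and
#' `EC50 = K_L / (tau + 1)`.
#'
#' @param tau transducer coefficient (`> 0`), vectorised.
#' @param K_L ligand-receptor dissociation constant, nM (`> 0`).
#' @param R_max maximal system response.
#' @return list with numeric `E_top` and `EC50`.
#' @export
etop_ec50_from_tau <- function(tau, K_L, R_max) {
  if (any(tau <= 0) || any(K_L <= 0)) {
    stop("tau and K_L must be > 0", call. = FALSE)
  }
  list(E_top = tau * R_max / (tau + 1), EC50 = K_L / (tau + 1))
}

#' Transducer coefficient recovered from Hill parameters
#'
#' Inverts the operational-model relations: `tau = E_top / (R_max - E_top)`
#' from the efficacy route and `tau = K_L / EC50 - 1` from the potency
#' route. Both must agree when the parameters are internally consistent.
#'
#' @param E_top,EC50 Hill parameters.
#' @param R_max,K_L system maximum and ligand dissociation constant.
#' @param via `"etop"` or `"ec50"`, selecting the route.
#' @return tau (numeric, vectorised).
#' @export
tau_from_hill <- function(E_top = NULL, EC50 = NULL, R_max = NULL, K_L = NULL,
                          via = c("etop", "ec50")) {
  via <- match.arg(via)
  if (via == "etop") {
    stopifnot(!is.null(E_top), !is.null(R_max))
    if (any(E_top >= R_max)) stop("E_top must be < R_max", call. = FALSE)
    E_top / (R_max - E_top)
  } else {
    stopifnot(!is.null(EC50), !is.null(K_L))
    if (any(EC50 <= 0)) stop("EC50 must be > 0", call. = FALSE)
    K_L / EC50 - 1
  }
}

#' Linear spectral unmixing of a FRET channel
#'
#' Removes donor bleed-through and direct acceptor excitation from a raw
#' FRET-channel intensity:
#' `sensitized = fret - donor_bleed * donor - acceptor_bleed * acceptor`.
#' Defaults are the measured bleed-through coefficients for mTurquoise
#' (33%) and AlexaFluor488 (7%). Negative results are reported as-is.
#'
#' @param fret,donor,acceptor channel intensities (vectorised, `>= 0`).
#' @param donor_bleed,acceptor_bleed bleed-through fractions (`>= 0`).
#' @return numeric sensitized-emission intensities.
#' @export
fret_unmix <- function(fret, donor, acceptor,
                       donor_bleed = 0.33, acceptor_bleed = 0.07) {
  if (donor_bleed < 0 || acceptor_bleed < 0) {
    stop("bleed-through coefficients must be >= 0", call. = FALSE)
  }
  fret - donor_bleed * donor - acceptor_bleed * acceptor
}
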