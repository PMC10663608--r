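#' Monte-Carlo propagation settings
#'
#' @param n_draws number of Gaussian draws per parameter (default `1e6`,
#'   minimum `1e3`).
#' @param seed optional RNG seed; propagation is deterministic given the
#'   seed.
#' @return object of class `mc_settings`.
#' @export
mc_settings <- function(n_draws = 1e6, seed = NULL) {
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 1e3) {
    stop("n_draws must be >= 1000", call. = FALSE)
  }
  structure(list(n_draws = n_draws,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "mc_settings")
}

#' Monte-Carlo standard error of a derived quantity
#'
#' For each of the `k` parameters, `n_draws` normally distributed numbers
#' are generated from the parameter's mean and standard error; the SE of
#' the derived quantity is the sample standard deviation of `fn` over the
#' joint draws (parameters sampled independently).
#'
#' `fn` should be vectorised over its `k` arguments and return `NA` for
#' draws outside its domain (e.g. a negative EC50 draw); such draws are
#' rejected and counted, and more than 1% rejections is an error. A
#' non-vectorised `fn` is detected and applied row-wise.
#'
#' @param fn scalar function of `k` parameters.
#' @param means,ses numeric vectors of length `k` (SEs `>= 0`).
#' @param settings [mc_settings()].
#' @return the Monte-Carlo SE (numeric scalar), with the rejected-draw
#'   count in attribute `"n_rejected"`.
#' @export
monte_carlo_se <- function(fn, means, ses, settings = mc_settings()) {
  stopifnot(length(means) == length(ses))
  if (any(!is.finite(ses)) || any(ses < 0)) {
    stop("ses must be finite and >= 0", call. = FALSE)
  }
  k <- length(means)
  n <- settings$n_draws
  draws <- with_seed(settings$seed, {
    m <- matrix(rnorm(n * k), nrow = n, ncol = k)
    sweep(sweep(m, 2, ses, "*"), 2, means, "+")
  })
  args <- lapply(seq_len(k), function(j) draws[, j])
  # NaN/NA from out-of-domain draws is the rejection mechanism, not a bug
  vals <- tryCatch(suppressWarnings(do.call(fn, args)), error = function(e) NULL)
  if (is.null(vals) || length(vals) != n) {
    # fn not vectorised: apply per draw
    vals <- vapply(seq_len(n), function(i) {
      v <- tryCatch(suppressWarnings(do.call(fn, as.list(draws[i, ]))),
                    error = function(e) NA_real_)
      as.numeric(v)
    }, numeric(1))
  }
  bad <- !is.finite(vals)
  n_bad <- sum(bad)
  if (n_bad > 0.01 * n) {
    stop(sprintf(
      "%.1f%% of Monte-Carlo draws fall outside the function's domain (%d of %d); parameter uncertainties are too large for this propagation",
      100 * n_bad / n, n_bad, n), call. = FALSE)
  }
  out <- stats::sd(vals[!bad])
  attr(out, "n_rejected") <- n_bad
  out
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values).
#' @return `data.frame` of class `test_results`, one row per pair:
#'   `comparison`, `estimate` (difference of means), `statistic` (pooled-t),
#'   `p_raw` (unadjusted pooled t-test), `p_adjusted` (Tukey HSD),
#'   `method`. ANOVA `F` and `p` are in attributes `"anova_F"` and
#'   `"anova_p"`; a degenerate (zero within-group variance) design is
#'   flagged in attribute `"degenerate"`.
#' @export
anova_tukey <- function(groups) {
  check_groups(groups, min_groups = 2)
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  mse <- an["Residuals", "Mean Sq"]
  degenerate <- !is.finite(mse) || mse <= .Machine$double.eps
  tuk <- stats::TukeyHSD(fit)$group
  pairs <- rownames(tuk)

  # unadjusted pooled-variance pairwise t-tests on the same error term
  df_err <- an["Residuals", "Df"]
  raw <- vapply(pairs, function(p) {
    gg <- strsplit(p, "-", fixed = TRUE)[[1]]
    a <- groups[[gg[1]]]; b <- groups[[gg[2]]]
    se <- sqrt(mse * (1 / length(a) + 1 / length(b)))
    if (se == 0) return(c(NA_real_, if (mean(a) == mean(b)) 1 else 0))
    tstat <- (mean(a) - mean(b)) / se
    c(tstat, 2 * stats::pt(-abs(tstat), df_err))
  }, numeric(2))

  out <- data.frame(
    comparison = pairs,
    estimate = tuk[, "diff"],
    statistic = raw[1, ],
    p_raw = raw[2, ],
    p_adjusted = tuk[, "p adj"],
    method = "one-way ANOVA + Tukey HSD",
    row.names = NULL
  )
  attr(out, "anova_F") <- an["group", "F value"]
  attr(out, "anova_p") <- an["group", "Pr(>F)"]
  attr(out, "degenerate") <- degenerate
  class(out) <- c("test_results", "data.frame")
  out
}

#' Pairwise two-tailed t-tests with Holm-Sidak adjustment
#'
#' Runs a two-tailed t-test for each supplied pair of groups and applies
#' the Holm-Sidak step-down adjustment: with raw p-values ordered
#' ascending, `p_adj(i) = 1 - (1 - p(i))^(m - i + 1)`, then enforced
#' monotone nondecreasing and capped at 1.
#'
#' @param pairs named list; each element a list/vector-pair of two numeric
#'   groups (each `n >= 2`).
#' @param var_equal use the pooled-variance t-test (`TRUE`) or Welch
#'   (`FALSE`, default).
#' @return `data.frame` of class `test_results` with `comparison`,
#'   `estimate`, `statistic`, `p_raw`, `p_adjusted`, `method`.
#' @export
ttests_holm_sidak <- function(pairs, var_equal = FALSE) {
  if (!length(pairs)) stop("no pairs supplied", call. = FALSE)
  if (is.null(names(pairs))) names(pairs) <- paste0("pair", seq_along(pairs))
  res <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2)
    a <- pr[[1]]; b <- pr[[2]]
    check_groups(list(a = a, b = b), min_groups = 2)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate variance: identical constants are "no difference"
      return(list(estimate = mean(a) - mean(b), statistic = NA_real_,
                  p = if (mean(a) == mean(b)) 1 else 0))
    }
    tt <- stats::t.test(a, b, var.equal = var_equal)
    list(estimate = unname(diff(rev(tt$estimate))), statistic = unname(tt$statistic),
         p = tt$p.value)
  })
  p_raw <- vapply(res, `[[`, numeric(1), "p")
  out <- data.frame(
    comparison = names(pairs),
    estimate = vapply(res, `[[`, numeric(1), "estimate"),
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    p_raw = p_raw,
    p_adjusted = holm_sidak_adjust(p_raw),
    method = sprintf("two-tailed t-test (%s), Holm-Sidak adjusted",
                     if (var_equal) "pooled" else "Welch"),
    row.names = NULL
  )
  class(out) <- c("test_results", "data.frame")
  out
}

#' Holm-Sidak step-down p-value adjustment
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the input order.
#' @export
holm_sidak_adjust <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- cummax(adj)       # enforce step-down monotonicity
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Pseudo-replicate groups from bias coefficients
#'
#' The figure-level hypothesis tests operate on groups of replicate bias
#' values; when only a coefficient's Monte-Carlo SE is available, this
#' bridge draws `n_per_group` Gaussian pseudo-replicates per coefficient
#' so the ANOVA / t-test machinery can run. The groups are labelled
#' reconstructions, not measured replicates.
#'
#' @param coeffs list of [bias_coefficient()] objects.
#' @param n_per_group draws per coefficient (default 3, `>= 2`).
#' @param settings [mc_settings()] (only the seed is used).
#' @return named list of numeric groups, named by `test_entity`.
#' @export
coefficient_groups_from_mc <- function(coeffs, n_per_group = 3,
                                       settings = mc_settings()) {
  if (inherits(coeffs, "bias_coefficient")) coeffs <- list(coeffs)
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  nm <- vapply(coeffs, function(co) co$test_entity, character(1))
  nm <- make.unique(nm)
  groups <- with_seed(settings$seed, {
    lapply(coeffs, function(co) stats::rnorm(n_per_group, co$value, co$se))
  })
  names(groups) <- nm
  groups
}

check_groups <- function(groups, min_groups = 2) {
  if (length(groups) < min_groups) {
    stop(sprintf("need >= %d groups", min_groups), call. = FALSE)
  }
  ns <- lengths(groups)
  if (any(ns < 2)) stop("each group needs n >= 2", call. = FALSE)
  invisible(TRUE)
}
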