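# Independent oracles used by the unit and acceptance tests. These are kept
# deliberately naive (grid search, closed forms) and never call the
# implementation paths they check.

# Brute-force SSE minimisation of y = top * x / (x + half) over a refined
# 2-D grid. Returns (top, half) at the grid optimum.
grid_search_hill <- function(x, y, top_range = NULL, half_range = NULL,
                             n_grid = 41, n_refine = 6) {
  if (is.null(top_range)) top_range <- c(1e-3, 4) * max(abs(y), 1e-6)
  if (is.null(half_range)) half_range <- range(x[x > 0]) * c(0.01, 100)
  lt <- log(top_range); lh <- log(half_range)
  best <- c(NA_real_, NA_real_)
  for (r in seq_len(n_refine)) {
    tops <- exp(seq(lt[1], lt[2], length.out = n_grid))
    halves <- exp(seq(lh[1], lh[2], length.out = n_grid))
    sse <- outer(tops, halves, Vectorize(function(tt, hh) {
      sum((y - tt * x / (x + hh))^2)
    }))
    idx <- arrayInd(which.min(sse), dim(sse))
    best <- c(tops[idx[1]], halves[idx[2]])
    # shrink the window around the optimum
    span_t <- (lt[2] - lt[1]) / (n_grid - 1)
    span_h <- (lh[2] - lh[1]) / (n_grid - 1)
    lt <- log(best[1]) + c(-2, 2) * span_t
    lh <- log(best[2]) + c(-2, 2) * span_h
  }
  list(top = best[1], half = best[2])
}

# First-order delta-method SE of the relative log10 bias (Eq.-1 form) for
# independent parameters: d(log10 u)/du = 1/(u ln 10), and every parameter
# enters the product with exponent +/-1.
delta_method_beta_se <- function(means, ses) {
  stopifnot(length(means) == 8, length(ses) == 8)
  sqrt(sum((ses / means)^2)) / log(10)
}

# One-way ANOVA F computed from explicit sums of squares.
anova_F_by_hand <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# Default small-world generator settings for fast tests.
quick_config <- function(...) {
  args <- list(...)
  defaults <- list(vesicles_per_concentration = 50, seed = 1L)
  for (k in names(args)) defaults[[k]] <- args[[k]]
  do.call(generative_config, defaults)
}

# Hill-fit quadruple for a simple condition, used to build bias inputs.
fit_from_params <- function(E_top, EC50, E_top_se = 0.01, EC50_se = 0.1) {
  structure(list(EC50 = EC50, EC50_se = EC50_se,
                 E_top = E_top, E_top_se = E_top_se,
                 E0 = 0, E0_se = 0, hill_slope = 1,
                 cov = matrix(0, 2, 2, dimnames = list(c("top", "half"),
                                                       c("top", "half"))),
                 n_points = 100L, sigma = 0, converged = TRUE,
                 ec50_identifiable = TRUE, e0_mode = "none"),
            class = "hill_fit")
}

fast_mc <- function(seed = 1L) mc_settings(n_draws = 2e4, seed = seed)
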