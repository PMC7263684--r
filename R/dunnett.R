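# One-way ANOVA with Dunnett many-to-one comparisons.
#
# Each treatment arm is compared with a shared control; family-wise
# adjusted p-values come from the joint null distribution of the maximum
# absolute Dunnett t statistic, evaluated by seeded Monte Carlo. For a
# comparison with observed statistic t_j, the adjusted p is
# P(max_i |T_i| >= |t_j|) where (T_1, ..., T_{k-1}) share the control
# group's mean and the pooled variance estimate, exactly as in the
# classical multivariate-t formulation.

#' One-way ANOVA with Monte-Carlo Dunnett comparisons against a control
#'
#' Fits a one-way fixed-effects ANOVA over the groups and compares every
#' non-control group with the control using Dunnett's many-to-one
#' procedure. The family-wise adjusted p-values are computed by Monte
#' Carlo: group means and a pooled variance are simulated under the joint
#' null (respecting the group sizes, hence the Dunnett correlation
#' structure), and each comparison's adjusted p is the tail probability of
#' the maximum absolute statistic.
#'
#' @param values Numeric response vector (per-fly best responses).
#' @param groups Group labels, same length as `values`.
#' @param control Label of the control group.
#' @param n_draws Monte-Carlo draws (default `1e5`).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return An object of class `"anova_dunnett"`: list with `anova` (data
#'   frame: `F`, `df1`, `df2`, `p`), `comparisons` (data frame: `group`,
#'   `n`, `diff`, `se`, `t`, `p_unadj`, `p_adj`), `control`, `df`,
#'   `n_draws`.
#' @export
#' @examples
#' v <- c(rnorm(8), rnorm(8, 1), rnorm(8, 2))
#' g <- rep(c("ctrl", "a", "b"), each = 8)
#' anova_dunnett(v, g, control = "ctrl", n_draws = 2e4, seed = 1)
anova_dunnett <- function(values, groups, control, n_draws = 1e5,
                          seed = NULL) {
  abort_if(!is.numeric(values) || anyNA(values),
           "'values' must be numeric without NAs")
  abort_if(length(values) != length(groups),
           "'values' and 'groups' must have equal length")
  groups <- as.character(groups)
  labs <- unique(groups)
  abort_if(length(labs) < 2L, "need at least 2 groups")
  abort_if(!control %in% labs, "control label '", control, "' not found")
  ns <- table(groups)
  abort_if(any(ns < 2L), "every group needs at least 2 observations")
  n_tot <- length(values)
  k <- length(labs)
  df <- n_tot - k
  means <- tapply(values, groups, mean)
  sse <- sum((values - means[groups])^2)
  abort_if(sse == 0, "degenerate: zero within-group variance everywhere")
  mse <- sse / df
  ssb <- sum(ns * (means - mean(values))^2)
  f <- (ssb / (k - 1)) / mse
  p_f <- stats::pf(f, k - 1, df, lower.tail = FALSE)

  treat <- setdiff(labs, control)
  n0 <- ns[[control]]
  comp <- data.frame(group = treat, n = as.integer(ns[treat]),
                     diff = as.numeric(means[treat] - means[[control]]),
                     stringsAsFactors = FALSE)
  comp$se <- sqrt(mse * (1 / comp$n + 1 / n0))
  comp$t <- comp$diff / comp$se
  comp$p_unadj <- 2 * stats::pt(-abs(comp$t), df)

  # joint null: shared control mean, independent group means, pooled s^2
  max_t <- with_seed(seed, {
    m0 <- stats::rnorm(n_draws, 0, 1 / sqrt(n0))
    s <- sqrt(stats::rchisq(n_draws, df) / df)
    mt <- rep(0, n_draws)
    for (j in seq_along(treat)) {
      mg <- stats::rnorm(n_draws, 0, 1 / sqrt(comp$n[j]))
      tj <- abs(mg - m0) / (s * sqrt(1 / comp$n[j] + 1 / n0))
      mt <- pmax(mt, tj)
    }
    mt
  })
  comp$p_adj <- vapply(comp$t, function(tj) mean(max_t >= abs(tj)), numeric(1))

  structure(
    list(anova = data.frame(F = f, df1 = k - 1, df2 = df, p = p_f),
         comparisons = comp, control = control, df = df,
         n_draws = n_draws),
    class = "anova_dunnett"
  )
}

#' @export
print.anova_dunnett <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  cat(sprintf("Dunnett comparisons vs '%s' (Monte Carlo, %g draws):\n",
              x$control, x$n_draws))
  print(x$comparisons, digits = 4, row.names = FALSE)
  invisible(x)
}
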