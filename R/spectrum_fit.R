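# The synergy-spectrum regression and annotation enrichment.
#
# Plotting Y (additional effect of G2019S) against X (solo effect of the
# Rab) across the screen reveals an inverse relationship: Rabs with a large
# solo effect gain little from G2019S, while Rabs with little solo effect
# show strong synergy. The regression of Y on X quantifies this spectrum;
# Rabs are classified above/below the line by raw residual sign, and
# annotation enrichment among the above-line Rabs is tested by Fisher's
# exact test.

#' Fit the synergy-spectrum regression
#'
#' Ordinary least squares of `Y` on `X` with intercept across the Rabs of
#' one harmonic. Unweighted by default (the screen plots means with SE
#' bars but imposes no weighting); `weighted = TRUE` uses `1 / se_Y^2`
#' weights.
#'
#' @param points A data frame with columns `rab_id`, `X`, `Y` (and `se_Y`
#'   when `weighted`), e.g. one harmonic's rows of
#'   `screen_summaries()$synergy`.
#' @param weighted Use inverse-variance weights `1 / se_Y^2`.
#' @return An object of class `"spectrum_fit"`: the underlying `lm` fit
#'   plus `slope`, `intercept`, `r_squared`, per-Rab `residuals` and the
#'   logical `above_line` classification (`residual > 0`). Methods:
#'   `print`, `summary`, `coef`, `predict`, `residuals`, `plot`.
#' @export
#' @examples
#' pts <- data.frame(rab_id = letters[1:4], X = 1:4, Y = 2 * (1:4) + 1)
#' coef(fit_spectrum(pts))
fit_spectrum <- function(points, weighted = FALSE) {
  abort_if(!is.data.frame(points) ||
             !all(c("rab_id", "X", "Y") %in% names(points)),
           "'points' needs columns rab_id, X, Y")
  abort_if(nrow(points) < 3L, "degenerate fit: need at least 3 points")
  abort_if(stats::var(points$X) == 0, "degenerate fit: zero variance in X")
  w <- NULL
  if (weighted) {
    abort_if(!"se_Y" %in% names(points) || any(points$se_Y <= 0),
             "weighted fit needs positive 'se_Y' for every point")
    w <- 1 / points$se_Y^2
  }
  fit <- stats::lm(Y ~ X, data = points, weights = w)
  res <- stats::residuals(fit)
  structure(
    list(lm = fit,
         slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = suppressWarnings(summary(fit)$r.squared),
         rab_id = points$rab_id,
         data = points,
         residuals = unname(res),
         above_line = unname(res) > 0,
         weighted = weighted),
    class = "spectrum_fit"
  )
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf(
    "Synergy-spectrum regression (%d Rabs%s):\n  Y = %.4g %+.4g * X,  R^2 = %.3f\n  %d Rab(s) above the line: %s\n",
    length(x$rab_id), if (x$weighted) ", weighted" else "",
    x$intercept, x$slope, x$r_squared, sum(x$above_line),
    paste(x$rab_id[x$above_line], collapse = ", ")))
  invisible(x)
}

#' @export
summary.spectrum_fit <- function(object, ...) summary(object$lm, ...)

#' @export
coef.spectrum_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.spectrum_fit <- function(object, ...) {
  stats::setNames(object$residuals, object$rab_id)
}

#' @export
predict.spectrum_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  unname(stats::predict(object$lm, newdata = newdata))
}

#' @export
plot.spectrum_fit <- function(x, label = TRUE, ...) {
  graphics::plot(x$data$X, x$data$Y, xlab = "X: Rab-only effect (µV)",
                 ylab = "Y: additional G2019S effect (µV)", ...)
  graphics::abline(x$intercept, x$slope)
  if (label) {
    graphics::text(x$data$X, x$data$Y, x$rab_id, pos = 3, cex = 0.7)
  }
  invisible(x)
}

#' Two-sided Fisher exact p for a 2x2 table
#'
#' Probability-mass rule: the p-value sums, over all tables with the
#' observed margins, the hypergeometric probabilities no larger than that
#' of the observed table. Degenerate tables (a zero margin) have p = 1.
#'
#' @param tab A 2x2 matrix of nonnegative counts.
#' @return The two-sided p-value.
#' @export
#' @examples
#' fisher_p(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
fisher_p <- function(tab) {
  abort_if(!is.matrix(tab) || any(dim(tab) != 2L) || any(tab < 0) ||
             any(tab != round(tab)),
           "'tab' must be a 2x2 matrix of nonnegative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Annotation enrichment above the spectrum line
#'
#' Cross-tabulates an annotation (e.g. "previously linked to Parkinson's
#' disease") against the above/below-line classification of a
#' [fit_spectrum()] and tests association with Fisher's exact test
#' (two-sided, probability-mass rule). The odds ratio is the sample
#' cross-product `ad / bc` (0/0 gives `NaN`, division by zero `Inf`).
#'
#' @param fit A `"spectrum_fit"`.
#' @param annotation Logical vector: either named by Rab, or in the order
#'   of `fit$rab_id`. Must cover every Rab in the fit.
#' @return An object of class `"enrichment_result"`: list with `table`
#'   (2x2 counts, annotated x above-line), `p_two_sided`, `odds_ratio`.
#' @export
enrichment_test <- function(fit, annotation) {
  abort_if(!inherits(fit, "spectrum_fit"), "'fit' must be a spectrum_fit")
  if (!is.null(names(annotation))) {
    abort_if(!all(fit$rab_id %in% names(annotation)),
             "annotation missing for: ",
             paste(setdiff(fit$rab_id, names(annotation)), collapse = ", "))
    annotation <- annotation[fit$rab_id]
  }
  abort_if(!is.logical(annotation) || length(annotation) != length(fit$rab_id) ||
             anyNA(annotation),
           "'annotation' must be a complete logical vector over the fitted Rabs")
  tab <- matrix(c(sum(annotation & fit$above_line),
                  sum(annotation & !fit$above_line),
                  sum(!annotation & fit$above_line),
                  sum(!annotation & !fit$above_line)),
                2L, 2L, byrow = TRUE,
                dimnames = list(annotated = c("yes", "no"),
                                above_line = c("yes", "no")))
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  or <- if (a * d == 0 && b * c_ == 0) NaN else (a * d) / (b * c_)
  structure(list(table = tab, p_two_sided = fisher_p(tab), odds_ratio = or),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Annotation vs above-line classification:\n")
  print(x$table)
  cat(sprintf("Fisher exact (two-sided): P = %.4g, odds ratio = %.4g\n",
              x$p_two_sided, x$odds_ratio))
  invisible(x)
}
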