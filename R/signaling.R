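# Lamina-versus-photoreceptor signaling regression and outlier detection.
#
# For each Rab, the G2019S-induced increase in lamina-neuron signaling
# (delta best 2F1) is plotted against the G2019S-induced increase in the
# photoreceptor signal (delta best 1F1). Across the screen these are
# tightly coupled; a Rab that drives the lamina far more than its
# photoreceptor drive predicts is flagged by a leave-one-out externally
# studentized residual.

#' Per-Rab signaling points
#'
#' Computes, for each Rab, `x = mean(best 1F1 | both) - mean(best 1F1 |
#' rab_only)` and `y = mean(best 2F1 | both) - mean(best 2F1 | rab_only)`:
#' the increases in photoreceptor and lamina-neuron signaling caused by
#' adding G2019S to the Rab background.
#'
#' @param flies A [fly_results()] data frame; both the `rab_only` and
#'   `both` arms must be present for every Rab.
#' @param age_group Optional label (e.g. `"day1"`, `"day7"`) attached to
#'   every point.
#' @return A data frame with columns `rab_id`, `x`, `y`, `se_x`, `se_y`,
#'   `age_group`.
#' @export
signaling_points <- function(flies, age_group = NA_character_) {
  need <- c("fly_id", "genotype_label", "rab_id", "best_1F1", "best_2F1")
  abort_if(!is.data.frame(flies) || !all(need %in% names(flies)),
           "fly results need columns: ", paste(need, collapse = ", "))
  rabs <- sort(unique(flies$rab_id[!is.na(flies$rab_id)]))
  abort_if(length(rabs) == 0L, "no Rab arms in fly results")
  rows <- lapply(rabs, function(r) {
    ro <- flies[flies$genotype_label == "rab_only" & flies$rab_id %in% r, ]
    bo <- flies[flies$genotype_label == "both" & flies$rab_id %in% r, ]
    abort_if(nrow(ro) == 0L || nrow(bo) == 0L,
             "missing rab_only or both arm for ", r)
    se <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
    data.frame(rab_id = r,
               x = mean(bo$best_1F1) - mean(ro$best_1F1),
               y = mean(bo$best_2F1) - mean(ro$best_2F1),
               se_x = sqrt(se(bo$best_1F1)^2 + se(ro$best_1F1)^2),
               se_y = sqrt(se(bo$best_2F1)^2 + se(ro$best_2F1)^2),
               age_group = age_group, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Leave-one-out outlier detection on the signaling regression
#'
#' For each point, an OLS line is fitted to the remaining points, and the
#' point is scored by its externally studentized residual
#' `(y - yhat) / sqrt(s^2 (1 + h))`, where `s` and the leverage `h` come
#' from the leave-one-out fit. Points at or beyond `threshold` in absolute
#' value are flagged. The ratio `y / yhat` (observed over predicted lamina
#' increase) is reported alongside, the scale on which a standout Rab is
#' usually quoted. A degenerate leave-one-out fit (zero x variance in the
#' remaining points) leaves that point unflagged with a warning record.
#'
#' @param points A [signaling_points()] data frame (columns `rab_id`, `x`,
#'   `y`); at least 4 points.
#' @param threshold Absolute studentized-residual threshold (default 3).
#' @return An object of class `"outlier_scan"`: a data frame with columns
#'   `rab_id`, `x`, `y`, `predicted`, `studentized`, `ratio`, `flagged`,
#'   with the threshold and any warning records as attributes.
#' @export
#' @examples
#' pts <- data.frame(rab_id = letters[1:5], x = 1:5, y = c(1, 2, 3, 4, 25))
#' detect_outliers(pts)
detect_outliers <- function(points, threshold = 3) {
  abort_if(!is.data.frame(points) ||
             !all(c("rab_id", "x", "y") %in% names(points)),
           "'points' needs columns rab_id, x, y")
  abort_if(nrow(points) < 4L, "need at least 4 points for leave-one-out fits")
  abort_if(!is_scalar_number(threshold) && !identical(threshold, Inf),
           "'threshold' must be a single number (possibly Inf)")
  n <- nrow(points)
  warnings <- character(0)
  out <- data.frame(rab_id = points$rab_id, x = points$x, y = points$y,
                    predicted = NA_real_, studentized = NA_real_,
                    ratio = NA_real_, flagged = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    rest <- points[-i, , drop = FALSE]
    if (stats::var(rest$x) == 0) {
      warnings <- c(warnings, sprintf(
        "degenerate leave-one-out fit for %s (zero x variance); not flagged",
        points$rab_id[i]))
      next
    }
    fit <- stats::lm(y ~ x, data = rest)
    pr <- stats::predict(fit, newdata = points[i, , drop = FALSE],
                         se.fit = TRUE)
    s2 <- pr$residual.scale^2
    e <- points$y[i] - unname(pr$fit)
    denom <- sqrt(s2 + pr$se.fit^2)   # s * sqrt(1 + h_new)
    stud <- if (denom > 0) e / denom else if (e == 0) 0 else Inf * sign(e)
    out$predicted[i] <- unname(pr$fit)
    out$studentized[i] <- stud
    out$ratio[i] <- if (pr$fit != 0) points$y[i] / unname(pr$fit) else NA_real_
    out$flagged[i] <- is.finite(threshold) && abs(stud) >= threshold
  }
  structure(out, threshold = threshold, warnings = warnings,
            class = c("outlier_scan", "data.frame"))
}

#' @export
print.outlier_scan <- function(x, ...) {
  cat(sprintf("Leave-one-out outlier scan (|studentized| >= %g):\n",
              attr(x, "threshold")))
  print.data.frame(x, digits = 4)
  w <- attr(x, "warnings")
  if (length(w)) cat("Warnings:\n", paste(" -", w, collapse = "\n"), "\n")
  invisible(x)
}
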