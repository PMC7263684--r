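# Genotype-level aggregation and the synergy coordinates of the screen.

#' Summarize best responses of one genotype arm
#'
#' Aggregates the per-fly best responses of one arm: mean with standard
#' error (sample SD, n - 1 denominator, over sqrt(n)), and median with
#' interquartile range (quartiles by linear interpolation). A single fly
#' yields `se = 0` by convention.
#'
#' @param bests Numeric vector of per-fly best responses (microvolts).
#' @param harmonic Optional harmonic tag (`"1F1"` or `"2F1"`) carried on
#'   the summary.
#' @param genotype_label,rab_id Optional arm metadata.
#' @return An object of class `"genotype_summary"`: list with `n`, `mean`,
#'   `se`, `median`, `iqr` and the metadata.
#' @export
#' @examples
#' summarize_genotype(c(1, 2, 3, 4))
summarize_genotype <- function(bests, harmonic = NA_character_,
                               genotype_label = NA_character_,
                               rab_id = NA_character_) {
  abort_if(!is.numeric(bests) || length(bests) == 0L || anyNA(bests),
           "'bests' must be a nonempty numeric vector without NAs")
  n <- length(bests)
  structure(
    list(n = n, mean = mean(bests),
         se = if (n > 1L) stats::sd(bests) / sqrt(n) else 0,
         median = stats::median(bests),
         iqr = if (n > 1L) stats::IQR(bests) else 0,
         harmonic = harmonic, genotype_label = genotype_label,
         rab_id = rab_id),
    class = "genotype_summary"
  )
}

#' @export
print.genotype_summary <- function(x, ...) {
  cat(sprintf("n = %d: mean %.4g +/- %.3g (SE) uV, median %.4g (IQR %.3g)\n",
              x$n, x$mean, x$se, x$median, x$iqr))
  invisible(x)
}

#' Fold change between two genotype arms
#'
#' Ratio of arm mean to reference mean; the standard way of quoting the
#' size of a synergistic increase (e.g. photoreceptor and lamina responses
#' of a synergistic cross several-fold above the driver-only control).
#'
#' @param arm,reference [summarize_genotype()] objects (or bare numbers).
#' @return `mean(arm) / mean(reference)`.
#' @export
fold_change <- function(arm, reference) {
  m_arm <- if (inherits(arm, "genotype_summary")) arm$mean else arm
  m_ref <- if (inherits(reference, "genotype_summary")) reference$mean else reference
  abort_if(!is_scalar_number(m_arm) || !is_scalar_number(m_ref),
           "arm and reference means must be single numbers")
  abort_if(m_ref <= 0, "undefined ratio: reference mean must be positive")
  m_arm / m_ref
}

#' Synergy coordinates (X, Y) of one Rab
#'
#' The screen locates each Rab by two differences of arm means:
#' `X = mean(Rab only) - mean(control)`, the visual effect of the Rab on
#' its own, and `Y = mean(both) - mean(Rab only)`, the additional effect of
#' co-expressing LRRK2-G2019S. A Rab with little solo effect but a large
#' additional effect (small X, large Y) is synergistic. Standard errors
#' combine in quadrature. By construction `X + Y = mean(both) -
#' mean(control)`.
#'
#' @param control,rab_only,both [summarize_genotype()] objects for the
#'   three arms, sharing the same harmonic.
#' @return An object of class `"synergy_point"`: list with `rab_id`, `X`,
#'   `Y`, `se_X`, `se_Y`, `harmonic`.
#' @export
#' @examples
#' s <- function(x) summarize_genotype(x, harmonic = "2F1")
#' synergy_xy(s(c(1.8, 2.2)), s(c(4.9, 5.1)), s(c(8.9, 9.1)))
synergy_xy <- function(control, rab_only, both) {
  for (s in list(control, rab_only, both)) {
    abort_if(!inherits(s, "genotype_summary"),
             "all three arms must be genotype_summary objects")
  }
  h <- c(control$harmonic, rab_only$harmonic, both$harmonic)
  abort_if(length(unique(h)) != 1L,
           "arms summarize different harmonics: ", paste(h, collapse = ", "))
  structure(
    list(rab_id = if (!is.na(rab_only$rab_id)) rab_only$rab_id else both$rab_id,
         X = rab_only$mean - control$mean,
         Y = both$mean - rab_only$mean,
         se_X = sqrt(rab_only$se^2 + control$se^2),
         se_Y = sqrt(both$se^2 + rab_only$se^2),
         harmonic = control$harmonic),
    class = "synergy_point"
  )
}

#' @export
print.synergy_point <- function(x, ...) {
  cat(sprintf("Synergy point %s (%s): X = %.4g +/- %.3g, Y = %.4g +/- %.3g uV\n",
              if (is.na(x$rab_id)) "" else x$rab_id,
              if (is.na(x$harmonic)) "?" else x$harmonic,
              x$X, x$se_X, x$Y, x$se_Y))
  invisible(x)
}

#' Arm summaries and synergy points for a whole screen
#'
#' Aggregates a per-fly results table into per-(Rab, arm, harmonic)
#' summaries and the per-Rab synergy points for both harmonics.
#'
#' @param flies A [fly_results()] data frame.
#' @return A list with `summaries` (data frame: one row per rab x arm x
#'   harmonic) and `synergy` (data frame: one row per rab x harmonic with
#'   `X`, `Y`, `se_X`, `se_Y`).
#' @export
screen_summaries <- function(flies) {
  need <- c("fly_id", "genotype_label", "rab_id", "best_1F1", "best_2F1")
  abort_if(!is.data.frame(flies) || !all(need %in% names(flies)),
           "fly results need columns: ", paste(need, collapse = ", "))
  rabs <- sort(unique(flies$rab_id[!is.na(flies$rab_id)]))
  arm_values <- function(label, rab, col) {
    sel <- flies$genotype_label == label &
      (if (label %in% c("control", "g2019s_only")) is.na(flies$rab_id)
       else flies$rab_id %in% rab)
    flies[[col]][sel]
  }
  sum_rows <- list()
  syn_rows <- list()
  for (h in c("1F1", "2F1")) {
    col <- paste0("best_", h)
    ctrl <- summarize_genotype(arm_values("control", NA, col), h, "control")
    g2 <- summarize_genotype(arm_values("g2019s_only", NA, col), h, "g2019s_only")
    sum_rows <- c(sum_rows, list(summary_row(ctrl), summary_row(g2)))
    for (r in rabs) {
      ro <- summarize_genotype(arm_values("rab_only", r, col), h, "rab_only", r)
      bo <- summarize_genotype(arm_values("both", r, col), h, "both", r)
      sum_rows <- c(sum_rows, list(summary_row(ro), summary_row(bo)))
      sp <- synergy_xy(ctrl, ro, bo)
      syn_rows <- c(syn_rows, list(data.frame(
        rab_id = r, harmonic = h, X = sp$X, Y = sp$Y,
        se_X = sp$se_X, se_Y = sp$se_Y, stringsAsFactors = FALSE)))
    }
  }
  list(summaries = do.call(rbind, sum_rows),
       synergy = do.call(rbind, syn_rows))
}

summary_row <- function(s) {
  data.frame(rab_id = s$rab_id, genotype_label = s$genotype_label,
             harmonic = s$harmonic, n = s$n, mean = s$mean, se = s$se,
             median = s$median, iqr = s$iqr, stringsAsFactors = FALSE)
}
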