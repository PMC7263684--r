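# Contrast-response functions and per-fly best responses.
#
# For each fly and harmonic, amplitude is plotted against stimulus contrast
# (the CRF) and the fly's "best response" is the plain maximum over the
# contrast series -- no smoothing or curve fit -- taken independently for
# the 1F1 and 2F1 components, which may peak at different contrasts.

#' Build a contrast-response function
#'
#' Orders per-contrast harmonic measures by ascending contrast into one
#' CRF. Exactly one measure per contrast is required; duplicated or missing
#' contrasts are an error.
#'
#' @param measures A data frame with a `contrast` column and an amplitude
#'   column for the requested harmonic (`a_1F1` or `a_2F1`); an optional
#'   matching SNR column (`snr_1F1` / `snr_2F1`) is carried along.
#' @param harmonic `"1F1"` (photoreceptor component) or `"2F1"`
#'   (lamina-neuron component).
#' @param fly_id,genotype_label,rab_id Optional metadata carried on the CRF.
#' @return An object of class `"crf"`: list with `contrasts`, `amps`,
#'   `snr` (or `NULL`), `harmonic` and the metadata.
#' @export
#' @examples
#' m <- data.frame(contrast = c(0.5, 0.1, 1), a_1F1 = c(4, 1, 6))
#' build_crf(m, "1F1")
build_crf <- function(measures, harmonic = c("1F1", "2F1"),
                      fly_id = NA_character_, genotype_label = NA_character_,
                      rab_id = NA_character_) {
  harmonic <- match.arg(harmonic)
  acol <- paste0("a_", harmonic)
  abort_if(!is.data.frame(measures) ||
             !all(c("contrast", acol) %in% names(measures)),
           "'measures' needs columns 'contrast' and '", acol, "'")
  abort_if(nrow(measures) < 1L, "'measures' must be nonempty")
  abort_if(anyNA(measures$contrast) || anyNA(measures[[acol]]),
           "'measures' contains missing contrasts or amplitudes")
  abort_if(anyDuplicated(measures$contrast) > 0L,
           "duplicated contrast in CRF input")
  ord <- order(measures$contrast)
  scol <- paste0("snr_", harmonic)
  structure(
    list(contrasts = measures$contrast[ord],
         amps = measures[[acol]][ord],
         snr = if (scol %in% names(measures)) measures[[scol]][ord] else NULL,
         harmonic = harmonic, fly_id = fly_id,
         genotype_label = genotype_label, rab_id = rab_id),
    class = "crf"
  )
}

#' @export
print.crf <- function(x, ...) {
  cat(sprintf("CRF (%s%s): %d contrasts, max %.4g uV\n", x$harmonic,
              if (is.na(x$fly_id)) "" else paste0(", fly ", x$fly_id),
              length(x$contrasts), max(x$amps)))
  invisible(x)
}

#' @export
plot.crf <- function(x, ...) {
  graphics::plot(x$contrasts, x$amps, type = "b", xlab = "Michelson contrast",
                 ylab = sprintf("%s amplitude (µV)", x$harmonic), ...)
  invisible(x)
}

#' Best response of a fly
#'
#' The maximum CRF amplitude over the contrast series. Ties are broken in
#' favour of the lowest contrast achieving the maximum. An optional SNR
#' gate restricts the maximum to contrasts whose measure reached a minimum
#' signal-to-noise ratio; no gate is applied by default (the screen applies
#' no exclusion rule).
#'
#' @param crf A [build_crf()] object.
#' @param snr_min Optional minimum SNR; requires the CRF to carry SNR
#'   values. Contrasts below the gate are ignored; if none pass, 0 is
#'   returned with contrast `NA`.
#' @return The best amplitude (microvolts) with attributes `"contrast"`
#'   (the contrast achieving it) and `"index"`.
#' @export
#' @examples
#' best_response(build_crf(data.frame(contrast = 1:3 / 3, a_1F1 = c(1, 5, 3)), "1F1"))
best_response <- function(crf, snr_min = NULL) {
  abort_if(!inherits(crf, "crf"), "'crf' must be a crf object")
  abort_if(length(crf$amps) < 1L, "empty CRF")
  keep <- rep(TRUE, length(crf$amps))
  if (!is.null(snr_min)) {
    abort_if(is.null(crf$snr), "CRF carries no SNR values to gate on")
    keep <- crf$snr >= snr_min
    if (!any(keep)) {
      return(structure(0, contrast = NA_real_, index = NA_integer_))
    }
  }
  amps <- ifelse(keep, crf$amps, -Inf)
  i <- which.max(amps)  # first maximum = lowest contrast, grid is ascending
  structure(crf$amps[i], contrast = crf$contrasts[i], index = i)
}

#' Per-fly best responses for a harmonic table
#'
#' Builds both CRFs for every fly in a harmonic table and extracts the best
#' 1F1 and 2F1 responses.
#'
#' @param harmonics A data frame as produced by [extract_harmonic_table()]:
#'   one row per (fly, contrast) with columns `fly_id`, `genotype_label`,
#'   `rab_id`, `contrast`, `a_1F1`, `a_2F1` (and optional SNR columns).
#' @param snr_min Optional SNR gate passed to [best_response()].
#' @return A data frame with one row per fly: `fly_id`, `genotype_label`,
#'   `rab_id`, `best_1F1`, `best_2F1`, `best_contrast_1F1`,
#'   `best_contrast_2F1`.
#' @export
fly_results <- function(harmonics, snr_min = NULL) {
  need <- c("fly_id", "genotype_label", "rab_id", "contrast", "a_1F1", "a_2F1")
  abort_if(!is.data.frame(harmonics) || !all(need %in% names(harmonics)),
           "harmonic table needs columns: ", paste(need, collapse = ", "))
  rows <- lapply(split(harmonics, harmonics$fly_id), function(d) {
    out <- data.frame(fly_id = d$fly_id[1L],
                      genotype_label = d$genotype_label[1L],
                      rab_id = d$rab_id[1L], stringsAsFactors = FALSE)
    for (h in c("1F1", "2F1")) {
      b <- best_response(build_crf(d, h, fly_id = d$fly_id[1L]), snr_min)
      out[[paste0("best_", h)]] <- as.numeric(b)
      out[[paste0("best_contrast_", h)]] <- attr(b, "contrast")
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(match(res$fly_id, unique(harmonics$fly_id))), , drop = FALSE]
}
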