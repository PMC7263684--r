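# Batch harmonic extraction over a trace set.

#' Harmonic table of a trace set
#'
#' For every (fly, contrast) cell, transforms each repeat with
#' [amplitude_spectrum()], averages the repeats with [average_repeats()],
#' and extracts the 1F1/2F1 amplitudes and noise floors with
#' [extract_harmonics()].
#'
#' @param ts A `"trace_set"` from [simulate_screen()] or
#'   [read_trace_dataset()].
#' @param f1 Stimulus fundamental in Hz (default: the trace set's stimulus).
#' @param mode Repeat-averaging mode, `"incoherent"` (default) or
#'   `"coherent"`; see [average_repeats()].
#' @param k_noise Noise-floor bins per side (default 5).
#' @return A data frame with one row per (fly, contrast): `fly_id`,
#'   `genotype_label`, `rab_id`, `contrast`, `a_1F1`, `a_2F1`,
#'   `noise_1F1`, `noise_2F1`, `snr_1F1`, `snr_2F1`, `n_averaged`.
#' @export
extract_harmonic_table <- function(ts, f1 = NULL,
                                   mode = c("incoherent", "coherent"),
                                   k_noise = 5L) {
  mode <- match.arg(mode)
  abort_if(!inherits(ts, "trace_set"), "'ts' must be a trace_set")
  if (is.null(f1)) f1 <- ts$stimulus$f1
  fs <- ts$stimulus$sample_rate
  key <- paste(ts$meta$fly_id, ts$meta$contrast, sep = "\r")
  groups <- split(seq_len(nrow(ts$meta)), key)
  rows <- lapply(groups, function(idx) {
    spectra <- lapply(idx, function(j) {
      amplitude_spectrum(ts$voltage[, j], sample_rate = fs)
    })
    hm <- extract_harmonics(average_repeats(spectra, mode = mode),
                            f1 = f1, k_noise = k_noise)
    m <- ts$meta[idx[1L], ]
    data.frame(fly_id = m$fly_id, genotype_label = m$genotype_label,
               rab_id = m$rab_id, contrast = m$contrast,
               a_1F1 = hm$a_1F1, a_2F1 = hm$a_2F1,
               noise_1F1 = hm$noise_1F1, noise_2F1 = hm$noise_2F1,
               snr_1F1 = hm$snr_1F1, snr_2F1 = hm$snr_2F1,
               n_averaged = hm$n_averaged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(match(out$fly_id, unique(ts$meta$fly_id)), out$contrast), ,
      drop = FALSE]
}
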