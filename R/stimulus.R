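# Contrast-flicker stimulus definition and synthesis.
#
# A stimulus is sinusoidal luminance flicker about a fixed mean light level:
#   L(t) = mean_level * (1 + contrast * sin(2 pi f1 t))
# with Michelson contrast (Lmax - Lmin) / (Lmax + Lmin) equal to `contrast`.
# Epochs always hold a whole number of flicker cycles so that downstream
# FFT analysis is leakage-free.

#' Specify a contrast-flicker stimulus
#'
#' Defines one flicker stimulus: a sinusoidal luminance modulation at
#' fundamental frequency `f1` about a fixed mean level, with a given
#' Michelson contrast. The constructor enforces the constraints the analysis
#' relies on: no clipping (`mean_level * (1 + contrast) <= 1`), a whole
#' number of cycles per epoch (`f1 * duration` integral), and a sampling
#' rate that resolves at least the second harmonic (`sample_rate > 4 * f1`).
#'
#' @param f1 Fundamental flicker frequency in Hz. The rig frequency is
#'   configurable; 12 Hz is the package default and all downstream analysis
#'   reads `f1` from the spec rather than assuming it.
#' @param mean_level Mean luminance on a normalized 0--1 scale.
#' @param contrast Michelson contrast fraction in `[0, 1]`.
#' @param duration Epoch duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `"stimulus_spec"`.
#' @seealso [synthesize_stimulus()], [contrast_series()]
#' @export
#' @examples
#' stimulus_spec(contrast = 0.5)
stimulus_spec <- function(f1 = 12, mean_level = 0.5, contrast = 1,
                          duration = 1, sample_rate = 1000) {
  for (nm in c("f1", "mean_level", "contrast", "duration", "sample_rate")) {
    abort_if(!is_scalar_number(get(nm)), sprintf("'%s' must be a single finite number", nm))
  }
  abort_if(contrast < 0 || contrast > 1, "'contrast' must lie in [0, 1]")
  abort_if(mean_level <= 0 || mean_level > 1, "'mean_level' must lie in (0, 1]")
  abort_if(mean_level * (1 + contrast) > 1 + 1e-12,
           "stimulus would clip: mean_level * (1 + contrast) exceeds 1")
  abort_if(f1 <= 0 || duration <= 0, "'f1' and 'duration' must be positive")
  abort_if(abs(f1 * duration - round(f1 * duration)) > 1e-9,
           "'f1 * duration' must be a whole number of cycles")
  abort_if(sample_rate <= 4 * f1,
           "'sample_rate' must exceed 4 * f1 to resolve the second harmonic")
  structure(
    list(f1 = f1, mean_level = mean_level, contrast = contrast,
         duration = duration, sample_rate = sample_rate),
    class = "stimulus_spec"
  )
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf(
    "Flicker stimulus: %g Hz sine, mean level %.3g, Michelson contrast %.3g\n%g s epoch (%g cycles) sampled at %g Hz\n",
    x$f1, x$mean_level, x$contrast, x$duration, x$f1 * x$duration,
    x$sample_rate))
  invisible(x)
}

#' Build an equally spaced contrast series
#'
#' The screen presents each fly with a fixed set of contrasts spanning a
#' range (9 stimuli from 10% to 100% contrast in the reference protocol).
#' Contrasts are linearly spaced and include both endpoints.
#'
#' @param n Number of contrasts (at least 2).
#' @param c_min,c_max Lowest and highest Michelson contrast, `0 <= c_min <
#'   c_max <= 1`.
#' @return A strictly increasing numeric vector of length `n`.
#' @export
#' @examples
#' contrast_series(9, 0.10, 1.00)
contrast_series <- function(n = 9, c_min = 0.10, c_max = 1.00) {
  abort_if(!is_scalar_number(n) || n < 2 || n != round(n),
           "'n' must be an integer >= 2")
  abort_if(!is_scalar_number(c_min) || !is_scalar_number(c_max),
           "contrast bounds must be single numbers")
  abort_if(c_min < 0 || c_max > 1 || c_min >= c_max,
           "need 0 <= c_min < c_max <= 1")
  seq(c_min, c_max, length.out = n)
}

#' Synthesize the luminance waveform of a stimulus
#'
#' Samples `L(t) = mean_level * (1 + contrast * sin(2 pi f1 t))` on the
#' spec's time grid. The sample mean equals `mean_level` for every contrast
#' (integral cycles), so the mean light level is contrast-independent, and
#' the Michelson contrast of the waveform equals `spec$contrast`.
#'
#' @param spec A [stimulus_spec()].
#' @return A data frame with columns `time_s` and `luminance`; the spec is
#'   attached as attribute `"spec"`.
#' @export
#' @examples
#' w <- synthesize_stimulus(stimulus_spec(contrast = 0.5))
#' mean(w$luminance)
synthesize_stimulus <- function(spec) {
  abort_if(!inherits(spec, "stimulus_spec"), "'spec' must be a stimulus_spec")
  n <- round(spec$sample_rate * spec$duration)
  t <- (seq_len(n) - 1) / spec$sample_rate
  lum <- spec$mean_level * (1 + spec$contrast * sin(2 * pi * spec$f1 * t))
  structure(data.frame(time_s = t, luminance = lum), spec = spec)
}

#' Serialize a stimulus spec to JSON
#'
#' Writes exactly the five defining fields (`f1`, `mean_level`, `contrast`,
#' `duration`, `sample_rate`) as a JSON object.
#'
#' @param spec A [stimulus_spec()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
stimulus_to_json <- function(spec, path = NULL) {
  abort_if(!inherits(spec, "stimulus_spec"), "'spec' must be a stimulus_spec")
  js <- jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a stimulus spec from JSON
#'
#' @param x A JSON string or a path to a JSON file holding the five fields
#'   written by [stimulus_to_json()].
#' @return A [stimulus_spec()] (validated on construction).
#' @export
stimulus_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  need <- c("f1", "mean_level", "contrast", "duration", "sample_rate")
  abort_if(!all(need %in% names(obj)),
           "stimulus JSON must hold fields: ", paste(need, collapse = ", "))
  do.call(stimulus_spec, obj[need])
}
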