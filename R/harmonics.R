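# Frequency-domain decomposition of SSVEP traces.
#
# Each epoch holds a whole number of stimulus cycles, so a rectangular
# window is leakage-free and a sinusoid of peak amplitude A lands entirely
# in its own bin with one-sided amplitude A. The first harmonic (1F1) of
# the response is attributed to the photoreceptors, the second (2F1) to the
# lamina neurons; higher harmonics are not analyzed.

#' One-sided amplitude spectrum of a voltage trace
#'
#' Computes the FFT of a uniformly sampled trace and scales it so that a
#' pure sinusoid of peak amplitude A microvolts yields a bin amplitude of A
#' at its frequency. The DC bin carries the magnitude of the trace mean.
#' Complex one-sided coefficients are retained so repeats can later be
#' averaged coherently if desired.
#'
#' @param voltage Numeric vector of sampled voltage (microvolts), or a data
#'   frame with columns `time_s` and `voltage_uv` (uniform sampling is then
#'   checked and `sample_rate` inferred).
#' @param sample_rate Sampling rate in Hz (ignored when `voltage` is a data
#'   frame carrying a time column).
#' @return An object of class `"amplitude_spectrum"`: a list with `freqs`
#'   (Hz, spacing `1/duration` from 0), `amps` (one-sided amplitude per
#'   bin), `cplx` (complex one-sided coefficients, same scaling), `duration`
#'   (s), `sample_rate`, and `n_averaged` (1 for a single trace).
#' @export
#' @examples
#' t <- (0:999) / 1000
#' sp <- amplitude_spectrum(5 * sin(2 * pi * 12 * t), sample_rate = 1000)
#' sp$amps[sp$freqs == 12]
amplitude_spectrum <- function(voltage, sample_rate = NULL) {
  if (is.data.frame(voltage)) {
    abort_if(!all(c("time_s", "voltage_uv") %in% names(voltage)),
             "trace data frame needs columns 'time_s' and 'voltage_uv'")
    dt <- diff(voltage$time_s)
    abort_if(length(dt) < 1L, "trace must hold at least 2 samples")
    abort_if(any(dt <= 0) || diff(range(dt)) > 1e-9 * mean(dt),
             "trace is not uniformly sampled")
    sample_rate <- 1 / mean(dt)
    voltage <- voltage$voltage_uv
  }
  abort_if(!is.numeric(voltage) || length(voltage) < 2L,
           "trace must be numeric with at least 2 samples")
  abort_if(anyNA(voltage) || any(!is.finite(voltage)),
           "trace contains missing or non-finite samples")
  abort_if(!is_scalar_number(sample_rate) || sample_rate <= 0,
           "'sample_rate' must be a single positive number")
  n <- length(voltage)
  x <- stats::fft(voltage)
  half <- n %/% 2L
  idx <- seq_len(half + 1L)
  cplx <- x[idx] / n
  scale <- rep(2, half + 1L)
  scale[1L] <- 1                       # DC
  if (n %% 2L == 0L) scale[half + 1L] <- 1  # Nyquist bin is unpaired
  cplx <- cplx * scale
  structure(
    list(freqs = (idx - 1L) * sample_rate / n,
         amps = Mod(cplx),
         cplx = cplx,
         duration = n / sample_rate,
         sample_rate = sample_rate,
         n_averaged = 1L),
    class = "amplitude_spectrum"
  )
}

#' @export
print.amplitude_spectrum <- function(x, ...) {
  cat(sprintf(
    "Amplitude spectrum: %d bins, 0-%.6g Hz (resolution %.6g Hz), %d repeat(s) averaged\n",
    length(x$freqs), max(x$freqs), 1 / x$duration, x$n_averaged))
  invisible(x)
}

#' @export
plot.amplitude_spectrum <- function(x, fmax = NULL, ...) {
  keep <- if (is.null(fmax)) rep(TRUE, length(x$freqs)) else x$freqs <= fmax
  graphics::plot(x$freqs[keep], x$amps[keep], type = "h",
                 xlab = "Frequency (Hz)", ylab = "Amplitude (µV)", ...)
  invisible(x)
}

#' Average repeat spectra
#'
#' Responses to a series of identical stimuli are transformed individually
#' and then averaged bin-wise. The default (`"incoherent"`) averages
#' amplitudes, which is robust to phase drift between repeats; the
#' `"coherent"` mode averages the complex coefficients before taking the
#' modulus, which suppresses non-phase-locked noise but assumes stable
#' phase.
#'
#' @param spectra A list of [amplitude_spectrum()] objects on an identical
#'   frequency grid.
#' @param mode `"incoherent"` (mean of amplitudes, default) or `"coherent"`
#'   (modulus of mean complex spectrum).
#' @return An `"amplitude_spectrum"` with `n_averaged` equal to the total
#'   number of repeats combined.
#' @export
average_repeats <- function(spectra, mode = c("incoherent", "coherent")) {
  mode <- match.arg(mode)
  abort_if(!is.list(spectra) || length(spectra) == 0L ||
             !all(vapply(spectra, inherits, logical(1), "amplitude_spectrum")),
           "'spectra' must be a nonempty list of amplitude_spectrum objects")
  f0 <- spectra[[1L]]$freqs
  same <- vapply(spectra, function(s) {
    length(s$freqs) == length(f0) && max(abs(s$freqs - f0)) <= 1e-9
  }, logical(1))
  abort_if(!all(same), "spectra are not on a common frequency grid")
  out <- spectra[[1L]]
  if (mode == "incoherent") {
    out$amps <- rowMeans(vapply(spectra, `[[`, numeric(length(f0)), "amps"))
    out$cplx <- NULL
  } else {
    cm <- Reduce(`+`, lapply(spectra, `[[`, "cplx")) / length(spectra)
    out$cplx <- cm
    out$amps <- Mod(cm)
  }
  out$n_averaged <- sum(vapply(spectra, `[[`, integer(1), "n_averaged"))
  out
}

# bins used for the local noise floor around harmonic bin `bin`:
# up to k nearest bins per side, skipping DC and every harmonic of f1
noise_floor_bins <- function(bin, nbins, f1_bin, k) {
  harm <- seq(1L, nbins, by = f1_bin)          # 1-based indices of m*f1 bins
  pick <- function(step) {
    sel <- integer(0)
    b <- bin
    while (length(sel) < k) {
      b <- b + step
      if (b < 2L || b > nbins) break
      if (b %in% harm) next
      sel <- c(sel, b)
    }
    sel
  }
  c(rev(pick(-1L)), pick(+1L))
}

#' Extract 1F1 and 2F1 harmonic amplitudes
#'
#' Reads the response amplitude at the stimulus fundamental (1F1,
#' photoreceptor component) and its double (2F1, lamina-neuron component)
#' from exact FFT bins, and estimates a local noise floor for each as the
#' mean amplitude of the `k` nearest bins on each side, excluding DC and
#' every harmonic of `f1`. Both harmonics must fall exactly on the
#' frequency grid; off-grid frequencies are an error, never silently
#' rounded.
#'
#' @param spectrum An [amplitude_spectrum()] (possibly repeat-averaged).
#' @param f1 Stimulus fundamental frequency in Hz.
#' @param k_noise Number of noise bins per side of each harmonic (default 5).
#' @return An object of class `"harmonic_measure"`: a list with `a_1F1`,
#'   `a_2F1` (microvolts), `noise_1F1`, `noise_2F1` (local noise floors),
#'   `snr_1F1`, `snr_2F1` (amplitude / floor; 0 when the amplitude is 0, by
#'   convention), `f1`, and `n_averaged`.
#' @export
#' @examples
#' t <- (0:999) / 1000
#' v <- 5 * sin(2 * pi * 12 * t) + 2 * sin(2 * pi * 24 * t)
#' extract_harmonics(amplitude_spectrum(v, 1000), f1 = 12)
extract_harmonics <- function(spectrum, f1, k_noise = 5L) {
  abort_if(!inherits(spectrum, "amplitude_spectrum"),
           "'spectrum' must be an amplitude_spectrum")
  abort_if(!is_scalar_number(f1) || f1 <= 0, "'f1' must be a positive number")
  abort_if(!is_scalar_number(k_noise) || k_noise < 1,
           "'k_noise' must be a positive count")
  r <- f1 * spectrum$duration
  abort_if(abs(r - round(r)) > 1e-9,
           "f1 is off the frequency grid (non-integral cycles); refusing nearest-bin fallback")
  f1_bin <- as.integer(round(r))
  nbins <- length(spectrum$freqs)
  i1 <- f1_bin + 1L
  i2 <- 2L * f1_bin + 1L
  abort_if(i2 > nbins || 2 * f1 >= spectrum$sample_rate / 2,
           "2*f1 exceeds the Nyquist range of this spectrum")
  floor_of <- function(bin) {
    sel <- noise_floor_bins(bin, nbins, f1_bin, as.integer(k_noise))
    if (length(sel) == 0L) return(0)
    mean(spectrum$amps[sel])
  }
  a1 <- spectrum$amps[i1]
  a2 <- spectrum$amps[i2]
  n1 <- floor_of(i1)
  n2 <- floor_of(i2)
  snr <- function(a, nf) {
    if (a == 0) 0 else if (nf > 0) a / nf else Inf
  }
  structure(
    list(a_1F1 = a1, a_2F1 = a2, noise_1F1 = n1, noise_2F1 = n2,
         snr_1F1 = snr(a1, n1), snr_2F1 = snr(a2, n2),
         f1 = f1, n_averaged = spectrum$n_averaged),
    class = "harmonic_measure"
  )
}

#' @export
print.harmonic_measure <- function(x, ...) {
  cat(sprintf(
    "Harmonics of %g Hz flicker (%d repeat(s)):\n  1F1 %.4g uV (floor %.3g, SNR %.3g)\n  2F1 %.4g uV (floor %.3g, SNR %.3g)\n",
    x$f1, x$n_averaged, x$a_1F1, x$noise_1F1, x$snr_1F1,
    x$a_2F1, x$noise_2F1, x$snr_2F1))
  invisible(x)
}
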