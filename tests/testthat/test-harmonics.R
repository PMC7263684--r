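# FFT harmonic decomposition, repeat averaging, noise floors.

test_that("amplitude spectrum matches a direct-summation DFT oracle", {
  fs <- 1000
  t <- (0:999) / fs
  v <- 5 * sin(2 * pi * 12 * t) + 2 * sin(2 * pi * 24 * t)
  sp <- amplitude_spectrum(v, fs)
  expect_equal(sp$amps[sp$freqs == 12], 5, tolerance = 1e-9)
  expect_equal(sp$amps[sp$freqs == 24], 2, tolerance = 1e-9)
  for (f in c(0, 7, 12, 24, 100)) {
    expect_equal(sp$amps[sp$freqs == f], dft_amp_oracle(v, fs, f),
                 tolerance = 1e-9)
  }
  expect_true(all(amplitude_spectrum(rep(0, 64), 64)$amps == 0))
})

test_that("squared sinusoid splits into DC and second harmonic", {
  t <- (0:999) / 1000
  v <- sin(2 * pi * 12 * t)^2  # = 1/2 - cos(2 pi 24 t)/2
  sp <- amplitude_spectrum(v, 1000)
  expect_equal(sp$amps[sp$freqs == 0], 0.5, tolerance = 1e-9)
  expect_equal(sp$amps[sp$freqs == 24], 0.5, tolerance = 1e-9)
  expect_equal(sp$amps[sp$freqs == 12], 0, tolerance = 1e-9)
})

test_that("spectrum input validation rejects bad traces", {
  expect_error(amplitude_spectrum(c(1), 100), "at least 2")
  expect_error(amplitude_spectrum(c(1, NA, 3), 100), "missing")
  bad <- data.frame(time_s = c(0, 0.1, 0.5), voltage_uv = 1:3)
  expect_error(amplitude_spectrum(bad), "not uniformly sampled")
})

test_that("repeat averaging is bin-wise and validates grids", {
  t <- (0:199) / 200
  sp1 <- amplitude_spectrum(sin(2 * pi * 10 * t), 200)
  sp2 <- amplitude_spectrum(3 * sin(2 * pi * 10 * t), 200)
  avg <- average_repeats(list(sp1, sp2))
  expect_equal(avg$n_averaged, 2L)
  expect_equal(avg$amps[avg$freqs == 10], 2, tolerance = 1e-9)  # mean(1, 3)
  same <- average_repeats(list(sp1, sp1))
  expect_equal(same$amps, sp1$amps, tolerance = 1e-12)
  other <- amplitude_spectrum(sin(2 * pi * 10 * (0:99) / 200), 200)
  expect_error(average_repeats(list(sp1, other)), "common frequency grid")
})

test_that("coherent averaging cancels phase-random noise faster", {
  t <- (0:199) / 200
  set.seed(41)
  reps <- lapply(1:20, function(i) {
    amplitude_spectrum(2 * sin(2 * pi * 10 * t) + rnorm(200, 0, 1), 200)
  })
  inc <- average_repeats(reps, mode = "incoherent")
  coh <- average_repeats(reps, mode = "coherent")
  off <- inc$freqs != 10 & inc$freqs != 0
  expect_lt(mean(coh$amps[off]), mean(inc$amps[off]))
  expect_equal(coh$amps[coh$freqs == 10], 2, tolerance = 0.2)
})

test_that("averaging five repeats shrinks the harmonic-bin spread ~ sqrt(5)", {
  t <- (0:199) / 200
  base <- 2 * sin(2 * pi * 10 * t)
  one_amp <- function() {
    sp <- amplitude_spectrum(base + rnorm(200, 0, 1.5), 200)
    sp$amps[sp$freqs == 10]
  }
  avg_amp <- function() {
    av <- average_repeats(lapply(1:5, function(i) {
      amplitude_spectrum(base + rnorm(200, 0, 1.5), 200)
    }))
    av$amps[av$freqs == 10]
  }
  set.seed(7)
  singles <- replicate(400, one_amp())
  avgs <- replicate(400, avg_amp())
  ratio <- sd(singles) / sd(avgs)
  expect_gt(ratio, sqrt(5) * 0.75)
  expect_lt(ratio, sqrt(5) * 1.25)
})

test_that("harmonic extraction reads exact bins and refuses off-grid f1", {
  t <- (0:999) / 1000
  v <- 5 * sin(2 * pi * 12 * t) + 2 * sin(2 * pi * 24 * t)
  hm <- extract_harmonics(amplitude_spectrum(v, 1000), f1 = 12)
  expect_equal(hm$a_1F1, 5, tolerance = 1e-9)
  expect_equal(hm$a_2F1, 2, tolerance = 1e-9)
  expect_equal(hm$noise_1F1, 0, tolerance = 1e-12)
  expect_equal(hm$noise_2F1, 0, tolerance = 1e-12)
  expect_error(extract_harmonics(amplitude_spectrum(v, 1000), f1 = 12.3),
               "off the frequency grid")
  expect_error(extract_harmonics(amplitude_spectrum(v, 1000), f1 = 400),
               "Nyquist")
})

test_that("zero spectrum yields zero measures with SNR 0 by convention", {
  hm <- extract_harmonics(amplitude_spectrum(rep(0, 200), 200), f1 = 10)
  expect_equal(hm$a_1F1, 0)
  expect_equal(hm$a_2F1, 0)
  expect_equal(hm$snr_1F1, 0)
  expect_equal(hm$snr_2F1, 0)
})

test_that("noise floor skips DC and all stimulus harmonics", {
  # energy only at harmonics of f1: the floor must be exactly zero even
  # though 3F1 sits within 5 bins of 2F1
  t <- (0:999) / 1000
  v <- 5 * sin(2 * pi * 12 * t) + 2 * sin(2 * pi * 24 * t) +
    1 * sin(2 * pi * 36 * t)
  hm <- extract_harmonics(amplitude_spectrum(v, 1000), f1 = 12)
  expect_equal(hm$noise_1F1, 0, tolerance = 1e-12)
  expect_equal(hm$noise_2F1, 0, tolerance = 1e-12)
  # and the 3F1 component does not leak into the extracted amplitudes
  expect_equal(hm$a_1F1, 5, tolerance = 1e-9)
  expect_equal(hm$a_2F1, 2, tolerance = 1e-9)
})

test_that("pure-noise traces give mean SNR near 1", {
  set.seed(11)
  snrs <- replicate(500, {
    hm <- extract_harmonics(amplitude_spectrum(rnorm(200, 0, 1), 200), f1 = 10)
    c(hm$snr_1F1, hm$snr_2F1)
  })
  expect_gt(mean(snrs), 0.9)
  expect_lt(mean(snrs), 1.2)
})

test_that("extraction is linear in trace amplitude", {
  t <- (0:499) / 500
  set.seed(3)
  v <- 4 * sin(2 * pi * 10 * t) + 1.5 * sin(2 * pi * 20 * t) + rnorm(500, 0, 0.5)
  for (k in c(0.5, 2, 7)) {
    h1 <- extract_harmonics(amplitude_spectrum(v, 500), 10)
    hk <- extract_harmonics(amplitude_spectrum(k * v, 500), 10)
    expect_equal(hk$a_1F1, k * h1$a_1F1, tolerance = 1e-9)
    expect_equal(hk$a_2F1, k * h1$a_2F1, tolerance = 1e-9)
  }
})
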