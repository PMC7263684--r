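# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the DFT oracle is a direct O(N) correlation sum
# (not stats::fft), and the Fisher oracle enumerates tables with choose().

# one-sided amplitude at frequency f of a uniformly sampled signal
dft_amp_oracle <- function(v, fs, f) {
  n <- length(v)
  t <- (seq_len(n) - 1) / fs
  z <- sum(v * exp(-2i * pi * f * t)) / n
  if (f == 0) Mod(z) else 2 * Mod(z)
}

# two-sided Fisher exact p by exhaustive enumeration over the margins
fisher_p_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# tiny noiseless screen helpers
tiny_stimulus <- function() {
  stimulus_spec(f1 = 10, mean_level = 0.5, contrast = 1,
                duration = 0.5, sample_rate = 200)
}

tiny_design <- function(rabs = "Rab7", n_flies = 1, n_contrasts = 2,
                        n_repeats = 1, noise_sd = 0, cv = 0, seed = 1L) {
  screen_design(
    rab_ids = rabs, n_flies_per_arm = n_flies,
    contrasts = if (n_contrasts == 1) 1 else
      contrast_series(n_contrasts, 0.10, 1.00),
    n_repeats = n_repeats, stimulus = tiny_stimulus(),
    population = fly_params(noise_sd = noise_sd),
    cv = cv, seed = seed
  )
}
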