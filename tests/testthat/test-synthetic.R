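# Generative model: deterministic amplitudes, trace simulation, fly
# variability, whole-screen simulation.

test_that("deterministic amplitudes follow the closed forms", {
  fp <- fly_params(r_max_P = 10, c50 = 0.3, hill_n = 2, g_L = 0.05)
  eff <- genotype_effect("control")
  a0 <- deterministic_amplitudes(fp, eff, 0)
  expect_equal(a0$A1, 0)
  expect_equal(a0$A2, 0)
  a <- deterministic_amplitudes(fp, eff, 0.3)  # c = c50: half saturation
  expect_equal(a$A1, 5)
  expect_equal(a$A2, 1.25)  # 0.05 * 25
  # monotone nondecreasing in contrast
  cc <- seq(0, 1, by = 0.05)
  expect_true(all(diff(deterministic_amplitudes(fp, eff, cc)$A1) >= 0))
})

test_that("synergy multipliers act only in the both arm", {
  fp <- fly_params()
  rab <- genotype_effect("rab_only", "Rab7", synergy_P = 3, synergy_L = 8)
  both <- genotype_effect("both", "Rab7", synergy_P = 3, synergy_L = 8)
  plain <- genotype_effect("rab_only", "Rab7")
  expect_equal(deterministic_amplitudes(fp, rab, 0.5),
               deterministic_amplitudes(fp, plain, 0.5))
  b <- deterministic_amplitudes(fp, both, 0.5)
  p <- deterministic_amplitudes(fp, plain, 0.5)
  expect_equal(b$A1, 3 * p$A1)
  expect_equal(b$A2, 8 * 9 * p$A2)  # synergy_L * synergy_P^2 through A1^2
})

test_that("noiseless traces return the generating amplitudes through the FFT", {
  fp <- fly_params(noise_sd = 0, phase1 = 0.7, phase2 = -1.1)
  eff <- genotype_effect("both", "Rab7", synergy_L = 4)
  for (ct in c(0.1, 0.45, 1)) {
    spec <- stimulus_spec(f1 = 12, contrast = ct, duration = 1,
                          sample_rate = 600)
    tr <- simulate_trace(fp, eff, spec)
    truth <- deterministic_amplitudes(fp, eff, ct)
    hm <- extract_harmonics(amplitude_spectrum(tr$voltage_uv, 600), 12)
    expect_equal(hm$a_1F1, truth$A1, tolerance = 1e-9)
    expect_equal(hm$a_2F1, truth$A2, tolerance = 1e-9)
    # cross-check against the direct-summation oracle as well
    expect_equal(dft_amp_oracle(tr$voltage_uv, 600, 12), truth$A1,
                 tolerance = 1e-9)
  }
})

test_that("trace simulation is seeded and degenerate cases are exact", {
  spec <- stimulus_spec(f1 = 10, contrast = 0.5, duration = 0.5,
                        sample_rate = 200)
  fp <- fly_params(noise_sd = 1)
  eff <- genotype_effect("control")
  t1 <- simulate_trace(fp, eff, spec, seed = 99)
  t2 <- simulate_trace(fp, eff, spec, seed = 99)
  expect_identical(t1$voltage_uv, t2$voltage_uv)
  zero <- simulate_trace(fly_params(r_max_P = 0, g_L = 0, noise_sd = 0),
                         eff, spec)
  expect_true(all(zero$voltage_uv == 0))
})

test_that("fly parameter draws have the requested lognormal spread", {
  pop <- fly_params()
  expect_identical(sample_fly_params(pop, cv = 0), pop)
  set.seed(5)
  draws <- replicate(10000, sample_fly_params(pop, cv = 0.3)$r_max_P)
  expect_equal(mean(draws), pop$r_max_P, tolerance = 0.02 * pop$r_max_P)
  cv_hat <- sd(draws) / mean(draws)
  expect_gt(cv_hat, 0.27)
  expect_lt(cv_hat, 0.33)
  s1 <- sample_fly_params(pop, cv = 0.3, seed = 12)
  s2 <- sample_fly_params(pop, cv = 0.3, seed = 12)
  expect_identical(s1, s2)
})

test_that("screen simulation emits every arm once and is reproducible", {
  d <- tiny_design(rabs = "Rab7", n_flies = 1, n_contrasts = 1, n_repeats = 1)
  ts <- simulate_screen(d, null_screen_effects("Rab7"))
  expect_equal(ncol(ts$voltage), 4)  # 4 arms x 1 fly x 1 contrast x 1 repeat
  expect_setequal(ts$meta$genotype_label,
                  c("control", "g2019s_only", "rab_only", "both"))
  d2 <- tiny_design(rabs = c("RabA", "RabB"), n_flies = 2, n_contrasts = 3,
                    n_repeats = 2, noise_sd = 1, cv = 0.2, seed = 42)
  eff <- null_screen_effects(c("RabA", "RabB"))
  ts1 <- simulate_screen(d2, eff)
  ts2 <- simulate_screen(d2, eff)
  expect_identical(ts1$voltage, ts2$voltage)
  expect_identical(ts1$meta, ts2$meta)
  # (2 shared + 4 rab arms) x 2 flies x 3 contrasts x 2 repeats
  expect_equal(ncol(ts1$voltage), 6 * 2 * 3 * 2)
})

test_that("missing arms in the effects table are an invalid design", {
  d <- tiny_design(rabs = "Rab7")
  eff <- null_screen_effects("Rab7")
  expect_error(simulate_screen(d, eff[eff$label != "both", ]),
               "invalid design")
  expect_error(simulate_screen(d, eff[eff$label != "control", ]),
               "invalid design")
})

test_that("with lamina synergy the both arm dominates all others in A2", {
  fp <- fly_params()
  for (sL in c(1.5, 4, 8)) {
    a2 <- sapply(c("control", "g2019s_only", "rab_only", "both"), function(l) {
      deterministic_amplitudes(
        fp, genotype_effect(l, "RabX", synergy_L = sL), 1)$A2
    })
    expect_gt(a2[["both"]], max(a2[c("control", "g2019s_only", "rab_only")]))
  }
})

test_that("noiseless screen reproduces closed-form amplitudes end to end", {
  d <- tiny_design(rabs = "Rab7", n_flies = 2, n_contrasts = 3, n_repeats = 2,
                   noise_sd = 0, cv = 0)
  eff <- recovery_screen_effects("Rab7")
  eff$synergy_L[eff$rab_id %in% "Rab7"] <- 6
  ts <- simulate_screen(d, eff)
  ht <- extract_harmonic_table(ts)
  for (i in seq_len(nrow(ht))) {
    lab <- ht$genotype_label[i]
    truth <- deterministic_amplitudes(
      d$population,
      genotype_effect(lab, ht$rab_id[i],
                      gain_P = eff$gain_P[match(lab, eff$label)],
                      gain_L = eff$gain_L[match(lab, eff$label)],
                      synergy_P = eff$synergy_P[match(lab, eff$label)],
                      synergy_L = eff$synergy_L[match(lab, eff$label)]),
      ht$contrast[i])
    expect_equal(ht$a_1F1[i], truth$A1, tolerance = 1e-9)
    expect_equal(ht$a_2F1[i], truth$A2, tolerance = 1e-9)
  }
})
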