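# Built-in screen scenarios.
#
# The reference scenario mirrors the qualitative outcome of the published
# screen: among 23 Rabs, three show strong lamina synergy with G2019S
# (one of them lamina-only, the standout), three have a large solo effect
# with no synergy, and the rest are neutral. The null scenario sets every
# multiplier to 1 and is used for calibration.

#' Rab identifiers of the screen
#'
#' The 23 fly Rab GTPases used by the built-in scenarios.
#' @return A character vector of length 23.
#' @export
screen_rab_ids <- function() {
  c("Rab1", "Rab2", "Rab3", "Rab4", "Rab5", "Rab6", "Rab7", "Rab8", "Rab9",
    "Rab10", "Rab11", "Rab14", "Rab18", "Rab19", "Rab21", "Rab23", "Rab26",
    "Rab27", "Rab30", "Rab32", "Rab35", "Rab39", "Rab40")
}

#' Genotype-effect table of the reference (recovery) scenario
#'
#' Three synergy Rabs: Rab10 with lamina-only synergy (`synergy_L = 8`,
#' `synergy_P = 1`; the standout whose lamina response far exceeds its
#' photoreceptor drive), and Rab14 / Rab27 with coupled synergy acting on
#' both stages (`synergy_L = 6`, `synergy_P = 1.5` and `synergy_L = 5`,
#' `synergy_P = 1.3`). The coupled pair share the same G2019S-induced
#' lamina-to-photoreceptor response ratio, so they sit on one signaling
#' regression line with the neutral Rabs while Rab10 lies far above it.
#' Three solo-effect Rabs (Rab3, Rab32, Rab1) have elevated gains in both
#' Rab-carrying arms (`gain_P = 1.8`, `gain_L = 2.5`) but no synergy. All
#' other multipliers are 1.
#'
#' @param rab_ids Rab identifiers (default [screen_rab_ids()]).
#' @return A data frame suitable for [simulate_screen()].
#' @export
recovery_screen_effects <- function(rab_ids = screen_rab_ids()) {
  eff <- null_screen_effects(rab_ids)
  syn <- data.frame(rab_id = c("Rab10", "Rab14", "Rab27"),
                    synergy_L = c(8, 6, 5),
                    synergy_P = c(1, 1.5, 1.3))
  for (i in seq_len(nrow(syn))) {
    sel <- eff$rab_id %in% syn$rab_id[i]   # synergy gated to 'both' downstream
    eff$synergy_L[sel] <- syn$synergy_L[i]
    eff$synergy_P[sel] <- syn$synergy_P[i]
  }
  solo <- eff$rab_id %in% c("Rab3", "Rab32", "Rab1")
  eff$gain_P[solo] <- 1.8
  eff$gain_L[solo] <- 2.5
  eff
}

#' Genotype-effect table with every multiplier equal to 1
#'
#' The null scenario: no Rab has any effect and there is no synergy, so
#' the expected synergy coordinates are `E[X] = E[Y] = 0` for every Rab.
#'
#' @param rab_ids Rab identifiers.
#' @return A data frame suitable for [simulate_screen()].
#' @export
null_screen_effects <- function(rab_ids = screen_rab_ids()) {
  rbind(
    data.frame(rab_id = NA_character_, label = c("control", "g2019s_only"),
               gain_P = 1, gain_L = 1, synergy_P = 1, synergy_L = 1,
               stringsAsFactors = FALSE),
    expand.grid(rab_id = rab_ids, label = c("rab_only", "both"),
                gain_P = 1, gain_L = 1, synergy_P = 1, synergy_L = 1,
                stringsAsFactors = FALSE)
  )
}

#' Design of the reference recovery screen
#'
#' 23 Rabs, 10 flies per arm, 9 contrasts from 10% to 100%, 5 repeats:
#' the geometry of the published protocol, with a 12 Hz sine flicker
#' sampled at 500 Hz for 1 s epochs, moderate recording noise (1 uV per
#' sample) and 10% fly-to-fly lognormal gain variability.
#'
#' @param seed Integer global seed.
#' @param n_flies_per_arm Flies per arm (default 10).
#' @return A [screen_design()].
#' @export
recovery_screen_design <- function(seed = 1L, n_flies_per_arm = 10) {
  screen_design(
    rab_ids = screen_rab_ids(),
    n_flies_per_arm = n_flies_per_arm,
    contrasts = contrast_series(9, 0.10, 1.00),
    n_repeats = 5,
    stimulus = stimulus_spec(f1 = 12, mean_level = 0.5, contrast = 1,
                             duration = 1, sample_rate = 500),
    population = fly_params(r_max_P = 10, c50 = 0.3, hill_n = 2,
                            g_L = 0.05, noise_sd = 1),
    cv = 0.1, seed = seed
  )
}

#' Small null-screen design for calibration runs
#'
#' A deliberately small design (4 Rabs, 5 flies per arm, 3 contrasts, 1
#' repeat, 0.5 s epochs at 120 Hz) used to check that the synergy
#' coordinates are centred on zero when no genotype has any effect.
#'
#' @param seed Integer global seed.
#' @return A [screen_design()].
#' @export
null_screen_design <- function(seed = 1L) {
  screen_design(
    rab_ids = c("RabA", "RabB", "RabC", "RabD"),
    n_flies_per_arm = 5,
    contrasts = contrast_series(3, 0.10, 1.00),
    n_repeats = 1,
    stimulus = stimulus_spec(f1 = 12, mean_level = 0.5, contrast = 1,
                             duration = 0.5, sample_rate = 120),
    population = fly_params(r_max_P = 10, c50 = 0.3, hill_n = 2,
                            g_L = 0.05, noise_sd = 1),
    cv = 0.1, seed = seed
  )
}
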