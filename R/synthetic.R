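# Generative model for synthetic SSVEP screens.
#
# Photoreceptor stage: Naka-Rushton contrast nonlinearity
#   A1(c) = gain_P * r_max_P * c^n / (c^n + c50^n)
# Lamina stage: static quadratic, converting fundamental drive into a pure
# second harmonic
#   A2(c) = gain_L * g_L * A1(c)^2
# Genotype arms multiply the stage gains; a synergy multiplier applies only
# when both the Rab and LRRK2-G2019S transgenes are expressed ("both" arm).
# Fly-to-fly variability is lognormal on the positive parameters; recording
# noise is additive white Gaussian on the voltage trace.

GENOTYPE_LABELS <- c("control", "g2019s_only", "rab_only", "both")

#' Photoreceptor/lamina parameters of one fly
#'
#' @param r_max_P Photoreceptor saturation amplitude in microvolts.
#' @param c50 Semi-saturation contrast (fraction in (0, 1]).
#' @param hill_n Naka-Rushton exponent (> 0).
#' @param g_L Lamina gain in uV per uV^2: second-harmonic amplitude per
#'   squared photoreceptor amplitude.
#' @param phase1,phase2 Response phases (radians) of the first and second
#'   harmonic.
#' @param noise_sd Standard deviation of additive Gaussian recording noise
#'   (microvolts per sample).
#' @return An object of class `"fly_params"`.
#' @export
fly_params <- function(r_max_P = 10, c50 = 0.3, hill_n = 2, g_L = 0.05,
                       phase1 = 0, phase2 = 0, noise_sd = 1) {
  abort_if(r_max_P < 0, "'r_max_P' must be nonnegative")
  abort_if(c50 <= 0 || c50 > 1, "'c50' must lie in (0, 1]")
  abort_if(hill_n <= 0, "'hill_n' must be positive")
  abort_if(g_L < 0, "'g_L' must be nonnegative")
  abort_if(noise_sd < 0, "'noise_sd' must be nonnegative")
  structure(list(r_max_P = r_max_P, c50 = c50, hill_n = hill_n, g_L = g_L,
                 phase1 = phase1, phase2 = phase2, noise_sd = noise_sd),
            class = "fly_params")
}

#' Genotype gain effects for one screen arm
#'
#' Each arm of the screen (no transgene, G2019S only, Rab only, or both)
#' carries multiplicative gain effects on the photoreceptor and lamina
#' stages. The synergy multipliers model a genetic interaction: they are
#' applied only when `label == "both"`, i.e. when the Rab and the
#' LRRK2-G2019S kinase are co-expressed in dopaminergic neurons.
#'
#' @param label One of `"control"`, `"g2019s_only"`, `"rab_only"`, `"both"`.
#' @param rab_id Rab identifier, or `NA` for the shared arms without a Rab
#'   transgene.
#' @param gain_P,gain_L Positive gain multipliers on the photoreceptor
#'   amplitude and the lamina gain.
#' @param synergy_P,synergy_L Positive extra multipliers applied only in the
#'   `"both"` arm; ignored (with their value retained for bookkeeping) in
#'   every other arm.
#' @return An object of class `"genotype_effect"`.
#' @export
genotype_effect <- function(label, rab_id = NA_character_,
                            gain_P = 1, gain_L = 1,
                            synergy_P = 1, synergy_L = 1) {
  label <- match.arg(label, GENOTYPE_LABELS)
  abort_if(any(c(gain_P, gain_L, synergy_P, synergy_L) <= 0),
           "all gain and synergy multipliers must be positive")
  structure(list(label = label, rab_id = rab_id,
                 gain_P = gain_P, gain_L = gain_L,
                 synergy_P = synergy_P, synergy_L = synergy_L),
            class = "genotype_effect")
}

#' Noise-free harmonic amplitudes for a fly, arm and contrast
#'
#' Closed-form expected amplitudes of the two harmonics:
#' `A1 = gain_P * (synergy_P) * r_max_P * c^n / (c^n + c50^n)` and
#' `A2 = gain_L * (synergy_L) * g_L * A1^2`, where the synergy factors enter
#' only in the `"both"` arm. Vectorized over `contrast`.
#'
#' @param fly A [fly_params()].
#' @param effect A [genotype_effect()].
#' @param contrast Michelson contrast(s) in `[0, 1]`.
#' @return A list with numeric vectors `A1` and `A2` (microvolts).
#' @export
#' @examples
#' fp <- fly_params(r_max_P = 10, c50 = 0.3, hill_n = 2, g_L = 0.05)
#' deterministic_amplitudes(fp, genotype_effect("control"), 0.3)
deterministic_amplitudes <- function(fly, effect, contrast) {
  abort_if(!inherits(fly, "fly_params"), "'fly' must be a fly_params")
  abort_if(!inherits(effect, "genotype_effect"),
           "'effect' must be a genotype_effect")
  abort_if(any(contrast < 0 | contrast > 1), "'contrast' must lie in [0, 1]")
  syn_on <- effect$label == "both"
  gP <- effect$gain_P * if (syn_on) effect$synergy_P else 1
  gL <- effect$gain_L * if (syn_on) effect$synergy_L else 1
  cn <- contrast^fly$hill_n
  a1 <- gP * fly$r_max_P * cn / (cn + fly$c50^fly$hill_n)
  a2 <- gL * fly$g_L * a1^2
  list(A1 = a1, A2 = a2)
}

#' Simulate one SSVEP voltage trace
#'
#' Generates `V(t) = A1 sin(2 pi f1 t + phase1) + A2 sin(2 pi 2 f1 t +
#' phase2) + N(0, noise_sd^2)` on the spec's time grid, with `A1`, `A2`
#' from [deterministic_amplitudes()] at the spec's contrast.
#'
#' @param fly A [fly_params()].
#' @param effect A [genotype_effect()].
#' @param spec A [stimulus_spec()]; its `contrast` field sets the stimulus.
#' @param seed Optional integer; when given, the trace is reproducible and
#'   the caller's RNG state is untouched.
#' @return A data frame with columns `time_s`, `voltage_uv`; attributes
#'   `"sample_rate"`, `"meta"` (list with the arm label, rab and contrast)
#'   and `"truth"` (the generating `A1`, `A2`).
#' @export
simulate_trace <- function(fly, effect, spec, seed = NULL) {
  abort_if(!inherits(spec, "stimulus_spec"), "'spec' must be a stimulus_spec")
  amps <- deterministic_amplitudes(fly, effect, spec$contrast)
  n <- round(spec$sample_rate * spec$duration)
  t <- (seq_len(n) - 1) / spec$sample_rate
  v <- amps$A1 * sin(2 * pi * spec$f1 * t + fly$phase1) +
    amps$A2 * sin(2 * pi * 2 * spec$f1 * t + fly$phase2)
  if (fly$noise_sd > 0) {
    v <- v + with_seed(seed, stats::rnorm(n, 0, fly$noise_sd))
  }
  structure(data.frame(time_s = t, voltage_uv = v),
            sample_rate = spec$sample_rate,
            meta = list(label = effect$label, rab_id = effect$rab_id,
                        contrast = spec$contrast),
            truth = amps)
}

#' Draw per-fly parameters around population means
#'
#' Fly-to-fly variability is modeled as lognormal on every positive
#' parameter (`r_max_P`, `c50`, `hill_n`, `g_L`, `noise_sd`), with a common
#' coefficient of variation and means equal to the population values, so
#' amplitudes stay positive. Phases are kept at their population values
#' (they do not affect amplitude measures). `cv = 0` returns the means
#' exactly.
#'
#' @param means A [fly_params()] giving population means.
#' @param cv Coefficient of variation (>= 0) shared by the varied
#'   parameters.
#' @param seed Optional integer seed for reproducible draws.
#' @return A [fly_params()] drawn from the population.
#' @export
sample_fly_params <- function(means, cv, seed = NULL) {
  abort_if(!inherits(means, "fly_params"), "'means' must be a fly_params")
  abort_if(!is_scalar_number(cv) || cv < 0, "'cv' must be a nonnegative number")
  if (cv == 0) return(means)
  with_seed(seed, {
    sig2 <- log(1 + cv^2)
    draw <- function(m) {
      if (m == 0) 0 else stats::rlnorm(1, meanlog = log(m) - sig2 / 2,
                                       sdlog = sqrt(sig2))
    }
    fly_params(
      r_max_P = draw(means$r_max_P),
      c50 = min(draw(means$c50), 1),
      hill_n = draw(means$hill_n),
      g_L = draw(means$g_L),
      phase1 = means$phase1, phase2 = means$phase2,
      noise_sd = draw(means$noise_sd)
    )
  })
}

#' Design of a simulated modifier screen
#'
#' Fixes the screen geometry: which Rabs are crossed, how many flies per
#' arm, the contrast series, repeats per stimulus, the stimulus template
#' and the global seed. The four arms per Rab are control (driver only),
#' G2019S only, Rab only, and Rab + G2019S; the two arms without a Rab
#' transgene are shared across Rabs.
#'
#' @param rab_ids Character vector of Rab identifiers.
#' @param n_flies_per_arm Flies recorded per arm (>= 1).
#' @param contrasts A [contrast_series()] (default: 9 contrasts, 10--100%).
#' @param n_repeats Stimulus repeats per contrast (>= 1; 5 in the reference
#'   protocol).
#' @param stimulus A [stimulus_spec()] template; its contrast field is
#'   overridden by the series.
#' @param population A [fly_params()] of population means.
#' @param cv Fly-to-fly coefficient of variation (lognormal), default 0.1.
#' @param seed Integer global seed; all per-fly seeds derive from it via
#'   [derive_seed()].
#' @return An object of class `"screen_design"`.
#' @export
screen_design <- function(rab_ids, n_flies_per_arm = 10,
                          contrasts = contrast_series(9, 0.10, 1.00),
                          n_repeats = 5,
                          stimulus = stimulus_spec(),
                          population = fly_params(),
                          cv = 0.1, seed = 1L) {
  abort_if(length(rab_ids) < 1L || anyNA(rab_ids), "'rab_ids' must be nonempty")
  abort_if(anyDuplicated(rab_ids) > 0L, "'rab_ids' must be unique")
  abort_if(!is_scalar_number(n_flies_per_arm) || n_flies_per_arm < 1,
           "'n_flies_per_arm' must be >= 1")
  abort_if(!is_scalar_number(n_repeats) || n_repeats < 1,
           "'n_repeats' must be >= 1")
  abort_if(any(diff(contrasts) <= 0) || any(contrasts < 0 | contrasts > 1),
           "'contrasts' must be strictly increasing within [0, 1]")
  abort_if(!inherits(stimulus, "stimulus_spec"),
           "'stimulus' must be a stimulus_spec")
  abort_if(!inherits(population, "fly_params"),
           "'population' must be a fly_params")
  structure(list(rab_ids = as.character(rab_ids),
                 n_flies_per_arm = as.integer(n_flies_per_arm),
                 contrasts = contrasts,
                 n_repeats = as.integer(n_repeats),
                 stimulus = stimulus, population = population,
                 cv = cv, seed = as.integer(seed)),
            class = "screen_design")
}

#' @export
print.screen_design <- function(x, ...) {
  cat(sprintf(
    "Screen design: %d Rab(s), %d flies/arm, %d contrasts x %d repeats, seed %d\n",
    length(x$rab_ids), x$n_flies_per_arm, length(x$contrasts),
    x$n_repeats, x$seed))
  invisible(x)
}

# effects: data.frame(rab_id, label, gain_P, gain_L, synergy_P, synergy_L).
# Shared arms (control, g2019s_only) have rab_id NA and appear once.
validate_effects <- function(effects, rab_ids) {
  need <- c("rab_id", "label", "gain_P", "gain_L", "synergy_P", "synergy_L")
  abort_if(!is.data.frame(effects) || !all(need %in% names(effects)),
           "effects table needs columns: ", paste(need, collapse = ", "))
  abort_if(!all(effects$label %in% GENOTYPE_LABELS),
           "unknown genotype label in effects table")
  for (lab in c("control", "g2019s_only")) {
    abort_if(sum(effects$label == lab) != 1L,
             "invalid design: effects table needs exactly one '", lab, "' arm")
  }
  for (r in rab_ids) {
    for (lab in c("rab_only", "both")) {
      abort_if(sum(effects$label == lab & effects$rab_id %in% r) != 1L,
               "invalid design: missing or duplicated '", lab,
               "' arm for ", r)
    }
  }
  invisible(effects)
}

effect_row <- function(effects, label, rab_id = NA) {
  row <- if (label %in% c("control", "g2019s_only")) {
    effects[effects$label == label, , drop = FALSE]
  } else {
    effects[effects$label == label & effects$rab_id %in% rab_id, , drop = FALSE]
  }
  genotype_effect(label = row$label, rab_id = row$rab_id,
                  gain_P = row$gain_P, gain_L = row$gain_L,
                  synergy_P = row$synergy_P, synergy_L = row$synergy_L)
}

#' Simulate a full modifier screen
#'
#' Generates every trace of the screen: for each arm, `n_flies_per_arm`
#' flies are drawn from the population, and each fly is presented with
#' every contrast `n_repeats` times. The control and G2019S-only arms are
#' simulated once and shared across Rabs. All randomness derives from the
#' design seed through [derive_seed()] keyed by arm, Rab and fly, so
#' identical designs give identical datasets.
#'
#' @param design A [screen_design()].
#' @param effects A data frame with columns `rab_id`, `label`, `gain_P`,
#'   `gain_L`, `synergy_P`, `synergy_L`: one row per shared arm
#'   (`control`, `g2019s_only`, `rab_id = NA`) and one row per Rab for
#'   `rab_only` and `both`. See [recovery_screen_effects()] and
#'   [null_screen_effects()].
#' @return An object of class `"trace_set"`: list with `voltage` (matrix,
#'   samples x traces), `meta` (data frame: `trace_id`, `fly_id`,
#'   `genotype_label`, `rab_id`, `contrast`, `rep`), `stimulus` (the
#'   template spec), `design`, and `truth` (data frame of population
#'   amplitudes at maximum contrast and the multipliers used, per arm).
#' @export
simulate_screen <- function(design, effects) {
  abort_if(!inherits(design, "screen_design"), "'design' must be a screen_design")
  validate_effects(effects, design$rab_ids)
  st <- design$stimulus
  n_samp <- round(st$sample_rate * st$duration)
  t <- (seq_len(n_samp) - 1) / st$sample_rate
  arms <- rbind(
    data.frame(rab_id = NA_character_,
               label = c("control", "g2019s_only"),
               stringsAsFactors = FALSE),
    expand.grid(rab_id = design$rab_ids, label = c("rab_only", "both"),
                stringsAsFactors = FALSE)
  )
  n_c <- length(design$contrasts)
  n_per_fly <- n_c * design$n_repeats
  blocks <- vector("list", nrow(arms))
  metas <- vector("list", nrow(arms))
  truth <- vector("list", nrow(arms))
  for (a in seq_len(nrow(arms))) {
    lab <- arms$label[a]
    rid <- arms$rab_id[a]
    eff <- effect_row(effects, lab, rid)
    arm_key <- paste(lab, ifelse(is.na(rid), "-", rid), sep = "/")
    vmat <- matrix(0, n_samp, design$n_flies_per_arm * n_per_fly)
    for (i in seq_len(design$n_flies_per_arm)) {
      fseed <- derive_seed(design$seed, paste0("simulate/", arm_key), i)
      cols <- (i - 1L) * n_per_fly + seq_len(n_per_fly)
      vmat[, cols] <- with_seed(fseed, {
        fly <- sample_fly_params(design$population, design$cv)
        amps <- deterministic_amplitudes(fly, eff, design$contrasts)
        s1 <- sin(2 * pi * st$f1 * t + fly$phase1)
        s2 <- sin(2 * pi * 2 * st$f1 * t + fly$phase2)
        clean <- outer(s1, amps$A1) + outer(s2, amps$A2)  # samples x contrasts
        clean <- clean[, rep(seq_len(n_c), each = design$n_repeats)]
        if (fly$noise_sd > 0) {
          clean <- clean + matrix(stats::rnorm(length(clean), 0, fly$noise_sd),
                                  nrow = n_samp)
        }
        clean
      })
    }
    blocks[[a]] <- vmat
    metas[[a]] <- data.frame(
      fly_id = rep(sprintf("%s_fly%02d", gsub("/", "_", arm_key),
                           seq_len(design$n_flies_per_arm)),
                   each = n_per_fly),
      genotype_label = lab, rab_id = rid,
      contrast = rep(rep(design$contrasts, each = design$n_repeats),
                     times = design$n_flies_per_arm),
      rep = rep(rep(seq_len(design$n_repeats), times = n_c),
                times = design$n_flies_per_arm),
      stringsAsFactors = FALSE
    )
    pop <- deterministic_amplitudes(design$population, eff, max(design$contrasts))
    truth[[a]] <- data.frame(rab_id = rid, genotype_label = lab,
                             A1_pop = pop$A1, A2_pop = pop$A2,
                             gain_P = eff$gain_P, gain_L = eff$gain_L,
                             synergy_P = eff$synergy_P, synergy_L = eff$synergy_L,
                             stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, metas)
  meta <- cbind(trace_id = seq_len(nrow(meta)), meta)
  structure(list(voltage = do.call(cbind, blocks), meta = meta,
                 stimulus = st, design = design,
                 truth = do.call(rbind, truth)),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf(
    "SSVEP trace set: %d traces (%d flies), %d samples each at %g Hz, %g Hz flicker\n",
    ncol(x$voltage), length(unique(x$meta$fly_id)), nrow(x$voltage),
    x$stimulus$sample_rate, x$stimulus$f1))
  invisible(x)
}
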