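---
title: "Methods: harmonic SSVEP analysis and synergy statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonic SSVEP analysis and synergy statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepscreen)
```

## The measurement model

A fly eye stimulated with sinusoidal luminance flicker at fundamental
frequency $f_1$ about a fixed mean level produces a periodic voltage whose
spectrum concentrates at harmonics of $f_1$. Genetic dissection attributes
the component at $f_1$ (1F1) mostly to the photoreceptors and the component
at $2 f_1$ (2F1) to the lamina neurons. The package treats one recording
epoch as

$$V(t) = A_1 \sin(2\pi f_1 t + \phi_1) + A_2 \sin(4\pi f_1 t + \phi_2)
  + \varepsilon(t),$$

with $\varepsilon$ white Gaussian recording noise, and estimates $A_1$,
$A_2$ from exact FFT bins. Epochs always contain a whole number of flicker
cycles ($f_1 \cdot \text{duration}$ integral): the stimulus generator is
under experimental control, so epochs can be cut to whole cycles, a
rectangular window is then leakage-free, and a sinusoid of peak amplitude
$A$ yields a one-sided bin amplitude of exactly $A$. This is what makes
the closed-form tests in the suite exact to numerical precision rather
than approximate. Off-grid harmonic frequencies are a hard error — there
is deliberately no nearest-bin fallback, because a silent fallback would
bias amplitudes downward by leakage.

Harmonics above 2F1 are measured by nothing and influence nothing: the
noise floor of each harmonic is the mean amplitude of the `k = 5` nearest
bins per side *excluding* the DC bin and every integer multiple of $f_1$,
so a distortion component at 3F1 neither leaks into the 2F1 estimate nor
inflates its floor. SNR is amplitude over floor, with the conventions
SNR = 0 for a zero amplitude and SNR = Inf for a nonzero amplitude over a
zero floor.

**Repeat averaging.** Responses to repeated identical stimuli are
transformed individually and averaged bin-wise on amplitudes (incoherent
averaging) by default. Whether the original rigs averaged amplitudes or
complex spectra is generally not stated in screen reports; incoherent
averaging is robust to phase drift between repeats, which is the safer
default for minutes-long recordings, and a coherent mode (mean of complex
spectra, then modulus) is available behind a flag for rigs with reliable
phase locking. The choice only matters in noise: for noiseless
phase-stable traces the two agree exactly.

## Contrast-response functions and best responses

For each fly, amplitude against Michelson contrast (9 contrasts, 10–100%,
linearly spaced with both endpoints) gives the CRF per harmonic, and the
fly's *best response* is the plain maximum of the CRF — no smoothing and
no curve fit, because the screen statistic quoted downstream is the
averaged maximum CRF, not a fitted parameter. The maximum is taken
independently for 1F1 and 2F1 (they may peak at different contrasts), and
ties resolve to the lowest contrast achieving the maximum. No fly is
excluded by default; an optional SNR gate (`snr_min`) can restrict the
maximum to measures above a floor multiple, since screens differ on
exclusion rules and none is assumed here.

## Screen statistics

Arms are summarized by mean ± SE (sample SD over $\sqrt{n}$; SE = 0 for a
single fly, by convention) and median ± IQR (linear-interpolation
quartiles). For each Rab and harmonic the synergy coordinates are

$$X = \bar{m}_{\text{Rab only}} - \bar{m}_{\text{control}}, \qquad
  Y = \bar{m}_{\text{both}} - \bar{m}_{\text{Rab only}},$$

with SEs combined in quadrature; $X + Y$ is identically the both-vs-control
difference, which the suite checks exactly. The synergy spectrum is the
OLS regression of $Y$ on $X$ with intercept, fitted separately per
harmonic and unweighted by default — screens plot means with SE bars but
typically state no weighting, so the unweighted fit is primary and an
inverse-variance mode ($1/\mathrm{se}_Y^2$) sits behind a flag. Rabs are
classified above/below the line by the raw residual sign, which is how
"lies above the line" reads on a plot. Annotation enrichment among
above-line Rabs uses Fisher's exact test with the probability-mass
two-sided rule (sum of hypergeometric probabilities no larger than the
observed table's); the odds ratio is reported as the sample cross-product
$ad/bc$ with $x/0 = \infty$ and $0/0$ undefined.

**Signaling regression and outliers.** The G2019S-induced increase in
lamina signaling ($y$, difference of best-2F1 means between the both and
Rab-only arms) is regressed on the corresponding photoreceptor increase
($x$). Each point is scored by its leave-one-out externally studentized
residual $(y_i - \hat y_{(i)}) / \sqrt{s_{(i)}^2 (1 + h_i)}$ and flagged
at $|t| \ge 3$ (configurable; `Inf` disables flagging). The observed-over-
predicted ratio $y_i/\hat y_{(i)}$ is reported alongside because standout
Rabs are usually quoted on that scale, but the flag is driven by the
studentized residual, which unlike the ratio is stable when the prediction
is near zero. A leave-one-out fit with zero $x$-variance leaves the point
unflagged with a warning record rather than failing.

**ANOVA and Dunnett.** Arm comparisons against the shared control use
one-way fixed-effects ANOVA plus Dunnett's many-to-one procedure. The
family-wise adjusted $p$ for comparison $j$ is
$P(\max_i |T_i| \ge |t_j|)$ under the joint null, evaluated by seeded
Monte Carlo (default $10^5$ draws): group means and the pooled variance
are simulated directly with the observed group sizes, which reproduces the
Dunnett correlation structure without tabulated critical points and stays
testable — with two groups the procedure must agree with the two-sample
$t$-test, and its family-wise type-I error must sit at 5% under the null,
both of which the suite measures.

## The synthetic screen generator

No raw screen recordings are publicly deposited, so the package carries a
generative model with the statistical structure the analysis assumes:

- **Photoreceptor stage**: Naka–Rushton contrast nonlinearity
  $A_1(c) = \text{gain}_P \cdot R_{\max} \, c^n / (c^n + c_{50}^n)$ with
  defaults $R_{\max} = 10\,\mu V$, $c_{50} = 0.3$, $n = 2$ — a saturating
  CRF of realistic shape and scale for eye potentials.
- **Lamina stage**: a static quadratic, $A_2 = \text{gain}_L \cdot g_L
  A_1^2$ with $g_L = 0.05\,\mu V^{-1}$. A quadratic is the simplest static
  nonlinearity that converts fundamental drive into pure second-harmonic
  output, and it gives closed forms the tests can verify exactly (a unit
  sinusoid through $x + 0.5x^2$ must yield 1F1 = 1, 2F1 = 0.25).
- **Genotype arms**: multiplicative gains per stage; synergy multipliers
  apply only when both transgenes are expressed. Aged cohorts are
  represented by different effect tables, not an internal time model.
- **Variability and noise**: lognormal fly-to-fly variation with one
  shared coefficient of variation (keeps amplitudes positive), additive
  white Gaussian voltage noise (default 1 µV per sample at 500 Hz; no 1/f
  component, though the hook exists). Phases are population-fixed since no
  amplitude statistic depends on them. A genotype-dependent cv (screens
  report more variable kinase-expressing flies) is a config option,
  default off.

All randomness flows from one global seed through a stage-keyed derivation
scheme (`derive_seed`), so whole runs and partial re-runs are reproducible
bit for bit.

### The reference (recovery) scenario

The built-in 23-Rab scenario fixes the screen geometry of the published
protocol — 10 flies per arm, 9 contrasts, 5 repeats — and plants six
non-neutral Rabs: three synergy Rabs with lamina synergy multipliers
8, 6, 5 and three solo-effect Rabs with elevated gains and no synergy.
Two construction choices matter and were genuinely open:

- **Geometry of the synergy trio.** Rab10 is lamina-only
  ($\text{synergy}_L = 8$, $\text{synergy}_P = 1$): a large 2F1 increase
  at a near-zero 1F1 increase, the standout the outlier scan must find.
  Rab14 and Rab27 act on both stages, and their photoreceptor multipliers
  (1.5 and 1.3) are chosen so the two share the same G2019S-induced
  lamina-to-photoreceptor response ratio: they define one signaling line
  together with the origin cluster, as coupled Rabs do on a real signaling
  regression, while Rab10 lies far off it. Without that collinearity the
  two coupled Rabs each fail their own leave-one-out fit and the scan
  flags all three — a geometry that contradicts what the scenario is meant
  to emulate.
- **Fly-to-fly cv = 0.1.** The recovery experiment asks whether the
  analysis separates 5–8× effects with 10 flies per arm. At cv = 0.1 the
  SE of an arm-mean difference is well under 1 µV, small against those
  effects; this is the "moderate variability" regime the scenario is
  meant to represent. Real screens show larger spread (and compensate with
  more animals); cv is an explicit design parameter, so users emulating
  noisier colonies should raise it and expect the qualitative separation
  to degrade accordingly.

What passing the recovery test shows — and what it does not: it
demonstrates that the estimator chain (FFT extraction → best response →
synergy coordinates → spectrum residuals → leave-one-out scan) recovers
a planted interaction structure of realistic effect size through the full
pipeline. It does not validate the generative model against real fly
physiology (no adaptation, no 1/f noise, no response drift, no outlier
flies), and it cannot reproduce numerical values of any particular
published screen, whose raw traces are unavailable.

## Problem sizes and numerical choices

The reference screen is simulated at 500 Hz for 1 s epochs (12 Hz flicker,
resolution 1 Hz), 21,600 traces in total — large enough that every
pipeline stage runs at realistic scale while a full analysis completes in
seconds. Null calibration uses 500 replicates of a deliberately small
4-Rab design (0.5 s epochs at 120 Hz) and 2,000 null ANOVA/Dunnett runs at
$10^5$ Monte-Carlo draws each. Tolerances: closed-form identities are
checked at $10^{-9}$ relative (they hold to machine precision); Monte-Carlo
quantities at 3 binomial standard errors; the two-group Dunnett reduction
at $|\Delta p| < 0.005$ for $10^5$ draws. Result CSVs are written with 9
significant digits, which is what makes repeated runs byte-identical;
trace CSVs use 17 significant digits so that write–read round-trips are
exact.

## Known limitations

- The lamina stage is static and memoryless; real lamina neurons adapt,
  and the 2F1/1F1 relationship in data need not be exactly quadratic.
- Incoherent averaging has a positive noise bias (Rayleigh-distributed
  bin amplitudes), so SNR near 1 means "no detectable response", not
  literal absence; the pure-noise calibration in the suite quantifies
  this.
- The enrichment machinery is generic over any logical annotation column;
  the shipped Rab annotation table is synthetic (see
  `inst/extdata/rab_annotations_synthetic.csv`) and carries no claims
  about real Rab biology.
- Dunnett adjustment by Monte Carlo has $O(10^{-3})$ jitter at the default
  draw count; raise `dunnett_draws` when adjusted p-values near a decision
  boundary matter.
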