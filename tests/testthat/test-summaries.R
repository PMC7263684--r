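# Genotype aggregation, fold changes, synergy coordinates.

test_that("genotype summaries match hand-computed statistics", {
  s <- summarize_genotype(c(3, 3, 3))
  expect_equal(c(s$mean, s$se, s$median, s$iqr), c(3, 0, 3, 0))
  s <- summarize_genotype(c(1, 2, 3, 4))
  expect_equal(s$mean, 2.5)
  expect_equal(s$se, sd(c(1, 2, 3, 4)) / 2, tolerance = 1e-12)
  expect_equal(s$se, 0.6455, tolerance = 1e-4)
  expect_equal(s$iqr, 1.5)  # quartiles by linear interpolation
  one <- summarize_genotype(7)
  expect_equal(c(one$mean, one$se, one$median), c(7, 0, 7))
  expect_error(summarize_genotype(numeric(0)), "nonempty")
})

test_that("summaries are permutation-invariant and scale-equivariant", {
  set.seed(2)
  x <- rlnorm(11)
  s <- summarize_genotype(x)
  p <- summarize_genotype(sample(x))
  expect_equal(s[c("mean", "se", "median", "iqr")],
               p[c("mean", "se", "median", "iqr")])
  for (k in c(0.25, 3)) {
    sk <- summarize_genotype(k * x)
    expect_equal(sk$mean, k * s$mean)
    expect_equal(sk$se, k * s$se)
    expect_equal(sk$median, k * s$median)
    expect_equal(sk$iqr, k * s$iqr)
  }
})

test_that("fold change divides arm mean by reference mean", {
  expect_equal(fold_change(summarize_genotype(c(2, 2)),
                           summarize_genotype(c(2, 2))), 1)
  expect_equal(fold_change(summarize_genotype(8.2), summarize_genotype(2)), 4.1)
  expect_error(fold_change(summarize_genotype(1), summarize_genotype(0)),
               "undefined ratio")
})

test_that("synergy coordinates are mean differences with quadrature SEs", {
  s <- function(x) summarize_genotype(x, harmonic = "2F1")
  p0 <- synergy_xy(s(c(1, 1)), s(c(1, 1)), s(c(1, 1)))
  expect_equal(c(p0$X, p0$Y), c(0, 0))
  p <- synergy_xy(s(c(1.5, 2.5)), s(c(4, 6)), s(c(8, 10)))
  expect_equal(p$X, 3)  # 5 - 2
  expect_equal(p$Y, 4)  # 9 - 5
  # se combination: sqrt(0.09 + 0.16) = 0.5
  a <- summarize_genotype(c(0, 0), harmonic = "1F1"); a$se <- 0.3
  b <- summarize_genotype(c(0, 0), harmonic = "1F1"); b$se <- 0.4
  d <- summarize_genotype(c(0, 0), harmonic = "1F1"); d$se <- 0
  expect_equal(synergy_xy(a, b, d)$se_X, 0.5)
  wrong <- summarize_genotype(c(1, 2), harmonic = "1F1")
  expect_error(synergy_xy(s(c(1, 2)), wrong, s(c(1, 2))),
               "different harmonics")
})

test_that("X + Y is conserved as mean(both) - mean(control)", {
  set.seed(9)
  for (i in 1:20) {
    ctrl <- rlnorm(8); rab <- rlnorm(8); both <- rlnorm(8)
    s <- function(x) summarize_genotype(x, harmonic = "1F1")
    p <- synergy_xy(s(ctrl), s(rab), s(both))
    expect_equal(p$X + p$Y, mean(both) - mean(ctrl), tolerance = 1e-12)
  }
})

test_that("screen_summaries aggregates arms and emits synergy per harmonic", {
  flies <- rbind(
    data.frame(fly_id = paste0("c", 1:3), genotype_label = "control",
               rab_id = NA_character_, best_1F1 = c(1, 2, 3),
               best_2F1 = c(0.5, 1, 1.5)),
    data.frame(fly_id = paste0("g", 1:3), genotype_label = "g2019s_only",
               rab_id = NA_character_, best_1F1 = c(2, 2, 2),
               best_2F1 = c(1, 1, 1)),
    data.frame(fly_id = paste0("r", 1:3), genotype_label = "rab_only",
               rab_id = "Rab7", best_1F1 = c(4, 5, 6),
               best_2F1 = c(2, 2, 2)),
    data.frame(fly_id = paste0("b", 1:3), genotype_label = "both",
               rab_id = "Rab7", best_1F1 = c(8, 9, 10),
               best_2F1 = c(8, 9, 10))
  )
  agg <- screen_summaries(flies)
  expect_equal(nrow(agg$summaries), 8)  # (2 shared + 2 rab arms) x 2 harmonics
  syn1 <- agg$synergy[agg$synergy$harmonic == "1F1", ]
  expect_equal(syn1$X, 5 - 2)
  expect_equal(syn1$Y, 9 - 5)
  syn2 <- agg$synergy[agg$synergy$harmonic == "2F1", ]
  expect_equal(syn2$X + syn2$Y, 9 - 1)
})
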