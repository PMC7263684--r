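# Synergy-spectrum regression and Fisher-exact enrichment.

test_that("an exact line is recovered with zero residuals", {
  pts <- data.frame(rab_id = letters[1:5], X = c(0, 1, 2, 3, 4),
                    Y = 2 * c(0, 1, 2, 3, 4) + 1)
  fit <- fit_spectrum(pts)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
  expect_equal(unname(coef(fit)), c(1, 2), tolerance = 1e-12)
  expect_equal(predict(fit, data.frame(X = 10)), 21, tolerance = 1e-10)
})

test_that("fits are order-invariant, centered, and validated", {
  set.seed(4)
  pts <- data.frame(rab_id = letters[1:8], X = rnorm(8), Y = rnorm(8))
  f1 <- fit_spectrum(pts)
  f2 <- fit_spectrum(pts[sample(8), ])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
  expect_equal(mean(f1$residuals), 0, tolerance = 1e-10)  # OLS with intercept
  expect_equal(f1$above_line, f1$residuals > 0)
  expect_error(fit_spectrum(pts[1:2, ]), "at least 3")
  bad <- pts; bad$X <- 1
  expect_error(fit_spectrum(bad), "zero variance")
  expect_error(fit_spectrum(pts, weighted = TRUE), "se_Y")
})

test_that("an inverse solo/synergy layout yields a negative slope", {
  # solo Rabs: large X, no Y; synergy Rabs: no X, large Y; rest at origin
  pts <- data.frame(
    rab_id = paste0("R", 1:10),
    X = c(25, 30, 28, rep(0.3, 7)),
    Y = c(0.5, -0.2, 0.1, 40, 52, 29, rep(-0.4, 4))
  )
  fit <- fit_spectrum(pts)
  expect_lt(fit$slope, 0)
  top3 <- pts$rab_id[order(fit$residuals, decreasing = TRUE)][1:3]
  expect_setequal(top3, c("R4", "R5", "R6"))
})

test_that("weighted fits downweight uncertain points", {
  pts <- data.frame(rab_id = letters[1:6], X = 1:6,
                    Y = c(1, 2, 3, 4, 5, 30),
                    se_Y = c(1, 1, 1, 1, 1, 100))
  wfit <- fit_spectrum(pts, weighted = TRUE)
  ufit <- fit_spectrum(pts)
  expect_lt(abs(wfit$slope - 1), abs(ufit$slope - 1))
})

test_that("Fisher p matches the worked small tables", {
  expect_equal(fisher_p(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)), 34 / 70,
               tolerance = 1e-9)
  expect_equal(fisher_p(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)), 2 / 252,
               tolerance = 1e-9)
  expect_equal(fisher_p(matrix(0, 2, 2)), 1)
  expect_equal(fisher_p(matrix(c(4, 0, 3, 0), 2)), 1)  # zero column margin
})

test_that("Fisher p equals brute-force enumeration for small margins", {
  for (a in 0:6) for (b in 0:6) for (c_ in 0:6) for (d in 0:6) {
    tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    if (any(c(a + b, c_ + d, a + c_, b + d) > 6)) next
    expect_equal(fisher_p(tab), fisher_p_oracle(tab), tolerance = 1e-9,
                 label = sprintf("table [%d %d; %d %d]", a, b, c_, d))
  }
})

test_that("enrichment builds the annotated-by-position table", {
  pts <- data.frame(rab_id = paste0("R", 1:8), X = 1:8,
                    Y = c(9, 8, 7, 6, 1, 2, 3, 4))
  fit <- fit_spectrum(pts)
  ann <- setNames(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                  pts$rab_id)
  er <- enrichment_test(fit, ann)
  expect_equal(sum(er$table), 8)
  expect_equal(unname(rowSums(er$table)), c(4, 4))
  expect_equal(er$p_two_sided, fisher_p(er$table))
  expect_equal(er$odds_ratio,
               (er$table[1, 1] * er$table[2, 2]) /
                 (er$table[1, 2] * er$table[2, 1]))
  expect_error(enrichment_test(fit, ann[1:4]), "missing")
})

test_that("odds-ratio conventions handle zero cells", {
  pts <- data.frame(rab_id = paste0("R", 1:6), X = 1:6,
                    Y = c(10, 9, 8, 1, 2, 3))
  fit <- fit_spectrum(pts)
  all_above_ann <- setNames(fit$above_line, pts$rab_id)
  er <- enrichment_test(fit, all_above_ann)  # perfect association
  expect_true(is.infinite(er$odds_ratio))
})
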