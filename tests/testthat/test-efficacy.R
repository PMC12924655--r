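# CFU enumeration, reduction arithmetic, group comparisons, zone
# summaries and formulation math.

test_that("cfu enumeration keeps only countable plates", {
  # duplicate plates of 50 at the 1e4 dilution, 50 uL each
  est <- cfu_from_counts(plate_counts(c(50, 50), dilution = 1e4))
  expect_equal(est$log10_cfu, 7)
  expect_equal(est$cfu_per_ml, 1e7)

  # nothing countable: explicit refusal, no extrapolation
  bad <- cfu_from_counts(plate_counts(c(250, 12), dilution = c(1e3, 1e4)))
  expect_false(bad$countable)
  expect_true(is.na(bad$log10_cfu))

  # mixed dilutions, one valid level: hand arithmetic on that level only
  mix <- cfu_from_counts(plate_counts(c(412, 380, 41, 45, 3, 6),
                                      dilution = rep(c(1e3, 1e4, 1e5),
                                                     each = 2)))
  expect_equal(mix$dilutions_used, 1e4)
  expect_equal(mix$cfu_per_ml, mean(c(41, 45)) / 0.05 * 1e4)

  # the countable window is a closed interval
  edge <- cfu_from_counts(plate_counts(c(30, 100), dilution = c(1e4, 1e4)))
  expect_equal(edge$dilutions_used, 1e4)
  expect_equal(edge$cfu_per_ml, 65 / 0.05 * 1e4)
})

test_that("log and percentage reduction follow the printed definitions", {
  expect_equal(log_reduction(6, 3), 3)
  expect_equal(log_reduction(4.2, 4.2), 0)
  expect_equal(percent_reduction(0), 0)

  # published table cells reproduced from their printed LR values
  expect_equal(round(percent_reduction(2.46), 2), 99.65)
  expect_equal(round(percent_reduction(2.34), 2), 99.54)
  expect_equal(round(percent_reduction(4.05), 3), 99.991)
  expect_equal(round(percent_reduction(0.09), 3), 18.717)
  expect_equal(round(percent_reduction(0.06), 3), 12.904)

  # monotone, bounded, and zero at no-reduction
  lr <- seq(0, 8, by = 0.01)
  pr <- percent_reduction(lr)
  expect_true(all(diff(pr) > 0))
  expect_true(all(pr >= 0 & pr < 100))
  expect_equal(percent_reduction(log_reduction(5.5, 5.5)), 0)

  # negative reduction (growth) is passed through, not clipped
  expect_lt(percent_reduction(-0.3), 0)

  # quadruplicate vectorization against hand arithmetic
  ctrl <- c(6.1, 6.0, 6.2, 5.9); trt <- c(3.7, 3.5, 3.8, 3.6)
  lrs <- log_reduction(ctrl, trt)
  expect_equal(mean(lrs), mean(ctrl) - mean(trt))
  expect_equal(sd(lrs), sd(ctrl - trt))
  tab <- reduction_summary(matrix(ctrl), matrix(trt))
  expect_equal(tab$mean_LR, 2.4)
})

test_that("group comparison matches the closed-form pooled t-test", {
  x <- c(5.1, 4.9, 5.3, 5.0); y <- c(4.2, 4.4, 4.1, 4.5)
  cmp <- compare_groups(x, y)
  sp2 <- (3 * var(x) + 3 * var(y)) / 6
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(cmp$t, t_hand, tolerance = 1e-12)
  expect_equal(cmp$p_value, 2 * pt(-abs(t_hand), 6), tolerance = 1e-12)
  expect_equal(round(cmp$p_value, 4),
               round(t.test(x, y, var.equal = TRUE)$p.value, 4))

  # identical groups: the degenerate convention
  same <- compare_groups(c(2, 2), c(2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  # well-separated trial-style fixture: strongly significant
  sep <- compare_groups(c(2.46, 2.2, 2.7, 2.5), c(0.06, 0.1, 0.0, 0.08))
  expect_lt(sep$p_value, 0.001)
  expect_true(sep$significant)

  # Welch flag delegates to the unequal-variance test
  w <- compare_groups(x, c(y, 2.0, 6.5), welch = TRUE)
  expect_equal(w$p_value, t.test(x, c(y, 2.0, 6.5))$p.value)
})

test_that("zone summaries reproduce the published spot-assay table", {
  zt <- read_zone_table()
  s <- summarize_zones(zt)
  expect_equal(s$n, 43)
  expect_equal(round(s$mean_mm, 2), 13.84)
  expect_equal(round(s$sd_mm, 2), 1.23)
  expect_equal(round(bactericidal_fraction(zt), 1), 34.9)
  expect_output(print(s), "13.84 ± 1.23 mm \\(n = 43\\)")

  # hand-computable fixture and degenerate cases
  small <- zone_table(c("a", "b", "c"), c(12, 14, 16),
                      c("Positive", "Negative", "Positive"))
  s2 <- summarize_zones(small)
  expect_equal(s2$mean_mm, 14)
  expect_equal(s2$sd_mm, 2)

  flat <- zone_table(c("a", "b"), c(10, 10), c("Positive", "Positive"))
  expect_equal(summarize_zones(flat)$sd_mm, 0)
  expect_equal(bactericidal_fraction(flat), 0)

  alt <- zone_table(letters[1:6], rep(12, 6),
                    rep(c("Positive", "Negative"), 3))
  expect_equal(bactericidal_fraction(alt), 50)

  # translation equivariance of the mean, invariance of the SD
  shifted <- zone_table(small$strain, small$diameter_mm + 3,
                        small$subculture)
  expect_equal(summarize_zones(shifted)$mean_mm, s2$mean_mm + 3)
  expect_equal(summarize_zones(shifted)$sd_mm, s2$sd_mm)
})

test_that("formulation arithmetic reproduces the published concentrations", {
  slurry <- slurry_concentration(3.05e8, 3.28, 2.33)
  expect_equal(signif(slurry, 3), 4.29e8)
  expect_equal(mix_concentration(4.29e8, 1, 1), 2.145e8)

  expect_equal(slurry_concentration(2e8, 1, 1), 2e8)
  expect_equal(slurry_concentration(2e8, 2, 1), 4e8)  # linear in mass
  expect_equal(mix_concentration(8e8, 1, 0), 8e8)
  expect_equal(mix_concentration(8e8, 1, 3), 2e8)
  expect_error(slurry_concentration(-1, 1, 1))
  expect_error(mix_concentration(1e8, 0, 0))
})

test_that("cfu estimation is scale-consistent across dilution choices", {
  # the same density enumerated at ten-fold shallower dilution with
  # ten-fold larger expected counts gives the same estimate in expectation
  set.seed(99)
  ests <- replicate(200, {
    a <- cfu_from_counts(gen_plate_counts(1.2e7, dilutions = 1e4,
                                          seed = NULL))
    b <- cfu_from_counts(gen_plate_counts(1.2e7, dilutions = 1e5,
                                          volume_ml = 0.5, seed = NULL))
    c(a$log10_cfu, b$log10_cfu)
  })
  expect_lt(abs(mean(ests[1, ], na.rm = TRUE) -
                  mean(ests[2, ], na.rm = TRUE)), 0.05)
})
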