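# Coefficient inference: self-consistency on exact data, bounded
# estimation, bootstrap behaviour and recovery studies.

fit_truth <- default_fixture(delta = 1.3)
fit_times <- seq(0, 8, by = 0.5)

test_that("noise-free data recover the generating coefficients", {
  dat <- gen_coculture(fit_truth, fit_times, noise = list(type = "none"))
  fit <- fit_glv(dat, default_fixture(delta = 0.5, beta = 0.5),
                 free = c("delta[1,1]", "beta[1,1]"), n_starts = 4,
                 seed = 11)
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[["delta[1,1]"]] - 1.3) / 1.3, 1e-3)
  expect_lt(abs(coef(fit)[["beta[1,1]"]] - 0.05) / 0.05, 1e-3)
})

test_that("the fit is at least as good as the truth in-sample", {
  for (seed in c(3, 5)) {
    dat <- gen_coculture(fit_truth, fit_times,
                         noise = list(type = "lognormal", sigma = 0.05),
                         seed = seed)
    fit <- fit_glv(dat, fit_truth, free = "delta[1,1]", n_starts = 3,
                   seed = seed)
    lobs <- log10(dat$observed + 1)
    sim_truth <- predict(fit, fit_times) # at estimate
    rss_fit <- fit$rss
    sim0 <- exclusim:::.glv_sim_at(fit_truth, dat$observed[1, ], fit_times)
    rss_truth <- sum((log10(sim0 + 1) - lobs)^2, na.rm = TRUE)
    expect_lte(rss_fit, rss_truth + 1e-10)
    # and the estimate respects its bounds
    expect_gte(coef(fit)[[1]], fit$lower[1])
    expect_lte(coef(fit)[[1]], fit$upper[1])
  }
})

test_that("missing cells are dropped, not imputed, and shortage is fatal", {
  dat <- gen_coculture(fit_truth, fit_times, noise = list(type = "none"))
  obs <- dat$observed
  obs[c(4, 9), 2] <- NA
  dat2 <- coculture_dataset(dat$times, obs)
  fit <- fit_glv(dat2, default_fixture(delta = 0.8),
                 free = "delta[1,1]", n_starts = 2, seed = 1)
  expect_lt(abs(coef(fit)[[1]] - 1.3) / 1.3, 1e-3)

  tiny <- coculture_dataset(c(0, 1), matrix(c(5e9, 4e9, 1.5e8, 1e8), 2),
                            ids = fit_truth$ids)
  expect_error(
    fit_glv(tiny, fit_truth,
            free = c("delta[1,1]", "beta[1,1]", "r[1]")),
    "under-determined")
})

test_that("bootstrap collapses on noise-free data and is seed-stable", {
  dat <- gen_coculture(fit_truth, fit_times, noise = list(type = "none"))
  fit <- fit_glv(dat, default_fixture(delta = 0.8), free = "delta[1,1]",
                 n_starts = 1)
  b <- bootstrap_ci(fit, n_resamples = 25, seed = 4)
  expect_lt(b$bootstrap$sd[[1]], 1e-6)

  noisy <- gen_coculture(fit_truth, fit_times,
                         noise = list(type = "lognormal", sigma = 0.05),
                         seed = 9)
  nf <- fit_glv(noisy, default_fixture(delta = 0.8), free = "delta[1,1]",
                n_starts = 1)
  b1 <- bootstrap_ci(nf, n_resamples = 40, seed = 21)
  b2 <- bootstrap_ci(nf, n_resamples = 40, seed = 21)
  expect_identical(b1$bootstrap$ci, b2$bootstrap$ci)
  expect_identical(b1$bootstrap$sd, b2$bootstrap$sd)
  # percentile interval brackets the point estimate on converged fits
  expect_lte(b1$bootstrap$ci[1, 1], coef(nf)[[1]])
  expect_gte(b1$bootstrap$ci[2, 1], coef(nf)[[1]])
  # published resample count is the default
  expect_equal(eval(formals(bootstrap_ci)$n_resamples), 1000)
})

test_that("bootstrap percentile intervals cover the truth near 95%", {
  # reduced-scale coverage study: 30 datasets x 99 resamples, one free
  # coefficient on a 24-point design whose pathogen series declines
  # smoothly within the window; empirical coverage should sit in the
  # [0.90, 0.99] band
  cov_truth <- default_fixture(delta = 0.8)
  cov_times <- seq(0, 9, length.out = 24)
  hits <- 0L
  n_data <- 30L
  for (s in seq_len(n_data)) {
    dat <- gen_coculture(cov_truth, cov_times,
                         noise = list(type = "lognormal", sigma = 0.05),
                         seed = 600 + s)
    fit <- fit_glv(dat, cov_truth, free = "delta[1,1]", n_starts = 1)
    b <- bootstrap_ci(fit, n_resamples = 99, seed = s)
    ci <- b$bootstrap$ci[, 1]
    if (ci[1] <= 0.8 && 0.8 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / n_data, 0.90)
  expect_lte(hits / n_data, 0.99)
})

test_that("recovery study: exact data give zero bias, noise inflates RMSE", {
  rs0 <- recovery_study(fit_truth, fit_times, free = "delta[1,1]",
                        noise = list(type = "none"), n_replicates = 3,
                        n_starts = 2, seed = 30)
  expect_lt(abs(rs0$bias), 1e-3)
  expect_lt(rs0$rmse, 1e-3)

  rs1 <- recovery_study(fit_truth, fit_times, free = "delta[1,1]",
                        noise = list(type = "lognormal", sigma = 0.05),
                        n_replicates = 8, n_starts = 2, seed = 40)
  rs2 <- recovery_study(fit_truth, fit_times, free = "delta[1,1]",
                        noise = list(type = "lognormal", sigma = 0.10),
                        n_replicates = 8, n_starts = 2, seed = 40)
  expect_lte(rs1$rmse, rs2$rmse)
  expect_equal(rs1$n_ok, 8)
})

test_that("denser sampling does not worsen recovery", {
  sparse <- seq(0, 8, length.out = 6)
  dense <- seq(0, 8, length.out = 24)
  rs_sparse <- recovery_study(fit_truth, sparse, free = "delta[1,1]",
                              noise = list(type = "lognormal",
                                           sigma = 0.05),
                              n_replicates = 12, n_starts = 1, seed = 50)
  rs_dense <- recovery_study(fit_truth, dense, free = "delta[1,1]",
                             noise = list(type = "lognormal",
                                          sigma = 0.05),
                             n_replicates = 12, n_starts = 1, seed = 50)
  expect_lte(rs_dense$rmse, rs_sparse$rmse)
})

test_that("fit results serialize with bootstrap summaries", {
  dat <- gen_coculture(fit_truth, fit_times,
                       noise = list(type = "lognormal", sigma = 0.05),
                       seed = 2)
  fit <- fit_glv(dat, default_fixture(delta = 0.8), free = "delta[1,1]",
                 n_starts = 1)
  fit <- bootstrap_ci(fit, n_resamples = 20, seed = 3)
  f <- tempfile(fileext = ".json")
  write_fit_result(fit, f)
  parsed <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(parsed$coefficients$`delta[1,1]`,
               unname(coef(fit)[1]), tolerance = 1e-12)
  expect_equal(parsed$bootstrap$n, 20)
  # reporting style: point +/- bootstrap SD at two decimals
  expect_output(print(fit, digits = 2), "delta\\[1,1\\] = \\d+\\.\\d{2} ± \\d+\\.\\d{2}")
})
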