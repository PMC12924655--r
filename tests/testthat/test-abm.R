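# Agent-based model: initialization, diffusion, Hill response, the step
# operator's kill/biofilm/starvation rules, replicated runs and spatial
# summaries.

test_that("world initialization is seeded, bounded and reproducible", {
  g <- small_grid(layout = c(A = 50, B = 80, C = 30, P = 40))
  w1 <- abm_init(g, abm_params(), seed = 7)
  w2 <- abm_init(g, abm_params(), seed = 7)
  expect_identical(w1$counts, w2$counts)
  expect_identical(vapply(w1$counts, sum, 0),
                   c(A = 50, B = 80, C = 30, P = 40))
  expect_true(all(w1$fields$M1 == 0) && all(w1$fields$M2 == 0))
  expect_true(all(w1$fields$nutrient == abm_params()$nutrient_init))

  empty <- abm_init(small_grid(layout = c(A = 0, B = 0, C = 0, P = 0)),
                    abm_params(), seed = 1)
  expect_identical(sum(vapply(empty$counts, sum, 0)), 0)

  expect_error(abm_grid(width = 5), "width")
  expect_error(abm_grid(layout = c(A = -1)), ">= 0")

  # uniform placement: chi-square over quadrant occupancy across seeds
  tot <- matrix(0, 2, 2)
  for (s in 1:100) {
    w <- abm_init(abm_grid(width = 40, height = 40,
                           layout = c(A = 100, B = 0, C = 0, P = 0)),
                  abm_params(), seed = s)
    m <- w$counts$A
    tot <- tot + rbind(c(sum(m[1:20, 1:20]), sum(m[1:20, 21:40])),
                       c(sum(m[21:40, 1:20]), sum(m[21:40, 21:40])))
  }
  expect_gt(stats::chisq.test(as.vector(tot))$p.value, 0.001)
})

test_that("the agent roster mirrors the patch counts", {
  w <- abm_init(small_grid(layout = c(A = 12, B = 5, C = 0, P = 3)),
                abm_params(), seed = 3)
  ros <- agent_roster(w)
  expect_identical(as.vector(table(factor(ros$type,
                                          c("A", "B", "C", "P")))),
                   c(12L, 5L, 0L, 3L))
})

test_that("diffusion conserves mass, fixes uniform fields, matches stencil", {
  p <- abm_params()
  # uniform field is a fixed point
  u <- matrix(5, 30, 30)
  expect_equal(abm_diffuse(u, p$D_m, p$timestep_s, 0.01), u)

  # arbitrary field: exact mass conservation
  set.seed(42)
  f <- matrix(runif(900), 30, 30)
  g <- abm_diffuse(f, p$D_m, p$timestep_s, 0.01)
  expect_lt(abs(sum(g) - sum(f)) / sum(f), 1e-9)

  # impulse response equals an independent brute-force stencil
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  a_total <- p$D_m * p$timestep_s / 0.01^2
  n_sub <- ceiling(a_total / 0.25)
  a <- a_total / n_sub
  ref <- imp
  for (s in seq_len(10 * n_sub)) {
    nr <- nrow(ref); nc <- ncol(ref)
    lap <- matrix(0, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      nb <- c(ref[max(i - 1, 1), j], ref[min(i + 1, nr), j],
              ref[i, max(j - 1, 1)], ref[i, min(j + 1, nc)])
      lap[i, j] <- sum(nb) - 4 * ref[i, j]
    }
    ref <- ref + a * lap
  }
  got <- imp
  for (k in 1:10) got <- abm_diffuse(got, p$D_m, p$timestep_s, 0.01)
  expect_equal(got, ref, tolerance = 1e-12)

  expect_error(abm_diffuse(matrix(c(1, NA, 1, 1), 2), 1e-6, 10, 0.01),
               "non-finite")
})

test_that("hill response satisfies its defining identities", {
  expect_equal(hill_response(0, 10, 2), 0)
  expect_equal(hill_response(10, 10, 2), 0.5)
  grid <- seq(0, 200, by = 0.5)
  v <- hill_response(grid, 10, 2)
  expect_true(all(diff(v) > 0))
  expect_true(all(v < 1))
  expect_error(hill_response(-1, 10, 2), "negative")
})

test_that("metabolite budget per step closes to secretion minus decay", {
  p <- abm_params()
  w <- abm_init(small_grid(layout = c(A = 200, B = 150, C = 0, P = 0)),
                p, seed = 2)
  for (k in 1:5) {
    before <- sum(w$fields$M1)
    nA <- sum(w$counts$A)  # secretion uses post-growth counts
    w2 <- abm_step(w)
    secreted <- p$secretion[["M1"]] * sum(w2$counts$A)
    expected <- (before + secreted) * (1 - p$decay[["M1"]])
    expect_lt(abs(sum(w2$fields$M1) - expected) / max(expected, 1), 1e-9)
    w <- w2
  }
})

test_that("no pathogen dies while both metabolites sit below threshold", {
  p <- abm_params(growth_enabled = FALSE, starvation_enabled = FALSE)
  w <- abm_init(small_grid(layout = c(A = 0, B = 0, C = 0, P = 500)),
                p, seed = 5)
  w$fields$M1[] <- p$kill_threshold[["M1"]] * 0.99
  w$fields$M2[] <- p$kill_threshold[["M2"]] * 0.99
  w2 <- abm_step(w)
  expect_identical(sum(w2$counts$P), 500L)
})

test_that("pathogen survival above threshold follows the geometric law", {
  # 1000 pathogens held above threshold, growth and starvation disabled:
  # survivors after 10 steps are Binomial(1000, 0.8^10); check the 99%
  # interval around the ~107 expected survivors
  p <- abm_params(growth_enabled = FALSE, starvation_enabled = FALSE,
                  D_m = 1e-7, decay = c(M1 = 0, M2 = 0))
  g <- small_grid(layout = c(A = 0, B = 0, C = 0, P = 1000))
  w <- abm_init(g, p, seed = 11)
  w$fields$M1[] <- p$kill_threshold[["M1"]] * 10
  for (s in 1:10) w <- abm_step(w)
  surv <- sum(w$counts$P)
  bounds <- stats::qbinom(c(0.005, 0.995), 1000, 0.8^10)
  expect_gte(surv, bounds[1])
  expect_lte(surv, bounds[2])

  # and the whole decay profile stays within pointwise 99.9% bounds
  w <- abm_init(g, p, seed = 12)
  w$fields$M1[] <- p$kill_threshold[["M1"]] * 10
  for (s in 1:6) {
    w <- abm_step(w)
    bnd <- stats::qbinom(c(0.0005, 0.9995), 1000, 0.8^s)
    expect_gte(sum(w$counts$P), bnd[1])
    expect_lte(sum(w$counts$P), bnd[2])
  }
})

test_that("biofilm flag flips exactly at the occupancy threshold", {
  p <- abm_params(growth_enabled = FALSE, starvation_enabled = FALSE)
  g <- small_grid(layout = c(A = 0, B = 0, C = 0, P = 0))
  w <- abm_init(g, p, seed = 1)
  w$counts$A[5, 5] <- 19L
  w$counts$B[8, 8] <- 20L
  w2 <- abm_step(w)
  expect_false(w2$biofilm[5, 5])
  expect_true(w2$biofilm[8, 8])
  # occupancy is summed across types
  w$counts$A[3, 3] <- 10L; w$counts$P[3, 3] <- 10L
  w3 <- abm_step(w)
  expect_true(w3$biofilm[3, 3])
})

test_that("identical seeds reproduce full runs; trivial exclusion cases", {
  g <- small_grid(layout = c(A = 40, B = 60, C = 30, P = 30))
  p <- abm_params()
  r1 <- abm_run(g, p, n_replicates = 2, n_iterations = 30, seed_base = 9)
  r2 <- abm_run(g, p, n_replicates = 2, n_iterations = 30, seed_base = 9)
  expect_identical(r1$results[[1]]$series, r2$results[[1]]$series)
  expect_identical(dominance_heatmap(r1$results[[2]]),
                   dominance_heatmap(r2$results[[2]]))

  # no pathogens seeded: excluded from step 0 in every replicate
  r0 <- abm_run(small_grid(layout = c(A = 20, B = 20, C = 10, P = 0)),
                p, n_replicates = 3, n_iterations = 10, seed_base = 1)
  expect_equal(r0$exclusion_probability, 1)
  expect_identical(r0$exclusion_steps, rep(0L, 3))

  # antagonism off with abundant nutrients: no exclusion
  rneg <- abm_run(small_grid(layout = c(A = 40, B = 60, C = 30, P = 30)),
                  abm_params(p_kill = 0, nutrient_inflow = 1),
                  n_replicates = 3, n_iterations = 60, seed_base = 2)
  expect_equal(rneg$exclusion_probability, 0)
})

test_that("series bookkeeping converts steps to hours", {
  r <- abm_run(small_grid(), abm_params(), n_replicates = 1,
               n_iterations = 10, seed_base = 4)
  s <- r$results[[1]]$series
  expect_equal(s$time_h, s$step * 172.8 / 3600)
  # the published default pairing: 500 steps at 172.8 s is 24 h
  expect_equal(500 * abm_params()$timestep_s / 3600, 24)
})

test_that("dominance heatmap labels winners, ties and empty patches", {
  g <- small_grid(layout = c(A = 0, B = 120, C = 0, P = 0))
  w <- abm_init(g, abm_params(), seed = 3)
  res <- structure(list(world = w, exclusion_step = NA, seed = 3),
                   class = "abm_result")
  hm <- dominance_heatmap(res)
  expect_true(all(hm[w$counts$B > 0] == 2))    # B-coded
  expect_true(all(hm[w$counts$B == 0] == 0))   # empty = none
  expect_identical(sum(table(hm)), length(hm)) # partition of the grid

  # tie broken in fixed order A > B > C > P
  w$counts$A[1, 1] <- 5L; w$counts$B[1, 1] <- 5L
  res$world <- w
  expect_identical(dominance_heatmap(res)[1, 1], 1L)
})

test_that("halo metric detects boundary enrichment and stays near 1 under mixing", {
  p <- abm_params()
  # constructed extreme: all Type A on the boundary ring
  g <- abm_grid(width = 20, height = 20,
                layout = c(A = 0, B = 200, C = 0, P = 0))
  w <- abm_init(g, p, seed = 2)
  ring <- matrix(0L, 20, 20)
  ring[1, ] <- 3L; ring[20, ] <- 3L; ring[, 1] <- 3L; ring[, 20] <- 3L
  w$counts$A <- ring
  res <- structure(list(world = w), class = "abm_result")
  expect_gt(halo_metric(res, annulus_fraction = 0.2), 5)

  # uniformly mixed A: ratio concentrates around 1 across seeds
  ratios <- vapply(1:50, function(s) {
    ww <- abm_init(abm_grid(width = 20, height = 20,
                            layout = c(A = 300, B = 300, C = 0, P = 0)),
                   p, seed = s)
    halo_metric(structure(list(world = ww), class = "abm_result"),
                annulus_fraction = 0.25)
  }, 0)
  expect_lt(abs(median(ratios) - 1), 0.15)

  # empty interior reported as undefined
  we <- abm_init(abm_grid(width = 20, height = 20,
                          layout = c(A = 0, B = 0, C = 0, P = 0)),
                 p, seed = 1)
  expect_message(
    out <- halo_metric(structure(list(world = we), class = "abm_result")),
    "undefined")
  expect_true(is.na(out))
})

test_that("sensitivity scan covers the factorial grid; single cell = plain run", {
  g <- small_grid(layout = c(A = 40, B = 60, C = 30, P = 30))
  p <- abm_params()
  tab <- abm_sensitivity_scan(g, p, param_grid = list(p_kill = 0.2),
                              n_replicates = 2, n_iterations = 25,
                              seed_base = 5)
  ref <- abm_run(g, p, n_replicates = 2, n_iterations = 25, seed_base = 5)
  expect_equal(tab$exclusion_probability, ref$exclusion_probability)
  expect_equal(nrow(tab), 1)

  # crossing secretion and D_m across the published diffusion range
  f <- tempfile(fileext = ".csv")
  tab2 <- abm_sensitivity_scan(
    g, p, param_grid = list(secretion.M1 = c(0.5, 1),
                            D_m = c(1e-7, 1e-6, 1e-5)),
    n_replicates = 1, n_iterations = 10, seed_base = 1, csv = f)
  expect_equal(nrow(tab2), 6)
  expect_true(file.exists(f))
  expect_equal(nrow(utils::read.csv(f)), 6)
})

test_that("exclusion probability responds monotonically to the kill probability", {
  # stochastic monotonicity, checked in expectation at small scale with a
  # fixed seed: higher p_kill cannot make exclusion rarer
  g <- small_grid(layout = c(A = 60, B = 90, C = 30, P = 40))
  p <- abm_params(kill_threshold = c(M1 = 5, M2 = 10))
  tab <- abm_sensitivity_scan(g, p,
                              param_grid = list(p_kill = c(0, 0.05, 0.3)),
                              n_replicates = 4, n_iterations = 120,
                              seed_base = 3)
  expect_true(all(diff(tab$exclusion_probability) >= 0))
  expect_equal(tab$exclusion_probability[1], 0)
})
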