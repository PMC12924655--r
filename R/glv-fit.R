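# Interaction-coefficient inference from coculture time series: bounded
# multi-start nonlinear least squares on log10 abundances, residual
# resampling bootstrap, and parameter-recovery studies on synthetic data.

#' Construct a coculture dataset
#'
#' @param times Observation times in hours, strictly increasing, at least 2.
#' @param observed Matrix of observed abundances (CFU per unit), one row per
#'   time, one column per strain; `NA` marks missing cells.
#' @param ids Strain ids (defaults to `colnames(observed)`).
#' @param meta Optional list of noise metadata (model, magnitude, seed,
#'   generating truth) carried along for recovery studies.
#' @return An object of class `"coculture_dataset"`.
#' @export
coculture_dataset <- function(times, observed, ids = colnames(observed),
                              meta = list()) {
  observed <- as.matrix(observed)
  stopifnot(length(times) == nrow(observed), length(times) >= 2,
            all(diff(times) > 0))
  if (any(observed < 0, na.rm = TRUE)) {
    stop("observed abundances must be non-negative", call. = FALSE)
  }
  if (is.null(ids)) ids <- paste0("strain", seq_len(ncol(observed)))
  colnames(observed) <- ids
  structure(list(times = as.numeric(times), observed = observed,
                 ids = ids, meta = meta),
            class = "coculture_dataset")
}

#' @export
print.coculture_dataset <- function(x, ...) {
  cat("Coculture dataset: ", length(x$times), " time points x ",
      ncol(x$observed), " strains (", sum(is.na(x$observed)),
      " missing cells)\n", sep = "")
  invisible(x)
}

#' Coculture dataset CSV + JSON sidecar round-trip
#'
#' The CSV holds `time_h` plus one column per strain; the JSON sidecar
#' (same path with extension `.json`) records metadata.
#'
#' @param data A `coculture_dataset`.
#' @param path CSV file path.
#' @export
write_coculture <- function(data, path) {
  stopifnot(inherits(data, "coculture_dataset"))
  utils::write.csv(data.frame(time_h = data$times, data$observed,
                              check.names = FALSE), path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  jsonlite::write_json(data$meta, side, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_coculture
#' @export
read_coculture <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
          else list()
  coculture_dataset(df$time_h, as.matrix(df[, -1, drop = FALSE]),
                    meta = meta)
}

# --- named-coefficient plumbing ---------------------------------------------
# Free coefficients are addressed as "r[i]", "alpha[i,j]", "beta[i,j]",
# "gamma[i,j]", "delta[i,j]" with guild-local indices.

.parse_par <- function(name) {
  m <- regmatches(name, regexec("^(r|K|alpha|beta|gamma|delta)\\[(\\d+)(,(\\d+))?\\]$",
                                name))[[1]]
  if (!length(m)) stop("cannot parse coefficient name '", name, "'",
                       call. = FALSE)
  list(family = m[2], i = as.integer(m[3]),
       j = if (nzchar(m[5])) as.integer(m[5]) else NA_integer_)
}

.par_get <- function(model, name) {
  p <- .parse_par(name)
  if (p$family %in% c("r", "K")) model[[p$family]][p$i]
  else model$interactions[[p$family]][p$i, p$j]
}

.par_set <- function(model, name, value) {
  p <- .parse_par(name)
  if (p$family %in% c("r", "K")) {
    model[[p$family]][p$i] <- value
    model$strains[[p$i]][[p$family]] <- value
  } else {
    model$interactions[[p$family]][p$i, p$j] <- value
  }
  model
}

.par_bounds <- function(names) {
  fam <- vapply(names, function(n) .parse_par(n)$family, "")
  lower <- vapply(fam, function(f)
    if (f == "K") 1e-6 else .glv_ranges[[f]][1], 0)
  upper <- vapply(fam, function(f)
    if (f == "K") Inf else .glv_ranges[[f]][2], 0)
  list(lower = unname(lower), upper = unname(upper))
}

.apply_pars <- function(model, names, values) {
  for (i in seq_along(names)) model <- .par_set(model, names[i], values[i])
  model
}

# Simulate model abundances exactly at the requested times (no intermediate
# output grid), used by the fitting objective.
.glv_sim_at <- function(model, initial, times, rtol = 1e-8, atol = 1e-3,
                        clamp = 1e-6) {
  mats <- .glv_full_matrices(model)
  r <- model$r; K <- model$K; A <- mats$A; C <- mats$C
  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)
    dy <- r * y * (1 - as.vector(A %*% y) / K) -
      y * as.vector(C %*% (y / K))
    list(dy)
  }
  out <- deSolve::ode(as.numeric(initial), times, rhs, NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  ab <- unname(out[, -1, drop = FALSE])
  ab[ab < clamp] <- 0
  ab
}

#' Fit gLV interaction coefficients to coculture data
#'
#' Minimizes the sum of squared residuals between simulated and observed
#' log10(abundance + 1) with bounded Levenberg-Marquardt least squares
#' ([minpack.lm::nls.lm]) from multiple random starts. The first observed
#' row is taken as the (experimentally validated) initial condition;
#' missing observations are dropped from the objective.
#'
#' @param data A [coculture_dataset()]; column order must match the
#'   skeleton's strain order.
#' @param skeleton A `glv_model` holding every fixed coefficient at its
#'   known value; the coefficients named in `free` are estimated.
#' @param free Character vector of free coefficient names, e.g.
#'   `c("delta[1,1]", "beta[1,1]")` (guild-local indices).
#' @param lower,upper Bounds per free coefficient; default to the published
#'   admissible range of each coefficient family.
#' @param n_starts Number of optimization starts: the skeleton's own values
#'   plus `n_starts - 1` uniform draws within bounds on a fixed sub-seed
#'   schedule.
#' @param seed Seed controlling the start draws.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return An object of class `"glv_fit"` with point estimates, residual
#'   sum of squares, convergence information and the inputs needed for
#'   bootstrapping; see [bootstrap_ci()].
#' @export
fit_glv <- function(data, skeleton, free, lower = NULL, upper = NULL,
                    n_starts = 8, seed = 1, maxiter = 200) {
  stopifnot(inherits(data, "coculture_dataset"),
            inherits(skeleton, "glv_model"), length(free) >= 1)
  if (ncol(data$observed) != length(skeleton$ids)) {
    stop("dataset has ", ncol(data$observed), " strains but skeleton has ",
         length(skeleton$ids), call. = FALSE)
  }
  obs <- data$observed
  n_res <- sum(!is.na(obs[-1, , drop = FALSE]))
  if (length(free) > n_res) {
    stop("under-determined fit: ", length(free), " free coefficients but only ",
         n_res, " usable observations", call. = FALSE)
  }
  b <- .par_bounds(free)
  if (is.null(lower)) lower <- b$lower
  if (is.null(upper)) upper <- b$upper
  stopifnot(length(lower) == length(free), length(upper) == length(free),
            all(lower < upper))
  init0 <- obs[1, ]
  if (any(is.na(init0))) {
    stop("first observed row (initial condition) contains missing values",
         call. = FALSE)
  }
  lobs <- log10(obs + 1)
  ok <- !is.na(lobs)
  resid_fn <- function(par) {
    m <- .apply_pars(skeleton, free, par)
    sim <- try(.glv_sim_at(m, init0, data$times), silent = TRUE)
    if (inherits(sim, "try-error") || nrow(sim) < length(data$times)) {
      return(rep(1e6, sum(ok)))
    }
    (log10(sim + 1) - lobs)[ok]
  }

  start0 <- pmin(pmax(vapply(free, .par_get, 0, model = skeleton), lower),
                 upper)
  starts <- list(start0)
  for (s in seq_len(max(0, n_starts - 1))) {
    set.seed(seed * 1000L + s)
    starts[[s + 1L]] <- lower + stats::runif(length(free)) * (upper - lower)
  }

  best <- NULL
  n_conv <- 0L
  for (st in starts) {
    res <- try(minpack.lm::nls.lm(
      par = st, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = maxiter)),
      silent = TRUE)
    if (inherits(res, "try-error")) next
    conv <- res$info %in% 1:4
    if (conv) n_conv <- n_conv + 1L
    rss <- sum(res$fvec^2)
    if (conv && (is.null(best) || rss < best$rss)) {
      best <- list(par = res$par, rss = rss, info = res$info,
                   niter = res$niter)
    }
  }
  if (is.null(best)) {
    stop("no optimization start converged (", length(starts), " attempted)",
         call. = FALSE)
  }
  est <- stats::setNames(as.numeric(best$par), free)
  mfit <- .apply_pars(skeleton, free, est)
  sim <- .glv_sim_at(mfit, init0, data$times)
  colnames(sim) <- skeleton$ids
  resmat <- log10(obs + 1) - log10(sim + 1)
  structure(list(estimates = est, rss = best$rss, converged = TRUE,
                 info = best$info, n_starts = length(starts),
                 n_converged = n_conv, free = free,
                 lower = lower, upper = upper, skeleton = skeleton,
                 data = data, seed = seed, fitted = sim,
                 residual_matrix = resmat, bootstrap = NULL),
            class = "glv_fit")
}

#' @export
coef.glv_fit <- function(object, ...) object$estimates

#' @export
residuals.glv_fit <- function(object, ...) object$residual_matrix

#' @export
fitted.glv_fit <- function(object, ...) object$fitted

#' @export
print.glv_fit <- function(x, digits = 2, ...) {
  cat("gLV coefficient fit (", length(x$free), " free, RSS = ",
      format(x$rss, digits = 4), ")\n", sep = "")
  for (i in seq_along(x$free)) {
    if (!is.null(x$bootstrap)) {
      cat(sprintf("  %s = %.*f %s %.*f (bootstrap SD, n = %d)\n",
                  x$free[i], digits, x$estimates[i], "±", digits,
                  x$bootstrap$sd[i], x$bootstrap$n))
    } else {
      cat(sprintf("  %s = %.*f\n", x$free[i], digits, x$estimates[i]))
    }
  }
  invisible(x)
}

#' @export
summary.glv_fit <- function(object, ...) {
  df <- data.frame(coefficient = object$free,
                   estimate = unname(object$estimates),
                   lower_bound = object$lower, upper_bound = object$upper)
  if (!is.null(object$bootstrap)) {
    df$boot_sd <- object$bootstrap$sd
    df$ci_lo <- object$bootstrap$ci[1, ]
    df$ci_hi <- object$bootstrap$ci[2, ]
  }
  structure(list(table = df, rss = object$rss,
                 n_converged = object$n_converged,
                 n_starts = object$n_starts,
                 bootstrap = object$bootstrap),
            class = "summary.glv_fit")
}

#' @export
print.summary.glv_fit <- function(x, ...) {
  cat("gLV fit summary: RSS =", format(x$rss, digits = 6), "| converged",
      x$n_converged, "of", x$n_starts, "starts\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
predict.glv_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$fitted)
  m <- .apply_pars(object$skeleton, object$free, object$estimates)
  sim <- .glv_sim_at(m, object$data$observed[1, ], times)
  colnames(sim) <- object$skeleton$ids
  sim
}

#' Bootstrap uncertainty for fitted gLV coefficients
#'
#' Residual-resampling bootstrap (default): log-scale residuals --
#' leverage-adjusted (`r / sqrt(1 - h)`) and re-centred within each strain
#' series, the standard modified-residual recipe for regression bootstraps
#' -- are resampled with replacement within the series (the first row, the
#' initial condition, is never perturbed), pseudo-data are rebuilt around
#' the fitted trajectory, and the model is refit from the point estimate.
#' The leverage adjustment matters here: the kill coefficient's
#' information is concentrated in the steep decline of the pathogen
#' series, and unadjusted residual resampling underestimates the sampling
#' variance. A case-resampling alternative (resampling time points) is
#' available via `scheme = "case"`.
#'
#' @param fit A converged [fit_glv()] result.
#' @param n_resamples Number of bootstrap resamples (default 1000).
#' @param seed RNG seed; identical seeds give bit-identical intervals.
#' @param scheme `"residual"` (default) or `"case"`.
#' @param level Confidence level for the percentile interval.
#' @return The fit augmented with a `bootstrap` element: per-coefficient
#'   `sd`, percentile `ci` (2 x p matrix), the resample `draws`, the
#'   failure count and the seed.
#' @export
bootstrap_ci <- function(fit, n_resamples = 1000, seed = 1,
                         scheme = c("residual", "case"), level = 0.95) {
  stopifnot(inherits(fit, "glv_fit"), fit$converged, n_resamples >= 2)
  scheme <- match.arg(scheme)
  obs <- fit$data$observed
  times <- fit$data$times
  nT <- length(times); p <- length(fit$free)
  lfit <- log10(fit$fitted + 1)
  resmat <- fit$residual_matrix
  draws <- matrix(NA_real_, n_resamples, p,
                  dimnames = list(NULL, fit$free))
  warm_skel <- .apply_pars(fit$skeleton, fit$free, fit$estimates)

  # leverage-adjusted, recentred residuals for the residual scheme
  resmod <- resmat
  if (scheme == "residual") {
    cells <- which(!is.na(resmat) & row(resmat) > 1)
    if (length(cells) > p) {
      J <- matrix(0, length(cells), p)
      base_sim <- log10(fit$fitted + 1)
      for (j in seq_len(p)) {
        h <- pmax(abs(fit$estimates[j]), 0.1) * 1e-4
        pert <- fit$estimates
        pert[j] <- pert[j] + h
        mj <- .apply_pars(fit$skeleton, fit$free, pert)
        simj <- log10(.glv_sim_at(mj, obs[1, ], times) + 1)
        J[, j] <- (simj[cells] - base_sim[cells]) / h
      }
      lev <- try(rowSums((J %*% solve(crossprod(J))) * J), silent = TRUE)
      if (!inherits(lev, "try-error")) {
        resmod[cells] <- resmat[cells] / sqrt(1 - pmin(pmax(lev, 0), 0.95))
      }
    }
    for (j in seq_len(ncol(resmod))) {
      rows <- which(!is.na(resmod[-1, j])) + 1L
      if (length(rows) > 1) {
        resmod[rows, j] <- resmod[rows, j] - mean(resmod[rows, j])
      }
    }
  }
  set.seed(seed)
  n_fail <- 0L
  for (b in seq_len(n_resamples)) {
    if (scheme == "residual") {
      pseudo <- obs
      for (j in seq_len(ncol(obs))) {
        rows <- which(!is.na(resmod[-1, j])) + 1L
        if (!length(rows)) next
        samp <- rows[sample.int(length(rows), length(rows), replace = TRUE)]
        pseudo[rows, j] <- pmax(10^(lfit[rows, j] + resmod[samp, j]) - 1, 0)
      }
      pdata <- coculture_dataset(times, pseudo, ids = fit$data$ids)
    } else {
      rows <- c(1L, sort(sample(2:nT, nT - 1L, replace = TRUE)))
      keep <- !duplicated(rows)
      pdata <- coculture_dataset(times[rows[keep]],
                                 obs[rows[keep], , drop = FALSE],
                                 ids = fit$data$ids)
    }
    # warm start: single start from the point estimate
    refit <- try(fit_glv(pdata, warm_skel, fit$free, fit$lower,
                         fit$upper, n_starts = 1, seed = seed,
                         maxiter = 100), silent = TRUE)
    if (inherits(refit, "try-error")) { n_fail <- n_fail + 1L; next }
    draws[b, ] <- refit$estimates
  }
  if (n_fail > 0.10 * n_resamples) {
    warning(sprintf("bootstrap: %d of %d resamples failed to converge (> 10%%)",
                    n_fail, n_resamples), call. = FALSE)
  }
  okdraws <- draws[stats::complete.cases(draws), , drop = FALSE]
  a <- (1 - level) / 2
  fit$bootstrap <- list(
    n = n_resamples, n_failed = n_fail, seed = seed, scheme = scheme,
    sd = apply(okdraws, 2, stats::sd),
    ci = apply(okdraws, 2, stats::quantile, probs = c(a, 1 - a)),
    draws = draws)
  fit
}

#' Parameter-recovery study on synthetic coculture data
#'
#' Generates `n_replicates` noisy datasets from a known model via
#' [gen_coculture()], refits the free coefficients on each, and tabulates
#' bias and root-mean-square error per coefficient. Fit failures are
#' counted, not fatal.
#'
#' @param truth Generating `glv_model`.
#' @param times Sampling times in hours (at least 3).
#' @param free Free coefficient names (see [fit_glv()]).
#' @param noise Noise specification passed to [gen_coculture()]: list with
#'   `type` (`"none"`, `"lognormal"`, `"plate"`) and `sigma`.
#' @param n_replicates Number of synthetic datasets.
#' @param initial Inoculum vector (defaults to the truth's `"inoculum"`
#'   attribute).
#' @param seed Base seed; replicate b uses `seed + b`.
#' @param ... Passed on to [fit_glv()] (e.g. `n_starts`).
#' @return A data frame with one row per coefficient: `truth`, `mean_est`,
#'   `bias`, `rmse`, `mae` (median absolute error) and `n_ok`; the
#'   per-replicate estimates are attached as attribute `"estimates"`.
#' @export
recovery_study <- function(truth, times, free, noise = list(type = "none"),
                           n_replicates = 20, initial = NULL, seed = 1,
                           ...) {
  stopifnot(length(times) >= 3)
  if (is.null(initial)) initial <- attr(truth, "inoculum")
  stopifnot(!is.null(initial))
  true_vals <- vapply(free, .par_get, 0, model = truth)
  est <- matrix(NA_real_, n_replicates, length(free),
                dimnames = list(NULL, free))
  for (b in seq_len(n_replicates)) {
    dat <- gen_coculture(truth, times, noise = noise, initial = initial,
                         seed = seed + b)
    f <- try(fit_glv(dat, truth, free, seed = seed + b, ...),
             silent = TRUE)
    if (!inherits(f, "try-error")) est[b, ] <- f$estimates
  }
  ok <- stats::complete.cases(est)
  out <- data.frame(
    coefficient = free,
    truth = unname(true_vals),
    mean_est = colMeans(est[ok, , drop = FALSE]),
    bias = colMeans(est[ok, , drop = FALSE]) - unname(true_vals),
    rmse = sqrt(colMeans((est[ok, , drop = FALSE] -
                            rep(true_vals, each = sum(ok)))^2)),
    mae = apply(abs(est[ok, , drop = FALSE] -
                      rep(true_vals, each = sum(ok))), 2, stats::median),
    n_ok = sum(ok))
  attr(out, "estimates") <- est
  rownames(out) <- NULL
  out
}

#' Write a fit result as JSON
#' @param fit A `glv_fit`.
#' @param path File path.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "glv_fit"))
  out <- list(coefficients = as.list(fit$estimates), rss = fit$rss,
              converged = fit$converged, n_starts = fit$n_starts,
              seed = fit$seed)
  if (!is.null(fit$bootstrap)) {
    out$bootstrap <- list(
      n = fit$bootstrap$n, seed = fit$bootstrap$seed,
      scheme = fit$bootstrap$scheme,
      sd = as.list(stats::setNames(fit$bootstrap$sd, fit$free)),
      ci_lower = as.list(stats::setNames(fit$bootstrap$ci[1, ], fit$free)),
      ci_upper = as.list(stats::setNames(fit$bootstrap$ci[2, ], fit$free)))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
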