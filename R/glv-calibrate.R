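# Baseline fixture, bisection calibration of the probiotic antagonism
# coefficient, and the single-strain vs consortium comparison experiment.

#' Default single-probiotic / single-pathogen fixture
#'
#' One probiotic (r = 0.1/h, K = 1e9 CFU/mL) against one pathogen
#' (r = 0.6/h, K = 1e9 CFU/mL) in liquid mode, with a mild pathogen-on-
#' probiotic load (beta = 0.05/h) and a probiotic-on-pathogen kill
#' coefficient `delta` that is normally set by [calibrate_delta()].
#' Inocula follow the standardized suspensions used experimentally:
#' 5e9 CFU/mL probiotic, 1.5e8 CFU/mL pathogen (stored in the
#' `"inoculum"` attribute).
#'
#' @param delta Probiotic-on-pathogen kill coefficient, per hour.
#' @param r_probiotic,r_pathogen Growth rates, per hour.
#' @param K Carrying capacity (both strains), CFU/mL.
#' @param beta Pathogen-on-probiotic loss coefficient, per hour.
#' @return A `glv_model` with an `"inoculum"` attribute.
#' @export
default_fixture <- function(delta = 0, r_probiotic = 0.1, r_pathogen = 0.6,
                            K = 1e9, beta = 0.05) {
  m <- glv_model(
    list(strain_spec("probiotic1", "probiotic", r = r_probiotic, K = K),
         strain_spec("pathogen1", "pathogen", r = r_pathogen, K = K)),
    interaction_set(beta = matrix(beta, 1, 1), delta = matrix(delta, 1, 1)),
    mode = "liquid")
  attr(m, "inoculum") <- c(probiotic1 = 5e9, pathogen1 = 1.5e8)
  m
}

# Extinction time of the (single) pathogen for a fixture model; NA when not
# extinct within the horizon.
.fixture_extinction <- function(model, initial = attr(model, "inoculum"),
                                threshold = 1, output_step = 0.05) {
  tr <- simulate(model, initial = initial, output_step = output_step)
  rep <- time_to_extinction(tr, threshold = threshold)
  if (rep$extinct[1]) rep$time_h[1] else NA_real_
}

# Replace the single delta entry of a 1x1-delta model.
.set_delta <- function(model, delta) {
  model$interactions$delta[1, 1] <- delta
  model
}

#' Calibrate the probiotic antagonism coefficient by bisection
#'
#' Finds the single probiotic-on-pathogen coefficient `delta` for which the
#' simulated pathogen time-to-extinction equals `target_time` within
#' `tol` hours. Extinction time is strictly decreasing in `delta`, so plain
#' bisection over `bounds` suffices.
#'
#' @param target_time Desired extinction time, hours.
#' @param fixture A single-probiotic/single-pathogen `glv_model` skeleton
#'   with an `"inoculum"` attribute; defaults to [default_fixture()].
#' @param bounds Search interval for `delta` (published admissible range
#'   \[0, 2\] by default).
#' @param threshold Extinction threshold, CFU/mL.
#' @param tol Acceptable absolute error on the achieved extinction time,
#'   hours.
#' @param max_iter Bisection iteration cap.
#' @return The calibrated `glv_model`, with attributes `"delta"` (the
#'   calibrated value) and `"achieved_time"` (simulated extinction time).
#' @export
#' @examples
#' \donttest{
#' base <- calibrate_delta(6.5)
#' attr(base, "delta")
#' }
calibrate_delta <- function(target_time, fixture = default_fixture(),
                            bounds = c(0, 2), threshold = 1, tol = 0.05,
                            max_iter = 80L) {
  stopifnot(target_time > 0, length(bounds) == 2, bounds[1] < bounds[2])
  t_hi <- .fixture_extinction(.set_delta(fixture, bounds[2]), threshold = threshold)
  if (is.na(t_hi) || t_hi > target_time + tol) {
    stop(sprintf(
      "target %.2f h unattainable within delta bounds [%g, %g]: delta = %g gives %s h",
      target_time, bounds[1], bounds[2], bounds[2],
      if (is.na(t_hi)) "no extinction" else sprintf("%.2f", t_hi)),
      call. = FALSE)
  }
  t_lo <- .fixture_extinction(.set_delta(fixture, bounds[1]), threshold = threshold)
  if (!is.na(t_lo) && t_lo < target_time - tol) {
    stop(sprintf(
      "target %.2f h unattainable within delta bounds [%g, %g]: delta = %g already gives %.2f h",
      target_time, bounds[1], bounds[2], bounds[1], t_lo), call. = FALSE)
  }
  lo <- bounds[1]; hi <- bounds[2]
  best <- c(delta = hi, time = t_hi)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    tm <- .fixture_extinction(.set_delta(fixture, mid), threshold = threshold)
    if (!is.na(tm) && abs(tm - target_time) < abs(best["time"] - target_time)) {
      best <- c(delta = mid, time = tm)
    }
    if (!is.na(tm) && abs(tm - target_time) <= tol) break
    if (is.na(tm) || tm > target_time) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  if (abs(best["time"] - target_time) > tol) {
    stop(sprintf(
      "bisection did not reach %.2f h within +/- %.2f h (best %.3f h at delta = %.4g; bracket [%g, %g])",
      target_time, tol, best["time"], best["delta"], lo, hi), call. = FALSE)
  }
  out <- .set_delta(fixture, unname(best["delta"]))
  attr(out, "inoculum") <- attr(fixture, "inoculum")
  attr(out, "delta") <- unname(best["delta"])
  attr(out, "achieved_time") <- unname(best["time"])
  out
}

#' Single strain vs multi-strain consortium suppression experiment
#'
#' Replicates the calibrated baseline probiotic `n_strains` times -- each
#' copy with its own kill coefficient (by default the baseline's calibrated
#' value) and its own inoculum -- and compares pathogen time-to-extinction
#' between the single-strain baseline and the consortium. Consortium
#' probiotics do not compete with each other (`alpha` identity), mirroring
#' compartmentalized strain-specific microenvironments, so the total
#' probiotic load scales with `n_strains`.
#'
#' @param baseline A calibrated single-probiotic/single-pathogen
#'   `glv_model` (see [calibrate_delta()]).
#' @param n_strains Number of probiotic strains in the consortium.
#' @param per_strain_inoculum CFU/mL seeded for each consortium probiotic
#'   (defaults to the baseline probiotic inoculum, so total load scales
#'   with `n_strains`).
#' @param delta_table Optional per-strain kill coefficients, length
#'   `n_strains`; defaults to the baseline delta for every strain.
#' @param threshold Extinction threshold, CFU/mL.
#' @return An object of class `"consortium_experiment"`: list with
#'   `baseline_time`, `consortium_time`, `ratio`
#'   (consortium / baseline), `n_strains` and the consortium model.
#' @export
consortium_experiment <- function(baseline, n_strains,
                                  per_strain_inoculum = NULL,
                                  delta_table = NULL, threshold = 1) {
  stopifnot(inherits(baseline, "glv_model"), n_strains >= 1)
  ip <- which(baseline$guild == "probiotic")
  ik <- which(baseline$guild == "pathogen")
  stopifnot(length(ip) == 1, length(ik) == 1)
  inoc <- attr(baseline, "inoculum")
  if (is.null(per_strain_inoculum)) per_strain_inoculum <- inoc[ip]
  if (is.null(delta_table)) {
    delta_table <- rep(baseline$interactions$delta[1, 1], n_strains)
  }
  stopifnot(length(delta_table) == n_strains)

  base_time <- .fixture_extinction(baseline, threshold = threshold)
  pro <- baseline$strains[[ip]]
  pat <- baseline$strains[[ik]]
  strains <- c(lapply(seq_len(n_strains), function(i)
    strain_spec(paste0(pro$id, "_", i), "probiotic", r = pro$r, K = pro$K)),
    list(pat))
  inter <- interaction_set(
    beta = matrix(baseline$interactions$beta[1, 1], n_strains, 1),
    delta = matrix(delta_table, 1, n_strains),
    n_probiotic = n_strains, n_pathogen = 1)
  cons <- glv_model(strains, inter, mode = baseline$mode,
                    horizon = baseline$horizon)
  cons_inoc <- c(rep(per_strain_inoculum, n_strains), inoc[ik])
  cons_time <- .fixture_extinction(cons, initial = cons_inoc,
                                   threshold = threshold)
  structure(list(baseline_time = base_time, consortium_time = cons_time,
                 ratio = cons_time / base_time, n_strains = n_strains,
                 consortium_model = cons, threshold = threshold),
            class = "consortium_experiment")
}

#' @export
print.consortium_experiment <- function(x, ...) {
  cat("Consortium suppression experiment (", x$n_strains, " strains)\n",
      sep = "")
  cat(sprintf("  baseline extinction:   %s h\n",
              if (is.na(x$baseline_time)) "none" else
                sprintf("%.3f", x$baseline_time)))
  cat(sprintf("  consortium extinction: %s h\n",
              if (is.na(x$consortium_time)) "none" else
                sprintf("%.3f", x$consortium_time)))
  cat(sprintf("  ratio (consortium/baseline): %.3f\n", x$ratio))
  invisible(x)
}
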