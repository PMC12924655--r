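# ODE integration of the gLV community and extinction diagnostics.

#' Integrate a gLV community model
#'
#' Solves the community ODE system with a stiff-capable adaptive integrator
#' (`deSolve::lsoda`). Populations that dip below a numerical floor
#' (`clamp`, default 1e-6 CFU) are clamped to zero in the returned
#' trajectory so that extinct populations cannot revive from numerical
#' dust.
#'
#' @param object A [glv_model()].
#' @param nsim,seed Unused (the model is deterministic); present for
#'   compatibility with the [stats::simulate()] generic.
#' @param initial Numeric vector of initial abundances (CFU per unit), one
#'   per strain in model order. All entries must be non-negative.
#' @param horizon Hours to integrate; defaults to the model horizon.
#' @param output_step Output grid spacing in hours.
#' @param rtol,atol Relative and absolute integration tolerances
#'   (defaults 1e-8 and 1e-3 CFU).
#' @param clamp Numerical extinction floor in CFU; values below it are set
#'   to zero.
#' @param ... Ignored.
#'
#' @return An object of class `"glv_trajectory"`: a list with `times`
#'   (hours), `abundance` (matrix, one row per time, one column per
#'   strain) and the generating `model`.
#' @export
#' @examples
#' m <- glv_model(list(strain_spec("p", "probiotic", r = 0.5, K = 1e9)))
#' tr <- simulate(m, initial = 1e7, horizon = 48, output_step = 1)
simulate.glv_model <- function(object, nsim = 1, seed = NULL, initial,
                               horizon = NULL, output_step = 0.1,
                               rtol = 1e-8, atol = 1e-3, clamp = 1e-6, ...) {
  model <- object
  n <- length(model$ids)
  if (length(initial) != n) {
    stop("initial state length ", length(initial), " but model has ", n,
         " strains", call. = FALSE)
  }
  if (any(!is.finite(initial)) || any(initial < 0)) {
    stop("initial abundances must be finite and non-negative", call. = FALSE)
  }
  if (is.null(horizon)) horizon <- model$horizon
  stopifnot(horizon > 0, output_step > 0)
  mats <- .glv_full_matrices(model)
  r <- model$r; K <- model$K; A <- mats$A; C <- mats$C
  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)
    x <- y / K
    dy <- r * y * (1 - as.vector(A %*% y) / K) - y * as.vector(C %*% x)
    list(dy)
  }
  times <- seq(0, horizon, by = output_step)
  if (times[length(times)] < horizon) times <- c(times, horizon)
  out <- try(deSolve::ode(y = as.numeric(initial), times = times, func = rhs,
                          parms = NULL, method = "lsoda",
                          rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(times)) {
    stop("gLV integration failed: ",
         if (inherits(out, "try-error")) attr(out, "condition")$message
         else "integrator stopped early; inspect parameters", call. = FALSE)
  }
  ab <- unname(out[, -1, drop = FALSE])
  ab[ab < clamp] <- 0
  ab[1, ] <- initial  # first row is the supplied initial state exactly
  colnames(ab) <- model$ids
  structure(list(times = out[, 1], abundance = ab, model = model),
            class = "glv_trajectory")
}

#' @export
print.glv_trajectory <- function(x, ...) {
  cat("gLV trajectory: ", length(x$times), " time points over ",
      max(x$times), " h, ", ncol(x$abundance), " strains\n", sep = "")
  fin <- x$abundance[nrow(x$abundance), ]
  cat("final abundances:\n")
  print(signif(fin, 4))
  invisible(x)
}

#' @export
as.data.frame.glv_trajectory <- function(x, ...) {
  data.frame(time_h = x$times, x$abundance, check.names = FALSE)
}

#' @export
plot.glv_trajectory <- function(x, log = "y", ...) {
  ab <- pmax(x$abundance, 1e-2)
  graphics::matplot(x$times, ab, type = "l", lty = 1, log = log,
                    xlab = "time (h)", ylab = "abundance (CFU/unit)", ...)
  graphics::legend("topright", legend = colnames(x$abundance),
                   col = seq_len(ncol(ab)), lty = 1, bty = "n")
  invisible(x)
}

#' Trajectory CSV round-trip
#'
#' First column `time_h`, one column per strain id.
#'
#' @param traj A `glv_trajectory` (or any data frame shaped like one).
#' @param path File path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a list with `times` and `abundance` (class
#'   `"glv_trajectory"` without a model reference).
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(names(df)[1] == "time_h")
  ab <- as.matrix(df[, -1, drop = FALSE])
  structure(list(times = df$time_h, abundance = ab, model = NULL),
            class = "glv_trajectory")
}

#' Time to extinction of each pathogen in a trajectory
#'
#' For each pathogen strain, reports the earliest time its abundance falls
#' below `threshold` and never rises above it again within the horizon,
#' with linear interpolation between output points. A pathogen that starts
#' below threshold (and stays there) has extinction time 0; one still above
#' threshold at the end of the trajectory is reported as not extinct.
#'
#' @param traj A `glv_trajectory` containing at least one pathogen strain.
#' @param threshold Extinction threshold in CFU per unit (default 1; the
#'   definition of "extinct" is a modelling choice, configurable here).
#' @return An object of class `"glv_extinction"`: data frame with columns
#'   `strain`, `extinct` (logical) and `time_h` (`NA` when not extinct),
#'   plus `threshold` and `horizon` attributes.
#' @export
time_to_extinction <- function(traj, threshold = 1) {
  stopifnot(inherits(traj, "glv_trajectory"), threshold > 0)
  model <- traj$model
  if (is.null(model)) {
    stop("trajectory carries no model reference; cannot identify pathogens",
         call. = FALSE)
  }
  ik <- which(model$guild == "pathogen")
  if (!length(ik)) stop("trajectory contains no pathogen strains",
                        call. = FALSE)
  tt <- traj$times
  res <- lapply(ik, function(j) {
    ab <- traj$abundance[, j]
    above <- which(ab >= threshold)
    if (!length(above)) {
      return(data.frame(strain = model$ids[j], extinct = TRUE, time_h = 0))
    }
    last <- max(above)
    if (last == length(ab)) {
      return(data.frame(strain = model$ids[j], extinct = FALSE,
                        time_h = NA_real_))
    }
    # linear interpolation across the final downward crossing
    t0 <- tt[last]; t1 <- tt[last + 1]
    a0 <- ab[last]; a1 <- ab[last + 1]
    tstar <- t0 + (a0 - threshold) / (a0 - a1) * (t1 - t0)
    data.frame(strain = model$ids[j], extinct = TRUE, time_h = tstar)
  })
  out <- do.call(rbind, res)
  structure(out, class = c("glv_extinction", "data.frame"),
            threshold = threshold, horizon = max(tt))
}

#' @export
print.glv_extinction <- function(x, ...) {
  cat("Pathogen extinction report (threshold ", attr(x, "threshold"),
      " CFU/unit, horizon ", attr(x, "horizon"), " h)\n", sep = "")
  df <- as.data.frame(x)
  df$time_h <- ifelse(df$extinct, sprintf("%.3f", df$time_h),
                      "not extinct within horizon")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an extinction report as JSON
#' @param report A `glv_extinction`.
#' @param path File path.
#' @export
write_extinction_report <- function(report, path) {
  stopifnot(inherits(report, "glv_extinction"))
  jsonlite::write_json(
    list(threshold = attr(report, "threshold"),
         horizon_h = attr(report, "horizon"),
         pathogens = as.data.frame(report)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
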