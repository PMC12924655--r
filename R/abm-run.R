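# Replicated ABM runs, exclusion probability, spatial summaries and the
# sensitivity scan.

#' Run seeded replicates of the agent-based model
#'
#' Runs `n_replicates` independent simulations; replicate `i` is seeded
#' with `seed_base + i`, so a whole experiment is reproducible from
#' `seed_base` alone. The exclusion step of a replicate is the first step
#' index (0 = initial state) at which no Type P agent remains.
#'
#' @param config An [abm_grid()].
#' @param params An [abm_params()].
#' @param n_replicates Number of replicates (published design: 10).
#' @param n_iterations Steps per replicate (published design: 500, which at
#'   the default timestep spans 24 h).
#' @param seed_base Base seed.
#' @param keep_world Keep each replicate's final world (needed for
#'   [dominance_heatmap()] and [halo_metric()]; default `TRUE`).
#' @return An object of class `"abm_runs"`: list with `results` (one
#'   `"abm_result"` per replicate, each holding the population `series`,
#'   `exclusion_step`, `seed` and final world), `exclusion_probability`
#'   (fraction of replicates with an exclusion step), and the inputs.
#' @export
abm_run <- function(config = abm_grid(), params = abm_params(),
                    n_replicates = 10, n_iterations = 500, seed_base = 1,
                    keep_world = TRUE) {
  stopifnot(n_replicates >= 1, n_iterations >= 1)
  dt_h <- params$timestep_s / 3600
  results <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    world <- abm_init(config, params, seed = seed_base + i)
    series <- matrix(0, n_iterations + 1L, 4,
                     dimnames = list(NULL, .abm_types))
    series[1, ] <- vapply(world$counts, sum, 0)
    for (s in seq_len(n_iterations)) {
      world <- abm_step(world)
      series[s + 1L, ] <- vapply(world$counts, sum, 0)
    }
    zero <- which(series[, "P"] == 0)
    exclusion_step <- if (length(zero)) zero[1] - 1L else NA_integer_
    results[[i]] <- structure(
      list(series = data.frame(step = 0:n_iterations,
                               time_h = (0:n_iterations) * dt_h,
                               series, check.names = FALSE),
           exclusion_step = exclusion_step,
           seed = seed_base + i,
           world = if (keep_world) world else NULL),
      class = "abm_result")
  }
  excl <- vapply(results, function(r) !is.na(r$exclusion_step), TRUE)
  structure(list(results = results,
                 exclusion_probability = mean(excl),
                 exclusion_steps = vapply(results, `[[`, 0L,
                                          "exclusion_step"),
                 config = config, params = params,
                 n_iterations = n_iterations, seed_base = seed_base),
            class = "abm_runs")
}

#' @export
print.abm_result <- function(x, ...) {
  fin <- x$series[nrow(x$series), .abm_types]
  cat("ABM replicate (seed ", x$seed, "): ",
      if (is.na(x$exclusion_step)) "pathogens not excluded"
      else paste0("pathogens excluded at step ", x$exclusion_step),
      "\n  final counts: ", paste(names(fin), unlist(fin), sep = "=",
                                  collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
print.abm_runs <- function(x, ...) {
  cat("ABM experiment: ", length(x$results), " replicates x ",
      x$n_iterations, " steps (", x$n_iterations *
        x$params$timestep_s / 3600, " h)\n", sep = "")
  cat(sprintf("  pathogen exclusion probability: %.2f\n",
              x$exclusion_probability))
  es <- x$exclusion_steps
  if (any(!is.na(es))) {
    cat("  exclusion steps:", paste(es, collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
plot.abm_result <- function(x, log = "", ...) {
  graphics::matplot(x$series$step, x$series[, .abm_types], type = "l",
                    lty = 1, log = log, xlab = "step",
                    ylab = "agent count", ...)
  graphics::legend("topleft", legend = .abm_types, col = 1:4, lty = 1,
                   bty = "n")
  invisible(x)
}

#' Spatial dominance heatmap
#'
#' Labels each patch with the type holding the highest end-state count,
#' ties broken in the fixed order A > B > C > P; empty patches are labelled
#' `"none"`.
#'
#' @param result An `abm_result` with its final world retained.
#' @return Integer matrix (0 = none, 1 = A, 2 = B, 3 = C, 4 = P) with a
#'   `"levels"` attribute `c("none", "A", "B", "C", "P")`.
#' @export
dominance_heatmap <- function(result) {
  stopifnot(inherits(result, "abm_result"))
  if (is.null(result$world)) {
    stop("replicate was run with keep_world = FALSE", call. = FALSE)
  }
  cnt <- result$world$counts
  stacked <- vapply(.abm_types, function(tp) as.vector(cnt[[tp]]),
                    numeric(length(cnt$A)))
  win <- max.col(stacked, ties.method = "first")  # order A > B > C > P
  win[rowSums(stacked) == 0] <- 0L
  out <- matrix(as.integer(win), nrow(cnt$A), ncol(cnt$A))
  attr(out, "levels") <- c("none", .abm_types)
  out
}

#' Write a dominance heatmap as integer-coded CSV
#' @param heatmap Matrix from [dominance_heatmap()].
#' @param path File path.
#' @export
write_heatmap <- function(heatmap, path) {
  utils::write.table(heatmap, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Type-A peripheral enrichment ("halo") metric
#'
#' Ratio of the Type-A share of agents in the outer annulus of the grid to
#' its share in the interior; values above 1 indicate peripheral
#' enrichment (inhibition-halo morphology).
#'
#' @param result An `abm_result` with its final world retained.
#' @param annulus_fraction Fraction of the half-width forming the outer
#'   annulus, in (0, 0.5).
#' @return The enrichment ratio, or `NA` (with a message) when either
#'   region holds no agents.
#' @export
halo_metric <- function(result, annulus_fraction = 0.25) {
  stopifnot(inherits(result, "abm_result"),
            annulus_fraction > 0, annulus_fraction < 0.5)
  if (is.null(result$world)) {
    stop("replicate was run with keep_world = FALSE", call. = FALSE)
  }
  cnt <- result$world$counts
  nr <- nrow(cnt$A); nc <- ncol(cnt$A)
  depth <- pmin(outer(seq_len(nr), rep(1, nc)) - 1,
                outer(nr - seq_len(nr), rep(1, nc)),
                outer(rep(1, nr), seq_len(nc)) - 1,
                outer(rep(1, nr), nc - seq_len(nc)))
  band <- floor(annulus_fraction * min(nr, nc) / 2)
  outer_ring <- depth < band
  tot <- cnt$A + cnt$B + cnt$C + cnt$P
  n_out <- sum(tot[outer_ring]); n_in <- sum(tot[!outer_ring])
  if (n_out == 0 || n_in == 0) {
    message("halo metric undefined: empty ", if (n_out == 0) "annulus"
            else "interior")
    return(NA_real_)
  }
  share_out <- sum(cnt$A[outer_ring]) / n_out
  share_in <- sum(cnt$A[!outer_ring]) / n_in
  share_out / share_in
}

#' Sensitivity scan over secretion and inhibition parameters
#'
#' Full-factorial scan: for every combination in `param_grid`, runs a
#' seeded replicate set and records the exclusion probability and the mean
#' exclusion step. Grid names address scalar parameters (`p_kill`, `D_m`,
#' `hill_K`) or named components written as `secretion.M1`,
#' `secretion.M2`, `kill_threshold.M1`, `kill_threshold.M2`,
#' `decay.M1`, `decay.M2`.
#'
#' @param config An [abm_grid()].
#' @param params Baseline [abm_params()].
#' @param param_grid Named list of value vectors to cross.
#' @param n_replicates Replicates per grid cell.
#' @param n_iterations Steps per replicate.
#' @param seed_base Base seed; cell j uses `seed_base + (j - 1) *
#'   n_replicates` as its replicate base.
#' @param csv Optional path to write the table as CSV.
#' @return Data frame with one row per cell: the parameter values,
#'   `exclusion_probability` and `mean_exclusion_step`.
#' @export
abm_sensitivity_scan <- function(config, params, param_grid,
                                 n_replicates = 10, n_iterations = 500,
                                 seed_base = 1, csv = NULL) {
  stopifnot(length(param_grid) >= 1, !is.null(names(param_grid)))
  cells <- expand.grid(param_grid, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  for (j in seq_len(nrow(cells))) {
    pj <- params
    for (nm in names(cells)) {
      val <- cells[j, nm]
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      if (length(parts) == 1) {
        pj[[nm]] <- val
      } else {
        pj[[parts[1]]][[parts[2]]] <- val
      }
    }
    runs <- abm_run(config, pj, n_replicates = n_replicates,
                    n_iterations = n_iterations,
                    seed_base = seed_base + (j - 1L) * n_replicates,
                    keep_world = FALSE)
    rows[[j]] <- data.frame(
      cells[j, , drop = FALSE],
      exclusion_probability = runs$exclusion_probability,
      mean_exclusion_step = mean(runs$exclusion_steps, na.rm = TRUE),
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}
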