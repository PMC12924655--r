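# Spatially explicit stochastic agent-based model of a four-guild surface
# community: Type A (Bacillus-like, secretes the lipopeptide field M1),
# Type B (Lactobacillus-like, secretes the organic-acid field M2), Type C
# (Bifidobacterium-like, oxygen-sensitive, cross-feeds on M2 via a Hill
# response) and Type P (pathogens, killed probabilistically where M1 or M2
# exceeds its threshold).
#
# Agents of one type within a patch are exchangeable, so the world state
# stores integer count matrices per type rather than an explicit roster;
# agent_roster() expands the counts when a per-agent view is needed.

.abm_types <- c("A", "B", "C", "P")

#' Grid configuration for the agent-based model
#'
#' @param width,height Grid size in patches (at least 10 each).
#' @param patch_size Patch edge length in cm (default 0.01 cm, i.e. a
#'   100 x 100 grid spans 1 cm^2, the experimental dosing scale).
#' @param layout Named integer vector of initial agent counts per type
#'   (`A`, `B`, `C`, `P`), placed uniformly at random.
#' @return An object of class `"abm_grid"`.
#' @export
abm_grid <- function(width = 100, height = 100, patch_size = 0.01,
                     layout = c(A = 400, B = 600, C = 300, P = 300)) {
  stopifnot(width >= 10, height >= 10, patch_size > 0)
  layout <- layout[.abm_types]
  names(layout) <- .abm_types
  layout[is.na(layout)] <- 0
  if (any(layout < 0)) stop("layout counts must be >= 0", call. = FALSE)
  if (any(layout > width * height * 50)) {
    stop("layout exceeds grid capacity", call. = FALSE)
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 patch_size = patch_size, layout = layout),
            class = "abm_grid")
}

#' Parameters of the agent-based model
#'
#' Defaults reproduce the published run conditions: 172.8 s timesteps so
#' that 500 iterations span 24 h, metabolite diffusion 1e-6 cm^2/s
#' (admissible 1e-7 to 1e-5), pathogen kill probability 0.2 per timestep
#' above threshold, and biofilm transition at 20 agents per patch. The
#' remaining rates (secretion, decay, thresholds, nutrient and oxygen
#' budgets, Hill constants) are package defaults calibrated once against
#' the reported exclusion dynamics; see the methods vignette.
#'
#' @param timestep_s Timestep in seconds (~3 min).
#' @param r Named per-type growth rates, per hour.
#' @param secretion Named secretion rates, field units per agent per step
#'   (`M1` by Type A, `M2` by Type B).
#' @param D_m Metabolite diffusion coefficient, cm^2/s.
#' @param decay Named per-step fractional decay of M1 and M2.
#' @param hill_K,hill_n Hill half-saturation (field units) and exponent for
#'   Type C cross-feeding on M2.
#' @param hill_base Baseline fraction of Type C growth available without
#'   any M2.
#' @param kill_threshold Named thresholds on local M1 and M2 above which a
#'   pathogen agent is at risk.
#' @param p_kill Kill probability per at-risk pathogen per timestep.
#' @param ratio_mode When `TRUE`, risk is triggered by the ratio M1/M2
#'   exceeding `kill_threshold["M1"]` instead of the default reading in
#'   which either field exceeding its own threshold triggers risk.
#' @param biofilm_threshold Patch occupancy (all types) at which the patch
#'   is flagged as biofilm.
#' @param hydration Scalar hydration factor in \[0, 1\] multiplying all
#'   growth (default 0.6, mid-range of the measured film water activity).
#' @param o2_max,o2_consumption Oxygen ceiling and per-division oxygen
#'   consumption (Types A, B, P; Type C is anaerobic and instead grows by
#'   the factor `1 - O2/o2_max`).
#' @param nutrient_init,nutrient_per_division Initial nutrient per patch
#'   and cost per division (no replenishment by default; surface
#'   scenario).
#' @param nutrient_inflow Nutrient added per patch per step.
#' @param starvation_level,p_starve Nutrient level below which agents
#'   starve, and their death probability per step (biofilm-flagged patches
#'   are exempt).
#' @param crowding_cap Soft per-patch, per-type cap above which daughters
#'   spill to a random neighbour patch.
#' @param growth_enabled,starvation_enabled Master switches used by
#'   controlled kill-law experiments.
#' @param strict Enforce the published admissible diffusion range.
#' @return An object of class `"abm_params"`.
#' @export
abm_params <- function(timestep_s = 172.8,
                       r = c(A = 0.6, B = 0.7, C = 0.5, P = 0.6),
                       secretion = c(M1 = 1, M2 = 1),
                       D_m = 1e-6,
                       decay = c(M1 = 0.01, M2 = 0.01),
                       hill_K = 10, hill_n = 2, hill_base = 0.1,
                       kill_threshold = c(M1 = 70, M2 = 150),
                       p_kill = 0.2, ratio_mode = FALSE,
                       biofilm_threshold = 20, hydration = 0.6,
                       o2_max = 1, o2_consumption = 0.08,
                       nutrient_init = 1, nutrient_per_division = 0.02,
                       nutrient_inflow = 0,
                       starvation_level = 0.05, p_starve = 0.02,
                       crowding_cap = 30,
                       growth_enabled = TRUE, starvation_enabled = TRUE,
                       strict = TRUE) {
  stopifnot(timestep_s > 0, p_kill >= 0, p_kill <= 1,
            biofilm_threshold >= 1, hydration >= 0, hydration <= 1,
            hill_K > 0, hill_n > 0, crowding_cap >= 1)
  if (D_m < 1e-7 || D_m > 1e-5) {
    msg <- sprintf("D_m = %g outside published range [1e-7, 1e-5] cm^2/s", D_m)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  r <- r[.abm_types]
  structure(as.list(environment()), class = "abm_params")
}

#' @export
print.abm_params <- function(x, ...) {
  cat("ABM parameters:\n")
  cat(sprintf("  timestep %.1f s (500 iterations = %.1f h)\n",
              x$timestep_s, 500 * x$timestep_s / 3600))
  cat(sprintf("  D_m %.2g cm^2/s | p_kill %.2f/step | biofilm at >= %d\n",
              x$D_m, x$p_kill, x$biofilm_threshold))
  invisible(x)
}

#' Hill saturation response
#'
#' `c^n / (K_half^n + c^n)`, the factor by which an M2 concentration `c`
#' boosts Type C growth: 0 at `c = 0`, 0.5 at `c = K_half`, approaching 1.
#'
#' @param concentration Non-negative concentration(s).
#' @param K_half Half-saturation constant (> 0).
#' @param n Hill exponent (> 0).
#' @return Values in \[0, 1\], same shape as `concentration`.
#' @export
hill_response <- function(concentration, K_half, n) {
  stopifnot(K_half > 0, n > 0)
  if (any(concentration < 0)) {
    stop("negative concentration", call. = FALSE)
  }
  cn <- concentration^n
  cn / (K_half^n + cn)
}

#' Explicit no-flux diffusion of a patch field
#'
#' Five-point-stencil explicit diffusion with reflecting (no-flux)
#' boundaries. The step is automatically split into substeps so each
#' substep satisfies the explicit stability criterion
#' `D * dt_sub / h^2 <= 0.25`. Total mass is conserved exactly (up to
#' floating point).
#'
#' @param field Numeric matrix of concentrations.
#' @param D Diffusion coefficient, cm^2/s.
#' @param dt Time interval, seconds.
#' @param patch_size Patch edge length, cm.
#' @return The diffused field matrix.
#' @export
abm_diffuse <- function(field, D, dt, patch_size) {
  if (any(!is.finite(field))) stop("non-finite field values", call. = FALSE)
  if (D <= 0 || dt <= 0) return(field)
  a_total <- D * dt / patch_size^2
  n_sub <- max(1L, ceiling(a_total / 0.25))
  a <- a_total / n_sub
  nr <- nrow(field); nc <- ncol(field)
  for (s in seq_len(n_sub)) {
    up    <- field[c(1L, seq_len(nr - 1L)), , drop = FALSE]
    down  <- field[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
    left  <- field[, c(1L, seq_len(nc - 1L)), drop = FALSE]
    right <- field[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
    field <- field + a * (up + down + left + right - 4 * field)
  }
  field
}

#' Initialize an ABM world
#'
#' Places the configured agent counts uniformly at random on the grid and
#' initializes fields (nutrient and oxygen uniform, metabolites zero).
#' Reproducible: the same `(config, params, seed)` give an identical
#' world.
#'
#' @param config An [abm_grid()].
#' @param params An [abm_params()].
#' @param seed Integer RNG seed.
#' @return An object of class `"abm_world"`.
#' @export
abm_init <- function(config, params = abm_params(), seed = 1) {
  stopifnot(inherits(config, "abm_grid"), inherits(params, "abm_params"))
  set.seed(seed)
  nr <- config$height; nc <- config$width
  counts <- lapply(stats::setNames(.abm_types, .abm_types), function(tp) {
    m <- matrix(0L, nr, nc)
    n <- config$layout[[tp]]
    if (n > 0) {
      idx <- sample.int(nr * nc, n, replace = TRUE)
      tab <- tabulate(idx, nbins = nr * nc)
      m <- matrix(as.integer(tab), nr, nc)
    }
    m
  })
  structure(list(
    config = config, params = params, step = 0L, seed = seed,
    counts = counts,
    fields = list(nutrient = matrix(params$nutrient_init, nr, nc),
                  o2 = matrix(params$o2_max, nr, nc),
                  M1 = matrix(0, nr, nc), M2 = matrix(0, nr, nc)),
    biofilm = matrix(FALSE, nr, nc)),
    class = "abm_world")
}

#' @export
print.abm_world <- function(x, ...) {
  tot <- vapply(x$counts, sum, 0)
  cat("ABM world ", x$config$width, "x", x$config$height, " at step ",
      x$step, "\n  agents: ", paste(names(tot), tot, sep = "=",
                                    collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Expand the world's patch counts into a per-agent roster
#'
#' @param world An `abm_world`.
#' @return Data frame with columns `type`, `row`, `col`.
#' @export
agent_roster <- function(world) {
  out <- lapply(.abm_types, function(tp) {
    m <- world$counts[[tp]]
    idx <- which(m > 0)
    if (!length(idx)) return(NULL)
    n <- m[idx]
    data.frame(type = tp,
               row = rep(((idx - 1L) %% nrow(m)) + 1L, n),
               col = rep(((idx - 1L) %/% nrow(m)) + 1L, n))
  })
  do.call(rbind, out)
}

# Move per-patch overflow counts to one uniformly drawn neighbour patch
# each; moves that would leave the grid stay in place (no-flux analogue).
.spill <- function(over) {
  if (!any(over > 0)) return(over * 0L)
  nr <- nrow(over); nc <- ncol(over)
  idx <- which(over > 0)
  dirs <- sample.int(4L, length(idx), replace = TRUE)
  moved <- matrix(0L, nr, nc)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  dr <- c(-1L, 1L, 0L, 0L)[dirs]
  dc <- c(0L, 0L, -1L, 1L)[dirs]
  nrw <- rows + dr; ncl <- cols + dc
  keep <- nrw < 1L | nrw > nr | ncl < 1L | ncl > nc
  nrw[keep] <- rows[keep]; ncl[keep] <- cols[keep]
  tgt <- (ncl - 1L) * nr + nrw
  for (g in seq_along(idx)) {
    moved[tgt[g]] <- moved[tgt[g]] + over[idx[g]]
  }
  moved
}

#' Advance the ABM world by one timestep
#'
#' Processes, in fixed order: (1) growth/division per type (binomial draws
#' with probability r * dt * nutrient * O2-response * hydration, Type C
#' additionally boosted by the Hill response to local M2), with nutrient
#' and oxygen consumption and daughter spill-over above the crowding cap;
#' (2) secretion of M1 by Type A and M2 by Type B; (3) diffusion of M1, M2
#' and O2 (boundary re-oxygenation) and metabolite decay; (4) antagonism:
#' each pathogen whose patch has M1 or M2 above threshold dies with
#' probability `p_kill`; (5) biofilm flagging of patches at or above the
#' occupancy threshold; (6) starvation death where nutrient is exhausted
#' (biofilm patches exempt). Random draws are consumed in this documented
#' order, so runs are reproducible given the world's RNG state.
#'
#' @param world An `abm_world`.
#' @param params Defaults to the world's parameters.
#' @return The advanced `abm_world`.
#' @export
abm_step <- function(world, params = world$params) {
  p <- params
  cfg <- world$config
  nr <- cfg$height; nc <- cfg$width
  npatch <- nr * nc
  dt_h <- p$timestep_s / 3600
  nutrient <- world$fields$nutrient
  o2 <- world$fields$o2
  M1 <- world$fields$M1
  M2 <- world$fields$M2
  counts <- world$counts

  # (1) growth --------------------------------------------------------------
  if (p$growth_enabled) {
    nutr_f <- pmin(pmax(nutrient / p$nutrient_init, 0), 1)
    o2_f_aer <- pmin(pmax(o2 / p$o2_max, 0), 1)
    o2_f_ana <- 1 - o2_f_aer
    hill_f <- p$hill_base + (1 - p$hill_base) *
      hill_response(M2, p$hill_K, p$hill_n)
    for (tp in .abm_types) {
      fac <- if (tp == "C") o2_f_ana * hill_f else o2_f_aer
      pdiv <- pmin(p$r[[tp]] * dt_h * nutr_f * fac * p$hydration, 1)
      cnt <- counts[[tp]]
      births <- matrix(stats::rbinom(npatch, as.vector(cnt),
                                     as.vector(pdiv)), nr, nc)
      # nutrient budget caps divisions
      if (p$nutrient_per_division > 0) {
        cap <- floor(pmax(nutrient, 0) / p$nutrient_per_division)
        births <- pmin(births, cap)
        nutrient <- nutrient - births * p$nutrient_per_division
      }
      if (tp != "C" && p$o2_consumption > 0) {
        o2 <- pmax(o2 - births * p$o2_consumption, 0)
      }
      newcnt <- cnt + births
      over <- pmax(newcnt - p$crowding_cap, 0L)
      counts[[tp]] <- newcnt - over + .spill(over)
    }
  }

  # (2) secretion -----------------------------------------------------------
  M1 <- M1 + p$secretion[["M1"]] * counts$A
  M2 <- M2 + p$secretion[["M2"]] * counts$B

  # (3) diffusion and decay -------------------------------------------------
  if (p$D_m > 0) {
    M1 <- abm_diffuse(M1, p$D_m, p$timestep_s, cfg$patch_size)
    M2 <- abm_diffuse(M2, p$D_m, p$timestep_s, cfg$patch_size)
  }
  M1 <- M1 * (1 - p$decay[["M1"]])
  M2 <- M2 * (1 - p$decay[["M2"]])
  o2[1, ] <- p$o2_max; o2[nr, ] <- p$o2_max
  o2[, 1] <- p$o2_max; o2[, nc] <- p$o2_max
  if (p$D_m > 0) o2 <- abm_diffuse(o2, p$D_m, p$timestep_s, cfg$patch_size)

  # (4) antagonism ----------------------------------------------------------
  if (p$p_kill > 0 && sum(counts$P) > 0) {
    at_risk <- if (p$ratio_mode) {
      (M1 / pmax(M2, .Machine$double.eps)) > p$kill_threshold[["M1"]]
    } else {
      (M1 > p$kill_threshold[["M1"]]) | (M2 > p$kill_threshold[["M2"]])
    }
    exposed <- ifelse(at_risk, as.vector(counts$P), 0L)
    kills <- matrix(stats::rbinom(npatch, exposed, p$p_kill), nr, nc)
    counts$P <- counts$P - kills
  }

  # (5) biofilm transition --------------------------------------------------
  occupancy <- counts$A + counts$B + counts$C + counts$P
  biofilm <- world$biofilm | (occupancy >= p$biofilm_threshold)

  # (6) starvation ----------------------------------------------------------
  if (p$starvation_enabled && p$p_starve > 0) {
    starving <- (nutrient < p$starvation_level) & !biofilm
    pdie <- ifelse(starving, p$p_starve, 0)
    for (tp in .abm_types) {
      deaths <- matrix(stats::rbinom(npatch, as.vector(counts[[tp]]),
                                     as.vector(pdie)), nr, nc)
      counts[[tp]] <- counts[[tp]] - deaths
    }
  }
  if (p$nutrient_inflow > 0) nutrient <- nutrient + p$nutrient_inflow

  world$counts <- counts
  world$fields <- list(nutrient = nutrient, o2 = o2, M1 = M1, M2 = M2)
  world$biofilm <- biofilm
  world$step <- world$step + 1L
  world
}
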