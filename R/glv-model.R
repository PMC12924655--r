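# Model constructors and validation for the generalized Lotka-Volterra
# (gLV) probiotic-pathogen community.
#
# Guild convention: probiotics are indexed i, j; pathogens k, m.  Intra-guild
# competition is logistic (alpha within probiotics, gamma within pathogens,
# both scaled by the focal strain's carrying capacity as printed in the
# equations).  Cross-guild antagonism acts on the antagonist's density
# normalized by its own carrying capacity, so beta and delta carry units of
# per hour and their admissible magnitudes match the published coefficient
# ranges (see the methods vignette for the nondimensionalization argument).

# Published admissible parameter ranges (used for strict validation).
.glv_ranges <- list(
  r     = c(0.05, 1.5),   # per hour
  alpha = c(-1, 1),       # dimensionless
  gamma = c(-1, 1),
  beta  = c(0, 2),        # per hour (normalized antagonism)
  delta = c(0, 2)
)

#' Define a strain for a gLV community model
#'
#' @param id Short unique label.
#' @param guild `"probiotic"` or `"pathogen"`.
#' @param r Intrinsic growth rate, per hour. The published admissible range
#'   is 0.05--1.5/h; values outside it are rejected when `strict = TRUE`.
#' @param K Carrying capacity in CFU per unit (CFU/mL in liquid mode,
#'   CFU/cm^2 in surface mode). Must be positive.
#' @param strict Enforce the published growth-rate range.
#'
#' @return An object of class `"strain_spec"`.
#' @export
#' @examples
#' strain_spec("Bp33", "probiotic", r = 0.1, K = 1e9)
strain_spec <- function(id, guild = c("probiotic", "pathogen"), r, K,
                        strict = TRUE) {
  guild <- match.arg(guild)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.finite(r) || !is.finite(K)) {
    stop("strain '", id, "': non-finite parameter", call. = FALSE)
  }
  if (K <= 0) stop("strain '", id, "': K must be > 0", call. = FALSE)
  .check_range(r, .glv_ranges$r, strict, sprintf("growth rate r of '%s'", id))
  structure(list(id = id, guild = guild, r = r, K = K),
            class = "strain_spec")
}

.check_range <- function(x, rng, strict, what) {
  bad <- x < rng[1] | x > rng[2]
  if (any(bad, na.rm = TRUE)) {
    msg <- sprintf("%s outside published range [%g, %g]", what, rng[1], rng[2])
    if (strict) stop(msg, call. = FALSE)
    warning(msg, " (strict range checking off)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Bundle gLV interaction matrices
#'
#' Holds the four coefficient families: `alpha` (probiotic x probiotic
#' competition), `gamma` (pathogen x pathogen competition), `beta`
#' (pathogen-on-probiotic loss) and `delta` (probiotic-on-pathogen loss,
#' i.e. the probiotic antagonism that drives pathogen exclusion).
#'
#' Diagonals of `alpha` and `gamma` are fixed at 1 so the intra-guild term
#' reduces to ordinary logistic self-limitation.
#'
#' @param alpha `n_p x n_p` matrix, dimensionless, entries in \[-1, 1\]
#'   under strict ranges. Defaults to the identity (no inter-strain
#'   competition, mirroring compartmentalized strain microenvironments).
#' @param beta `n_p x n_k` matrix, per hour, entries in \[0, 2\] under
#'   strict ranges: row i, column k is the loss rate on probiotic i per
#'   unit normalized pathogen-k density.
#' @param gamma `n_k x n_k` matrix, like `alpha` but for pathogens.
#' @param delta `n_k x n_p` matrix, per hour, entries in \[0, 2\] under
#'   strict ranges: row k, column i is the kill rate on pathogen k per unit
#'   normalized probiotic-i density.
#' @param n_probiotic,n_pathogen Guild sizes, used to build identity/zero
#'   defaults for omitted matrices.
#' @param strict Enforce published coefficient ranges.
#'
#' @return An object of class `"interaction_set"`.
#' @export
interaction_set <- function(alpha = NULL, beta = NULL, gamma = NULL,
                            delta = NULL, n_probiotic = NULL,
                            n_pathogen = NULL, strict = TRUE) {
  if (is.null(n_probiotic)) {
    n_probiotic <- if (!is.null(alpha)) nrow(as.matrix(alpha)) else
      if (!is.null(beta)) nrow(as.matrix(beta)) else
      if (!is.null(delta)) ncol(as.matrix(delta)) else 0L
  }
  if (is.null(n_pathogen)) {
    n_pathogen <- if (!is.null(gamma)) nrow(as.matrix(gamma)) else
      if (!is.null(delta)) nrow(as.matrix(delta)) else
      if (!is.null(beta)) ncol(as.matrix(beta)) else 0L
  }
  if (is.null(alpha)) alpha <- diag(nrow = n_probiotic)
  if (is.null(gamma)) gamma <- diag(nrow = n_pathogen)
  if (is.null(beta)) beta <- matrix(0, n_probiotic, n_pathogen)
  if (is.null(delta)) delta <- matrix(0, n_pathogen, n_probiotic)
  alpha <- as.matrix(alpha); beta <- as.matrix(beta)
  gamma <- as.matrix(gamma); delta <- as.matrix(delta)

  .dim_check(alpha, n_probiotic, n_probiotic, "alpha")
  .dim_check(beta, n_probiotic, n_pathogen, "beta")
  .dim_check(gamma, n_pathogen, n_pathogen, "gamma")
  .dim_check(delta, n_pathogen, n_probiotic, "delta")
  for (nm in c("alpha", "beta", "gamma", "delta")) {
    m <- get(nm)
    if (any(!is.finite(m))) stop("non-finite entries in ", nm, call. = FALSE)
    .check_range(m, .glv_ranges[[nm]], strict,
                 sprintf("interaction matrix %s entries", nm))
  }
  if (n_probiotic > 0 && any(diag(alpha) != 1)) {
    stop("alpha diagonal must equal 1 (logistic self-limitation convention)",
         call. = FALSE)
  }
  if (n_pathogen > 0 && any(diag(gamma) != 1)) {
    stop("gamma diagonal must equal 1 (logistic self-limitation convention)",
         call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta),
            class = "interaction_set")
}

.dim_check <- function(m, nr, nc, what) {
  if (nrow(m) != nr || ncol(m) != nc) {
    stop(sprintf("matrix %s has shape %dx%d, expected %dx%d",
                 what, nrow(m), ncol(m), nr, nc), call. = FALSE)
  }
  invisible(TRUE)
}

#' Build a gLV community model
#'
#' Assembles validated strain specifications and interaction matrices into a
#' community model ready for integration. The dynamics are, for probiotic i
#' and pathogen k (P in CFU per unit, x = P/K the normalized density):
#'
#' \deqn{dP_i/dt = r_i P_i (1 - \sum_j \alpha_{ij} P_j / K_i)
#'       - \sum_k \beta_{ik} P_i x_k}
#' \deqn{dP_k/dt = r_k P_k (1 - \sum_m \gamma_{km} P_m / K_k)
#'       - \sum_i \delta_{ki} P_k x_i}
#'
#' @param strains List of [strain_spec()] objects (probiotics and pathogens
#'   in any order; internal bookkeeping is by guild).
#' @param interactions An [interaction_set()] whose shapes match the guild
#'   counts. Defaults to identity competition and zero antagonism.
#' @param mode `"liquid"` (K in CFU/mL, default horizon 48 h) or
#'   `"surface"` (K in CFU/cm^2, default horizon 504 h = 21 days).
#' @param horizon Integration horizon in hours; `NULL` takes the mode
#'   default.
#' @param strict Enforce published parameter ranges; when `FALSE`,
#'   out-of-range values are accepted with a warning.
#'
#' @return An object of class `"glv_model"`.
#' @export
#' @examples
#' pro <- strain_spec("probiotic1", "probiotic", r = 0.1, K = 1e9)
#' pat <- strain_spec("pathogen1", "pathogen", r = 0.6, K = 1e9)
#' m <- glv_model(list(pro, pat))
glv_model <- function(strains, interactions = NULL,
                      mode = c("liquid", "surface"), horizon = NULL,
                      strict = TRUE) {
  mode <- match.arg(mode)
  if (inherits(strains, "strain_spec")) strains <- list(strains)
  if (length(strains) < 1L) stop("at least one strain required", call. = FALSE)
  stopifnot(all(vapply(strains, inherits, TRUE, "strain_spec")))
  ids <- vapply(strains, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate strain ids", call. = FALSE)
  guild <- vapply(strains, `[[`, "", "guild")
  n_p <- sum(guild == "probiotic")
  n_k <- sum(guild == "pathogen")
  if (is.null(interactions)) {
    interactions <- interaction_set(n_probiotic = n_p, n_pathogen = n_k)
  }
  stopifnot(inherits(interactions, "interaction_set"))
  .dim_check(interactions$alpha, n_p, n_p, "alpha")
  .dim_check(interactions$beta, n_p, n_k, "beta")
  .dim_check(interactions$gamma, n_k, n_k, "gamma")
  .dim_check(interactions$delta, n_k, n_p, "delta")
  if (is.null(horizon)) horizon <- if (mode == "liquid") 48 else 504
  stopifnot(is.finite(horizon), horizon > 0)
  structure(
    list(strains = strains, interactions = interactions, mode = mode,
         horizon = horizon, ids = ids, guild = guild,
         r = vapply(strains, `[[`, 0, "r"),
         K = vapply(strains, `[[`, 0, "K")),
    class = "glv_model")
}

#' @export
print.glv_model <- function(x, ...) {
  cat("gLV community model (", x$mode, " mode, horizon ", x$horizon,
      " h)\n", sep = "")
  cat("  probiotics:", sum(x$guild == "probiotic"),
      " pathogens:", sum(x$guild == "pathogen"), "\n")
  df <- data.frame(id = x$ids, guild = x$guild, r = x$r, K = x$K)
  print(df, row.names = FALSE)
  invisible(x)
}

# Full-community coefficient matrices in strain order: A is the intra-guild
# competition block matrix (zero across guilds), C the cross-guild loss
# matrix acting on normalized densities.
.glv_full_matrices <- function(model) {
  n <- length(model$ids)
  ip <- which(model$guild == "probiotic")
  ik <- which(model$guild == "pathogen")
  A <- matrix(0, n, n)
  C <- matrix(0, n, n)
  A[ip, ip] <- model$interactions$alpha
  A[ik, ik] <- model$interactions$gamma
  if (length(ip) && length(ik)) {
    C[ip, ik] <- model$interactions$beta
    C[ik, ip] <- model$interactions$delta
  }
  list(A = A, C = C)
}

#' Write / read a gLV model configuration as JSON
#'
#' The JSON layout has keys `strains` (id, guild, r, K), `interactions`
#' (alpha, beta, gamma, delta), `mode` and `horizon_h`.
#'
#' @param model A `glv_model`.
#' @param path File path.
#' @param strict Passed to the validating constructors on read.
#' @return `write_glv_config` returns `path` invisibly; `read_glv_config`
#'   returns a `glv_model`.
#' @export
write_glv_config <- function(model, path) {
  stopifnot(inherits(model, "glv_model"))
  cfg <- list(
    strains = lapply(model$strains, function(s)
      list(id = s$id, guild = s$guild, r = s$r, K = s$K)),
    interactions = lapply(model$interactions[c("alpha", "beta", "gamma",
                                               "delta")], unclass),
    mode = model$mode,
    horizon_h = model$horizon
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_glv_config
#' @export
read_glv_config <- function(path, strict = TRUE) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  strains <- lapply(seq_len(nrow(cfg$strains)), function(i)
    strain_spec(cfg$strains$id[i], cfg$strains$guild[i],
                r = cfg$strains$r[i], K = cfg$strains$K[i], strict = strict))
  as_mat <- function(m) if (is.null(dim(m))) matrix(m, nrow = 1) else as.matrix(m)
  n_p <- sum(cfg$strains$guild == "probiotic")
  n_k <- sum(cfg$strains$guild == "pathogen")
  fix <- function(m, nr, nc) {
    if (is.null(m) || length(m) == 0) return(NULL)
    matrix(as.numeric(as_mat(m)), nr, nc)
  }
  inter <- interaction_set(
    alpha = fix(cfg$interactions$alpha, n_p, n_p),
    beta = fix(cfg$interactions$beta, n_p, n_k),
    gamma = fix(cfg$interactions$gamma, n_k, n_k),
    delta = fix(cfg$interactions$delta, n_k, n_k * 0 + n_p),
    n_probiotic = n_p, n_pathogen = n_k, strict = strict)
  glv_model(strains, inter, mode = cfg$mode, horizon = cfg$horizon_h,
            strict = strict)
}
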