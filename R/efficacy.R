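# Disinfection-trial arithmetic and statistics: CFU enumeration from
# serial-dilution plate counts, log/percentage reduction, pooled t-test
# comparisons, inhibition-zone summaries and formulation concentration
# math.

#' Build a plate-count table
#'
#' @param colonies Integer colony counts (>= 0).
#' @param dilution Ten-fold dilution factors (>= 1), e.g. `1e4` for the
#'   fourth decimal dilution.
#' @param volume_ml Plated volume in mL (default 0.05, i.e. 50 uL
#'   aliquots).
#' @param replicate Replicate labels (defaults to sequence).
#' @return Data frame of class `"plate_counts"`.
#' @export
plate_counts <- function(colonies, dilution, volume_ml = 0.05,
                         replicate = seq_along(colonies)) {
  stopifnot(length(colonies) >= 1, all(colonies >= 0), all(dilution >= 1),
            all(volume_ml > 0))
  df <- data.frame(colonies = as.integer(colonies),
                   dilution = dilution,
                   volume_ml = volume_ml,
                   replicate = replicate)
  class(df) <- c("plate_counts", "data.frame")
  df
}

#' Viable density from serial-dilution plate counts
#'
#' Keeps only plates whose colony count lies in the countable window
#' (30--100 inclusive), averages replicate counts within each dilution
#' level, converts each usable level to a density
#' (mean count / plated volume x dilution factor), averages across usable
#' levels, and reports log10 CFU/mL. When no plate is countable the result
#' is an explicit "uncountable" record -- never an extrapolation.
#'
#' @param counts A [plate_counts()] table (or data frame with columns
#'   `colonies`, `dilution`, `volume_ml`).
#' @param window Countable colony window, closed interval (default
#'   `c(30, 100)`).
#' @return List of class `"cfu_estimate"`: `log10_cfu` (NA when
#'   uncountable), `cfu_per_ml`, `countable` flag, `dilutions_used` and
#'   `dilutions_rejected`.
#' @export
#' @examples
#' cfu_from_counts(plate_counts(c(50, 50), dilution = 1e4))
cfu_from_counts <- function(counts, window = c(30, 100)) {
  stopifnot(nrow(counts) >= 1)
  ok <- counts$colonies >= window[1] & counts$colonies <= window[2]
  used <- counts[ok, , drop = FALSE]
  rejected <- unique(counts$dilution[!ok])
  if (!nrow(used)) {
    return(structure(list(log10_cfu = NA_real_, cfu_per_ml = NA_real_,
                          countable = FALSE,
                          dilutions_used = numeric(0),
                          dilutions_rejected = rejected),
                     class = "cfu_estimate"))
  }
  per_level <- vapply(split(used, used$dilution), function(d)
    mean(d$colonies) / d$volume_ml[1] * d$dilution[1], 0)
  dens <- mean(per_level)
  structure(list(log10_cfu = log10(dens), cfu_per_ml = dens,
                 countable = TRUE,
                 dilutions_used = as.numeric(names(per_level)),
                 dilutions_rejected = setdiff(rejected,
                                              as.numeric(names(per_level)))),
            class = "cfu_estimate")
}

#' @export
print.cfu_estimate <- function(x, ...) {
  if (!x$countable) {
    cat("CFU estimate: uncountable (no plate within the countable window)\n")
  } else {
    cat(sprintf("CFU estimate: %.2f log10 CFU/mL (%.3g CFU/mL) from dilution(s) %s\n",
                x$log10_cfu, x$cfu_per_ml,
                paste(format(x$dilutions_used, scientific = TRUE),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Log10 reduction
#'
#' `LR = control - treated` on the log10 CFU scale. Negative values
#' (growth under treatment) are reported as such. Vectorized.
#'
#' @param control,treated Viable densities, log10 CFU per unit.
#' @return Log reduction(s).
#' @export
log_reduction <- function(control, treated) {
  stopifnot(all(is.finite(control)), all(is.finite(treated)))
  control - treated
}

#' Percentage reduction from a log reduction
#'
#' `PR = (1 - 10^-LR) x 100`. Exact at full precision; rounding is a
#' reporting concern.
#'
#' @param LR Log10 reduction(s).
#' @return Percentage reduction(s).
#' @export
#' @examples
#' percent_reduction(2.46)  # 99.65 at 2 d.p.
percent_reduction <- function(LR) {
  stopifnot(all(is.finite(LR)))
  (1 - 10^(-LR)) * 100
}

#' Two-group comparison by pooled Student's t-test
#'
#' Classical unpaired, two-tailed, pooled-variance Student's t-test (the
#' named test of the trial design); Welch's correction is available behind
#' `welch = TRUE`. When both groups have zero variance and equal means the
#' comparison is reported as t = 0, p = 1 by convention.
#'
#' @param a,b Numeric replicate vectors (each n >= 2).
#' @param welch Use Welch's unequal-variance t-test instead.
#' @param alpha Significance level for the flag (default 0.05).
#' @return List of class `"group_comparison"`: `t`, `df`, `p_value`,
#'   `significant`, group means and sizes.
#' @export
compare_groups <- function(a, b, welch = FALSE, alpha = 0.05) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      res <- list(statistic = 0, parameter = length(a) + length(b) - 2,
                  p.value = 1)
    } else {
      res <- list(statistic = sign(mean(a) - mean(b)) * Inf,
                  parameter = length(a) + length(b) - 2, p.value = 0)
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = !welch)
    res <- list(statistic = unname(ht$statistic),
                parameter = unname(ht$parameter), p.value = ht$p.value)
  }
  structure(list(t = res$statistic, df = res$parameter,
                 p_value = res$p.value,
                 significant = res$p.value < alpha,
                 mean_a = mean(a), mean_b = mean(b),
                 n_a = length(a), n_b = length(b), welch = welch),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s t-test: t = %.4f, df = %.4g, p = %.4g%s\n",
              if (x$welch) "Welch" else "Pooled Student's",
              x$t, x$df, x$p_value,
              if (x$significant) " (significant at 0.05)" else ""))
  invisible(x)
}

#' Build an inhibition-zone record table
#'
#' @param strain Strain labels.
#' @param diameter_mm Inhibition zone diameters, mm (>= 0).
#' @param subculture `"Positive"` (regrowth: bacteriostatic) or
#'   `"Negative"` (no regrowth: bactericidal).
#' @return Data frame of class `"zone_table"`.
#' @export
zone_table <- function(strain, diameter_mm, subculture) {
  stopifnot(all(diameter_mm >= 0),
            all(subculture %in% c("Positive", "Negative")))
  df <- data.frame(strain = strain, diameter_mm = diameter_mm,
                   subculture = subculture)
  class(df) <- c("zone_table", "data.frame")
  df
}

#' Read the bundled (or any) inhibition-zone CSV
#'
#' Columns: `strain`, `diameter_mm`, `subculture`. The package bundles the
#' published 43-strain spot-assay table as
#' `system.file("extdata", "inhibition_zones.csv", package = "exclusim")`.
#'
#' @param path CSV path; defaults to the bundled table.
#' @return A [zone_table()].
#' @export
read_zone_table <- function(path = system.file("extdata",
                                               "inhibition_zones.csv",
                                               package = "exclusim")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  zone_table(df$strain, df$diameter_mm, df$subculture)
}

#' Summarize inhibition-zone diameters
#'
#' @param table A [zone_table()].
#' @return List of class `"zone_summary"`: `n`, `mean_mm`, `sd_mm`
#'   (sample, n-1 denominator), at full precision; the print method
#'   reports 2 d.p.
#' @export
summarize_zones <- function(table) {
  stopifnot(nrow(table) >= 2)
  structure(list(n = nrow(table), mean_mm = mean(table$diameter_mm),
                 sd_mm = stats::sd(table$diameter_mm)),
            class = "zone_summary")
}

#' @export
print.zone_summary <- function(x, ...) {
  cat(sprintf("Inhibition zones: %.2f %s %.2f mm (n = %d)\n",
              x$mean_mm, "±", x$sd_mm, x$n))
  invisible(x)
}

#' Bactericidal fraction of a zone table
#'
#' Percent of strains with a Negative subculture (no regrowth, i.e.
#' bactericidal rather than bacteriostatic outcome), at full precision;
#' report to 1 d.p.
#'
#' @param table A [zone_table()].
#' @return Percentage in \[0, 100\].
#' @export
bactericidal_fraction <- function(table) {
  stopifnot(nrow(table) >= 1)
  100 * sum(table$subculture == "Negative") / nrow(table)
}

#' Probiotic slurry concentration
#'
#' Converts a gravimetric load into a volumetric concentration:
#' `load (CFU/g) x mass (g) / volume (mL)`.
#'
#' @param load CFU per gram.
#' @param mass Grams.
#' @param volume mL.
#' @return CFU/mL.
#' @export
#' @examples
#' slurry_concentration(3.05e8, 3.28, 2.33)  # ~4.29e8 CFU/mL
slurry_concentration <- function(load, mass, volume) {
  stopifnot(load > 0, mass > 0, volume > 0)
  load * mass / volume
}

#' Concentration after blending with a sterile carrier
#'
#' Blend `ratio_a` parts of active slurry with `ratio_b` parts of sterile
#' carrier: `conc x a / (a + b)`.
#'
#' @param conc CFU/mL of the active part.
#' @param ratio_a,ratio_b Positive mixing ratio parts (part b sterile).
#' @return CFU/mL of the blend.
#' @export
#' @examples
#' mix_concentration(4.29e8, 1, 1)  # 2.145e8 CFU/mL
mix_concentration <- function(conc, ratio_a, ratio_b) {
  stopifnot(conc > 0, ratio_a >= 0, ratio_b >= 0, ratio_a + ratio_b > 0)
  conc * ratio_a / (ratio_a + ratio_b)
}

#' Reduction summary table in the trial layout
#'
#' Computes mean log reduction, its SD and the percentage reduction of the
#' mean for one or more treatment groups against replicate log10 counts,
#' mirroring the disinfection-trial table layout.
#'
#' @param control Numeric matrix or data frame of control log10 counts,
#'   one column per pathogen, replicate rows.
#' @param treated Same shape for the treated group.
#' @param digits_lr,digits_pr Reporting precisions (defaults 2 and 2).
#' @return Data frame with `pathogen`, `mean_LR`, `sd_LR` and `PR_percent`
#'   (full precision) plus formatted reporting columns.
#' @export
reduction_summary <- function(control, treated, digits_lr = 2,
                              digits_pr = 2) {
  control <- as.matrix(control); treated <- as.matrix(treated)
  stopifnot(ncol(control) == ncol(treated))
  lr <- vapply(seq_len(ncol(control)), function(j)
    mean(log_reduction(control[, j], treated[, j])), 0)
  sdlr <- vapply(seq_len(ncol(control)), function(j)
    stats::sd(log_reduction(control[, j], treated[, j])), 0)
  pr <- percent_reduction(lr)
  data.frame(
    pathogen = colnames(control) %||% paste0("pathogen", seq_along(lr)),
    mean_LR = lr, sd_LR = sdlr, PR_percent = pr,
    LR_report = sprintf("%.*f %s %.*f", digits_lr, lr, "±", digits_lr,
                        sdlr),
    PR_report = sprintf("%.*f%%", digits_pr, pr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
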