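#' Standardized regression of an analyte on sex and age
#'
#' Ordinary least squares of the z-scored Box-Cox-transformed value on the
#' z-scored male indicator and z-scored age (age as a continuous covariate).
#' The coefficients are the standardized regression coefficients commonly
#' reported alongside variance components when judging whether reference
#' intervals need partitioning.
#'
#' @param table measurement data.frame.
#' @param analyte analyte to analyse; NULL if the table holds a single analyte.
#' @param lambda \code{"auto"}, a fixed exponent, or \code{"none"}.
#' @return named numeric vector \code{c(sex = ..., age = ...)}.
#' @export
standardized_regression <- function(table, analyte = NULL, lambda = "auto") {
  d <- pick_analyte(table, analyte)
  if (length(unique(d$sex)) < 2L) stop("standardized_regression: singular design (single sex)")
  if (length(unique(d$age)) < 2L) stop("standardized_regression: singular design (constant age)")
  y <- as.numeric(scale(bc_fwd(d$value, resolve_lambda(d$value, lambda))))
  zs <- as.numeric(scale(as.numeric(d$sex == "M")))
  za <- as.numeric(scale(d$age))
  fit <- stats::lm(y ~ zs + za)
  co <- stats::coef(fit)
  c(sex = unname(co["zs"]), age = unname(co["za"]))
}

#' Variance components for sex and age-band factors
#'
#' Method-of-moments decomposition on the crossed sex x age-band layout of
#' the Box-Cox-transformed values. The residual SD is the pooled within-cell
#' SD; the between-group SDs are the population SDs of the (unweighted) sex
#' and band means, each debiased by the sampling noise of the cell means and
#' truncated at zero. Deterministic and closed-form, adequate for the balanced
#' designs produced by [balance_strata()].
#'
#' @param table measurement data.frame; every sex x band cell must be
#'   non-empty.
#' @param analyte analyte to analyse; NULL for a single-analyte table.
#' @param age_bands list of half-open bands (default [default_age_bands()]).
#' @param cutoff SDR partition cut-off (default 0.4, strict).
#' @param lambda \code{"auto"}, fixed exponent, or \code{"none"}.
#' @return object of class \code{partition_analysis} with fields
#'   \code{sd_sex}, \code{sd_age}, \code{sd_residual}, \code{sdr_sex},
#'   \code{sdr_age}, \code{partition_by_sex}, \code{partition_by_age},
#'   \code{cutoff} and \code{std_coefficients}.
#' @export
variance_components <- function(table, analyte = NULL,
                                age_bands = default_age_bands(),
                                cutoff = 0.4, lambda = "auto") {
  d <- pick_analyte(table, analyte)
  band <- assign_band(d$age, age_bands)
  if (anyNA(band)) stop("variance_components: ages outside the configured bands")
  y <- bc_fwd(d$value, resolve_lambda(d$value, lambda))
  sexes <- c("F", "M")
  a <- length(sexes); b <- length(age_bands)
  cell_n <- matrix(0L, a, b); cell_mean <- matrix(NA_real_, a, b)
  ss_within <- 0
  for (i in seq_len(a)) for (j in seq_len(b)) {
    v <- y[d$sex == sexes[i] & band == j]
    if (length(v) == 0L) {
      stop(sprintf("variance_components: unbalanced design, empty cell sex %s band %s",
                   sexes[i], band_label(age_bands[[j]])))
    }
    cell_n[i, j] <- length(v)
    cell_mean[i, j] <- mean(v)
    ss_within <- ss_within + sum((v - mean(v))^2)
  }
  n_tot <- sum(cell_n)
  var_res <- ss_within / (n_tot - a * b)
  sd_residual <- sqrt(max(var_res, 0))
  r_h <- 1 / mean(1 / cell_n)  # harmonic mean cell size
  popvar <- function(m) mean((m - mean(m))^2)
  # E[popvar of k noisy group means] = popvar of true means + (k-1)/k * noise
  sd_sex <- sqrt(max(0, popvar(rowMeans(cell_mean)) -
                        (a - 1) / a * var_res / (b * r_h)))
  sd_age <- sqrt(max(0, popvar(colMeans(cell_mean)) -
                        (b - 1) / b * var_res / (a * r_h)))
  if (sd_residual < 1e-12) stop("variance_components: zero residual SD, SDR undefined")
  sdr_sex <- sd_sex / sd_residual
  sdr_age <- sd_age / sd_residual
  structure(list(analyte = d$analyte[1],
                 std_coefficients = NULL,
                 sd_sex = sd_sex, sd_age = sd_age, sd_residual = sd_residual,
                 sdr_sex = sdr_sex, sdr_age = sdr_age,
                 partition_by_sex = partition_decision(sdr_sex, cutoff),
                 partition_by_age = partition_decision(sdr_age, cutoff),
                 cutoff = cutoff),
            class = "partition_analysis")
}

#' SDR partition rule
#'
#' Reference intervals are partitioned by a factor when its standard
#' deviation ratio (between-group SD over residual SD) strictly exceeds the
#' cut-off.
#'
#' @param sdr nonnegative standard deviation ratio.
#' @param cutoff positive cut-off (default 0.4).
#' @return TRUE iff \code{sdr > cutoff}.
#' @export
partition_decision <- function(sdr, cutoff = 0.4) {
  stopifnot(is.numeric(sdr), length(sdr) == 1L, sdr >= 0,
            is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  sdr > cutoff
}

#' Full partitioning analysis for one analyte
#'
#' Combines [variance_components()] (SDs, SDRs, decisions) with
#' [standardized_regression()] (standardized coefficients) into a single
#' report object.
#'
#' @inheritParams variance_components
#' @return a \code{partition_analysis} object with standardized coefficients
#'   filled in.
#' @export
partition_analysis <- function(table, analyte = NULL,
                               age_bands = default_age_bands(),
                               cutoff = 0.4, lambda = "auto") {
  pa <- variance_components(table, analyte, age_bands, cutoff, lambda)
  pa$std_coefficients <- standardized_regression(table, analyte, lambda)
  pa
}

#' @export
print.partition_analysis <- function(x, ...) {
  cat(sprintf("Partitioning analysis: %s\n", x$analyte))
  cat(sprintf("  SD_sex = %.4f  SD_age = %.4f  SD_residual = %.4f\n",
              x$sd_sex, x$sd_age, x$sd_residual))
  cat(sprintf("  SDR_sex = %.3f (%s)  SDR_age = %.3f (%s)  [cutoff %.2f]\n",
              x$sdr_sex, if (x$partition_by_sex) "partition" else "pooled",
              x$sdr_age, if (x$partition_by_age) "partition" else "pooled",
              x$cutoff))
  if (!is.null(x$std_coefficients)) {
    cat(sprintf("  standardized coefficients: sex = %.3f, age = %.3f\n",
                x$std_coefficients["sex"], x$std_coefficients["age"]))
  }
  invisible(x)
}

# Subset one analyte out of a measurement table.
pick_analyte <- function(table, analyte) {
  stopifnot(is.data.frame(table),
            all(c("analyte", "value", "sex", "age") %in% names(table)))
  if (is.null(analyte)) {
    if (length(unique(table$analyte)) > 1L) {
      stop("multiple analytes present; specify `analyte`")
    }
    return(table)
  }
  d <- table[table$analyte == analyte, , drop = FALSE]
  if (nrow(d) == 0L) stop(sprintf("no rows for analyte %s", analyte))
  d
}
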