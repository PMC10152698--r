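#' Read a measurement table from CSV
#'
#' Expects a header with at least \code{analyte,value,sex,age}; optional
#' \code{truth_label} and \code{id} columns are preserved. Rows whose value is
#' not a positive number, whose sex is not M/F, or whose age is not a finite
#' number are dropped with a logged count.
#'
#' @param path CSV file path.
#' @return data.frame with the validated rows; attribute \code{"n_dropped"}
#'   records how many rows were discarded.
#' @export
read_measurements <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("analyte", "value", "sex", "age")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("read_measurements: missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  value <- suppressWarnings(as.numeric(raw$value))
  age <- suppressWarnings(as.numeric(raw$age))
  ok <- !is.na(value) & is.finite(value) & value > 0 &
    raw$sex %in% c("M", "F") & !is.na(age) & is.finite(age)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(sprintf("read_measurements: dropped %d invalid row(s)", n_dropped))
  }
  out <- data.frame(analyte = as.character(raw$analyte)[ok], value = value[ok],
                    sex = raw$sex[ok], age = as.integer(round(age[ok])),
                    stringsAsFactors = FALSE)
  for (extra in intersect(c("truth_label", "id"), names(raw))) {
    out[[extra]] <- raw[[extra]][ok]
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a measurement table to CSV
#'
#' @param table measurement data.frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_measurements <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a reference-interval report
#'
#' Tabulates estimates as one row per (method, analyte, subgroup) with the
#' limits and their 90% CIs. Rounding to analyte-specific decimals happens
#' only here, at the report layer; internal computations always carry full
#' precision.
#'
#' @param results either a data.frame with columns \code{method, analyte,
#'   subgroup, ll, ll_lo, ll_hi, ul, ul_lo, ul_hi}, or a list of entries
#'   \code{list(analyte =, ri = reference_interval)}.
#' @param path output CSV path, or NULL to return the data.frame only.
#' @param rounding named vector/list mapping analyte to decimals; analytes
#'   not listed use \code{default_digits}.
#' @param default_digits decimals for unlisted analytes (default 6).
#' @return the (rounded) report data.frame, invisibly when written.
#' @export
write_ri_report <- function(results, path = NULL, rounding = NULL,
                            default_digits = 6L) {
  if (!is.data.frame(results)) {
    stopifnot(is.list(results), length(results) >= 1L)
    results <- do.call(rbind, lapply(results, function(e) {
      ri <- if (inherits(e$ri, "ri_estimate")) e$ri$ri else e$ri
      data.frame(method = ri$method, analyte = e$analyte,
                 subgroup = ri$subgroup,
                 ll = ri$ll,
                 ll_lo = if (is.null(ri$ci_ll)) NA_real_ else ri$ci_ll[1],
                 ll_hi = if (is.null(ri$ci_ll)) NA_real_ else ri$ci_ll[2],
                 ul = ri$ul,
                 ul_lo = if (is.null(ri$ci_ul)) NA_real_ else ri$ci_ul[1],
                 ul_hi = if (is.null(ri$ci_ul)) NA_real_ else ri$ci_ul[2],
                 stringsAsFactors = FALSE)
    }))
  }
  digits_for <- function(analyte) {
    d <- if (!is.null(rounding) && analyte %in% names(rounding)) {
      rounding[[analyte]]
    } else {
      default_digits
    }
    as.integer(d)
  }
  num_cols <- c("ll", "ll_lo", "ll_hi", "ul", "ul_lo", "ul_hi")
  for (i in seq_len(nrow(results))) {
    d <- digits_for(results$analyte[i])
    results[i, num_cols] <- round(as.numeric(results[i, num_cols]), d)
  }
  rownames(results) <- NULL
  if (!is.null(path)) {
    utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
    return(invisible(results))
  }
  results
}

#' Run configuration
#'
#' Validated container of the knobs shared across pipeline stages. Defaults
#' match the documented per-stage defaults.
#'
#' @param analytes analytes to process; NULL means every analyte present.
#' @param partition_cutoff SDR partition cut-off (default 0.4).
#' @param tukey_k Tukey fence multiplier (default 1.5).
#' @param bootstrap_B bootstrap replicates for limit CIs (default 100).
#' @param ci_level CI coverage (default 0.90).
#' @param methods indirect methods to run (default all five).
#' @param seed master integer seed; per-stage seeds are derived from it.
#' @param standard_lambda Box-Cox exponent for the gold-standard direct fit
#'   (default 0, the log-transform variant; \code{"auto"} estimates it).
#' @param em_k mixture components for the EM estimator (default 3: healthy
#'   plus low and high pathological lobes).
#' @param rounding named decimals per analyte for report output.
#' @return validated list of class \code{run_config}.
#' @export
run_config <- function(analytes = NULL, partition_cutoff = 0.4, tukey_k = 1.5,
                       bootstrap_B = 100L, ci_level = 0.90,
                       methods = c("hoffmann", "bhattacharya", "em", "kosmic",
                                   "refiner"),
                       seed = 1L, standard_lambda = 0, em_k = 3L,
                       rounding = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(partition_cutoff > 0, tukey_k >= 0, bootstrap_B >= 0,
            ci_level > 0, ci_level < 1, em_k >= 1)
  structure(list(analytes = analytes, partition_cutoff = partition_cutoff,
                 tukey_k = tukey_k, bootstrap_B = as.integer(bootstrap_B),
                 ci_level = ci_level, methods = methods, seed = as.integer(seed),
                 standard_lambda = standard_lambda, em_k = as.integer(em_k),
                 rounding = rounding),
            class = "run_config")
}
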