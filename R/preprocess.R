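#' Default age bands
#'
#' Four decade bands covering the non-elderly adult range: 18-29, 30-39,
#' 40-49 and 50-59 years. Bands are half-open \code{[lo, hi)}.
#'
#' @return list of length-2 integer vectors \code{c(lo, hi)}.
#' @export
default_age_bands <- function() {
  list(c(18L, 30L), c(30L, 40L), c(40L, 50L), c(50L, 60L))
}

band_label <- function(band) sprintf("[%d,%d)", band[1], band[2])

# Assign each age to its band index; NA when outside all bands.
assign_band <- function(age, age_bands) {
  lo <- vapply(age_bands, function(b) as.numeric(b[1]), 0)
  hi <- vapply(age_bands, function(b) as.numeric(b[2]), 0)
  idx <- rep(NA_integer_, length(age))
  for (b in seq_along(age_bands)) idx[age >= lo[b] & age < hi[b]] <- b
  idx
}

#' Tukey fence outlier identification
#'
#' Flags values outside \eqn{[Q_1 - k\,\mathrm{IQR},\; Q_3 + k\,\mathrm{IQR}]}
#' with quartiles computed by linear interpolation of order statistics
#' (quantile type 7). Values are used as given; in the preprocessing pipeline
#' this runs on the Box-Cox-transformed subgroup, never on the raw aggregate.
#'
#' @param values numeric vector, at least 4 observations.
#' @param k fence multiplier (default 1.5, the standard Tukey fences).
#' @return list with elements \code{kept}, \code{removed} (values),
#'   \code{kept_idx} (logical mask into the input), \code{fences}
#'   \code{c(lower, upper)} and \code{quartiles} \code{c(q1, q3)}.
#' @export
tukey_filter <- function(values, k = 1.5) {
  stopifnot(is.numeric(values), all(is.finite(values)), k >= 0)
  if (length(values) < 4L) stop("tukey_filter: need at least 4 observations")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - k * iqr, q[2] + k * iqr)
  keep <- values >= fences[1] & values <= fences[2]
  list(kept = values[keep], removed = values[!keep], kept_idx = keep,
       fences = fences, quartiles = q)
}

#' Stratified sex/age balancing by random downsampling
#'
#' First step of the two-step preprocessing: draws, without replacement, the
#' largest subsample in which every age band has the same total and the target
#' sex ratio. For each band the feasible total at ratio \eqn{r} is
#' \eqn{\lfloor\min(n_M/r,\; n_F/(1-r))\rfloor}; the minimum feasible total
#' across bands is applied to all bands, so with \code{target_sex_ratio = 0.5}
#' every sex x band cell ends up with the minimum cell count (1:1 sex ratio).
#'
#' @param table measurement data.frame with \code{analyte, value, sex, age};
#'   balancing is performed independently per analyte.
#' @param target_sex_ratio target male fraction (default 0.5).
#' @param age_bands list of \code{c(lo, hi)} half-open bands
#'   (default [default_age_bands()]).
#' @param seed optional integer seed for reproducible sampling.
#' @return the downsampled data.frame (row order follows the input).
#' @export
balance_strata <- function(table, target_sex_ratio = 0.5,
                           age_bands = default_age_bands(), seed = NULL) {
  stopifnot(is.data.frame(table),
            all(c("analyte", "value", "sex", "age") %in% names(table)),
            target_sex_ratio > 0, target_sex_ratio < 1)
  if (!is.null(seed)) set.seed(seed)
  r <- target_sex_ratio
  out <- lapply(split(seq_len(nrow(table)), table$analyte), function(rows) {
    sub <- table[rows, , drop = FALSE]
    band <- assign_band(sub$age, age_bands)
    if (anyNA(band)) stop("balance_strata: ages outside the configured bands")
    tots <- integer(length(age_bands))
    for (b in seq_along(age_bands)) {
      nm <- sum(sub$sex == "M" & band == b)
      nf <- sum(sub$sex == "F" & band == b)
      if (nm == 0L || nf == 0L) {
        stop(sprintf("balance_strata: empty cell for analyte %s, sex %s, band %s",
                     sub$analyte[1], if (nm == 0L) "M" else "F",
                     band_label(age_bands[[b]])))
      }
      tots[b] <- floor(min(nm / r, nf / (1 - r)))
    }
    t_all <- min(tots)
    n_m <- round(t_all * r)
    n_f <- t_all - n_m
    keep <- integer(0)
    for (b in seq_along(age_bands)) {
      im <- rows[sub$sex == "M" & band == b]
      iff <- rows[sub$sex == "F" & band == b]
      keep <- c(keep,
                im[sample.int(length(im), n_m)],
                iff[sample.int(length(iff), n_f)])
    }
    keep
  })
  idx <- sort(unlist(out, use.names = FALSE))
  table[idx, , drop = FALSE]
}

# Keep the last record per (subject id, analyte). No-op without an id column.
dedup_last <- function(table) {
  if (!"id" %in% names(table)) return(table)
  keep <- !duplicated(table[, c("id", "analyte")], fromLast = TRUE)
  table[keep, , drop = FALSE]
}

#' Two-step preprocessing pipeline
#'
#' Implements the simplified preprocessing used before indirect estimation:
#' (1) stratified balancing of sex and age-band ratios by random downsampling
#' ([balance_strata()]); (2) within every sex x age-band subgroup, Box-Cox
#' transformation (exponent estimated per subgroup by profile ML) followed by
#' Tukey outlier removal on the transformed values ([tukey_filter()]).
#' Outliers are removed per subgroup rather than on the aggregate to avoid
#' discarding values that are only extreme relative to the wrong stratum.
#' If a subject \code{id} column is present, repeat results are first reduced
#' to the last record per subject. Subgroups too small for exponent
#' estimation (< 20) fall back to raw-scale fences; subgroups below 4 are
#' passed through untouched.
#'
#' @param table measurement data.frame (\code{analyte, value, sex, age}).
#' @param tukey_k Tukey fence multiplier (default 1.5).
#' @param balance apply the balancing step (default TRUE).
#' @param target_sex_ratio,age_bands,seed passed to [balance_strata()].
#' @param lambda \code{"auto"} (per-subgroup profile-ML estimate), a fixed
#'   numeric exponent, or \code{"none"} for raw-scale fences.
#' @return filtered data.frame; attribute \code{"log"} holds a per-subgroup
#'   data.frame with columns \code{analyte, sex, band, n_in, n_removed}.
#' @export
preprocess_table <- function(table, tukey_k = 1.5, balance = TRUE,
                             target_sex_ratio = 0.5,
                             age_bands = default_age_bands(), seed = NULL,
                             lambda = "auto") {
  stopifnot(is.data.frame(table),
            all(c("analyte", "value", "sex", "age") %in% names(table)))
  table <- dedup_last(table)
  if (balance) {
    table <- balance_strata(table, target_sex_ratio, age_bands, seed)
  }
  band <- assign_band(table$age, age_bands)
  key <- interaction(table$analyte, table$sex, band, drop = TRUE)
  keep <- rep(TRUE, nrow(table))
  logs <- list()
  for (g in levels(key)) {
    rows <- which(key == g)
    x <- table$value[rows]
    removed <- 0L
    if (length(x) >= 4L) {
      lam <- if (identical(lambda, "auto") && length(x) < 20L) NULL
             else resolve_lambda(x, lambda)
      tf <- tukey_filter(bc_fwd(x, lam), k = tukey_k)
      keep[rows[!tf$kept_idx]] <- FALSE
      removed <- sum(!tf$kept_idx)
    }
    logs[[g]] <- data.frame(analyte = table$analyte[rows[1]],
                            sex = table$sex[rows[1]],
                            band = band_label(age_bands[[band[rows[1]]]]),
                            n_in = length(x), n_removed = removed,
                            stringsAsFactors = FALSE)
  }
  out <- table[keep, , drop = FALSE]
  lg <- do.call(rbind, unname(logs))
  attr(out, "log") <- lg[order(lg$analyte, lg$sex, lg$band), ]
  out
}
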