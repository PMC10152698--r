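#' Bias ratio of a test interval against a standard interval
#'
#' Scores the discrepancy between an algorithm-calculated reference interval
#' and the gold-standard interval:
#' \deqn{BR_{LL} = \frac{|LL - LL_0|}{SD_{RI}}, \quad
#'       BR_{UL} = \frac{|UL - UL_0|}{SD_{RI}}, \quad
#'       SD_{RI} = \frac{UL_0 - LL_0}{3.92}.}
#' A limit is flagged when its BR strictly exceeds the threshold (default
#' 0.375), indicating a clinically meaningful discrepancy. BR is invariant
#' to a common rescaling of all four limits and symmetric in the sign of the
#' deviation.
#'
#' @param test the algorithm interval: a [reference_interval()],
#'   [ri_estimate()] or numeric \code{c(ll, ul)}.
#' @param standard the gold-standard interval, same accepted forms;
#'   must satisfy \code{ll < ul}.
#' @param threshold flagging threshold (default 0.375).
#' @param digits optional number of decimals to round the test and standard
#'   limits to before computing BR (reproduces report-scale arithmetic);
#'   NULL (default) uses the limits as given.
#' @return object of class \code{br_result} with fields \code{br_ll},
#'   \code{br_ul}, \code{sd_ri}, \code{flag_ll}, \code{flag_ul},
#'   \code{threshold}.
#' @examples
#' bias_ratio(c(0.970, 4.276), c(0.801, 4.221))$br_ul  # 0.063 at 3 decimals
#' @export
bias_ratio <- function(test, standard, threshold = 0.375, digits = NULL) {
  t_lim <- as_limits(test)
  s_lim <- as_limits(standard)
  if (!is.null(digits)) {
    t_lim <- round(t_lim, digits)
    s_lim <- round(s_lim, digits)
  }
  if (!(s_lim[1] < s_lim[2])) stop("bias_ratio: invalid reference (UL0 <= LL0)")
  stopifnot(threshold > 0)
  sd_ri <- (s_lim[2] - s_lim[1]) / 3.92
  br_ll <- abs(t_lim[1] - s_lim[1]) / sd_ri
  br_ul <- abs(t_lim[2] - s_lim[2]) / sd_ri
  structure(list(br_ll = br_ll, br_ul = br_ul, sd_ri = sd_ri,
                 flag_ll = br_ll > threshold, flag_ul = br_ul > threshold,
                 threshold = threshold),
            class = "br_result")
}

#' @export
print.br_result <- function(x, ...) {
  mark <- function(f) if (f) " *" else ""
  cat(sprintf("BR_LL = %.3f%s  BR_UL = %.3f%s  (SD_RI = %.5f, threshold %.3f)\n",
              x$br_ll, mark(x$flag_ll), x$br_ul, mark(x$flag_ul),
              x$sd_ri, x$threshold))
  invisible(x)
}

#' Bias-ratio matrix
#'
#' Scores every (method, analyte, subgroup) estimate against the matching
#' standard interval and tabulates the BR values with threshold flags. The
#' result is independent of the input row order.
#'
#' @param estimates data.frame with columns
#'   \code{method, analyte, subgroup, ll, ul}.
#' @param standards data.frame with columns \code{analyte, subgroup, ll, ul};
#'   one row per (analyte, subgroup).
#' @param threshold flagging threshold (default 0.375).
#' @param digits optional report-scale rounding, as in [bias_ratio()].
#' @return data.frame of class \code{br_matrix} with columns
#'   \code{method, analyte, subgroup, br_ll, br_ul, sd_ri, flag_ll, flag_ul},
#'   sorted by analyte, subgroup, method.
#' @export
br_matrix <- function(estimates, standards, threshold = 0.375, digits = NULL) {
  req_e <- c("method", "analyte", "subgroup", "ll", "ul")
  req_s <- c("analyte", "subgroup", "ll", "ul")
  stopifnot(is.data.frame(estimates), all(req_e %in% names(estimates)),
            is.data.frame(standards), all(req_s %in% names(standards)))
  skey <- paste(standards$analyte, standards$subgroup, sep = "|")
  if (anyDuplicated(skey)) stop("br_matrix: duplicate standards per (analyte, subgroup)")
  rows <- lapply(seq_len(nrow(estimates)), function(i) {
    e <- estimates[i, ]
    j <- match(paste(e$analyte, e$subgroup, sep = "|"), skey)
    if (is.na(j)) {
      stop(sprintf("br_matrix: no standard for analyte %s, subgroup %s",
                   e$analyte, e$subgroup))
    }
    br <- bias_ratio(c(e$ll, e$ul), c(standards$ll[j], standards$ul[j]),
                     threshold = threshold, digits = digits)
    data.frame(method = e$method, analyte = e$analyte, subgroup = e$subgroup,
               br_ll = br$br_ll, br_ul = br$br_ul, sd_ri = br$sd_ri,
               flag_ll = br$flag_ll, flag_ul = br$flag_ul,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$analyte, out$subgroup, out$method), ]
  rownames(out) <- NULL
  class(out) <- c("br_matrix", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' @export
print.br_matrix <- function(x, ...) {
  y <- as.data.frame(x)
  y$br_ll <- sprintf("%.3f%s", y$br_ll, ifelse(y$flag_ll, "*", " "))
  y$br_ul <- sprintf("%.3f%s", y$br_ul, ifelse(y$flag_ul, "*", " "))
  cat(sprintf("Bias-ratio matrix (threshold %.3f, * = flagged)\n",
              attr(x, "threshold")))
  print(y[, c("method", "analyte", "subgroup", "br_ll", "br_ul")],
        row.names = FALSE)
  invisible(x)
}
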