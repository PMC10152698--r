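#' Reference interval object
#'
#' Container for a reference interval: lower limit (LL), upper limit (UL),
#' optional 90% confidence intervals for each limit, and identifiers for the
#' producing method and the population subgroup.
#'
#' @param ll,ul lower and upper limits on the measurement scale; \code{ll < ul}.
#' @param ci_ll,ci_ul optional length-2 numeric vectors \code{c(lo, hi)}
#'   bracketing the respective limit, or NULL when no CI was computed.
#' @param method method identifier, e.g. \code{"hoffmann"}.
#' @param subgroup subgroup identifier, e.g. \code{"T"}, \code{"F"}, \code{"M"}.
#' @return an object of class \code{reference_interval}.
#' @export
reference_interval <- function(ll, ul, ci_ll = NULL, ci_ul = NULL,
                               method = NA_character_, subgroup = NA_character_) {
  stopifnot(is.numeric(ll), is.numeric(ul), length(ll) == 1L, length(ul) == 1L,
            is.finite(ll), is.finite(ul))
  if (!(ll < ul)) stop("reference_interval: ll must be < ul")
  chk_ci <- function(ci, lim, what) {
    if (is.null(ci)) return(NULL)
    stopifnot(is.numeric(ci), length(ci) == 2L, all(is.finite(ci)))
    if (ci[1] > lim || ci[2] < lim) {
      stop(sprintf("reference_interval: %s CI does not bracket the limit", what))
    }
    unname(ci)
  }
  structure(list(ll = ll, ul = ul,
                 ci_ll = chk_ci(ci_ll, ll, "LL"), ci_ul = chk_ci(ci_ul, ul, "UL"),
                 method = method, subgroup = subgroup),
            class = "reference_interval")
}

#' @export
print.reference_interval <- function(x, digits = 4, ...) {
  fmt <- function(v) format(round(v, digits), trim = TRUE)
  ci <- function(ci) if (is.null(ci)) "" else
    sprintf(" (90%% CI %s-%s)", fmt(ci[1]), fmt(ci[2]))
  cat(sprintf("Reference interval [%s%s]: LL = %s%s, UL = %s%s\n",
              x$method, if (is.na(x$subgroup)) "" else paste0(", ", x$subgroup),
              fmt(x$ll), ci(x$ci_ll), fmt(x$ul), ci(x$ci_ul)))
  invisible(x)
}

#' Check the reporting quality of bootstrap confidence intervals
#'
#' An interval is considered well determined when the 90% CI of each limit is
#' narrower than 0.2 times the width of the reference interval itself
#' (strictly).
#'
#' @param ri a [reference_interval()] with both CIs present.
#' @return TRUE or FALSE.
#' @export
ci_width_ok <- function(ri) {
  stopifnot(inherits(ri, "reference_interval"))
  if (is.null(ri$ci_ll) || is.null(ri$ci_ul)) {
    stop("ci_width_ok: reference interval has no confidence intervals")
  }
  w <- 0.2 * (ri$ul - ri$ll)
  (diff(ri$ci_ll) < w) && (diff(ri$ci_ul) < w)
}

#' Indirect estimate container
#'
#' Bundles the reference interval produced by an indirect algorithm together
#' with the Box-Cox exponent used and the fitted model (linear region, mixture
#' components, or a power-normal parameter triple) that produced it.
#'
#' @param ri a [reference_interval()].
#' @param method method identifier.
#' @param lambda Box-Cox exponent used, or NULL if the data were not transformed.
#' @param model method-specific fitted model object.
#' @param diagnostics named list of scalar diagnostics.
#' @return object of class \code{ri_estimate}.
#' @export
ri_estimate <- function(ri, method, lambda = NULL, model = NULL, diagnostics = list()) {
  stopifnot(inherits(ri, "reference_interval"))
  structure(list(ri = ri, method = method, lambda = lambda,
                 model = model, diagnostics = diagnostics),
            class = "ri_estimate")
}

#' @export
print.ri_estimate <- function(x, ...) {
  print(x$ri)
  if (!is.null(x$lambda)) cat(sprintf("  Box-Cox lambda: %.4f\n", x$lambda))
  if (length(x$diagnostics)) {
    d <- vapply(x$diagnostics, function(v) format(v, digits = 4), "")
    cat("  diagnostics:", paste(names(d), d, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# Coerce a reference_interval / ri_estimate / numeric c(ll, ul) to limits.
as_limits <- function(x) {
  if (inherits(x, "ri_estimate")) x <- x$ri
  if (inherits(x, "reference_interval")) return(c(x$ll, x$ul))
  stopifnot(is.numeric(x), length(x) == 2L)
  unname(x)
}
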