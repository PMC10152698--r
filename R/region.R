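#' Automated linear-region selection
#'
#' The Hoffmann and Bhattacharya methods traditionally rely on a visually
#' chosen straight segment of a diagnostic plot. This selector replaces the
#' visual step with a deterministic criterion: among all contiguous index
#' windows of at least \code{min_span} points, it returns the window
#' maximizing
#' \deqn{r^2 - c\,(1 - \mathrm{span\ fraction}),}
#' i.e. the coefficient of determination of the within-window least-squares
#' line, mildly rewarding longer windows (penalty weight \code{c}) so that
#' trivially perfect tiny windows do not beat a long, nearly straight
#' mainstream segment. The default \code{c = 0.005} is matched to the scale
#' on which \eqn{r^2} actually varies on a probit/log-count plot of a few
#' hundred points (curvature from tail contamination moves \eqn{r^2} by a few
#' thousandths); a much larger penalty would always select near-full windows
#' and drag the fitted line into the bent tails. Ties resolve to the earliest
#' window, so the result is fully reproducible.
#'
#' @param x,y ordered point coordinates (equal length).
#' @param min_span minimum window length; default 40% of the points
#'   (at least 3).
#' @param penalty span penalty weight \code{c} (default 0.005).
#' @param contain optional point index that every candidate window must
#'   include (used to anchor the search at the modal histogram bin).
#' @param slope_sign optional +1/-1: only windows whose fitted slope has this
#'   sign are admissible (a probit plot must rise, a log-count-ratio plot
#'   must fall); NULL accepts any slope.
#' @return list of class \code{linear_region} with \code{start}, \code{end}
#'   (inclusive indices), \code{slope}, \code{intercept}, \code{r_squared}
#'   and \code{score}.
#' @export
select_linear_region <- function(x, y, min_span = NULL, penalty = 0.005,
                                 contain = NULL, slope_sign = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, is.numeric(x), is.numeric(y),
            all(is.finite(x)), all(is.finite(y)))
  if (is.null(min_span)) min_span <- ceiling(0.4 * n)
  min_span <- max(3L, as.integer(min_span))
  if (n < min_span) stop("select_linear_region: fewer points than min_span")
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x * x); cyy <- cumsum(y * y); cxy <- cumsum(x * y)
  seg <- function(c, i, j) c[j] - if (i > 1L) c[i - 1L] else 0
  best_score <- -Inf; best <- NULL
  starts <- seq_len(n - min_span + 1L)
  if (!is.null(contain)) starts <- starts[starts <= contain]
  for (i in starts) {
    js <- (i + min_span - 1L):n
    if (!is.null(contain)) js <- js[js >= contain]
    if (length(js) == 0L) next
    m <- js - i + 1L
    sx <- seg(cx, i, js); sy <- seg(cy, i, js)
    sxx <- seg(cxx, i, js); syy <- seg(cyy, i, js); sxy <- seg(cxy, i, js)
    ssx <- sxx - sx^2 / m
    ssy <- syy - sy^2 / m
    sxy_c <- sxy - sx * sy / m
    r2 <- ifelse(ssx > 0 & ssy > 0, sxy_c^2 / (ssx * ssy),
                 ifelse(ssy <= 0, 1, 0))  # constant y fits a line exactly
    r2 <- pmin(pmax(r2, 0), 1)
    score <- r2 - penalty * (1 - m / n)
    if (!is.null(slope_sign)) {
      slopes <- ifelse(ssx > 0, sxy_c / ssx, 0)
      score[sign(slopes) != sign(slope_sign)] <- -Inf
    }
    k <- which.max(score)
    if (score[k] > best_score + 1e-15) {
      j <- js[k]
      slope <- if (ssx[k] > 0) sxy_c[k] / ssx[k] else 0
      best_score <- score[k]
      best <- list(start = i, end = j, slope = slope,
                   intercept = (sy[k] - slope * sx[k]) / m[k],
                   r_squared = r2[k], score = score[k])
    }
  }
  if (is.null(best)) stop("select_linear_region: no admissible window")
  structure(best, class = "linear_region")
}
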