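#' Mixture component specification
#'
#' One component of a synthetic cohort: a Gaussian on the Box-Cox-transformed
#' scale (a "power normal" on the measurement scale), with a mixing weight and
#' a clinical label. The dominant \code{healthy} component is the recovery
#' target for every indirect estimator; \code{patho_low}/\code{patho_high}
#' components emulate disease states shifted below/above the healthy core.
#'
#' @param weight mixing fraction in \[0, 1\].
#' @param lambda Box-Cox exponent of the component.
#' @param mu,sigma mean and SD on the transformed scale; \code{sigma >= 0}
#'   (0 is allowed as a degenerate point mass, useful for tests).
#' @param label one of \code{"healthy"}, \code{"patho_low"}, \code{"patho_high"}.
#' @return object of class \code{component_spec}.
#' @export
component_spec <- function(weight, lambda, mu, sigma, label = "healthy") {
  label <- match.arg(label, c("healthy", "patho_low", "patho_high"))
  stopifnot(is.numeric(weight), length(weight) == 1L, weight >= 0, weight <= 1,
            is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  structure(list(weight = weight, lambda = lambda, mu = mu, sigma = sigma,
                 label = label), class = "component_spec")
}

#' Synthetic cohort specification
#'
#' Describes one analyte's mixed population: an ordered list of
#' [component_spec()] mixture components (weights summing to 1, healthy
#' dominant), additive sex and per-year age effects on the transformed scale,
#' and sampling controls. Ages are drawn uniformly over the integer range and
#' the age effect is centred at the midpoint of \code{age_range}.
#'
#' @param analyte analyte identifier string.
#' @param components list of [component_spec()]; weights must sum to 1 within
#'   1e-12 and the healthy component must carry the largest weight.
#' @param sex_shift additive male-vs-female effect on the transformed scale.
#' @param age_slope per-year effect on the transformed scale.
#' @param n number of rows to generate (>= 1).
#' @param sex_ratio target male fraction in (0, 1).
#' @param age_range integer ages \code{c(lo, hi)}, within \[18, 60).
#' @return object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(analyte, components, sex_shift = 0, age_slope = 0,
                        n = 1000L, sex_ratio = 0.5, age_range = c(18L, 59L)) {
  stopifnot(is.character(analyte), length(analyte) == 1L,
            is.list(components), length(components) >= 1L,
            all(vapply(components, inherits, TRUE, "component_spec")),
            is.numeric(sex_shift), is.finite(sex_shift),
            is.numeric(age_slope), is.finite(age_slope),
            n >= 1, sex_ratio > 0, sex_ratio < 1,
            length(age_range) == 2L, age_range[1] >= 18, age_range[2] < 60,
            age_range[1] <= age_range[2])
  w <- vapply(components, `[[`, 0, "weight")
  if (abs(sum(w) - 1) > 1e-12) stop("cohort_spec: component weights must sum to 1")
  lab <- vapply(components, `[[`, "", "label")
  if (sum(lab == "healthy") != 1L) stop("cohort_spec: exactly one healthy component required")
  if (w[lab == "healthy"] < max(w)) stop("cohort_spec: healthy weight must be the largest")
  structure(list(analyte = analyte, components = components,
                 sex_shift = sex_shift, age_slope = age_slope,
                 n = as.integer(n), sex_ratio = sex_ratio,
                 age_range = as.integer(age_range)),
            class = "cohort_spec")
}

#' Generate a synthetic mixed cohort
#'
#' Draws \code{spec$n} rows. Each row picks a mixture component by weight,
#' a sex by \code{sex_ratio}, an integer age uniformly over the range, then
#' draws Gaussian(\eqn{\mu + shift \cdot I(male) + slope \cdot (age - mid)},
#' \eqn{\sigma}) on the component's transformed scale and maps it back through
#' the inverse Box-Cox transform. Draws that land outside the inverse-transform
#' domain (\eqn{\lambda y + 1 \le 0}) are rejected and redrawn; if the overall
#' rejection rate exceeds 10% of \code{n} the generator aborts.
#'
#' The \code{truth_label} column records the generating component; estimators
#' never see it, it exists purely so evaluation code can compute oracle
#' quantities.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; the same seed always yields the same table.
#' @return data.frame with columns \code{analyte, value, sex, age, truth_label}.
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- spec$n
  w <- vapply(spec$components, `[[`, 0, "weight")
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  sex <- ifelse(stats::runif(n) < spec$sex_ratio, "M", "F")
  ages <- seq.int(spec$age_range[1], spec$age_range[2])
  age <- ages[sample.int(length(ages), n, replace = TRUE)]
  mid <- mean(spec$age_range)
  mu_i <- vapply(spec$components, `[[`, 0, "mu")[comp] +
    spec$sex_shift * (sex == "M") + spec$age_slope * (age - mid)
  sd_i <- vapply(spec$components, `[[`, 0, "sigma")[comp]
  lam_i <- vapply(spec$components, `[[`, 0, "lambda")[comp]
  y <- stats::rnorm(n, mu_i, sd_i)
  bad <- abs(lam_i) >= 1e-10 & (lam_i * y + 1 <= 0)
  rejected <- 0L
  while (any(bad)) {
    rejected <- rejected + sum(bad)
    if (rejected > 0.1 * n) {
      stop("generate_cohort: inverse-transform rejection rate exceeds 10%")
    }
    y[bad] <- stats::rnorm(sum(bad), mu_i[bad], sd_i[bad])
    bad <- bad & (lam_i * y + 1 <= 0)
  }
  value <- ifelse(abs(lam_i) < 1e-10, exp(y), (lam_i * y + 1)^(1 / ifelse(lam_i == 0, 1, lam_i)))
  lab <- vapply(spec$components, `[[`, "", "label")[comp]
  data.frame(analyte = spec$analyte, value = value, sex = sex, age = age,
             truth_label = lab, stringsAsFactors = FALSE)
}

#' Default synthetic thyroid panel
#'
#' Returns cohort specifications for five thyroid-hormone-like analytes whose
#' distributional shapes drive indirect-algorithm behaviour: a strongly
#' right-skewed TSH-like analyte (log-normal healthy core), near-Gaussian
#' FT3/TT3/TT4-like analytes, and a moderately skewed FT4-like analyte. FT3
#' and FT4 carry a sex shift large enough to require sex-partitioned
#' intervals (SDR around 0.7 and 0.5); the other analytes carry only small
#' sex/age effects. Pathological contamination defaults to 5% shifted low
#' plus 5% shifted high.
#'
#' @param n sample size per analyte.
#' @param patho_frac total pathological fraction, split evenly low/high
#'   (default 0.10).
#' @return named list of [cohort_spec()], one per analyte.
#' @export
thyroid_panel_spec <- function(n, patho_frac = 0.10) {
  stopifnot(n >= 1, patho_frac >= 0, patho_frac < 0.5)
  wh <- 1 - patho_frac
  wp <- patho_frac / 2
  mk <- function(analyte, lambda, mu, sigma, lo_mu, lo_sd, hi_mu, hi_sd,
                 sex_shift, age_slope) {
    cohort_spec(analyte, list(
      component_spec(wh, lambda, mu, sigma, "healthy"),
      component_spec(wp, lambda, lo_mu, lo_sd, "patho_low"),
      component_spec(wp, lambda, hi_mu, hi_sd, "patho_high")),
      sex_shift = sex_shift, age_slope = age_slope, n = n)
  }
  list(
    # TSH in uIU/L: log-normal healthy core centred near 1.84, RI ~ (0.8, 4.2)
    TSH = mk("TSH", 0, 0.609, 0.424, log(0.02), 1.0, log(12), 0.8,
             sex_shift = -0.05, age_slope = 0.002),
    # FT3 in pg/mL: near-Gaussian, female RI ~ (2.5, 3.5), sex SDR ~ 0.73
    FT3 = mk("FT3", 1, 1.99, 0.255, 0.80, 0.35, 4.50, 0.80,
             sex_shift = 0.37, age_slope = -0.003),
    # FT4 in ng/dL: moderately skewed (lambda 0.5), sex SDR ~ 0.5
    FT4 = mk("FT4", 0.5, 0.166, 0.111, -0.735, 0.15, 1.46, 0.30,
             sex_shift = 0.11, age_slope = 0),
    # TT3 in ng/mL: near-Gaussian, RI ~ (0.8, 1.4)
    TT3 = mk("TT3", 1, 0.090, 0.148, -0.55, 0.12, 1.20, 0.35,
             sex_shift = 0.03, age_slope = 0),
    # TT4 in ug/dL: near-Gaussian, RI ~ (5.5, 10.1)
    TT4 = mk("TT4", 1, 6.755, 1.171, 2.0, 0.8, 14.0, 2.0,
             sex_shift = 0.12, age_slope = 0)
  )
}

#' Ground-truth reference interval of a cohort specification
#'
#' Computes the healthy component's true limits on the measurement scale.
#' On the transformed scale the healthy distribution marginalized over sex
#' and age is a finite mixture of Gaussians (one per sex x age cell); its
#' quantiles at \eqn{\Phi(\mp 1.96)} are found by root-finding on the exact
#' mixture CDF and mapped back through the inverse Box-Cox transform. With no
#' covariate effects this reduces to the closed form
#' \eqn{BC^{-1}(\mu \pm 1.96\sigma)}.
#'
#' @param spec a [cohort_spec()].
#' @param sex \code{"all"} for the sex-marginal truth, or \code{"M"}/\code{"F"}
#'   for a sex-specific truth.
#' @param z half-width in SD units of the central interval (default 1.96,
#'   the central 95%).
#' @return numeric \code{c(ll, ul)} on the measurement scale.
#' @export
true_ri <- function(spec, sex = c("all", "M", "F"), z = 1.96) {
  stopifnot(inherits(spec, "cohort_spec"))
  sex <- match.arg(sex)
  lab <- vapply(spec$components, `[[`, "", "label")
  h <- spec$components[[which(lab == "healthy")]]
  if (h$sigma <= 0) stop("true_ri: healthy component has zero variance")
  mid <- mean(spec$age_range)
  ages <- seq.int(spec$age_range[1], spec$age_range[2])
  shifts <- switch(sex,
    all = c(rep(0, length(ages)) , rep(spec$sex_shift, length(ages))),
    F = rep(0, length(ages)),
    M = rep(spec$sex_shift, length(ages)))
  wts <- switch(sex,
    all = c(rep((1 - spec$sex_ratio) / length(ages), length(ages)),
            rep(spec$sex_ratio / length(ages), length(ages))),
    rep(1 / length(ages), length(ages)))
  mus <- h$mu + rep(spec$age_slope * (ages - mid), times = length(shifts) / length(ages)) + shifts
  cdf <- function(q) sum(wts * stats::pnorm(q, mus, h$sigma))
  qmix <- function(p) {
    lo <- min(mus) - 10 * h$sigma
    hi <- max(mus) + 10 * h$sigma
    stats::uniroot(function(q) cdf(q) - p, c(lo, hi), tol = 1e-10)$root
  }
  p <- stats::pnorm(c(-z, z))
  inverse_boxcox(c(qmix(p[1]), qmix(p[2])), h$lambda)
}
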