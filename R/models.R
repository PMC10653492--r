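#' Gompertz and gamma-Gompertz hazard, survival and quantile functions
#'
#' The Gompertz hazard is \eqn{\mu(x) = a e^{bx}}, where `a` is the mortality
#' level at the starting age (age offset 0) and `b` the rate of aging.  Under
#' gamma-distributed frailty with mean 1 and variance \eqn{\sigma^2}, the
#' marginal (population) hazard is
#' \deqn{\bar\mu(x) = \frac{a e^{bx}}{1 + \sigma^2 (a/b)(e^{bx} - 1)},}
#' which decelerates at old ages and approaches the plateau \eqn{b/\sigma^2}.
#' With \eqn{\sigma^2 = 0} the marginal model reduces exactly to the Gompertz.
#'
#' Ages `x` are offsets in years from the first modelled age (for example,
#' `x = 0` corresponds to calendar age 70 when fitting data for ages 70+).
#'
#' For `sigma2` below `1e-8` the survival and quantile functions switch to the
#' Gompertz limit formula: the exponent \eqn{-1/\sigma^2} in the marginal
#' survival is numerically unusable there, and penalized fits drive
#' \eqn{\hat\sigma^2} to values around 1e-20.
#'
#' @param x Age offset(s) in years, non-negative.
#' @param a Baseline hazard level at age offset 0 (per year, > 0).
#' @param b Rate of aging (per year, > 0).
#' @param sigma2 Frailty variance \eqn{\sigma^2} (>= 0).
#' @param u Survival probability (or probabilities) in (0, 1).
#'
#' @return `gompertz_hazard()` and `gg_hazard()` return hazard rates per year;
#'   `gompertz_survival()` and `gg_survival()` return survival probabilities;
#'   `gg_quantile()` returns the age offset at which the marginal survival
#'   equals `u`.
#'
#' @examples
#' gg_hazard(0:30, a = 1e-4, b = 0.1, sigma2 = 0.2)
#' gg_survival(gg_quantile(0.5, 1e-4, 0.1, 0.2), 1e-4, 0.1, 0.2)  # 0.5
#' @name gg_models
NULL

.sigma2_gompertz_limit <- 1e-8

check_theta <- function(a, b, sigma2) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' must be a single positive number", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop("'b' must be a single positive number", call. = FALSE)
  if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) ||
      sigma2 < 0)
    stop("'sigma2' must be a single non-negative number", call. = FALSE)
  invisible(NULL)
}

check_age <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0))
    stop("ages 'x' must be non-negative numbers", call. = FALSE)
  invisible(NULL)
}

#' @rdname gg_models
#' @export
gompertz_hazard <- function(x, a, b, sigma2 = 0) {
  check_theta(a, b, sigma2)
  check_age(x)
  a * exp(b * x)
}

#' @rdname gg_models
#' @export
gg_hazard <- function(x, a, b, sigma2) {
  check_theta(a, b, sigma2)
  check_age(x)
  if (sigma2 == 0) return(a * exp(b * x))
  ebx1 <- expm1(b * x)                    # e^{bx} - 1, exact near 0
  q <- sigma2 * (a / b) * ebx1            # denominator - 1
  out <- a * exp(b * x) / (1 + q)
  # extinct-cohort tail: e^{bx} overflows, hazard is at the plateau b/sigma2
  out[!is.finite(q)] <- b / sigma2
  out
}

#' @rdname gg_models
#' @export
gompertz_survival <- function(x, a, b, sigma2 = 0) {
  check_theta(a, b, sigma2)
  check_age(x)
  H <- (a / b) * expm1(b * x)             # cumulative hazard
  exp(-H)
}

#' @rdname gg_models
#' @export
gg_survival <- function(x, a, b, sigma2) {
  check_theta(a, b, sigma2)
  check_age(x)
  if (sigma2 < .sigma2_gompertz_limit)
    return(gompertz_survival(x, a, b))
  q <- sigma2 * (a / b) * expm1(b * x)
  out <- exp(-log1p(q) / sigma2)
  out[!is.finite(q)] <- 0
  out
}

#' @rdname gg_models
#' @export
gg_quantile <- function(u, a, b, sigma2) {
  check_theta(a, b, sigma2)
  if (!is.numeric(u) || anyNA(u) || any(u <= 0) || any(u >= 1))
    stop("'u' must lie strictly inside (0, 1)", call. = FALSE)
  if (sigma2 < .sigma2_gompertz_limit) {
    # Gompertz inverse: S(x) = u  =>  x = (1/b) log(1 - (b/a) log u)
    return(log1p(-(b / a) * log(u)) / b)
  }
  # u^{-sigma2} - 1 computed as expm1(-sigma2 log u) to keep precision
  log1p((b / (a * sigma2)) * expm1(-sigma2 * log(u))) / b
}
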