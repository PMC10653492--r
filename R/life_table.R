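#' Life tables: death counts and person-years exposures by single year of age
#'
#' A life table holds, for consecutive one-year age intervals
#' \eqn{[x, x+1)}, the death count \eqn{D_x} and the person-years of exposure
#' \eqn{E_x}.  These are the sufficient data for the Poisson likelihood used
#' throughout the package.  `start_age` records the calendar age of the first
#' interval; model age offsets always start at 0, so `a` in a fitted model is
#' the hazard level at `start_age`.
#'
#' `life_table()` validates and constructs the object.  `build_life_table()`
#' aggregates individual lifespans (ages at death, as offsets from
#' `start_age`) into exact death counts and person-years: an individual dying
#' at age \eqn{T} contributes \eqn{\min(T, x+1) - x} years to each interval
#' with \eqn{x < T}, so that total exposure equals total lifespan lived.
#'
#' @param deaths Non-negative death counts \eqn{D_x} (may be fractional, as
#'   published HMD counts are).
#' @param exposure Non-negative person-years \eqn{E_x}, same length as
#'   `deaths`.  Any age with zero exposure must have zero deaths.
#' @param start_age Integer calendar age of the first interval.
#' @param lifespans Numeric vector of non-negative ages at death (offsets from
#'   `start_age`).
#'
#' @return An object of class `"life_table"`: a data frame with columns
#'   `age` (calendar age, left endpoint), `deaths` and `exposure`, and an
#'   attribute `start_age`.
#'
#' @examples
#' build_life_table(c(0.5, 1.5))  # D = (1, 1), E = (1.5, 0.5)
#' @export
life_table <- function(deaths, exposure, start_age = 0) {
  if (!is.numeric(deaths) || !is.numeric(exposure))
    stop("'deaths' and 'exposure' must be numeric", call. = FALSE)
  if (length(deaths) != length(exposure))
    stop("'deaths' and 'exposure' must have the same length", call. = FALSE)
  if (length(deaths) < 2L)
    stop("a life table needs at least two age intervals", call. = FALSE)
  if (anyNA(deaths) || anyNA(exposure) || any(deaths < 0) || any(exposure < 0))
    stop("death counts and exposures must be non-negative", call. = FALSE)
  if (any(deaths > 0 & exposure == 0))
    stop("ages with zero exposure must have zero deaths", call. = FALSE)
  start_age <- as.integer(start_age)
  out <- data.frame(age = start_age + seq_along(deaths) - 1L,
                    deaths = as.numeric(deaths),
                    exposure = as.numeric(exposure))
  attr(out, "start_age") <- start_age
  class(out) <- c("life_table", "data.frame")
  out
}

#' @rdname life_table
#' @export
build_life_table <- function(lifespans, start_age = 0) {
  if (length(lifespans) == 0L)
    stop("'lifespans' is empty", call. = FALSE)
  if (!is.numeric(lifespans) || anyNA(lifespans) || any(lifespans < 0))
    stop("'lifespans' must be non-negative ages at death", call. = FALSE)
  m <- max(floor(max(lifespans)), 1)            # at least two intervals
  idx <- floor(lifespans)                       # interval of death, 0-based
  D <- tabulate(pmin(idx, m) + 1L, nbins = m + 1L)
  # exposure: full years from everyone alive past x+1, plus the fractional
  # year lived by those dying inside [x, x+1)
  frac <- vapply(0:m, function(x) sum(lifespans[idx == x] - x), numeric(1))
  frac[m + 1L] <- sum(lifespans[idx >= m] - m)  # terminal open-ended interval
  alive_past <- length(lifespans) - cumsum(D)   # survivors beyond x+1
  E <- alive_past + frac
  E[m + 1L] <- frac[m + 1L]                     # nobody outlives the last bin
  life_table(D, E, start_age = start_age)
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("Life table: ages %d-%d, %s deaths, %s person-years\n",
              min(x$age), max(x$age),
              format(sum(x$deaths)), format(round(sum(x$exposure), 1))))
  NextMethod()
}

as_life_table <- function(x) {
  if (inherits(x, "life_table")) return(x)
  if (is.data.frame(x) && all(c("deaths", "exposure") %in% names(x))) {
    sa <- if ("age" %in% names(x)) min(x$age) else 0L
    return(life_table(x$deaths, x$exposure, start_age = sa))
  }
  stop("cannot interpret 'x' as a life table", call. = FALSE)
}
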