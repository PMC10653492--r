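#' Goodness of fit on the log death-rate scale
#'
#' The mean squared error between observed log death rates
#' \eqn{\ln m_x = \ln(D_x/E_x)} and the fitted log marginal hazard,
#' \deqn{MSE = \frac{1}{n}\sum_x (\ln m_x - \ln\bar\mu(x;\theta))^2,}
#' where the sum runs over the \eqn{n} ages with \eqn{D_x > 0} and
#' \eqn{E_x > 0} and the hazard is evaluated at the same within-interval
#' point used in fitting.
#'
#' @param lt A [life_table].
#' @param theta Parameters `c(a, b, sigma2)` (e.g. `coef(fit)`).
#' @param age_offset Within-interval evaluation point (0 or 0.5).
#' @return The MSE (dimensionless, log-rate scale).
#' @export
gg_mse <- function(lt, theta, age_offset = 0) {
  lt <- as_life_table(lt)
  theta <- unpack_theta(theta)
  keep <- lt$deaths > 0 & lt$exposure > 0
  if (!any(keep))
    stop("no ages with positive deaths and exposure", call. = FALSE)
  x <- (seq_len(nrow(lt)) - 1 + age_offset)[keep]
  m <- lt$deaths[keep] / lt$exposure[keep]
  mu <- gg_hazard(x, theta[1], theta[2], theta[3])
  mean((log(m) - log(mu))^2)
}

#' Compare the ML and MAP fits of one life table
#'
#' Fits both estimators and compares their goodness of fit by [gg_mse()].
#'
#' @inheritParams gg_fit
#' @param id Optional dataset label.
#' @return An object of class `"gg_comparison"`: list with the two
#'   `"gg_fit"` objects, their MSEs, and `winner` (the method with the
#'   smaller MSE).
#' @export
compare_methods <- function(x, control = gg_control(), seed = NULL,
                            id = NULL) {
  lt <- as_life_table(x)
  fits <- list(ML = gg_fit(lt, "ML", control = control, seed = seed),
               MAP = gg_fit(lt, "MAP", control = control, seed = seed))
  mses <- vapply(fits, function(f)
    gg_mse(lt, coef(f), age_offset = control$age_offset), 0)
  structure(list(id = id, fits = fits, mse = mses,
                 winner = names(mses)[which.min(mses)]),
            class = "gg_comparison")
}

#' @export
print.gg_comparison <- function(x, digits = 6, ...) {
  if (!is.null(x$id)) cat("Dataset:", x$id, "\n")
  tab <- t(vapply(x$fits, coef, numeric(3)))
  tab <- cbind(tab, MSE = x$mse)
  print(round(tab, digits))
  cat("smaller MSE:", x$winner, "\n")
  invisible(x)
}
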