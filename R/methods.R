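#' @export
print.gg_fit <- function(x, digits = 6, ...) {
  cat(sprintf("Gamma-Gompertz fit (%s%s)\n", x$method,
              if (x$method == "MAP") sprintf(", lambda = %g", x$lambda) else ""))
  print(round(x$coefficients, digits))
  cat(sprintf("log-likelihood: %.4f", x$loglik))
  if (!is.null(x$penalized_loglik))
    cat(sprintf("   penalized: %.4f", x$penalized_loglik))
  cat("\n")
  invisible(x)
}

#' @export
summary.gg_fit <- function(object, level = 0.95, ...) {
  co <- object$coefficients
  se <- if (is.null(object$se)) rep(NA_real_, 3L) else object$se
  tab <- cbind(Estimate = co, `Std. Error` = se)
  out <- list(coefficients = tab, method = object$method,
              lambda = object$lambda, loglik = object$loglik,
              penalized_loglik = object$penalized_loglik,
              mse = gg_mse(object$data, co,
                           age_offset = object$control$age_offset),
              deceleration = detect_deceleration(object, level = level),
              ci_sigma2 = tryCatch(
                wald_ci_sigma2(object, level = level),
                error = function(e) NULL),
              level = level,
              converged = object$converged, nobs = object$nobs)
  class(out) <- "summary.gg_fit"
  out
}

#' @export
print.summary.gg_fit <- function(x, digits = 6, ...) {
  cat(sprintf("Gamma-Gompertz frailty model, %s estimate%s\n", x$method,
              if (x$method == "MAP") sprintf(" (lambda = %g)", x$lambda) else ""))
  stats::printCoefmat(x$coefficients, digits = digits, na.print = "-")
  cat(sprintf("\nlog-likelihood %.4f", x$loglik))
  if (!is.null(x$penalized_loglik))
    cat(sprintf(", penalized %.4f", x$penalized_loglik))
  cat(sprintf("\nMSE (log death-rate scale): %.6f\n", x$mse))
  if (!is.null(x$ci_sigma2))
    cat(sprintf("%d%% Wald CI for sigma2: (%.6f, %.6f)\n", round(100 * x$level),
                x$ci_sigma2[["lower"]], x$ci_sigma2[["upper"]]))
  cat(sprintf("mortality deceleration: %s\n",
              sub("_", " ", x$deceleration)))
  if (!x$converged) cat("warning: local optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.gg_fit <- function(object, ...) object$coefficients

#' @export
logLik.gg_fit <- function(object, ...) {
  structure(object$loglik, df = 3L, nobs = object$nobs, class = "logLik")
}

#' @export
vcov.gg_fit <- function(object, ...) object$vcov

#' @export
confint.gg_fit <- function(object, parm = c("a", "b", "sigma2"),
                           level = 0.95, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  z <- stats::qnorm((1 + level) / 2)
  co <- object$coefficients[parm]
  se <- object$se[parm]
  out <- cbind(co - z * se, co + z * se)
  out["sigma2" == rownames(out), 1] <- pmax(0, out["sigma2" == rownames(out), 1])
  colnames(out) <- paste(format(100 * c((1 - level) / 2, (1 + level) / 2)), "%")
  out
}

#' Predicted hazard or survival from a fitted model
#'
#' @param object A `"gg_fit"` object.
#' @param ages Age offsets (years from the table's start age) at which to
#'   evaluate; defaults to the fitted table's age grid.
#' @param type `"hazard"` (marginal force of mortality) or `"survival"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.gg_fit <- function(object, ages = NULL,
                           type = c("hazard", "survival"), ...) {
  type <- match.arg(type)
  if (is.null(ages))
    ages <- seq_len(nrow(object$data)) - 1 + object$control$age_offset
  co <- object$coefficients
  switch(type,
         hazard = gg_hazard(ages, co[["a"]], co[["b"]], co[["sigma2"]]),
         survival = gg_survival(ages, co[["a"]], co[["b"]], co[["sigma2"]]))
}

#' @export
fitted.gg_fit <- function(object, ...) {
  object$data$exposure * predict(object, type = "hazard")
}

#' @export
residuals.gg_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  r <- object$data$deaths - mu
  if (type == "pearson") r <- ifelse(mu > 0, r / sqrt(mu), 0)
  r
}

#' Simulate cohorts from a fitted model
#'
#' Draws `nsim` cohorts of the same size as the fitted cohort (rounded total
#' deaths) from the fitted parameters and returns them as life tables.
#'
#' @param object A `"gg_fit"` object.
#' @param nsim Number of cohorts.
#' @param seed Optional integer seed.
#' @param n Cohort size; defaults to the fitted table's total deaths.
#' @param ... Unused.
#' @return A list of [life_table] objects.
#' @export
simulate.gg_fit <- function(object, nsim = 1, seed = NULL, n = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n)) n <- max(2L, round(sum(object$data$deaths)))
  co <- object$coefficients
  replicate(nsim, build_life_table(
    gg_sample(n, co[["a"]], co[["b"]], co[["sigma2"]]),
    start_age = attr(object$data, "start_age")), simplify = FALSE)
}

#' Plot observed log death rates with the fitted log hazard
#'
#' @param x A `"gg_fit"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gg_fit <- function(x, ...) {
  lt <- x$data
  keep <- lt$deaths > 0 & lt$exposure > 0
  obs <- log(lt$deaths[keep] / lt$exposure[keep])
  graphics::plot(lt$age[keep], obs, xlab = "age", ylab = "log death rate",
                 pch = 16, cex = 0.6, ...)
  xg <- seq(0, nrow(lt) - 1, by = 0.1)
  graphics::lines(lt$age[1] + xg,
                  log(predict(x, ages = xg, type = "hazard")), col = 2)
  graphics::legend("topleft", bty = "n",
                   legend = c("observed", paste0("fitted (", x$method, ")")),
                   pch = c(16, NA), lty = c(NA, 1), col = c(1, 2))
  invisible(x)
}
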