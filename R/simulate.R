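#' Simulate Gompertz / gamma-Gompertz lifespans
#'
#' Draws i.i.d. ages at death by inverse-transform sampling of the marginal
#' survival function: \eqn{X = \bar S^{-1}(U)} with \eqn{U \sim} Uniform(0,1)
#' (Gompertz branch when `sigma2 = 0`).  Marginally this is identical to the
#' two-stage frailty mechanism that first draws an individual frailty
#' \eqn{Z \sim} Gamma(mean 1, variance \eqn{\sigma^2}) and then a Gompertz
#' lifespan with level \eqn{Z a}.  Uses the current RNG state; call
#' `set.seed()` for reproducibility.
#'
#' @param n Number of lifespans.
#' @inheritParams gg_models
#' @return Numeric vector of `n` ages at death (years, offsets from age 0 of
#'   the model).
#' @examples
#' set.seed(1)
#' summary(gg_sample(1000, a = 1e-4, b = 0.1, sigma2 = 0.2))
#' @export
gg_sample <- function(n, a, b, sigma2) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  gg_quantile(stats::runif(n), a, b, sigma2)
}

#' Monte Carlo study designs for the estimator comparison
#'
#' `gg_scenarios()` builds the two standard designs: the heterogeneity
#' design crosses \eqn{a \in \{10^{-4}, 10^{-5}\}}, \eqn{b \in \{0.1,
#' 0.15\}} and \eqn{\sigma^2 \in \{0.2, 0.8\}} (8 scenarios); the
#' no-heterogeneity (Gompertz, \eqn{\sigma^2 = 0}) design crosses
#' \eqn{a \in \{1, 3, 5\} \times 10^{-4}} and \eqn{b \in \{0.09, 0.10,
#' 0.11\}} (9 scenarios).
#'
#' @param type `"heterogeneity"`, `"gompertz"`, or `"both"` (17 scenarios).
#' @return A data frame with columns `label`, `a`, `b`, `sigma2`.
#' @export
gg_scenarios <- function(type = c("both", "heterogeneity", "gompertz")) {
  type <- match.arg(type)
  het <- expand.grid(sigma2 = c(0.2, 0.8), b = c(0.1, 0.15),
                     a = c(1e-4, 1e-5))[, 3:1]
  het$label <- sprintf("a%d,b%d,s%d",
                       match(het$a, c(1e-4, 1e-5)),
                       match(het$b, c(0.1, 0.15)),
                       match(het$sigma2, c(0.2, 0.8)))
  gom <- expand.grid(b = c(0.09, 0.10, 0.11), a = c(1e-4, 3e-4, 5e-4))[, 2:1]
  gom$sigma2 <- 0
  gom$label <- sprintf("a%d,b%d,s0",
                       match(gom$a, c(1e-4, 3e-4, 5e-4)),
                       match(gom$b, c(0.09, 0.10, 0.11)))
  out <- switch(type, heterogeneity = het, gompertz = gom,
                both = rbind(het, gom))
  rownames(out) <- NULL
  out[c("label", "a", "b", "sigma2")]
}

#' Monte Carlo evaluation of the ML and MAP estimators
#'
#' For each scenario and replicate: simulate a cohort of `n` lifespans from
#' the true parameters, aggregate it into a life table, fit by each method,
#' and record the estimates and the deceleration decision.  Summaries are
#' the bias (mean estimate minus truth) and standard deviation of each
#' parameter's estimates per scenario and method, plus pooled detection
#' error rates: the type I rate is the share of \eqn{\sigma^2 = 0}-truth
#' replicates in which a method detects deceleration, the type II rate the
#' share of \eqn{\sigma^2 > 0}-truth replicates in which it does not.
#'
#' Per-replicate seeds are pre-drawn from the master seed into a
#' scenario-by-replicate table, so the study is reproducible bit-for-bit
#' and any single replicate can be re-run in isolation.
#'
#' @param scenarios Data frame with columns `label`, `a`, `b`, `sigma2`
#'   (see [gg_scenarios()]).
#' @param n Cohort size per replicate (10,000 in the reference design;
#'   2,000 and 5,000 are the reduced companion sizes).
#' @param reps Replicates per scenario (>= 2).
#' @param methods Character subset of `c("ML", "MAP")`.
#' @param control A [gg_control()]; `lambda` applies to MAP fits.
#' @param seed Master seed for the whole study.
#' @return An object of class `"gg_mc_study"`: list with `summary` (tidy
#'   data frame: scenario, method, parameter, truth, bias, sd, reps),
#'   `estimates` (per-replicate estimates), `detection` (per-replicate
#'   decisions), `error_rates`, `failures`, `n`, `reps`, `seed`.
#' @examples
#' run_mc_study(gg_scenarios("heterogeneity")[1, ], n = 2000, reps = 2,
#'              methods = "ML", seed = 1)
#' @export
run_mc_study <- function(scenarios, n = 10000, reps = 200,
                         methods = c("ML", "MAP"),
                         control = gg_control(), seed = 1) {
  stopifnot(is.data.frame(scenarios),
            all(c("label", "a", "b", "sigma2") %in% names(scenarios)),
            reps >= 2, n >= 10)
  methods <- match.arg(methods, c("ML", "MAP"), several.ok = TRUE)
  set.seed(as.integer(seed))
  seed_tab <- matrix(sample.int(.Machine$integer.max, nrow(scenarios) * reps),
                     nrow = nrow(scenarios))
  est <- list()
  failures <- 0L
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    for (r in seq_len(reps)) {
      rs <- seed_tab[i, r]
      set.seed(rs)
      lt <- build_life_table(gg_sample(n, sc$a, sc$b, sc$sigma2))
      for (meth in methods) {
        fit <- tryCatch(
          gg_fit(lt, method = meth, control = control, seed = rs, se = FALSE),
          error = function(e) NULL)
        if (is.null(fit)) { failures <- failures + 1L; next }
        est[[length(est) + 1L]] <- data.frame(
          scenario = sc$label, method = meth, rep = r,
          a_true = sc$a, b_true = sc$b, sigma2_true = sc$sigma2,
          a = fit$coefficients[["a"]], b = fit$coefficients[["b"]],
          sigma2 = fit$coefficients[["sigma2"]],
          detected = detect_deceleration(fit) == "deceleration")
      }
    }
  }
  est <- do.call(rbind, est)
  summ <- do.call(rbind, lapply(split(est, est[c("method", "scenario")],
                                      drop = TRUE), function(d) {
    truth <- c(a = d$a_true[1], b = d$b_true[1], sigma2 = d$sigma2_true[1])
    data.frame(scenario = d$scenario[1], method = d$method[1],
               parameter = names(truth), truth = unname(truth),
               bias = vapply(names(truth),
                             function(p) mean(d[[p]]) - truth[[p]], 0),
               sd = vapply(names(truth), function(p) stats::sd(d[[p]]), 0),
               reps = nrow(d), row.names = NULL)
  }))
  rownames(summ) <- NULL
  out <- structure(list(summary = summ, estimates = est,
                        failures = failures, n = n, reps = reps,
                        seed = seed, methods = methods),
                   class = "gg_mc_study")
  out$error_rates <- error_rates(out)
  out
}

#' Pooled deceleration-detection error rates from a Monte Carlo study
#'
#' Type I: proportion of replicates with true \eqn{\sigma^2 = 0} in which
#' deceleration was detected.  Type II: proportion of replicates with true
#' \eqn{\sigma^2 > 0} in which it was not.  Rates are pooled over all
#' scenarios of the respective truth class; a missing truth class gives
#' `NA`, not 0.
#'
#' @param study A `"gg_mc_study"` object.
#' @param method Method whose decisions are assessed (default `"MAP"`,
#'   falling back to the study's only method).
#' @return Named list `type_I`, `type_II`.
#' @export
error_rates <- function(study, method = NULL) {
  stopifnot(inherits(study, "gg_mc_study"))
  if (is.null(method))
    method <- if ("MAP" %in% study$methods) "MAP" else study$methods[1]
  d <- study$estimates[study$estimates$method == method, ]
  null_class <- d$sigma2_true == 0
  list(type_I = if (any(null_class)) mean(d$detected[null_class]) else NA_real_,
       type_II = if (any(!null_class)) mean(!d$detected[!null_class])
                 else NA_real_)
}

#' @export
print.gg_mc_study <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo study: %d scenario/method cells, n = %d, %d reps, seed %s\n",
    nrow(unique(x$summary[c("scenario", "method")])), x$n, x$reps,
    format(x$seed)))
  if (x$failures > 0) cat(sprintf("fit failures excluded: %d\n", x$failures))
  er <- x$error_rates
  cat(sprintf("pooled detection error rates: type I = %s, type II = %s\n",
              format(er$type_I), format(er$type_II)))
  invisible(x)
}

#' @export
summary.gg_mc_study <- function(object, ...) object$summary

#' @export
as.data.frame.gg_mc_study <- function(x, ...) x$summary

#' Write a study's tidy summary and a report table
#'
#' Writes the tidy per-cell summary as CSV and, alongside it, a plain-text
#' report with one row per scenario showing bias and SD of each parameter
#' for every method.
#'
#' @param study A `"gg_mc_study"`.
#' @param path CSV output path; the report gets extension `.txt`.
#' @return `path`, invisibly.
#' @export
write_mc_study <- function(study, path) {
  s <- study$summary
  s$n <- study$n
  s$seed <- study$seed
  utils::write.csv(s, path, row.names = FALSE)
  rep_path <- sub("\\.csv$", ".txt", path)
  if (identical(rep_path, path)) rep_path <- paste0(path, ".txt")
  con <- file(rep_path, "w")
  on.exit(close(con))
  writeLines(sprintf("Monte Carlo study (n = %d, reps = %d, seed = %s)",
                     study$n, study$reps, format(study$seed)), con)
  wide <- stats::reshape(
    s[c("scenario", "method", "parameter", "bias", "sd")],
    direction = "wide", idvar = c("scenario", "method"),
    timevar = "parameter")
  utils::capture.output(print(wide, row.names = FALSE), file = con,
                        append = TRUE)
  er <- study$error_rates
  writeLines(sprintf("type I = %s   type II = %s",
                     format(er$type_I), format(er$type_II)), con)
  invisible(path)
}
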