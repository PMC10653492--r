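test_that("ML recovers the truth region and beats the true parameters' likelihood", {
  lt <- make_cohort_table(10000, 1e-4, 0.1, 0.2, seed = 11)
  fit <- gg_fit(lt, "ML", seed = 1)
  expect_true(fit$converged)
  # maximizer property: at least as good as the generating parameters
  expect_gte(fit$loglik, poisson_loglik(theta_ref, lt) - 1e-6)
  # self-consistency: stored loglik is the recomputed one
  expect_equal(fit$loglik, poisson_loglik(coef(fit), lt), tolerance = 1e-12)
  # sanity on the estimates (3-4 sampling SDs at this n)
  expect_equal(coef(fit)[["a"]], 1e-4, tolerance = 0.5)
  expect_equal(coef(fit)[["b"]], 0.1, tolerance = 0.06)
  expect_lt(abs(coef(fit)[["sigma2"]] - 0.2), 0.08)
})

test_that("MAP shrinks sigma2 exactly to zero on Gompertz data but not on frailty data", {
  lt0 <- make_cohort_table(10000, 1e-4, 0.1, 0, seed = 12)
  map0 <- gg_fit(lt0, "MAP", seed = 1)
  ml0 <- gg_fit(lt0, "ML", seed = 1)
  expect_identical(coef(map0)[["sigma2"]], 0)
  expect_lt(coef(ml0)[["sigma2"]], 0.05)           # small, reported as found
  expect_identical(detect_deceleration(map0), "no_deceleration")

  lt1 <- make_cohort_table(10000, 1e-4, 0.1, 0.2, seed = 13)
  map1 <- gg_fit(lt1, "MAP", seed = 1)
  expect_gt(coef(map1)[["sigma2"]], 0.05)
  expect_identical(detect_deceleration(map1), "deceleration")
  # penalized objective is consistently stored
  expect_equal(map1$penalized_loglik,
               penalized_loglik(map1$theta_interior, lt1, lambda = 0.5),
               tolerance = 1e-12)
})

test_that("fits are bit-reproducible given a seed and lambda = 0 makes MAP equal ML", {
  lt <- make_cohort_table(5000, 1e-4, 0.1, 0.2, seed = 14)
  f1 <- gg_fit(lt, "ML", seed = 9, se = FALSE)
  f2 <- gg_fit(lt, "ML", seed = 9, se = FALSE)
  expect_identical(coef(f1), coef(f2))
  ml <- gg_fit(lt, "ML", seed = 5, se = FALSE)
  map0 <- gg_fit(lt, "MAP", control = gg_control(lambda = 0), seed = 5,
                 se = FALSE)
  expect_identical(coef(ml), coef(map0))
})

test_that("MAP never exceeds ML in sigma2 across replicated tables", {
  reps <- 200
  set.seed(15)
  seeds <- sample.int(.Machine$integer.max, reps)
  le <- logical(reps)
  for (i in seq_len(reps)) {
    set.seed(seeds[i])
    lt <- build_life_table(gg_sample(2000, 1e-4, 0.1, 0.2))
    s_ml <- coef(gg_fit(lt, "ML", seed = seeds[i], se = FALSE))[["sigma2"]]
    s_map <- coef(gg_fit(lt, "MAP", seed = seeds[i], se = FALSE))[["sigma2"]]
    le[i] <- s_map <= s_ml + 1e-8
  }
  expect_gte(mean(le), 0.95)
})

test_that("degenerate tables are rejected", {
  expect_error(gg_fit(life_table(c(0, 0), c(5, 5))), "no deaths")
  expect_error(gg_fit(life_table(c(1, 0), c(5, 0))), "3 ages")
})

test_that("observed information matches the closed-form Poisson variance in 1 parameter", {
  # constant-hazard model mu = exp(eta): Var(eta_hat) = 1 / sum(E mu)
  D <- c(7, 4, 6, 9)
  E <- c(50, 40, 60, 55)
  eta_hat <- log(sum(D) / sum(E))
  f <- function(p) sum(D * p) - sum(E) * exp(p)
  H <- ggfrailty:::num_hessian(f, eta_hat)
  expect_equal(-1 / H[1, 1], 1 / (sum(E) * exp(eta_hat)), tolerance = 1e-4)
})

test_that("standard errors: symmetry, zero-exposure invariance, boundary NA", {
  lt <- make_cohort_table(10000, 1e-4, 0.1, 0.2, seed = 16)
  fit <- gg_fit(lt, "ML", seed = 2)
  expect_true(isSymmetric(fit$vcov))
  expect_true(all(diag(fit$vcov) >= 0))
  expect_true(all(fit$se[c("a", "b", "sigma2")] > 0))
  # appending an empty age changes nothing
  lt_aug <- life_table(c(lt$deaths, 0), c(lt$exposure, 0))
  fit_aug <- gg_fit(lt_aug, "ML", seed = 2)
  expect_equal(fit$se, fit_aug$se, tolerance = 1e-6)
  # MAP at the boundary: no fabricated sigma2 standard error
  lt0 <- make_cohort_table(10000, 1e-4, 0.1, 0, seed = 17)
  map0 <- gg_fit(lt0, "MAP", seed = 2)
  expect_identical(coef(map0)[["sigma2"]], 0)
  expect_true(is.na(map0$se[["sigma2"]]))
  expect_true(all(is.finite(map0$se[c("a", "b")])))
})

test_that("Wald interval arithmetic, degenerate cases, and the detection rule", {
  expect_equal(wald_ci_sigma2(0.070513, se = 0.021156),
               c(lower = 0.029047, upper = 0.111978), tolerance = 2e-5)
  expect_identical(wald_ci_sigma2(0.3, se = 0),
                   c(lower = 0.3, upper = 0.3))
  expect_identical(wald_ci_sigma2(0.3, se = 0.1, level = 0),
                   c(lower = 0.3, upper = 0.3))
  # lower endpoint floored at zero
  expect_identical(wald_ci_sigma2(0.01, se = 0.1)[["lower"]], 0)
  expect_error(wald_ci_sigma2(0.3, se = NA), "standard error")
})

test_that("fit methods behave like a standard modelling object", {
  lt <- make_cohort_table(10000, 1e-4, 0.1, 0.2, seed = 18)
  fit <- gg_fit(lt, "ML", seed = 3)
  expect_named(coef(fit), c("a", "b", "sigma2"))
  expect_s3_class(logLik(fit), "logLik")
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_equal(dim(vcov(fit)), c(3L, 3L))
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= ci[, 2]))
  expect_length(predict(fit), nrow(lt))
  expect_equal(predict(fit, ages = 0, type = "survival"), 1)
  expect_length(residuals(fit), nrow(lt))
  # Pearson residuals have roughly unit scale
  expect_lt(abs(mean(residuals(fit))), 0.5)
  sims <- simulate(fit, nsim = 2, seed = 4, n = 500)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "life_table")
  expect_output(print(fit), "Gamma-Gompertz fit")
  expect_output(print(summary(fit)), "Wald CI")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
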