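# Shared fixtures, built in code.  Cohort tables are generated once per test
# run at fixed seeds; tests that need independent draws reseed locally.

theta_ref <- c(a = 1e-4, b = 0.1, sigma2 = 0.2)

make_cohort_table <- function(n, a, b, sigma2, seed) {
  set.seed(seed)
  build_life_table(gg_sample(n, a, b, sigma2))
}

# small deterministic toy table for likelihood arithmetic
toy_table <- function() {
  life_table(deaths = c(2, 3, 5, 4, 1),
             exposure = c(10, 9.5, 8, 6.5, 3), start_age = 0)
}

fast_control <- function(...) {
  # reduced global-search budget for smoke tests where accuracy is not
  # under test
  gg_control(de_np = 15L, de_maxiter = 60L, de_tol = 1e-6, ...)
}
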