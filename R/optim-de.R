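# Classic differential evolution (DE/rand/1/bin) over a box, used as the
# global pre-step before local refinement.  The objective is evaluated for
# the whole population in a single call per generation (fn_pop takes a
# d x NP matrix and returns NP values to MAXIMIZE), which keeps the search
# cheap enough for Monte Carlo studies with thousands of fits.
de_maximize <- function(fn_pop, lower, upper, np = 40L, maxiter = 300L,
                        tol = 1e-8, F = 0.8, CR = 0.9, init = NULL) {
  d <- length(lower)
  pop <- matrix(stats::runif(d * np, lower, upper), nrow = d)
  if (!is.null(init)) pop[, 1L] <- pmin(pmax(init, lower), upper)
  val <- fn_pop(pop)
  val[!is.finite(val)] <- -Inf
  iter <- 0L
  nevals <- np
  while (iter < maxiter) {
    iter <- iter + 1L
    # indices r1 != r2 != r3 != target (approximate: random triples)
    r <- vapply(seq_len(np), function(i) sample.int(np, 3L), integer(3L))
    donor <- pop[, r[1L, ], drop = FALSE] +
      F * (pop[, r[2L, ], drop = FALSE] - pop[, r[3L, ], drop = FALSE])
    cross <- matrix(stats::runif(d * np) < CR, nrow = d)
    # guarantee at least one mutated coordinate per member
    forced <- cbind(sample.int(d, np, replace = TRUE), seq_len(np))
    cross[forced] <- TRUE
    trial <- ifelse(cross, donor, pop)
    trial <- pmin(pmax(trial, lower), upper)
    tval <- fn_pop(trial)
    tval[!is.finite(tval)] <- -Inf
    nevals <- nevals + np
    better <- tval >= val
    pop[, better] <- trial[, better]
    val[better] <- tval[better]
    if (max(val) - min(val) < tol) break
  }
  best <- which.max(val)
  list(par = pop[, best], value = val[best], iter = iter, nevals = nevals,
       converged = max(val) - min(val) < tol)
}
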