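test_that("MSE is zero at a perfect fit and matches hand-built cases", {
  th <- c(1e-4, 0.1, 0.2)
  x <- 0:9
  mu <- gg_hazard(x, th[1], th[2], th[3])
  lt <- life_table(deaths = mu * 100, exposure = rep(100, 10))
  expect_equal(gg_mse(lt, th), 0, tolerance = 1e-24)

  # two ages with rates (0.01, 0.05); model rates (0.01 e, 0.05)
  # => ((ln e)^2 + 0) / 2 = 0.5
  th0 <- c(a = 0.01 * exp(1), b = log(0.05 / (0.01 * exp(1))), sigma2 = 0)
  lt2 <- life_table(deaths = c(0.01 * 5, 0.05 * 5), exposure = c(5, 5))
  expect_equal(gg_hazard(0:1, th0[1], th0[2], th0[3]),
               c(0.01 * exp(1), 0.05))
  expect_equal(gg_mse(lt2, th0), 0.5, tolerance = 1e-12)
})

test_that("MSE agrees with a per-age loop and skips non-eligible ages", {
  set.seed(41)
  D <- c(rpois(6, 10), 0)
  E <- c(runif(6, 20, 50), 10)
  lt <- life_table(D, E)
  th <- c(0.02, 0.11, 0.3)
  acc <- 0; n <- 0
  for (x in 0:6) {
    if (D[x + 1] > 0 && E[x + 1] > 0) {
      acc <- acc + (log(D[x + 1] / E[x + 1]) -
                      log(gg_hazard(x, th[1], th[2], th[3])))^2
      n <- n + 1
    }
  }
  expect_equal(gg_mse(lt, th), acc / n, tolerance = 1e-12)
  expect_error(gg_mse(life_table(c(0, 0), c(1, 1)), th), "positive deaths")
})

test_that("CSV life tables round-trip losslessly", {
  lt <- make_cohort_table(2000, 1e-4, 0.1, 0.2, seed = 42)
  path <- file.path(tempdir(), "lt.csv")
  write_life_table(lt, path)
  back <- read_life_table(path)
  expect_equal(as.data.frame(back), as.data.frame(lt))
  # and write -> read -> write is byte-identical
  path2 <- file.path(tempdir(), "lt2.csv")
  write_life_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), bad)
  expect_error(read_life_table(bad), "columns")
})

test_that("HMD dialect: read restricted to year/sex/min_age, terminal row, round-trip", {
  set.seed(43)
  lt <- build_life_table(gg_sample(3000, 5e-3, 0.11, 0.1), start_age = 70)
  stem <- file.path(tempdir(), "synthetic_hmd")
  ggfrailty:::write_hmd_pair(lt, 2000L, paste0(stem, "_Deaths.txt"),
                             paste0(stem, "_Exposures.txt"))
  back <- read_hmd_table(paste0(stem, "_Deaths.txt"),
                         paste0(stem, "_Exposures.txt"),
                         year = 2000, sex = "Female", min_age = 70)
  # min_age maps calendar age 70 to model age 0
  expect_identical(attr(back, "start_age"), 70L)
  expect_equal(back$age[1], 70)
  expect_equal(back$deaths, round(lt$deaths, 2))
  expect_equal(back$exposure, round(lt$exposure, 2))
  # read -> write -> read is exact
  stem2 <- file.path(tempdir(), "synthetic_hmd2")
  ggfrailty:::write_hmd_pair(back, 2000L, paste0(stem2, "_Deaths.txt"),
                             paste0(stem2, "_Exposures.txt"))
  back2 <- read_hmd_table(paste0(stem2, "_Deaths.txt"),
                          paste0(stem2, "_Exposures.txt"),
                          year = 2000, sex = "Female", min_age = 70)
  expect_equal(as.data.frame(back2), as.data.frame(back))
  # selecting a later min_age drops leading ages
  trimmed <- read_hmd_table(paste0(stem, "_Deaths.txt"),
                            paste0(stem, "_Exposures.txt"),
                            year = 2000, sex = "Male", min_age = 75)
  expect_equal(nrow(trimmed), nrow(back) - 5L)
  expect_error(read_hmd_table(paste0(stem, "_Deaths.txt"),
                              paste0(stem, "_Exposures.txt"),
                              year = 1901, sex = "Female"), "1901")
})

test_that("missing '.' markers are zeroed with a warning", {
  stem <- file.path(tempdir(), "synthetic_miss")
  set.seed(44)
  lt <- build_life_table(gg_sample(500, 1e-3, 0.1, 0), start_age = 70)
  ggfrailty:::write_hmd_pair(lt, 2000L, paste0(stem, "_D.txt"),
                             paste0(stem, "_E.txt"))
  lines <- readLines(paste0(stem, "_D.txt"))
  lines[5] <- sub("[0-9.]+$", ".", lines[5])
  writeLines(lines, paste0(stem, "_D.txt"))
  expect_warning(
    back <- read_hmd_table(paste0(stem, "_D.txt"), paste0(stem, "_E.txt"),
                           year = 2000, sex = "Total", min_age = 70),
    "missing")
  expect_equal(back$deaths[2], 0)
})

test_that("fixture generation is byte-reproducible and records the truth", {
  out <- file.path(tempdir(), "fix.csv")
  f1 <- generate_fixture(1e-4, 0.1, 0.2, n = 1000, format = "csv",
                         seed = 7, out_path = out)
  bytes1 <- readLines(out)
  generate_fixture(1e-4, 0.1, 0.2, n = 1000, format = "csv", seed = 7,
                   out_path = out)
  expect_identical(readLines(out), bytes1)
  meta <- jsonlite::read_json(paste0(out, ".meta.json"))
  expect_equal(meta$theta_true$sigma2, 0.2)
  expect_equal(meta$seed, 7)
  expect_true(meta$synthetic)
  # HMD flavour writes a pair plus metadata
  files <- generate_fixture(1e-4, 0.1, 0, n = 1000, format = "hmd", seed = 7,
                            out_path = file.path(tempdir(), "fixh"))
  expect_length(files, 3L)
  expect_true(all(file.exists(files)))
})

test_that("fitting a generated fixture recovers the generating parameters", {
  out <- file.path(tempdir(), "fix_big.csv")
  generate_fixture(1e-4, 0.1, 0.2, n = 30000, format = "csv", seed = 8,
                   out_path = out)
  fit <- gg_fit(read_life_table(out), "ML", seed = 1, se = FALSE)
  expect_equal(coef(fit)[["a"]], 1e-4, tolerance = 0.3)
  expect_equal(coef(fit)[["b"]], 0.1, tolerance = 0.05)
  expect_lt(abs(coef(fit)[["sigma2"]] - 0.2), 0.05)
})

test_that("method comparison is internally consistent and favours MAP under Gompertz truth", {
  lt <- make_cohort_table(10000, 1e-4, 0.1, 0, seed = 45)
  cmp <- compare_methods(lt, seed = 1)
  expect_identical(cmp$winner, names(cmp$mse)[which.min(cmp$mse)])
  expect_output(print(cmp), "smaller MSE")

  nfix <- 50
  set.seed(46)
  seeds <- sample.int(.Machine$integer.max, nfix)
  map_wins <- 0L
  for (i in seq_len(nfix)) {
    set.seed(seeds[i])
    lt <- build_life_table(gg_sample(5000, 1e-4, 0.1, 0))
    cmp <- compare_methods(lt, seed = seeds[i])
    if (cmp$winner == "MAP") map_wins <- map_wins + 1L
  }
  # "at least as often": reject only if MAP wins significantly less than half
  expect_gt(binom.test(map_wins, nfix, 0.5,
                       alternative = "less")$p.value, 0.05)
})
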