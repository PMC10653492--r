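#' Read and write life tables as CSV
#'
#' The CSV schema has a header and columns `age`, `deaths`, `exposure`;
#' ages are consecutive single-year intervals labelled by their integer left
#' endpoint, and deaths may be fractional (HMD publishes non-integer
#' counts).
#'
#' @param path File path.
#' @param lt A [life_table].
#' @return `read_life_table()` returns a [life_table];
#'   `write_life_table()` returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  d <- utils::read.csv(path)
  need <- c("age", "deaths", "exposure")
  if (!all(need %in% names(d)))
    stop("CSV must have columns age, deaths, exposure", call. = FALSE)
  d <- d[order(d$age), ]
  if (!all(diff(d$age) == 1))
    stop("ages must be consecutive single-year intervals", call. = FALSE)
  life_table(d$deaths, d$exposure, start_age = d$age[1])
}

#' @rdname read_life_table
#' @export
write_life_table <- function(lt, path) {
  lt <- as_life_table(lt)
  utils::write.csv(as.data.frame(lt)[c("age", "deaths", "exposure")], path,
                   row.names = FALSE)
  invisible(path)
}

# Parse one HMD 1x1 file (Deaths or Exposures): header lines precede a
# whitespace-delimited table with columns Year, Age, Female, Male, Total;
# the terminal age is "110+"; missing values are ".".
parse_hmd_file <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*Year\\s+Age\\s+Female", lines)
  if (length(hdr) == 0)
    stop("not an HMD 1x1 table: ", path, call. = FALSE)
  d <- utils::read.table(text = lines[-seq_len(hdr[1] - 1L)], header = TRUE,
                         colClasses = "character")
  need <- c("Year", "Age", "Female", "Male", "Total")
  if (!all(need %in% names(d)))
    stop("malformed HMD table: ", path, call. = FALSE)
  d$Age <- sub("\\+$", "", d$Age)        # "110+" -> terminal interval 110
  for (col in c("Year", "Age", "Female", "Male", "Total")) {
    miss <- d[[col]] == "."
    if (any(miss)) {
      warning("treating ", sum(miss), " missing '.' entries as 0 in ",
              basename(path), call. = FALSE)
      d[[col]][miss] <- "0"
    }
    d[[col]] <- as.numeric(d[[col]])
    if (anyNA(d[[col]]))
      stop("malformed rows in HMD table: ", path, call. = FALSE)
  }
  d
}

#' Read a life table from HMD-style Deaths and Exposures files
#'
#' Reads the Human Mortality Database 1x1 text dialect (period or cohort —
#' the layout is the same): header lines, then whitespace-separated columns
#' `Year Age Female Male Total` with a terminal `110+` age.  Returns the
#' selected year and sex restricted to ages `>= min_age`, so that the model
#' age offset 0 corresponds to calendar age `min_age`.
#'
#' @param deaths_path,exposures_path Paths to the Deaths and Exposures
#'   files.
#' @param year Calendar (or cohort) year to extract.
#' @param sex One of `"Female"`, `"Male"`, `"Total"`.
#' @param min_age First age to keep (e.g. 70 for old-age analyses).
#' @return A [life_table] with `start_age = min_age`.
#' @export
read_hmd_table <- function(deaths_path, exposures_path, year,
                           sex = c("Female", "Male", "Total"), min_age = 0) {
  sex <- match.arg(sex)
  dd <- parse_hmd_file(deaths_path)
  ee <- parse_hmd_file(exposures_path)
  dd <- dd[dd$Year == year & dd$Age >= min_age, ]
  ee <- ee[ee$Year == year & ee$Age >= min_age, ]
  if (nrow(dd) == 0 || nrow(ee) == 0)
    stop("year ", year, " not present in the HMD files", call. = FALSE)
  if (!identical(dd$Age, ee$Age))
    stop("Deaths and Exposures age grids differ", call. = FALSE)
  life_table(dd[[sex]], ee[[sex]], start_age = min_age)
}

write_hmd_pair <- function(lt, year, deaths_path, exposures_path) {
  lt <- as_life_table(lt)
  fmt <- function(values, what) {
    ages <- as.character(lt$age)
    ages[length(ages)] <- paste0(ages[length(ages)], "+")
    c(sprintf("Synthetic cohort, %s (period 1x1)", what),
      "",
      sprintf("%6s %6s %14s %14s %14s", "Year", "Age", "Female", "Male",
              "Total"),
      sprintf("%6d %6s %14.2f %14.2f %14.2f", year, ages, values, values,
              values))
  }
  writeLines(fmt(lt$deaths, "Deaths"), deaths_path)
  writeLines(fmt(lt$exposure, "Exposures"), exposures_path)
  invisible(NULL)
}

#' Generate a synthetic life-table fixture on disk
#'
#' Simulates a cohort from known parameters, aggregates it into a life
#' table, and writes it in either the CSV dialect or the HMD 1x1 dialect
#' (a Deaths/Exposures file pair), together with a JSON sidecar
#' (`<out>.meta.json`) recording the true parameters, cohort size and seed.
#' Regeneration with the same seed is byte-identical.
#'
#' @param a,b,sigma2 True parameters of the generating model.
#' @param n Cohort size.
#' @param start_age Calendar age assigned to model age 0.
#' @param format `"csv"` or `"hmd"`.
#' @param seed Integer seed.
#' @param out_path Output path.  For `"hmd"`, `out_path` is a stem: files
#'   `<stem>_Deaths.txt` and `<stem>_Exposures.txt` are written.
#' @return Character vector of the files written, invisibly.
#' @export
generate_fixture <- function(a, b, sigma2, n, start_age = 0,
                             format = c("csv", "hmd"), seed = 1,
                             out_path) {
  format <- match.arg(format)
  set.seed(as.integer(seed))
  lt <- build_life_table(gg_sample(n, a, b, sigma2), start_age = start_age)
  if (format == "csv") {
    write_life_table(lt, out_path)
    files <- out_path
    meta_path <- paste0(out_path, ".meta.json")
  } else {
    files <- paste0(out_path, c("_Deaths.txt", "_Exposures.txt"))
    write_hmd_pair(lt, year = 2000L, files[1], files[2])
    meta_path <- paste0(out_path, ".meta.json")
  }
  jsonlite::write_json(
    list(theta_true = list(a = a, b = b, sigma2 = sigma2), n = n,
         start_age = start_age, seed = seed, format = format,
         synthetic = TRUE),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(files, meta_path))
}
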