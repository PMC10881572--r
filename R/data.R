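# Packaged benchmark datasets and plain-text sample I/O.

.ofhl_fixtures <- c(
  covid_mexico = "covid19_mexico_mortality.txt",
  chemo_survival = "chemo_survival_times.txt")

#' Benchmark datasets
#'
#' The two published validation datasets, shipped as plain text:
#'
#' * `"covid_mexico"` — 108 daily COVID-19 mortality rates for Mexico,
#'   4 March to 20 July 2020.
#' * `"chemo_survival"` — survival times in years of patients treated with
#'   chemotherapy alone; 45 values as printed in the source (the
#'   accompanying text mentions 46 patients, but only 45 values were ever
#'   published, and the published fits reproduce from these 45).
#'
#' @param name `"covid_mexico"` or `"chemo_survival"`.
#' @return Sorted numeric vector with attribute `label` giving provenance.
#' @examples
#' length(ofhl_data("covid_mexico"))  # 108
#' range(ofhl_data("chemo_survival")) # 0.047 4.033
#' @export
ofhl_data <- function(name = c("covid_mexico", "chemo_survival")) {
  name <- match.arg(name)
  path <- system.file("extdata", .ofhl_fixtures[[name]], package = "ofhl",
                      mustWork = TRUE)
  x <- read_sample(path)
  attr(x, "label") <- switch(name,
    covid_mexico = "COVID-19 mortality rate, Mexico, 108 days (2020-03-04 to 2020-07-20)",
    chemo_survival = "Survival times (years), chemotherapy-only patients, 45 values")
  x
}

#' Read a univariate positive sample from a text/CSV file
#'
#' Accepts one numeric value per line, optionally preceded by a single
#' header line and with `#` comment lines ignored. Values must be strictly
#' positive; offending line numbers are reported.
#'
#' @param path file path.
#' @return Sorted numeric vector.
#' @export
read_sample <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  vals <- suppressWarnings(as.numeric(sub(",\\s*$", "", trimws(lines[keep]))))
  if (length(vals) && is.na(vals[1]) && length(vals) > 1) {
    # single header line allowed
    vals <- vals[-1]
    lineno <- lineno[-1]
  }
  if (length(vals) == 0) stop("no numeric values in ", path, call. = FALSE)
  bad <- which(is.na(vals) | vals <= 0)
  if (length(bad))
    stop(sprintf("non-numeric or non-positive values at line(s) %s of %s",
                 paste(lineno[bad], collapse = ", "), path), call. = FALSE)
  sort(vals)
}

#' Write a fit, goodness-of-fit or simulation report to disk
#'
#' `"json"` serialises the object's fields with `jsonlite`; `"csv"` writes
#' the tabular form (the metrics table for an `"ofhl_sim"`, a one-row table
#' for fits and reports).
#'
#' @param x an `"ofhl_fit"`, `"ofhl_gof"`, `"ofhl_sim"` object, a
#'   `data.frame` or a plain list of scalars.
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("json", "csv")) {
  format <- match.arg(format)
  tab <- if (inherits(x, "ofhl_sim")) x$metrics
         else if (is.data.frame(x)) x
         else as.data.frame(unclass(x)[vapply(unclass(x), function(f)
           is.atomic(f) && length(f) == 1, logical(1))])
  if (format == "csv") {
    write.csv(tab, path, row.names = FALSE)
  } else {
    obj <- if (inherits(x, "ofhl_sim"))
      list(metrics = x$metrics, rank_summary = x$rank_summary,
           overall = x$overall, flags = x$flags)
    else unclass(x)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}
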