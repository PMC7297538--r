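#' Assemble a figure-style report bundle
#'
#' Collects the pipeline's tidy tables (per fly-day feeding metrics,
#' per-ROI calcium metrics), the statistical test results, and run
#' metadata into one bundle, optionally writing each part as CSV.
#'
#' @param feeding per fly-day metrics data.frame (from
#'   [analyze_flic_experiment()]); required (may have zero rows).
#' @param calcium per-ROI metrics data.frame (from [ca_metrics_table()]);
#'   required (may have zero rows).
#' @param tests data.frame of test results (columns such as `test`,
#'   `groups`, `n`, `statistic`, `p`, `method`); optional.
#' @param params named list of run parameters and seeds recorded as
#'   metadata.
#' @param dir output directory; when non-NULL the tables are written as
#'   `feeding_metrics.csv`, `calcium_metrics.csv`, `test_results.csv`,
#'   `run_metadata.csv`.
#' @return list of class `flic_report`: `feeding`, `calcium`, `tests`,
#'   `metadata`.
#' @export
build_report <- function(feeding, calcium, tests = NULL, params = list(),
                         dir = NULL) {
  if (missing(feeding) || is.null(feeding))
    stop("missing required table: feeding")
  if (missing(calcium) || is.null(calcium))
    stop("missing required table: calcium")
  if (!is.data.frame(feeding) || !is.data.frame(calcium))
    stop("feeding and calcium must be data.frames")
  if (!is.null(tests)) {
    bad <- which(!is.na(tests$p) & (tests$p <= 0 | tests$p > 1))
    if (length(bad) > 0L)
      stop("invalid p-value in tests row ", bad[1L])
  }
  meta <- data.frame(
    key = c("r_version", "package_version", names(params)),
    value = c(as.character(getRversion()),
              as.character(utils::packageVersion("flicmeal")),
              vapply(params, function(v) paste(format(v), collapse = ";"),
                     character(1))),
    stringsAsFactors = FALSE)
  report <- structure(list(feeding = feeding, calcium = calcium,
                           tests = tests, metadata = meta),
                      class = "flic_report")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(feeding, file.path(dir, "feeding_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(calcium, file.path(dir, "calcium_metrics.csv"),
                     row.names = FALSE)
    if (!is.null(tests))
      utils::write.csv(tests, file.path(dir, "test_results.csv"),
                       row.names = FALSE)
    utils::write.csv(meta, file.path(dir, "run_metadata.csv"),
                     row.names = FALSE)
  }
  report
}

#' @export
print.flic_report <- function(x, ...) {
  cat(sprintf("<flic_report: %d feeding rows, %d calcium rows, %s tests>\n",
              nrow(x$feeding), nrow(x$calcium),
              if (is.null(x$tests)) "no" else nrow(x$tests)))
  invisible(x)
}
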