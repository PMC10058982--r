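#' Flow--area curve set over one cardiac cycle
#'
#' Container for a sampled QA dataset: through-plane volumetric flow and
#' lumen cross-sectional area at a single vessel cross-section, sampled over
#' one cardiac cycle.  This is the raw input of the chi-method and the output
#' of [extract_curves()] and [synthesize_qa_curves()].
#'
#' All quantities are strict SI: seconds, m^3/s, m^2.  Sampling need not be
#' uniform; only strict time ordering is required.
#'
#' @param time Numeric vector of sample times (s), strictly increasing,
#'   contained in `[0, period]`.
#' @param flow Numeric vector of volumetric flow (m^3/s), same length as
#'   `time`.
#' @param area Numeric vector of lumen cross-sectional area (m^2), strictly
#'   positive, same length as `time`.
#' @param period Cardiac cycle duration (s), positive.
#'
#' @return An object of class `qa_curves`: a list with elements `time`,
#'   `flow`, `area`, `period`.
#' @seealso [read_qa_csv()], [write_qa_csv()], [estimate_elasticity()]
#' @export
#' @examples
#' t <- seq(0, 1.05, length.out = 30)
#' qa <- qa_curves(t, flow = 1e-4 * pmax(sin(2 * pi * t / 1.12), 0),
#'                 area = 8e-4 * (1 + 0.02 * sin(2 * pi * t / 1.12)),
#'                 period = 1.12)
#' qa
qa_curves <- function(time, flow, area, period) {
  time <- as.numeric(time)
  flow <- as.numeric(flow)
  area <- as.numeric(area)
  period <- as.numeric(period)
  n <- length(time)
  if (length(flow) != n || length(area) != n) {
    stop("time, flow and area must have equal length", call. = FALSE)
  }
  if (n < 8L) {
    stop("a QA curve set needs at least 8 samples, got ", n, call. = FALSE)
  }
  if (length(period) != 1L || !is.finite(period) || period <= 0) {
    stop("period must be a single positive number (seconds)", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(diff(time) <= 0)) {
    stop("time must be finite and strictly increasing", call. = FALSE)
  }
  if (time[1L] < 0 || time[n] > period + 1e-9 * period) {
    stop("time samples must lie within [0, period]", call. = FALSE)
  }
  if (any(!is.finite(flow))) stop("flow contains non-finite values", call. = FALSE)
  if (any(!is.finite(area)) || any(area <= 0)) {
    stop("area must be finite and strictly positive", call. = FALSE)
  }
  structure(list(time = time, flow = flow, area = area, period = period),
            class = "qa_curves")
}

#' @export
print.qa_curves <- function(x, ...) {
  cat(sprintf("<qa_curves> %d samples over %.4g s cycle\n",
              length(x$time), x$period))
  cat(sprintf("  flow: [%.4g, %.4g] m^3/s\n", min(x$flow), max(x$flow)))
  cat(sprintf("  area: [%.4g, %.4g] m^2\n", min(x$area), max(x$area)))
  invisible(x)
}

#' @export
length.qa_curves <- function(x) length(x$time)

#' Read / write QA curves as CSV
#'
#' The on-disk schema has one row per cardiac frame and header columns
#' `time_s`, `flow_m3_per_s`, `area_m2`.  Lines starting with `#` are
#' comments; the writer records the cycle duration in a
#' `# period_s=<value>` comment which the reader recovers.  When the comment
#' is absent the period is inferred as the last sample time plus the median
#' sampling interval.
#'
#' Areas outside `[1e-6, 1e-2]` m^2 trigger a unit-sanity warning (values in
#' mm^2 or cm^2 are a common import mistake).
#'
#' @param path File path.
#' @param curves A [qa_curves()] object.
#' @return `read_qa_csv()` returns a [qa_curves()] object; `write_qa_csv()`
#'   returns `path` invisibly.
#' @export
read_qa_csv <- function(path) {
  if (!file.exists(path)) stop("QA CSV not found: ", path, call. = FALSE)
  lines <- readLines(path)
  comment <- grep("^\\s*#", lines, value = TRUE)
  period <- NA_real_
  m <- regmatches(comment, regexpr("period_s\\s*[=:]\\s*[0-9.eE+-]+", comment))
  if (length(m) > 0L) {
    period <- as.numeric(sub("period_s\\s*[=:]\\s*", "", m[[1L]]))
  }
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", strip.white = TRUE),
    error = function(e) stop("malformed QA CSV: ", conditionMessage(e),
                             call. = FALSE)
  )
  needed <- c("time_s", "flow_m3_per_s", "area_m2")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("QA CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in needed) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("QA CSV column %s has a non-numeric value at data row %d",
                   col, bad[1L]), call. = FALSE)
    }
  }
  if (any(df$area_m2 < 1e-6 | df$area_m2 > 1e-2)) {
    warning("area values outside [1e-6, 1e-2] m^2; check units (expected m^2)",
            call. = FALSE)
  }
  if (!is.finite(period)) {
    dt <- stats::median(diff(df$time_s))
    period <- df$time_s[nrow(df)] + dt
  }
  qa_curves(df$time_s, df$flow_m3_per_s, df$area_m2, period = period)
}

#' @rdname read_qa_csv
#' @export
write_qa_csv <- function(curves, path) {
  stopifnot(inherits(curves, "qa_curves"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# period_s=%.17g", curves$period), con)
  df <- data.frame(time_s = curves$time,
                   flow_m3_per_s = curves$flow,
                   area_m2 = curves$area)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
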