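# Stationary-interval selection and normalized distributions.
#
# Time windows are half-open [t0, t1) so that adjacent windows partition a
# trajectory without double counting. Stationarity is declared by the user
# (e.g. discarding the first microsecond of a run); no changepoint
# detection is attempted.

#' Restrict a time series to a time window
#'
#' Keeps frames with `t0 <= time < t1`, preserving order.
#'
#' @param series an `angle_series`, or a data.frame with a `time_us`
#'   column.
#' @param t0,t1 window bounds in microseconds, `t0 < t1`.
#' @return object of the same type restricted to the window.
#' @export
select_interval <- function(series, t0, t1) {
  if (!(t0 < t1)) stop("need t0 < t1")
  if (inherits(series, "angle_series")) {
    keep <- series$times >= t0 & series$times < t1
    if (!any(keep)) stop(sprintf("no frames in interval [%g, %g) us", t0, t1))
    out <- angle_series(series$times[keep], series$values[keep], series$label)
    return(out)
  }
  if (is.data.frame(series) && "time_us" %in% names(series)) {
    keep <- series$time_us >= t0 & series$time_us < t1
    if (!any(keep)) stop(sprintf("no frames in interval [%g, %g) us", t0, t1))
    return(series[keep, , drop = FALSE])
  }
  stop("series must be an angle_series or a data.frame with a time_us column")
}

#' Density-normalized histogram of a series
#'
#' @param series numeric values, an `angle_series`, or a data.frame whose
#'   last column holds the values.
#' @param bin_width bin width in the units of the series (ignored when
#'   `edges` is given). Defaults: no default — state it explicitly or pass
#'   `edges`.
#' @param edges explicit, strictly increasing bin edges covering the data.
#' @param interval optional c(t0, t1) annotation recording the time window
#'   the values came from.
#' @return object of class `distribution_result` with fields `bin_edges`,
#'   `density` (integrating to 1), `interval`, `n`, and the raw `values`.
#' @details With `bin_width` given, edges are anchored at integer multiples
#'   of the width so binning is deterministic and comparable across series.
#' @export
histogram_density <- function(series, bin_width = NULL, edges = NULL,
                              interval = NULL) {
  values <- if (inherits(series, "angle_series")) series$values
            else if (is.data.frame(series)) series[[ncol(series)]]
            else series
  if (length(values) < 1) stop("need at least one value")
  if (any(!is.finite(values)))
    stop("non-finite values at positions ",
         paste(utils::head(which(!is.finite(values)), 5), collapse = ","))
  if (is.null(edges)) {
    if (is.null(bin_width) || bin_width <= 0)
      stop("give a positive bin_width or explicit edges")
    lo <- floor(min(values) / bin_width) * bin_width
    hi <- ceiling(max(values) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    edges <- seq(lo, hi, by = bin_width)
    if (max(values) >= edges[length(edges)])
      edges <- c(edges, edges[length(edges)] + bin_width)
  }
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  h <- graphics::hist(values, breaks = edges, plot = FALSE, right = FALSE,
                      include.lowest = TRUE)
  structure(list(bin_edges = h$breaks, density = h$density,
                 interval = interval, n = length(values), values = values),
            class = "distribution_result")
}

#' @export
print.distribution_result <- function(x, ...) {
  cat(sprintf("<distribution_result> %d values in %d bins, range [%g, %g]\n",
              x$n, length(x$density), min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' Plain linear summaries of a distribution
#'
#' Mean and standard deviation of the underlying values plus the modal bin
#' of the density histogram. Angles are summarized linearly on [0, 180];
#' circular statistics are deliberately not used because deviation angles
#' from a fixed axis live on a bounded interval, not a circle.
#'
#' @param dist a `distribution_result`.
#' @return list with `mean`, `width` (sd), and `mode_bin` (length-2 edges
#'   of the highest-density bin).
#' @export
summarize_distribution <- function(dist) {
  stopifnot(inherits(dist, "distribution_result"))
  i <- which.max(dist$density)
  list(mean = mean(dist$values),
       width = if (dist$n > 1) stats::sd(dist$values) else 0,
       mode_bin = c(dist$bin_edges[i], dist$bin_edges[i + 1]))
}
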