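#' Uniformly sampled electrophysiology trace
#'
#' The basic container used throughout the package: a uniformly sampled time
#' series of either membrane voltage (mV) or current (pA), with its sample
#' interval in milliseconds.
#'
#' @param values Numeric vector of samples; must be finite.
#' @param dt Sample interval in ms (> 0).
#' @param kind Either `"voltage"` (mV) or `"current"` (pA).
#' @param t0 Time of the first sample in ms.
#' @return An object of class `ephys_trace`.
#' @export
ephys_trace <- function(values, dt, kind = c("voltage", "current"), t0 = 0) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) < 1L) stop("trace must contain at least one sample")
  if (!all(is.finite(values))) stop("trace values must be finite")
  if (!is.finite(dt) || dt <= 0) stop("dt must be a positive finite number")
  structure(
    list(values = values, dt = dt, kind = kind,
         units = if (kind == "voltage") "mV" else "pA", t0 = t0),
    class = "ephys_trace")
}

#' @export
print.ephys_trace <- function(x, ...) {
  cat(sprintf("<ephys_trace> %s [%s], %d samples, dt = %g ms (%.3f s)\n",
              x$kind, x$units, length(x$values), x$dt,
              length(x$values) * x$dt / 1000))
  cat(sprintf("  range [%.4g, %.4g] %s, t0 = %g ms\n",
              min(x$values), max(x$values), x$units, x$t0))
  invisible(x)
}

#' Time axis of a trace
#'
#' @param x An `ephys_trace`.
#' @return Numeric vector of sample times in ms.
#' @export
trace_time <- function(x) {
  stopifnot(inherits(x, "ephys_trace"))
  x$t0 + (seq_along(x$values) - 1) * x$dt
}

#' Extract a time window from a trace
#'
#' @param x An `ephys_trace`.
#' @param from,to Window bounds in ms (inclusive), on the trace's own axis.
#' @return An `ephys_trace` covering the requested window.
#' @export
trace_window <- function(x, from = -Inf, to = Inf) {
  stopifnot(inherits(x, "ephys_trace"))
  t <- trace_time(x)
  keep <- t >= from - 1e-9 & t <= to + 1e-9
  if (!any(keep)) stop("window [", from, ", ", to, "] ms is outside the trace")
  ephys_trace(x$values[keep], x$dt, x$kind, t0 = t[which(keep)[1]])
}

#' @export
plot.ephys_trace <- function(x, ...) {
  graphics::plot(trace_time(x) / 1000, x$values, type = "l",
                 xlab = "time (s)",
                 ylab = sprintf("%s (%s)", x$kind, x$units), ...)
  invisible(x)
}

#' @export
length.ephys_trace <- function(x) length(x$values)

# internal: check two traces share a time base
check_aligned <- function(a, b) {
  if (!inherits(a, "ephys_trace") || !inherits(b, "ephys_trace"))
    stop("both arguments must be ephys_trace objects")
  if (abs(a$dt - b$dt) > 1e-12 * a$dt)
    stop("traces have different sample intervals")
  if (length(a$values) != length(b$values))
    stop("traces have different lengths")
  invisible(TRUE)
}

#' Read a trace from CSV
#'
#' CSV dialect: header `time_ms,<quantity>_<unit>` where the second column is
#' `voltage_mV` or `current_pA`; the time base must be uniform.
#'
#' @param path File path.
#' @return An `ephys_trace`.
#' @export
read_trace <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (ncol(d) != 2L || names(d)[1] != "time_ms")
    stop("expected two columns with header 'time_ms,<quantity>_<unit>'")
  qcol <- names(d)[2]
  kind <- switch(qcol,
                 voltage_mV = "voltage",
                 current_pA = "current",
                 stop("unrecognized quantity/unit column: ", qcol))
  tt <- d[[1]]
  if (length(tt) < 2L) stop("trace file must contain at least two samples")
  dts <- diff(tt)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6 * dt))
    stop("non-uniform time base in ", path)
  vals <- d[[2]]
  if (anyNA(vals)) stop("NA values in ", path)
  ephys_trace(vals, dt, kind, t0 = tt[1])
}

#' Write a trace to CSV
#'
#' @param x An `ephys_trace`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "ephys_trace"))
  qcol <- if (x$kind == "voltage") "voltage_mV" else "current_pA"
  d <- data.frame(time_ms = trace_time(x), q = x$values)
  names(d)[2] <- qcol
  utils::write.csv(format(d, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
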