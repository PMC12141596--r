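#' Welch power spectral density of a voltage trace
#'
#' Linearly detrends the trace, splits it into `n_segments` segments with
#' 50% overlap, applies a Hann taper to each, and averages the one-sided
#' periodograms.  The peak is searched within `band_Hz`.  Set
#' `n_segments = 1` for a plain (single-window) periodogram.
#'
#' @param V Voltage trace (mV), at least 10 s long.
#' @param band_Hz Analysis band (Hz), default `c(0.5, 40)`.
#' @param n_segments Number of Welch segments (before overlap).
#' @param min_duration_s Minimum trace duration (s).
#' @return A `psd_result`: `freq_Hz`, `psd` (mV^2/Hz), `peak_freq_Hz`,
#'   `peak_psd`, `median_psd` (in-band), plus the same peak statistics for
#'   each half of the trace (used by [detect_oscillation()]).
#' @export
power_spectrum <- function(V, band_Hz = c(0.5, 40), n_segments = 4,
                           min_duration_s = 10) {
  stopifnot(inherits(V, "ephys_trace"), V$kind == "voltage")
  n <- length(V$values)
  fs <- 1000 / V$dt
  if (n * V$dt / 1000 < min_duration_s)
    stop("trace shorter than ", min_duration_s, " s")

  welch <- function(y) {
    y <- stats::residuals(stats::lm(y ~ seq_along(y)))   # linear detrend
    m <- length(y)
    seg <- floor(m / n_segments)
    starts <- seq(1L, m - seg + 1L, by = max(1L, floor(seg / 2)))
    w <- 0.5 * (1 - cos(2 * pi * (seq_len(seg) - 1) / (seg - 1)))  # Hann
    scale <- fs * sum(w^2)
    acc <- NULL
    for (s in starts) {
      yk <- y[s:(s + seg - 1L)] * w
      p <- Mod(stats::fft(yk))^2 / scale
      acc <- if (is.null(acc)) p else acc + p
    }
    p <- acc / length(starts)
    nb <- floor(seg / 2)
    psd <- 2 * p[2:(nb + 1)]             # one-sided
    freq <- (1:nb) * fs / seg
    list(freq = freq, psd = psd)
  }

  peak_stats <- function(sp) {
    in_band <- sp$freq >= band_Hz[1] & sp$freq <= band_Hz[2]
    if (!any(in_band)) stop("analysis band outside the spectral grid")
    i <- which(in_band)[which.max(sp$psd[in_band])]
    list(peak_freq_Hz = sp$freq[i], peak_psd = sp$psd[i],
         median_psd = stats::median(sp$psd[in_band]))
  }

  full <- welch(V$values)
  st <- peak_stats(full)
  half <- floor(n / 2)
  h1 <- peak_stats(welch(V$values[1:half]))
  h2 <- peak_stats(welch(V$values[(half + 1):n]))

  structure(list(freq_Hz = full$freq, psd = full$psd,
                 band_Hz = band_Hz,
                 peak_freq_Hz = st$peak_freq_Hz, peak_psd = st$peak_psd,
                 median_psd = st$median_psd,
                 halves = list(h1, h2)),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf(
    "<psd_result> peak %.3g mV^2/Hz at %.2f Hz (in-band median %.3g)\n",
    x$peak_psd, x$peak_freq_Hz, x$median_psd))
  invisible(x)
}

#' Detect a sustained membrane-potential oscillation
#'
#' Flags an oscillation when the spectral peak is at least
#' `prominence_ratio` times the in-band median PSD *and* the peak persists
#' in both halves of the trace: each half shows the same prominence at a
#' nearby frequency, and the second half retains at least `sustain_frac` of
#' the first half's peak power (a damped ring decays between halves and is
#' rejected).  Adding a DC offset to the underlying trace does not change
#' the decision (the PSD is computed on the detrended signal).
#'
#' @param psd A `psd_result`.
#' @param prominence_ratio Peak-to-median prominence threshold.
#' @param freq_tol_rel Allowed relative drift of the peak between halves.
#' @param sustain_frac Minimum second-half / first-half peak-power ratio.
#' @return Logical flag.
#' @export
detect_oscillation <- function(psd, prominence_ratio = 20,
                               freq_tol_rel = 0.3, sustain_frac = 0.25) {
  stopifnot(inherits(psd, "psd_result"))
  if (psd$peak_psd <= 1e-12) return(FALSE)   # numerically flat trace
  prominent <- psd$peak_psd >= prominence_ratio * psd$median_psd
  if (!prominent) return(FALSE)
  persists <- vapply(psd$halves, function(h) {
    h$peak_psd >= prominence_ratio * h$median_psd &&
      abs(h$peak_freq_Hz - psd$peak_freq_Hz) <=
        freq_tol_rel * psd$peak_freq_Hz + 1e-9
  }, logical(1))
  sustained <- psd$halves[[2]]$peak_psd >=
    sustain_frac * psd$halves[[1]]$peak_psd
  all(persists) && sustained
}
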