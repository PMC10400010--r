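#' Common average reference (CAR) spatial filter
#'
#' Subtracts the across-channel mean from every channel at each time
#' point, removing channel-common superficial interference. The output's
#' across-channel mean is exactly zero at every sample; any series added
#' identically to all channels is removed exactly, and the filter is
#' idempotent. Applied to both hemoglobin species.
#'
#' @param hemo a [hemo_series()] with at least 2 channels.
#' @return A [hemo_series()] with stage flag `"car"`.
#' @export
car_filter <- function(hemo) {
  stopifnot(inherits(hemo, "hemo_series"))
  if (ncol(hemo$hbo2) < 2L)
    stopf("CAR is undefined for a single channel")
  center <- function(x) x - rowMeans(x)
  hemo_series(center(hemo$hbo2), center(hemo$hb), fs = hemo$fs,
              channel_ids = hemo$channel_ids,
              stages = c(hemo$stages, "car"))
}

# zero-phase Butterworth band-pass of a samples x channels matrix,
# forward-backward with odd-reflection edge padding
butter_bandpass <- function(x, fs, low, high, order = 3L) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  n <- nrow(x)
  pad <- min(n - 1L, ceiling(1.5 / low * fs))
  apply(x, 2L, function(col) {
    pre <- 2 * col[1L] - col[(pad + 1L):2L]
    post <- 2 * col[n] - col[(n - 1L):(n - pad)]
    y <- signal::filtfilt(bf, c(pre, col, post))
    y[(pad + 1L):(pad + n)]
  })
}

#' Band-pass filter hemodynamic series
#'
#' Zero-phase 3rd-order Butterworth band-pass (applied forward-backward,
#' so the effective response is 6th order with no group delay), with
#' odd-reflection edge padding to suppress filter transients. The default
#' 0.01-0.1 Hz band isolates spontaneous hemodynamic fluctuations,
#' removing slow drift below and physiological oscillations (Mayer waves,
#' respiration, cardiac pulsation) above the band.
#'
#' @param hemo a [hemo_series()].
#' @param low,high band edges in Hz; require `0 < low < high < fs/2`.
#' @param order Butterworth order of each pass.
#' @return A [hemo_series()] with stage flag `"bandpass"`.
#' @export
bandpass_filter <- function(hemo, low = 0.01, high = 0.1, order = 3L) {
  stopifnot(inherits(hemo, "hemo_series"))
  if (!(low > 0 && low < high && high < hemo$fs / 2))
    stopf("band edges must satisfy 0 < low < high < fs/2 (fs = %g Hz)", hemo$fs)
  hemo_series(butter_bandpass(hemo$hbo2, hemo$fs, low, high, order),
              butter_bandpass(hemo$hb, hemo$fs, low, high, order),
              fs = hemo$fs, channel_ids = hemo$channel_ids,
              stages = c(hemo$stages, "bandpass"))
}

#' Trim recording edges and select the analysis window
#'
#' Removes `trim` seconds from each end of the recording, then selects a
#' contiguous analysis window of `window` seconds. `strategy =
#' "fixed_start"` takes the first post-trim window; `"min_variance"`
#' (default) scans candidate start points at 1 s stride and picks the
#' window minimizing the summed across-channel variance — an automated
#' stand-in for the "relatively stable segment" a rater would pick by eye.
#' An optional logical exclusion mask (length = sample count, `TRUE` =
#' excluded, e.g. hand-flagged motion artifacts) disqualifies windows
#' overlapping flagged samples.
#'
#' @param hemo a [hemo_series()].
#' @param trim seconds removed from each end.
#' @param window analysis window length in seconds.
#' @param strategy `"min_variance"` or `"fixed_start"`.
#' @param exclude optional logical vector, length `nrow(hemo$hbo2)`.
#' @return A [hemo_series()] of exactly `window * fs` samples with stage
#'   flag `"window"` and attribute `window_start` (first sample index in
#'   the input).
#' @export
trim_and_window <- function(hemo, trim = 3, window = 180,
                            strategy = c("min_variance", "fixed_start"),
                            exclude = NULL) {
  stopifnot(inherits(hemo, "hemo_series"))
  strategy <- match.arg(strategy)
  fs <- hemo$fs
  n <- nrow(hemo$hbo2)
  wlen <- as.integer(round(window * fs))
  t0 <- as.integer(round(trim * fs)) + 1L
  t1 <- n - as.integer(round(trim * fs))
  if (t1 - t0 + 1L < wlen)
    stopf("recording too short: need at least %g s (%d samples) after trimming, have %g s",
          2 * trim + window, wlen, n / fs)
  starts <- seq.int(t0, t1 - wlen + 1L, by = as.integer(round(fs)))
  if (!is.null(exclude)) {
    stopifnot(length(exclude) == n)
    bad <- which(exclude)
    ok <- vapply(starts, function(s) !any(bad >= s & bad <= s + wlen - 1L),
                 logical(1))
    if (!any(ok)) stopf("no candidate window avoids the exclusion mask")
    starts <- starts[ok]
  }
  if (strategy == "fixed_start") {
    s <- starts[1L]
  } else {
    # summed across-channel variance per candidate window via cumulative sums
    cost <- vapply(starts, function(s) {
      seg <- hemo$hbo2[s:(s + wlen - 1L), , drop = FALSE]
      sum(apply(seg, 2L, stats::var))
    }, numeric(1))
    s <- starts[which.min(cost)]
  }
  idx <- s:(s + wlen - 1L)
  out <- hemo_series(hemo$hbo2[idx, , drop = FALSE],
                     hemo$hb[idx, , drop = FALSE],
                     fs = fs, channel_ids = hemo$channel_ids,
                     stages = c(hemo$stages, "window"))
  attr(out, "window_start") <- s
  out
}

#' Full preprocessing chain for one subject
#'
#' Convenience wrapper running the standard stage order on an
#' optical-density recording: Beer-Lambert inversion, common average
#' reference, band-pass, trimming and window selection. Each stage can be
#' toggled; the order matches offline fNIRS practice (interference removal
#' on concentration series, then temporal filtering, then segment
#' selection).
#'
#' @param od an [od_series()].
#' @param optics an [optics_config()].
#' @param band band edges in Hz.
#' @param trim,window,strategy,exclude see [trim_and_window()].
#' @param car apply CAR? (default `TRUE`).
#' @return A windowed [hemo_series()].
#' @export
preprocess_subject <- function(od, optics = optics_config(),
                               band = c(0.01, 0.1), trim = 3, window = 180,
                               strategy = "min_variance", exclude = NULL,
                               car = TRUE) {
  hemo <- beer_lambert_invert(od, optics)
  if (car) hemo <- car_filter(hemo)
  hemo <- bandpass_filter(hemo, band[1L], band[2L])
  trim_and_window(hemo, trim = trim, window = window, strategy = strategy,
                  exclude = exclude)
}
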