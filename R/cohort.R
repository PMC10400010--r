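#' Nuisance model configuration for the synthetic generator
#'
#' Amplitudes of the structured noise added to the latent hemodynamic
#' signal, in units of the latent per-channel standard deviation (which is
#' 1): a channel-common slow "superficial interference" series, a
#' per-channel linear drift, band-limited physiological oscillations
#' (cardiac, respiratory and Mayer-wave sinusoids with channel-specific
#' phases), and white sensor noise. Defaults put the interference on the
#' same scale as the signal and the oscillations at half that scale, so
#' preprocessing visibly matters but recovery succeeds.
#'
#' @param global_interference_sd sd of the channel-common interference.
#' @param drift_slope_sd sd of per-channel linear drift slopes, units/s.
#' @param cardiac_freq,resp_freq,mayer_freq oscillation frequencies (Hz).
#' @param oscillation_amps amplitude(s) of the three oscillations; scalar
#'   or length 3 (cardiac, respiratory, Mayer).
#' @param sensor_noise_sd sd of white sensor noise.
#' @return An object of class `nuisance_config`.
#' @export
nuisance_config <- function(global_interference_sd = 1.0,
                            drift_slope_sd = 0.005,
                            cardiac_freq = 1.1, resp_freq = 0.25,
                            mayer_freq = 0.1,
                            oscillation_amps = 0.5,
                            sensor_noise_sd = 0.3) {
  amps <- rep_len(oscillation_amps, 3L)
  vals <- c(global_interference_sd, drift_slope_sd, amps, sensor_noise_sd)
  if (any(vals < 0)) stopf("nuisance amplitudes must be >= 0")
  structure(list(global_interference_sd = global_interference_sd,
                 drift_slope_sd = drift_slope_sd,
                 cardiac_freq = cardiac_freq, resp_freq = resp_freq,
                 mayer_freq = mayer_freq, oscillation_amps = amps,
                 sensor_noise_sd = sensor_noise_sd),
            class = "nuisance_config")
}

#' Synthetic cohort specification
#'
#' Study-design parameters of the synthetic two-group resting fNIRS
#' cohort. Defaults mirror the emulated study: 21 subjects in group A
#' (lattice-like truth networks, the neglect-like group) and 12 in group B
#' (random-like truth networks), 22 channels sampled at 10 Hz for 6
#' minutes. The two groups share the ring degree and differ only in
#' rewiring probability, which places them at different points of the
#' lattice-to-random axis.
#'
#' @param n_group_a,n_group_b group sizes (each >= 2).
#' @param n_channels number of measurement channels.
#' @param fs sampling rate, Hz.
#' @param duration recording duration, seconds.
#' @param seed master integer seed.
#' @param topology_a,topology_b [topology_params()] per group.
#' @param coupling adjacency coupling of the covariance model, see
#'   [topology_to_covariance()].
#' @param base_correlation common correlation floor of the model.
#' @param signal_band latent signal band (Hz).
#' @param nuisance a [nuisance_config()].
#' @param optics an [optics_config()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group_a = 21L, n_group_b = 12L, n_channels = 22L,
                        fs = 10, duration = 360, seed = 1L,
                        topology_a = topology_params(k = 4L, p = 0.1),
                        topology_b = topology_params(k = 4L, p = 0.3),
                        coupling = 0.9, base_correlation = 0,
                        signal_band = c(0.01, 0.1),
                        nuisance = nuisance_config(),
                        optics = optics_config()) {
  if (n_group_a < 2L || n_group_b < 2L) stopf("each group needs >= 2 subjects")
  if (fs <= 2 * signal_band[2L])
    stopf("sampling rate must exceed twice the signal band's upper edge")
  n_samples <- duration * fs
  if (abs(n_samples - round(n_samples)) > 1e-9)
    stopf("duration x fs must be an integer sample count")
  structure(list(n_group_a = as.integer(n_group_a),
                 n_group_b = as.integer(n_group_b),
                 n_channels = as.integer(n_channels),
                 fs = fs, duration = duration, seed = as.integer(seed),
                 topology_a = topology_a, topology_b = topology_b,
                 coupling = coupling, base_correlation = base_correlation,
                 signal_band = signal_band, nuisance = nuisance,
                 optics = optics),
            class = "cohort_spec")
}

# band-limited unit-variance Gaussian noise, n samples x p columns.
# Shaped in the frequency domain with the squared Butterworth magnitude
# response (the zero-phase forward-backward response); for stationary
# white input this is the circular equivalent of filtfilt and runs as a
# single FFT per matrix.
band_limited_noise <- function(n, p, fs, low, high) {
  bf <- signal::butter(3L, c(low, high) / (fs / 2), type = "pass")
  w <- 2 * pi * (seq_len(n) - 1L) / n
  ejw <- exp(-1i * outer(w, seq(0, length(bf$b) - 1L)))
  gain <- Mod((ejw %*% bf$b) / (ejw %*% bf$a))^2
  x <- matrix(stats::rnorm(n * p), n, p)
  y <- Re(stats::mvfft(stats::mvfft(x) * as.vector(gain), inverse = TRUE)) / n
  sweep(y, 2L, apply(y, 2L, stats::sd), "/")
}

# empirically whitened band-limited noise: sample covariance exactly I,
# so chol mixing realises the model covariance exactly over the full
# series (narrowband draws otherwise carry cross-correlations ~1/sqrt(n_eff)
# that a near-critical kernel amplifies)
band_limited_whitened <- function(n, p, fs, low, high) {
  y <- band_limited_noise(n, p, fs, low, high)
  y <- sweep(y, 2L, colMeans(y))
  y %*% solve(chol(stats::cov(y)))
}

#' Simulate one subject's recording
#'
#' Forward model (the inverse of the preprocessing chain): draw
#' band-limited correlated latent oxyhemoglobin series with the covariance
#' implied by the subject's truth network, derive deoxyhemoglobin as an
#' anticorrelated mixture, add the nuisance terms, and convert to
#' dual-wavelength optical density with [forward_optics()]. Deterministic
#' for a fixed seed.
#'
#' @param net the subject's [truth network][generate_topology].
#' @param spec a [cohort_spec()].
#' @param seed integer seed for this subject.
#' @param subject_id subject identifier.
#' @param group_label `"A"` or `"B"`.
#' @return An object of class `subject_record` with elements `subject_id`,
#'   `group_label`, `optical` (an [od_series()]), `truth` and
#'   `model_sigma`.
#' @export
simulate_subject <- function(net, spec, seed, subject_id = "S01",
                             group_label = "A") {
  stopifnot(inherits(spec, "cohort_spec"))
  sigma <- topology_to_covariance(net, spec$coupling, spec$base_correlation)
  n <- as.integer(round(spec$duration * spec$fs))
  p <- spec$n_channels
  nui <- spec$nuisance
  tt <- (seq_len(n) - 1L) / spec$fs
  hemo <- withr::with_seed(as.integer(seed), {
    latent <- band_limited_whitened(n, p, spec$fs,
                                    spec$signal_band[1L], spec$signal_band[2L])
    hbo2 <- latent %*% chol(sigma)
    hb_idio <- band_limited_noise(n, p, spec$fs,
                                  spec$signal_band[1L], spec$signal_band[2L])
    hb <- -0.5 * hbo2 + 0.5 * hb_idio
    if (nui$global_interference_sd > 0) {
      g <- band_limited_noise(n, 1L, spec$fs, 0.01, 0.2) *
        nui$global_interference_sd
      hbo2 <- hbo2 + g[, 1L]
      hb <- hb + 0.5 * g[, 1L]
    }
    if (nui$drift_slope_sd > 0) {
      slopes <- stats::rnorm(p, 0, nui$drift_slope_sd)
      drift <- outer(tt, slopes)
      hbo2 <- hbo2 + drift
      hb <- hb + 0.5 * drift
    }
    freqs <- c(nui$cardiac_freq, nui$resp_freq, nui$mayer_freq)
    for (k in seq_along(freqs)) {
      if (nui$oscillation_amps[k] <= 0) next
      phases <- stats::runif(p, 0, 2 * pi)
      osc <- nui$oscillation_amps[k] *
        sin(outer(2 * pi * freqs[k] * tt, rep(1, p)) +
              matrix(phases, n, p, byrow = TRUE))
      hbo2 <- hbo2 + osc
      hb <- hb + 0.5 * osc
    }
    if (nui$sensor_noise_sd > 0) {
      hbo2 <- hbo2 + matrix(stats::rnorm(n * p, 0, nui$sensor_noise_sd), n, p)
      hb <- hb + matrix(stats::rnorm(n * p, 0, nui$sensor_noise_sd), n, p)
    }
    hemo_series(hbo2, hb, fs = spec$fs)
  })
  structure(list(subject_id = subject_id, group_label = group_label,
                 optical = forward_optics(hemo, spec$optics),
                 truth = net, model_sigma = sigma, seed = seed),
            class = "subject_record")
}

#' Generate a synthetic two-group cohort
#'
#' Draws every subject's truth network and recording. Per-subject seeds
#' are derived deterministically from the master seed (`seed + i` for the
#' recording noise, `seed + 10000 + i` for the topology draw of subject
#' `i`), so the same specification always yields the identical cohort.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `neglect_cohort`: list with `subjects` (list
#'   of [subject_record][simulate_subject]s, group A first) and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_total <- spec$n_group_a + spec$n_group_b
  subjects <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    in_a <- i <= spec$n_group_a
    net <- generate_topology(spec$n_channels,
                             if (in_a) spec$topology_a else spec$topology_b,
                             seed = spec$seed + 10000L + i)
    subjects[[i]] <- simulate_subject(net, spec, seed = spec$seed + i,
                                      subject_id = sprintf("S%02d", i),
                                      group_label = if (in_a) "A" else "B")
  }
  structure(list(subjects = subjects, spec = spec), class = "neglect_cohort")
}

#' @export
print.neglect_cohort <- function(x, ...) {
  lab <- vapply(x$subjects, `[[`, "", "group_label")
  cat(sprintf("<neglect_cohort> %d subjects (%d A / %d B), %d channels @ %g Hz, %g s\n",
              length(x$subjects), sum(lab == "A"), sum(lab == "B"),
              x$spec$n_channels, x$spec$fs, x$spec$duration))
  invisible(x)
}

#' Cohort group labels
#' @param cohort a [generate_cohort()] result.
#' @return Character vector of group labels, one per subject.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$subjects, `[[`, "", "group_label")
}

#' Source-detector channel layout of an alternating probe grid
#'
#' Enumerates the measurement channels of a rectangular optode grid in
#' which sources and detectors alternate in a checkerboard pattern (the
#' layout of a 3 x 5 patch with 8 sources and 7 detectors over the right
#' cerebral cortex). Every horizontally or vertically adjacent optode pair
#' is a source-detector pair at nearest-neighbour separation and forms one
#' channel; a 3 x 5 grid yields 3*4 + 2*5 = 22 channels.
#'
#' @param rows,cols grid dimensions.
#' @return Data frame with one row per channel: `channel`, source and
#'   detector grid positions.
#' @export
probe_grid_channels <- function(rows = 3L, cols = 5L) {
  pos <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  pos$type <- ifelse((pos$row + pos$col) %% 2L == 0L, "S", "D")
  pairs <- list()
  for (a in seq_len(nrow(pos))) {
    for (b in seq_len(nrow(pos))) {
      if (b <= a) next
      if (abs(pos$row[a] - pos$row[b]) + abs(pos$col[a] - pos$col[b]) != 1L) next
      src <- if (pos$type[a] == "S") a else b
      det <- if (pos$type[a] == "S") b else a
      pairs[[length(pairs) + 1L]] <-
        data.frame(source_row = pos$row[src], source_col = pos$col[src],
                   detector_row = pos$row[det], detector_col = pos$col[det])
    }
  }
  out <- do.call(rbind, pairs)
  out <- cbind(channel = sprintf("ch%02d", seq_len(nrow(out))), out)
  out
}
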