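# Optional voltage pathway: render two-unit extracellular traces from spike
# times, detect spikes by threshold crossing, and split units by amplitude.
# Substitutes for manual spike counting on sensilla housing a large (A) and
# a small (B) unit.

#' Render a synthetic extracellular voltage trace
#'
#' Places a biphasic spike template at each ground-truth spike time of the
#' transgene-bearing A unit and of an independent background Poisson B unit,
#' with additive Gaussian noise. By convention the A unit has the larger
#' amplitude.
#'
#' @param spike_times_a sorted spike times (s) of the A unit.
#' @param window recording window `c(start, end)` in seconds.
#' @param unitA_amp,unitB_amp peak amplitudes (arbitrary units, `> 0`;
#'   `unitA_amp > unitB_amp`).
#' @param unitB_rate firing rate (spikes/s) of the background B unit.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param sampling_rate sampling rate in Hz (`>= 5000`).
#' @param seed integer seed (B-unit times and noise).
#' @return A `voltage_trace`: list with `samples`, `time`,
#'   `sampling_rate_hz`, `true_a`, `true_b`, `unitA_amp`, `unitB_amp`.
#' @export
render_voltage <- function(spike_times_a, window = c(-1, 1.5),
                           unitA_amp = 1, unitB_amp = 0.45, unitB_rate = 10,
                           noise_sd = 0.05, sampling_rate = 10000, seed) {
  if (missing(seed)) stop_("seed is required")
  if (unitA_amp <= 0 || unitB_amp <= 0) stop_("amplitudes must be > 0")
  if (sampling_rate < 5000) stop_("sampling_rate must be >= 5000 Hz")
  assert_sorted(spike_times_a)
  n <- ceiling(diff(window) * sampling_rate)
  time <- window[1] + (seq_len(n) - 1) / sampling_rate

  # biphasic template: one positive then one negative lobe, ~1.2 ms total
  tpl_t <- seq(0, 0.0012, by = 1 / sampling_rate)
  tpl <- sin(2 * pi * tpl_t / 0.0012) * exp(-tpl_t / 0.0008)
  tpl <- tpl / max(tpl)

  peak_offset <- which.max(tpl) - 1L   # align template peak on the spike time

  add_unit <- function(samples, times, amp) {
    idx <- round((times - window[1]) * sampling_rate) + 1 - peak_offset
    for (i in idx) {
      j <- i:(i + length(tpl) - 1)
      ok <- j >= 1 & j <= n
      samples[j[ok]] <- samples[j[ok]] + amp * tpl[ok]
    }
    samples
  }

  with_seed(seed, {
    true_b <- if (unitB_rate > 0) {
      k <- rpois(1, unitB_rate * diff(window))
      sort(runif(k, window[1], window[2]))
    } else numeric(0)
    samples <- numeric(n)
    samples <- add_unit(samples, spike_times_a, unitA_amp)
    samples <- add_unit(samples, true_b, unitB_amp)
    if (noise_sd > 0) samples <- samples + rnorm(n, 0, noise_sd)
    structure(list(samples = samples, time = time,
                   sampling_rate_hz = sampling_rate,
                   true_a = spike_times_a, true_b = true_b,
                   unitA_amp = unitA_amp, unitB_amp = unitB_amp),
              class = "voltage_trace")
  })
}

#' Detect spikes in a voltage trace
#'
#' Threshold-crossing peak detection: local maxima above `threshold`, with a
#' dead time so each spike is detected once. A flat trace yields an empty
#' result, not an error.
#'
#' @param trace a `voltage_trace` (or list with `samples`, `time`,
#'   `sampling_rate_hz`).
#' @param threshold detection threshold; `NULL` (default) uses half the
#'   largest peak, falling back to 5 robust SDs of the trace.
#' @param dead_time_s minimum separation between detections in seconds.
#' @return Tibble: `time`, `amplitude` of each detection.
#' @export
detect_spikes <- function(trace, threshold = NULL, dead_time_s = 0.002) {
  v <- trace$samples
  if (length(v) < 3 || max(v) - min(v) < sqrt(.Machine$double.eps)) {
    return(tibble::tibble(time = numeric(0), amplitude = numeric(0)))
  }
  if (is.null(threshold)) {
    threshold <- max(5 * stats::mad(v), max(v) / 2)
  }
  is_peak <- v > threshold &
    v >= c(-Inf, v[-length(v)]) & v > c(v[-1], -Inf)
  idx <- which(is_peak)
  if (length(idx) == 0) {
    return(tibble::tibble(time = numeric(0), amplitude = numeric(0)))
  }
  dead <- max(1L, round(dead_time_s * trace$sampling_rate_hz))
  keep <- integer(0)
  last <- -Inf
  for (i in idx) {
    if (i - last >= dead) {
      keep <- c(keep, i)
      last <- i
    } else if (v[i] > v[keep[length(keep)]]) {
      keep[length(keep)] <- i   # keep the larger peak within the dead time
      last <- i
    }
  }
  tibble::tibble(time = trace$time[keep], amplitude = v[keep])
}

#' Split detections into two amplitude units
#'
#' 2-means clustering on detection amplitudes; the larger-amplitude cluster
#' is the A (transgene-bearing) unit. If the amplitudes show no evidence of
#' two units (coefficient of variation below `cv_tol`), all detections are
#' assigned to A when `expect_units = "auto"`; with `expect_units = "two"`
#' the degenerate case (e.g. equal A and B amplitudes) is an error.
#'
#' @param detections tibble from [detect_spikes()].
#' @param expect_units `"auto"` (tolerate a single apparent unit) or
#'   `"two"` (demand separable clusters).
#' @param cv_tol amplitude coefficient-of-variation below which the
#'   detections are treated as a single unit.
#' @return Tibble: `time`, `amplitude`, `unit` (`"A"` or `"B"`).
#' @export
sort_two_units <- function(detections, expect_units = c("auto", "two"),
                           cv_tol = 0.1) {
  expect_units <- match.arg(expect_units)
  n <- nrow(detections)
  if (n == 0) {
    return(tibble::tibble(time = numeric(0), amplitude = numeric(0),
                          unit = character(0)))
  }
  amps <- detections$amplitude
  cv <- sd(amps) / mean(amps)
  if (n < 4 || is.na(cv) || cv < cv_tol) {
    if (expect_units == "two") {
      stop_("amplitude distribution is unimodal (cv = ",
            signif(cv %||% 0, 3), "); units are unsortable")
    }
    return(tibble::tibble(time = detections$time, amplitude = amps,
                          unit = "A"))
  }
  km <- kmeans(amps, centers = 2, nstart = 5)
  a_cluster <- which.max(km$centers)
  sep <- abs(diff(km$centers)) /
    max(sqrt(max(km$tot.withinss / n, .Machine$double.eps)), 1e-12)
  if (expect_units == "two" && sep < 2) {
    stop_("amplitude clusters are not separable; units are unsortable")
  }
  tibble::tibble(time = detections$time, amplitude = amps,
                 unit = ifelse(km$cluster == a_cluster, "A", "B"))
}
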