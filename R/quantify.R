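# Spike-train quantification: windowed counts -> solvent-corrected
# delta spikes/s -> replicate-aggregated response records.

#' Counting windows
#'
#' The response statistic counts spikes in a 1 s pre-stimulus window and a
#' 200 ms response window positioned 0.2-0.4 s after the stimulus-onset
#' command (the odor needs ~200 ms to reach the antenna). Both windows are
#' half-open `[a, b)`.
#'
#' @param pre pre-stimulus window `c(start, end)` in seconds.
#' @param response response window `c(start, end)` in seconds.
#' @return List with elements `pre` and `response`.
#' @export
response_windows <- function(pre = c(-1, 0), response = c(0.2, 0.4)) {
  if (pre[2] <= pre[1] || response[2] <= response[1]) {
    stop_("windows must have positive width")
  }
  if (pre[2] > response[1]) stop_("pre and response windows must not overlap")
  list(pre = pre, response = response)
}

#' Count spikes in a half-open window
#'
#' @param spike_times sorted numeric vector of spike times in seconds.
#' @param window `c(start, end)`; a spike at exactly `end` is excluded.
#' @return Integer count of times `t` with `start <= t < end`.
#' @examples
#' count_spikes(c(-0.5, 0.25, 0.3), c(0.2, 0.4))  # 2
#' @export
count_spikes <- function(spike_times, window) {
  assert_sorted(spike_times)
  sum(spike_times >= window[1] & spike_times < window[2])
}

#' Compute the response statistic for one trial
#'
#' Both counts are converted to frequencies before subtraction:
#' `delta = response_count / response_width - pre_count / pre_width`
#' (with the default windows, `count / 0.2 s - count / 1 s`). Spikes outside
#' both windows do not contribute.
#'
#' @param spike_times sorted spike times in seconds relative to stimulus
#'   onset.
#' @param windows a [response_windows()] object.
#' @param recording_window `c(start, end)` actually recorded; must cover both
#'   counting windows.
#' @return delta spikes/s (numeric scalar, not yet solvent-corrected).
#' @examples
#' compute_delta(c(-0.9, -0.7, -0.5, -0.3, -0.1, 0.25))  # 5 - 5 = 0
#' @export
compute_delta <- function(spike_times, windows = response_windows(),
                          recording_window = c(-1, 1.5)) {
  if (recording_window[1] > windows$pre[1] ||
      recording_window[2] < windows$response[2]) {
    stop_("recording window [", recording_window[1], ", ", recording_window[2],
          "] does not cover the counting windows")
  }
  pre_f <- count_spikes(spike_times, windows$pre) / diff(windows$pre)
  resp_f <- count_spikes(spike_times, windows$response) / diff(windows$response)
  resp_f - pre_f
}

#' Solvent normalization
#'
#' Responses are corrected by subtracting the receptor's mean solvent
#' (pentane) response, keeping the statistic in delta spikes/s.
#'
#' @param delta raw delta spikes/s value(s).
#' @param solvent_delta the same receptor's mean solvent delta.
#' @return `delta - solvent_delta`.
#' @export
normalize_to_solvent <- function(delta, solvent_delta) {
  if (length(solvent_delta) != 1 || is.na(solvent_delta)) {
    stop_("solvent_delta must be a single non-missing value")
  }
  delta - solvent_delta
}

#' Aggregate replicate deltas
#'
#' @param deltas per-replicate delta spikes/s values (non-empty).
#' @return List with `mean` (arithmetic mean), `sem` (sample SD over
#'   `sqrt(n)`; 0 with a warning for a single replicate), and `n`.
#' @examples
#' aggregate_replicates(c(10, 20, 30))  # mean 20, sem 5.7735
#' @export
aggregate_replicates <- function(deltas) {
  if (length(deltas) == 0) stop_("no replicate values to aggregate")
  n <- length(deltas)
  if (n == 1) {
    warning("single replicate: SEM reported as 0", call. = FALSE)
    return(list(mean = deltas, sem = 0, n = 1L))
  }
  list(mean = mean(deltas), sem = sd(deltas) / sqrt(n), n = as.integer(n))
}

#' Quantify trials into response records
#'
#' Computes a delta for every trial, averages each receptor's solvent trials
#' into a per-receptor solvent correction (a receptor without solvent trials
#' is an error), and aggregates replicates per (receptor, hydrocarbon, dose).
#'
#' @param trials a trials tibble ([generate_experiment()] / [read_trials()]).
#' @param windows a [response_windows()] object.
#' @param solvent solvent stimulus name (default `"pentane"`).
#' @return Long tibble: `receptor`, `hydrocarbon`, `dose_nmol`, `mean_delta`,
#'   `sem`, `n` (solvent rows are consumed by the correction, not reported).
#' @export
quantify_trials <- function(trials, windows = response_windows(),
                            solvent = "pentane") {
  stopifnot(all(c("receptor", "stimulus", "dose_nmol", "replicate",
                  "spike_times") %in% names(trials)))
  rec_win <- c(
    if ("window_start" %in% names(trials)) min(trials$window_start) else -1,
    if ("window_end" %in% names(trials)) max(trials$window_end) else 1.5
  )
  trials$delta <- vapply(trials$spike_times, compute_delta, numeric(1),
                         windows = windows, recording_window = rec_win)

  is_solv <- trials$stimulus == solvent
  solvent_mean <- tapply(trials$delta[is_solv], trials$receptor[is_solv], mean)
  no_solvent <- setdiff(unique(trials$receptor), names(solvent_mean))
  if (length(no_solvent) > 0) {
    stop_("no solvent ('", solvent, "') trials for receptor(s): ",
          paste(no_solvent, collapse = ", "))
  }

  odor <- trials[!is_solv, ]
  odor$delta <- odor$delta - as.numeric(solvent_mean[odor$receptor])
  odor |>
    dplyr::group_by(.data$receptor, hydrocarbon = .data$stimulus,
                    .data$dose_nmol) |>
    dplyr::summarise(
      mean_delta = mean(.data$delta),
      sem = if (dplyr::n() > 1) sd(.data$delta) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$receptor, .data$hydrocarbon, .data$dose_nmol)
}

#' Build a response matrix from trials
#'
#' Runs [quantify_trials()] and pivots the records at one dose into a
#' [response_matrix()] spanning the full panel; untested pairs stay missing.
#'
#' @inheritParams quantify_trials
#' @param panel a [stimulus_panel()] defining the HC columns.
#' @param dose_nmol dose to tabulate (default: the panel screen dose).
#' @return A [response_matrix()] with `mean`, `sem` and `n` grids.
#' @export
build_response_matrix <- function(trials, panel = default_panel(),
                                  windows = response_windows(),
                                  dose_nmol = default_dose(panel)) {
  records <- quantify_trials(trials, windows = windows,
                             solvent = solvent_name(panel))
  records <- records[records$dose_nmol == dose_nmol, ]
  if (nrow(records) == 0) {
    stop_("no trials at dose ", dose_nmol, " nmol")
  }
  unknown <- setdiff(unique(records$hydrocarbon), panel$name)
  if (length(unknown) > 0) {
    stop_("stimuli not in panel: ", paste(unknown, collapse = ", "))
  }
  rids <- unique(records$receptor)
  shape <- function(values) {
    g <- matrix(NA_real_, length(rids), nrow(panel),
                dimnames = list(rids, panel$name))
    g[cbind(match(records$receptor, rids),
            match(records$hydrocarbon, panel$name))] <- values
    g
  }
  response_matrix(mean = shape(records$mean_delta), sem = shape(records$sem),
                  n = shape(records$n))
}
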