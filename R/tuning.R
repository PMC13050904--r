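# Tuning classification and dose-response (Hill) fitting.

#' Classify a single response against the responder threshold
#'
#' The responder threshold (default 30 delta spikes/s, six times the native
#' ab2A spontaneous rate of ~5 spikes/s) is applied with a *strict*
#' inequality: a response of exactly 30 is `"below"`.
#'
#' @param mean_delta response value(s) in delta spikes/s.
#' @param threshold responder threshold.
#' @return `"above"` or `"below"` for each value.
#' @examples
#' classify_response(c(87.5, 3.8, 33, 30))
#' @export
classify_response <- function(mean_delta, threshold = 30) {
  ifelse(mean_delta > threshold, "above", "below")
}

#' Tuning profile of one receptor
#'
#' Counts above-threshold and inhibitory hydrocarbons over the non-missing
#' cells of a receptor's response row and assigns a tuning class:
#'
#' * `broad` — at least `broad_min` (default 7) HCs above threshold;
#' * `narrow` — exactly 1 HC above threshold;
#' * `intermediate` — 2 to `broad_min - 1` HCs above threshold;
#' * `inhibited` — none above threshold and at least `inhibit_min` pairs at
#'   or below `inhibition_threshold` (default -10 delta spikes/s);
#' * `nonresponder` — none above threshold, fewer inhibitory pairs.
#'
#' @param row named numeric vector of mean deltas (`NA` = untested); at
#'   least one non-missing cell.
#' @param receptor optional receptor id carried into the result.
#' @param threshold responder threshold (strict `>`).
#' @param inhibition_threshold inhibition bound (pairs with
#'   `delta <= inhibition_threshold` count as inhibitory).
#' @param broad_min minimum above-threshold count for `broad`.
#' @param inhibit_min minimum inhibitory-pair count for `inhibited`.
#' @return One-row tibble: `receptor`, `n_above`, `class`, `max_hc`,
#'   `max_delta`, `n_inhibitory_pairs`, `hcs_above_threshold` (list column).
#' @export
profile_receptor <- function(row, receptor = NA_character_, threshold = 30,
                             inhibition_threshold = -10, broad_min = 7,
                             inhibit_min = 5) {
  vals <- row[!is.na(row)]
  if (length(vals) == 0) stop_("all cells missing for receptor ", receptor)
  above <- names(vals)[vals > threshold]
  n_above <- length(above)
  n_inhib <- sum(vals <= inhibition_threshold)
  cls <- if (n_above >= broad_min) "broad"
  else if (n_above == 1) "narrow"
  else if (n_above >= 2) "intermediate"
  else if (n_inhib >= inhibit_min) "inhibited"
  else "nonresponder"
  best <- most_efficacious_ligand(row)
  tibble::tibble(
    receptor = receptor,
    n_above = n_above,
    class = cls,
    max_hc = best$hc_name,
    max_delta = best$mean_delta,
    n_inhibitory_pairs = n_inhib,
    hcs_above_threshold = list(sort(above))
  )
}

#' Tuning profiles for every receptor of a matrix
#'
#' @param x a [response_matrix()].
#' @inheritParams profile_receptor
#' @return Tibble with one [profile_receptor()] row per receptor.
#' @export
profile_receptors <- function(x, threshold = 30, inhibition_threshold = -10,
                              broad_min = 7, inhibit_min = 5) {
  stopifnot(inherits(x, "response_matrix"))
  dplyr::bind_rows(lapply(receptors(x), function(r) {
    profile_receptor(x$mean[r, ], receptor = r, threshold = threshold,
                     inhibition_threshold = inhibition_threshold,
                     broad_min = broad_min, inhibit_min = inhibit_min)
  }))
}

#' Number of responding receptors
#'
#' A receptor responds if at least one non-missing cell exceeds the
#' threshold (strictly).
#'
#' @inheritParams profile_receptors
#' @return Integer count.
#' @export
count_responding_receptors <- function(x, threshold = 30) {
  stopifnot(inherits(x, "response_matrix"))
  sum(apply(x$mean, 1, function(v) any(v > threshold, na.rm = TRUE)))
}

#' Most efficacious ligand of a receptor
#'
#' Argmax over the non-missing cells of a response row; ties are broken
#' alphabetically by hydrocarbon name.
#'
#' @param row named numeric vector of mean deltas (`NA` = untested).
#' @return List with `hc_name` and `mean_delta`.
#' @examples
#' most_efficacious_ligand(c(C28 = 87.5, C27 = 2))
#' @export
most_efficacious_ligand <- function(row) {
  vals <- row[!is.na(row)]
  if (length(vals) == 0) stop_("all cells missing")
  vals <- vals[order(names(vals), method = "radix")]  # alphabetical tie-break
  best <- which.max(vals)
  list(hc_name = names(vals)[best], mean_delta = unname(vals[best]))
}

#' Fit a Hill dose-response curve
#'
#' Least-squares fit of the saturating Hill model
#' `delta(d) = max_delta * d^h / (ec50^h + d^h)` via
#' [minpack.lm::nlsLM()] with bounded parameters (`h` in `[0.3, 6]`, `ec50`
#' in `[min(dose)/10, max(dose)*10]`). Non-convergence (including
#' degenerate all-zero responses) is reported through the `converged` flag,
#' never raised.
#'
#' @param doses dose series in nmol (`> 0`, at least 3 distinct values).
#' @param mean_deltas responses in delta spikes/s, same length.
#' @param receptor,hc_name optional identifiers carried into the result.
#' @return A `dose_response_fit` list: `receptor`, `hc_name`, `doses`,
#'   `mean_deltas`, `max_delta`, `ec50_nmol`, `hill_slope`, `converged`,
#'   `rmse`.
#' @export
fit_dose_response <- function(doses, mean_deltas, receptor = NA_character_,
                              hc_name = NA_character_) {
  if (length(doses) != length(mean_deltas)) {
    stop_("doses and mean_deltas must have the same length")
  }
  keep <- !is.na(doses) & !is.na(mean_deltas)
  doses <- doses[keep]; mean_deltas <- mean_deltas[keep]
  if (length(unique(doses)) < 3) stop_("need at least 3 distinct doses")
  if (any(doses <= 0)) stop_("doses must be > 0")

  out <- list(receptor = receptor, hc_name = hc_name, doses = doses,
              mean_deltas = mean_deltas, max_delta = NA_real_,
              ec50_nmol = NA_real_, hill_slope = NA_real_,
              converged = FALSE, rmse = NA_real_)
  class(out) <- "dose_response_fit"
  if (max(abs(mean_deltas)) < sqrt(.Machine$double.eps)) {
    return(out)  # flat zero data: parameters undetermined
  }

  lower <- c(max_delta = -Inf, ec50 = min(doses) / 10, h = 0.3)
  upper <- c(max_delta = Inf, ec50 = max(doses) * 10, h = 6)
  start <- list(max_delta = max(mean_deltas),
                ec50 = exp(mean(log(range(doses)))), h = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ max_delta * d^h / (ec50^h + d^h),
      data = data.frame(d = doses, y = mean_deltas),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit)) return(out)
  cf <- coef(fit)
  out$max_delta <- unname(cf["max_delta"])
  out$ec50_nmol <- unname(cf["ec50"])
  out$hill_slope <- unname(cf["h"])
  out$rmse <- sqrt(mean(resid(fit)^2))
  out$converged <- TRUE
  out
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<dose_response_fit> %s / %s: max %.1f, EC50 %.2f nmol, slope %.2f (rmse %.2f)\n",
      x$receptor, x$hc_name, x$max_delta, x$ec50_nmol, x$hill_slope, x$rmse))
  } else {
    cat("<dose_response_fit>", x$receptor, "/", x$hc_name,
        ": did not converge (parameters undetermined)\n")
  }
  invisible(x)
}

#' Check for low-dose silence
#'
#' Verifies the screening observation that no receptor shows a response above
#' `response_cutoff` (default 10 delta spikes/s) at doses at or below
#' `dose_cutoff` (default 2 nmol).
#'
#' @param records dose-resolved long tibble with `receptor`, `hydrocarbon`,
#'   `dose_nmol`, `mean_delta` ([quantify_trials()] output).
#' @param dose_cutoff dose bound in nmol (inclusive).
#' @param response_cutoff response bound in delta spikes/s (inclusive).
#' @return List with `ok` (logical) and `violations` (tibble of offending
#'   rows, empty when `ok`). If no doses at or below the cutoff exist the
#'   check is vacuously true, with a warning.
#' @export
check_low_dose_silence <- function(records, dose_cutoff = 2,
                                   response_cutoff = 10) {
  stopifnot(all(c("receptor", "hydrocarbon", "dose_nmol", "mean_delta")
                %in% names(records)))
  low <- records[!is.na(records$dose_nmol) & records$dose_nmol <= dose_cutoff &
                   records$dose_nmol > 0, ]
  if (nrow(low) == 0) {
    warning("no doses at or below ", dose_cutoff,
            " nmol present; check is vacuously true", call. = FALSE)
    return(list(ok = TRUE, violations = low))
  }
  bad <- low[!is.na(low$mean_delta) & low$mean_delta > response_cutoff, ]
  list(ok = nrow(bad) == 0, violations = tibble::as_tibble(bad))
}
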