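# Synthetic single-sensillum experiments with known ground truth.

#' Generate one spike train
#'
#' Simulates an extracellular recording as a piecewise-homogeneous Poisson
#' process: spontaneous firing at `baseline_rate` outside the stimulus epoch
#' and `evoked_rate` inside it, where the epoch runs from `delay_s` (odor
#' transit time from cartridge to antenna, default 200 ms) for
#' `stim_duration_s` (1 s puff). A refractory period is enforced by deleting
#' any spike closer than `refractory_s` to the previously kept spike.
#'
#' Deletion dead time lowers the realized rate of a Poisson process from
#' \eqn{\lambda}{lambda} to \eqn{\lambda/(1+\lambda\tau)}{lambda/(1+lambda*tau)}.
#' By default the generator compensates — the Poisson intensity is inflated
#' to \eqn{r/(1-r\tau)}{r/(1-r*tau)} so that the realized post-refractory
#' rate equals the nominal rate exactly — which keeps the downstream
#' delta spikes/s estimator unbiased at any firing rate. Set
#' `compensate_refractory = FALSE` for raw thinning.
#'
#' @param baseline_rate,evoked_rate firing rates in spikes/s (`>= 0`; under
#'   compensation each must stay below `1/refractory_s`).
#' @param delay_s stimulus-delivery delay in seconds.
#' @param stim_duration_s stimulus duration in seconds.
#' @param window recording window `c(start, end)` in seconds relative to the
#'   stimulus-onset command at t = 0; must cover at least `[-1, 1]`.
#' @param refractory_s minimum inter-spike interval in seconds.
#' @param seed integer seed; the same seed reproduces the train exactly.
#' @param compensate_refractory keep realized rates equal to nominal rates
#'   (see Details).
#' @return Sorted numeric vector of spike times in seconds.
#' @examples
#' generate_spike_train(5, 105, seed = 1)
#' @export
generate_spike_train <- function(baseline_rate, evoked_rate, delay_s = 0.2,
                                 stim_duration_s = 1,
                                 window = c(-1, 1.5),
                                 refractory_s = 0.002, seed,
                                 compensate_refractory = TRUE) {
  if (missing(seed)) stop_("seed is required")
  if (baseline_rate < 0 || evoked_rate < 0) stop_("rates must be >= 0")
  if (refractory_s < 0) stop_("refractory_s must be >= 0")
  if (window[1] > -1 || window[2] < 1) {
    stop_("recording window must cover at least [-1, 1] s")
  }
  intensity <- function(r) {
    if (!compensate_refractory || refractory_s == 0) return(r)
    if (r * refractory_s >= 1) {
      stop_("rate ", r, " spikes/s is not attainable with a ",
            refractory_s * 1000, " ms refractory period")
    }
    r / (1 - r * refractory_s)
  }
  stim <- c(delay_s, delay_s + stim_duration_s)
  # segment boundaries clipped to the recording window
  breaks <- sort(unique(pmin(pmax(c(window[1], stim, window[2]), window[1]),
                             window[2])))
  with_seed(seed, {
    times <- numeric(0)
    for (i in seq_len(length(breaks) - 1)) {
      a <- breaks[i]; b <- breaks[i + 1]
      if (b <= a) next
      mid <- (a + b) / 2
      rate <- if (mid >= stim[1] && mid < stim[2]) evoked_rate else baseline_rate
      lam <- intensity(rate)
      k <- rpois(1, lam * (b - a))
      if (k > 0) times <- c(times, runif(k, a, b))
    }
    times <- sort(times)
    if (refractory_s > 0 && length(times) > 1) {
      keep <- logical(length(times))
      last <- -Inf
      for (i in seq_along(times)) {
        if (times[i] - last >= refractory_s) {
          keep[i] <- TRUE
          last <- times[i]
        }
      }
      times <- times[keep]
    }
    times
  })
}

# Hill saturation, zero baseline: delta(d) = max * d^h / (ec50^h + d^h)
hill_response <- function(dose, max_delta, ec50, h) {
  max_delta * dose^h / (ec50^h + dose^h)
}

#' Assign receptor archetypes and ground-truth tuning
#'
#' Builds the latent truth of a synthetic screen. Each receptor draws one of
#' four archetypes:
#'
#' * **narrow** — a single ligand (chosen among panel HCs with chain length
#'   >= 21) with true delta drawn from U\[60, 110\] spikes/s, all other HCs
#'   near 0;
#' * **broad** — Gaussian tuning over chain length (center C28-C35, width
#'   2-4 carbons, peak 30-60 spikes/s), redrawn until at least `broad_min`
#'   panel HCs sit above the 30 spikes/s threshold, so broad receptors are
#'   broad by construction;
#' * **inhibited** — true delta U\[-15, -5\] across the whole panel, none
#'   excitatory; the spontaneous rate for this archetype is raised to
#'   `inhibited_baseline` so suppressions below -5 spikes/s are observable
#'   (a 5 spikes/s baseline floors at -5);
#' * **nonresponder** — delta 0 everywhere (evoked == baseline).
#'
#' Every pair also carries a saturating Hill dose curve
#' (`ec50` U\[20, 60\] nmol, slope U\[1.5, 3\]) anchored so the screen dose
#' reproduces the drawn delta; with `ec50 >= 20` nmol no pair exceeds
#' 10 delta spikes/s at or below 2 nmol. Worker-antenna FPKM values are drawn
#' log-normally for receptivity weighting downstream.
#'
#' @param n_receptors number of receptors (ids `R01`, `R02`, ...), or a
#'   character vector of receptor ids.
#' @param panel a [stimulus_panel()].
#' @param mix named archetype proportions summing to 1; counts are allocated
#'   by largest remainder, assignment order shuffled by `seed`. The default
#'   mirrors a 23-receptor screen repertoire: 1 narrow, 6 broad, 4 inhibited,
#'   12 non-responders.
#' @param baseline_rate spontaneous rate in spikes/s (default 5 — one sixth
#'   of the 30 delta spikes/s responder threshold).
#' @param inhibited_baseline spontaneous rate for inhibited receptors.
#' @param threshold responder threshold in delta spikes/s used by the broad
#'   redraw rule.
#' @param broad_min minimum true above-threshold HC count for a broad draw.
#' @param seed integer seed.
#' @return An `or_ground_truth`: list with `receptors` (receptor, archetype,
#'   baseline_rate, worker_fpkm) and `pairs` (receptor, hydrocarbon,
#'   delta_true, ec50_nmol, hill_slope) tibbles plus the panel.
#' @export
assign_archetypes <- function(n_receptors = 23, panel = default_panel(),
                              mix = c(narrow = 1, broad = 6, inhibited = 4,
                                      nonresponder = 12) / 23,
                              baseline_rate = 5, inhibited_baseline = 20,
                              threshold = 30, broad_min = 7, seed) {
  if (missing(seed)) stop_("seed is required")
  if (nrow(panel) == 0) stop_("panel is empty")
  if (abs(sum(mix) - 1) > 1e-8) stop_("mix proportions must sum to 1")
  archetypes <- c("narrow", "broad", "inhibited", "nonresponder")
  if (!all(names(mix) %in% archetypes)) {
    stop_("mix names must be among: ", paste(archetypes, collapse = ", "))
  }
  ids <- if (is.character(n_receptors)) n_receptors else
    sprintf("R%02d", seq_len(n_receptors))
  n <- length(ids)

  # largest-remainder allocation of archetype counts
  quota <- mix[archetypes]
  quota[is.na(quota)] <- 0
  names(quota) <- archetypes
  counts <- floor(quota * n)
  rem <- quota * n - counts
  short <- n - sum(counts)
  if (short > 0) {
    top <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[top] <- counts[top] + 1
  }

  chain <- setNames(panel$chain_length, panel$name)
  long_chain <- panel$name[panel$chain_length >= 21]
  if (length(long_chain) == 0) long_chain <- panel$name

  with_seed(seed, {
    arche <- sample(rep(archetypes, times = counts))
    receptors <- tibble::tibble(
      receptor = ids,
      archetype = arche,
      baseline_rate = ifelse(arche == "inhibited", inhibited_baseline,
                             baseline_rate),
      worker_fpkm = round(exp(rnorm(n, meanlog_fpkm(), 0.8)), 1)
    )
    pairs <- vector("list", n)
    for (i in seq_len(n)) {
      delta <- switch(
        arche[i],
        nonresponder = rep(0, nrow(panel)),
        narrow = {
          d <- runif(nrow(panel), -2, 2)
          d[match(sample(long_chain, 1), panel$name)] <- runif(1, 60, 110)
          d
        },
        broad = {
          # redraw until the tuning curve truly clears the threshold on at
          # least broad_min HCs (capped by the panel size); after 200 tries
          # keep the widest-reaching draw seen (tiny panels cannot be broad)
          eff_min <- min(broad_min, nrow(panel))
          best <- NULL; best_count <- -1L
          for (try in seq_len(200)) {
            center <- runif(1, 28, 35)
            width <- runif(1, 2, 4)
            peak <- runif(1, threshold, 60)
            d <- peak * exp(-((chain[panel$name] - center)^2) / (2 * width^2)) +
              runif(nrow(panel), -2, 2)
            cnt <- sum(d > threshold)
            if (cnt > best_count) { best <- d; best_count <- cnt }
            if (cnt >= eff_min) break
          }
          best
        },
        inhibited = runif(nrow(panel), -15, -5)
      )
      pairs[[i]] <- tibble::tibble(
        receptor = ids[i],
        hydrocarbon = panel$name,
        delta_true = delta,
        ec50_nmol = runif(nrow(panel), 20, 60),
        hill_slope = runif(nrow(panel), 1.5, 3)
      )
    }
    truth <- list(receptors = receptors, pairs = dplyr::bind_rows(pairs),
                  panel = panel)
    class(truth) <- "or_ground_truth"
    truth
  })
}

# log-mean chosen so median worker FPKM ~ 12, matching the scale of the
# packaged synthetic expression table
meanlog_fpkm <- function() log(12)

#' @export
print.or_ground_truth <- function(x, ...) {
  tab <- table(x$receptors$archetype)
  cat("<or_ground_truth>", nrow(x$receptors), "receptor(s) x",
      nrow(x$panel), "hydrocarbon(s)\n  archetypes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a full synthetic experiment
#'
#' Produces one [generate_spike_train()] trial per (receptor, hydrocarbon,
#' dose, replicate), plus `n_reps` solvent trials per receptor
#' (`dose_nmol = 0`, no evoked response). The evoked rate for a pair at dose
#' d scales its ground-truth delta by the pair's Hill curve, anchored so the
#' screen dose reproduces `delta_true`; rates are floored at 0 spikes/s.
#' Randomness is split hierarchically (experiment -> receptor -> trial), so
#' adding a receptor leaves all other trains untouched.
#'
#' @param truth an `or_ground_truth` from [assign_archetypes()].
#' @param n_reps replicates per stimulus (default 6).
#' @param doses dose series in nmol; default the panel screen dose (20 nmol).
#' @param seed integer seed.
#' @param max_rate firing-rate ceiling in spikes/s: evoked rates are clamped
#'   here, mimicking spike-rate saturation at high doses.
#' @inheritParams generate_spike_train
#' @return A trials tibble: `receptor`, `stimulus`, `dose_nmol`, `replicate`,
#'   `spike_times` (list column), `window_start`, `window_end`.
#' @export
generate_experiment <- function(truth, n_reps = 6,
                                doses = default_dose(truth$panel), seed,
                                window = c(-1, 1.5), delay_s = 0.2,
                                stim_duration_s = 1, refractory_s = 0.002,
                                max_rate = 300) {
  if (missing(seed)) stop_("seed is required")
  stopifnot(inherits(truth, "or_ground_truth"), n_reps >= 1)
  panel <- truth$panel
  screen_dose <- default_dose(panel)
  solvent <- solvent_name(panel)
  n_hc <- nrow(panel)
  stim_names <- c(panel$name, solvent)

  rows <- vector("list", nrow(truth$receptors))
  for (i in seq_len(nrow(truth$receptors))) {
    rec <- truth$receptors$receptor[i]
    base <- truth$receptors$baseline_rate[i]
    rec_seed <- split_seed(seed, i)
    p <- truth$pairs[truth$pairs$receptor == rec, ]
    p <- p[match(panel$name, p$hydrocarbon), ]

    grid <- expand.grid(rep = seq_len(n_reps), dose = doses,
                        hc = seq_len(n_hc), KEEP.OUT.ATTRS = FALSE)
    # solvent trials: dose 0, no evoked change
    grid <- rbind(grid, data.frame(rep = seq_len(n_reps), dose = 0,
                                   hc = n_hc + 1L))
    spikes <- vector("list", nrow(grid))
    evoked <- numeric(nrow(grid))
    for (j in seq_len(nrow(grid))) {
      h <- grid$hc[j]
      if (h > n_hc) {
        ev <- base
      } else {
        scale <- hill_response(grid$dose[j], 1, p$ec50_nmol[h],
                               p$hill_slope[h]) /
          hill_response(screen_dose, 1, p$ec50_nmol[h], p$hill_slope[h])
        ev <- min(max_rate, max(0, base + p$delta_true[h] * scale))
      }
      evoked[j] <- ev
      trial_key <- (grid$hc[j] - 1L) * 100000L +
        match(grid$dose[j], c(0, doses)) * 1000L + grid$rep[j]
      spikes[[j]] <- generate_spike_train(
        base, ev, delay_s = delay_s, stim_duration_s = stim_duration_s,
        window = window, refractory_s = refractory_s,
        seed = split_seed(rec_seed, trial_key))
    }
    rows[[i]] <- tibble::tibble(
      receptor = rec,
      stimulus = stim_names[grid$hc],
      dose_nmol = grid$dose,
      replicate = as.integer(grid$rep),
      spike_times = spikes,
      window_start = window[1],
      window_end = window[2]
    )
  }
  dplyr::bind_rows(rows)
}

#' Simulate a complete screen
#'
#' Convenience wrapper: draws ground truth with [assign_archetypes()] and
#' records it with [generate_experiment()].
#'
#' @inheritParams assign_archetypes
#' @inheritParams generate_experiment
#' @param ... further arguments passed to [assign_archetypes()].
#' @return List with elements `truth` and `trials`.
#' @examples
#' scr <- simulate_screen(n_receptors = 3, seed = 42)
#' nrow(scr$trials)  # 3 receptors x (39 HCs + solvent) x 6 replicates
#' @export
simulate_screen <- function(n_receptors = 23, panel = default_panel(),
                            n_reps = 6, doses = default_dose(panel), seed,
                            ...) {
  if (missing(seed)) stop_("seed is required")
  truth <- assign_archetypes(n_receptors, panel = panel,
                             seed = split_seed(seed, 1L), ...)
  trials <- generate_experiment(truth, n_reps = n_reps, doses = doses,
                                seed = split_seed(seed, 2L))
  list(truth = truth, trials = trials)
}
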