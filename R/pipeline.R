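# End-to-end convenience: simulate -> quantify -> tune -> code, and the
# archetype-recovery score used to validate the whole chain.

#' Run a complete synthetic screen end to end
#'
#' Simulates a screen with known ground truth, quantifies the trials into a
#' response matrix at the screen dose, classifies every receptor, and
#' computes the combinatorial-coding summaries using the ground-truth FPKM
#' values.
#'
#' @inheritParams simulate_screen
#' @param threshold responder threshold in delta spikes/s.
#' @return List: `truth`, `trials`, `matrix` ([response_matrix()]),
#'   `profiles` ([profile_receptors()]), `summaries` ([hc_summaries()]),
#'   `n_responding`, `recovery` ([archetype_recovery()]).
#' @examples
#' \donttest{
#' res <- run_screen(n_receptors = 6, seed = 7)
#' res$n_responding
#' }
#' @export
run_screen <- function(n_receptors = 23, panel = default_panel(), n_reps = 6,
                       seed, threshold = 30, ...) {
  if (missing(seed)) stop_("seed is required")
  sim <- simulate_screen(n_receptors = n_receptors, panel = panel,
                         n_reps = n_reps, seed = seed, ...)
  m <- build_response_matrix(sim$trials, panel = panel)
  profiles <- profile_receptors(m, threshold = threshold)
  expr <- tibble::tibble(receptor = sim$truth$receptors$receptor,
                         worker_fpkm = sim$truth$receptors$worker_fpkm)
  list(
    truth = sim$truth,
    trials = sim$trials,
    matrix = m,
    profiles = profiles,
    summaries = hc_summaries(m, expr),
    n_responding = count_responding_receptors(m, threshold = threshold),
    recovery = archetype_recovery(sim$truth, profiles)
  )
}

#' Fraction of receptors classified to their generated archetype
#'
#' Compares ground-truth archetypes with tuning classes; the generative
#' archetypes map one-to-one onto the classes of the same name
#' (`intermediate` has no generative counterpart and always counts as a
#' miss).
#'
#' @param truth an `or_ground_truth`.
#' @param profiles a [profile_receptors()] table for the same receptors.
#' @return Fraction in `[0, 1]`.
#' @export
archetype_recovery <- function(truth, profiles) {
  stopifnot(inherits(truth, "or_ground_truth"))
  want <- truth$receptors$archetype
  got <- profiles$class[match(truth$receptors$receptor, profiles$receptor)]
  mean(want == got)
}
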