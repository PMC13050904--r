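# Shared in-code fixtures for the suite.

# tiny 3-HC panel for fast simulator tests
tiny_panel <- function() {
  stimulus_panel(data.frame(
    name = c("C27", "C28", "C29"),
    chain_length = 27:29,
    hc_class = "n-alkane",
    on_cuticle = c(FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  ))
}

# random small response matrix (<= 5 x 5) with missing cells
random_small_matrix <- function(seed, p_missing = 0.2) {
  set.seed(seed)
  nr <- sample(2:5, 1)
  nc <- sample(2:5, 1)
  m <- matrix(round(runif(nr * nc, -20, 90), 1), nr, nc,
              dimnames = list(paste0("R", seq_len(nr)),
                              paste0("HC", seq_len(nc))))
  m[runif(nr * nc) < p_missing] <- NA
  # keep every row usable for profiling: at least one non-missing cell
  for (i in seq_len(nr)) if (all(is.na(m[i, ]))) m[i, 1] <- 0
  response_matrix(m)
}

random_subfamily_map <- function(x, seed) {
  set.seed(seed)
  tibble::tibble(
    receptor = receptors(x),
    subfamily = sample(LETTERS[1:3], length(receptors(x)), replace = TRUE)
  )
}

random_expression <- function(x, seed, p_missing = 0.25) {
  set.seed(seed)
  n <- length(receptors(x))
  fpkm <- round(runif(n, 0, 50), 1)
  fpkm[runif(n) < p_missing] <- NA
  tibble::tibble(receptor = receptors(x), worker_fpkm = fpkm)
}

# hand-built trials tibble from explicit spike-time lists
manual_trials <- function(receptor, stimulus, spikes_by_rep, dose = 20) {
  tibble::tibble(
    receptor = receptor,
    stimulus = stimulus,
    dose_nmol = dose,
    replicate = seq_along(spikes_by_rep),
    spike_times = spikes_by_rep,
    window_start = -1,
    window_end = 1.5
  )
}
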