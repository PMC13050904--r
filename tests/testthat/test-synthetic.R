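test_that("spike-train generator handles degenerate and invalid inputs", {
  expect_length(generate_spike_train(0, 0, seed = 1), 0)
  expect_error(generate_spike_train(-1, 5, seed = 1), ">= 0")
  expect_error(generate_spike_train(5, 5, window = c(-0.5, 1), seed = 1),
               "window")
  expect_error(generate_spike_train(5, 5), "seed")
  # a rate at/above 1/refractory cannot be realized under compensation
  expect_error(generate_spike_train(5, 600, seed = 1), "not attainable")
})

test_that("identical seeds give identical trains; different seeds differ", {
  a <- generate_spike_train(5, 50, seed = 123)
  b <- generate_spike_train(5, 50, seed = 123)
  c <- generate_spike_train(5, 50, seed = 124)
  expect_identical(a, b)
  expect_false(identical(a, c))
  # and the generator leaves the caller's RNG stream untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); generate_spike_train(5, 50, seed = 1); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("trains are sorted, within window, and respect the refractory period", {
  for (s in 1:20) {
    st <- generate_spike_train(20, 100, window = c(-1, 1.5), seed = s)
    expect_false(is.unsorted(st))
    expect_true(all(st >= -1 & st <= 1.5))
    if (length(st) > 1) expect_true(min(diff(st)) >= 0.002)
  }
})

test_that("realized spike counts match the Poisson expectation (flat rate)", {
  # baseline == evoked == 5 spikes/s over a [-1, 1] window: expected 10
  counts <- vapply(1:1000, function(s) {
    length(generate_spike_train(5, 5, window = c(-1, 1), seed = s))
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 10), 3 * se)
})

test_that("raw thinning lowers the rate by the dead-time factor; compensation removes it", {
  rate <- 100; tau <- 0.002
  stim_count <- function(compensate, s) {
    st <- generate_spike_train(0, rate, delay_s = 0.2, stim_duration_s = 1,
                               window = c(-1, 1.5), refractory_s = tau,
                               seed = s, compensate_refractory = compensate)
    sum(st >= 0.25 & st < 1.15)  # interior of the stimulus epoch, 0.9 s
  }
  raw <- vapply(1:400, stim_count, numeric(1), compensate = FALSE)
  comp <- vapply(401:800, stim_count, numeric(1), compensate = TRUE)
  exp_raw <- rate / (1 + rate * tau) * 0.9
  expect_lt(abs(mean(raw) - exp_raw), 3 * sd(raw) / sqrt(length(raw)))
  expect_lt(abs(mean(comp) - rate * 0.9), 3 * sd(comp) / sqrt(length(comp)))
})

test_that("archetype assignment honours the mix and its structural guarantees", {
  panel <- default_panel()
  gt <- assign_archetypes(10, panel,
                          mix = c(nonresponder = 1), seed = 5)
  expect_true(all(gt$receptors$archetype == "nonresponder"))
  expect_true(all(gt$pairs$delta_true == 0))

  gt <- assign_archetypes(20, panel, mix = c(narrow = 1), seed = 6)
  n_above <- tapply(gt$pairs$delta_true > 30, gt$pairs$receptor, sum)
  expect_true(all(n_above == 1))
  peaks <- gt$pairs[gt$pairs$delta_true > 30, ]
  expect_true(all(peaks$delta_true >= 60 & peaks$delta_true <= 110))
  # narrow ligands sit in the long-chain (>= C21) range
  expect_true(all(panel$chain_length[match(peaks$hydrocarbon,
                                           panel$name)] >= 21))

  gt <- assign_archetypes(10, panel, mix = c(broad = 1), seed = 7)
  n_above <- tapply(gt$pairs$delta_true > 30, gt$pairs$receptor, sum)
  expect_true(all(n_above >= 7))

  gt <- assign_archetypes(10, panel, mix = c(inhibited = 1), seed = 8)
  expect_true(all(gt$pairs$delta_true <= -5 & gt$pairs$delta_true >= -15))
  expect_true(all(gt$receptors$baseline_rate == 20))

  expect_error(assign_archetypes(5, panel, mix = c(narrow = 0.5), seed = 1),
               "sum to 1")
  expect_error(assign_archetypes(5, panel[0, ], seed = 1), "empty")
})

test_that("default archetype mix reproduces the screen repertoire counts", {
  gt <- assign_archetypes(23, seed = 3)
  tab <- table(gt$receptors$archetype)
  expect_equal(as.integer(tab[c("narrow", "broad", "inhibited",
                                "nonresponder")]), c(1, 6, 4, 12))
  expect_equal(as.integer(tab["narrow"] + tab["broad"]), 7)
  expect_true(all(gt$receptors$baseline_rate[
    gt$receptors$archetype != "inhibited"] == 5))
})

test_that("a full experiment covers every pair with the requested replication", {
  panel <- tiny_panel()
  gt <- assign_archetypes(4, panel, seed = 2)
  trials <- generate_experiment(gt, n_reps = 6, seed = 2)
  odor <- trials[trials$stimulus != "pentane", ]
  pairs <- unique(paste(odor$receptor, odor$stimulus))
  expect_length(pairs, 4 * 3)
  reps <- table(paste(odor$receptor, odor$stimulus))
  expect_true(all(reps == 6))
  solvent <- trials[trials$stimulus == "pentane", ]
  expect_equal(nrow(solvent), 4 * 6)
  expect_true(all(solvent$dose_nmol == 0))
})

test_that("experiments are seed-deterministic and receptor streams are independent", {
  panel <- tiny_panel()
  gt <- assign_archetypes(3, panel, seed = 10)
  t1 <- generate_experiment(gt, n_reps = 2, seed = 77)
  t2 <- generate_experiment(gt, n_reps = 2, seed = 77)
  expect_identical(t1$spike_times, t2$spike_times)

  # appending a receptor must not perturb the first three receptors' trains
  extra <- assign_archetypes("R99", panel, seed = 11)
  gt4 <- gt
  gt4$receptors <- rbind(gt$receptors, extra$receptors)
  gt4$pairs <- rbind(gt$pairs, extra$pairs)
  t3 <- generate_experiment(gt4, n_reps = 2, seed = 77)
  first3 <- t3[t3$receptor %in% gt$receptors$receptor, ]
  expect_identical(first3$spike_times, t1$spike_times)
})

test_that("ground-truth dose curves are silent at low doses by construction", {
  hill <- function(d, ec50, h) d^h / (ec50^h + d^h)
  for (s in 1:5) {
    gt <- assign_archetypes(23, seed = s)
    scale2 <- hill(2, gt$pairs$ec50_nmol, gt$pairs$hill_slope) /
      hill(20, gt$pairs$ec50_nmol, gt$pairs$hill_slope)
    expect_true(all(gt$pairs$delta_true * scale2 < 10))
  }
})
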