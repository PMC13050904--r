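test_that("the responder threshold is strict", {
  expect_equal(classify_response(87.5), "above")
  expect_equal(classify_response(3.8), "below")
  expect_equal(classify_response(33.0), "above")
  expect_equal(classify_response(30.0), "below")     # boundary
  expect_equal(classify_response(30.0, threshold = 25), "above")
})

test_that("tuning classes follow the counting rules", {
  hcs <- paste0("HC", 1:10)
  mk <- function(vals) setNames(vals, hcs[seq_along(vals)])

  broad <- mk(c(rep(40, 7), rep(0, 3)))
  expect_equal(profile_receptor(broad, "B")$class, "broad")
  expect_equal(profile_receptor(broad, "B")$n_above, 7L)

  narrow <- mk(c(87.5, rep(5, 9)))
  p <- profile_receptor(narrow, "N")
  expect_equal(p$class, "narrow")
  expect_equal(p$max_hc, "HC1")
  expect_equal(p$max_delta, 87.5)

  six <- mk(c(rep(40, 6), rep(0, 4)))
  expect_equal(profile_receptor(six, "I")$class, "intermediate")

  inhibited <- mk(rep(c(-12, -14), 5))
  p <- profile_receptor(inhibited, "V")
  expect_equal(p$class, "inhibited")
  expect_equal(p$n_inhibitory_pairs, 10L)

  few_inhib <- mk(c(rep(-12, 4), rep(0, 6)))   # below inhibit_min = 5
  expect_equal(profile_receptor(few_inhib, "W")$class, "nonresponder")

  expect_error(profile_receptor(mk(rep(NA_real_, 3)), "X"), "missing")
})

test_that("missing cells are excluded from profile counts, not zeroed", {
  row <- c(A = 40, B = NA, C = -12, D = NA, E = 35)
  p <- profile_receptor(row, "R")
  expect_equal(p$n_above, 2L)
  expect_equal(p$n_inhibitory_pairs, 1L)
  expect_equal(sort(p$hcs_above_threshold[[1]]), c("A", "E"))
})

test_that("raising the threshold never increases counts (monotonicity)", {
  for (s in 1:10) {
    m <- random_small_matrix(s)
    p30 <- profile_receptors(m, threshold = 30)
    p50 <- profile_receptors(m, threshold = 50)
    expect_true(all(p50$n_above <= p30$n_above))
    expect_lte(count_responding_receptors(m, 50),
               count_responding_receptors(m, 30))
  }
})

test_that("classification is invariant under hydrocarbon reordering", {
  m <- random_small_matrix(31)
  perm <- sample(ncol(m$mean))
  m2 <- response_matrix(m$mean[, perm, drop = FALSE])
  p1 <- profile_receptors(m)
  p2 <- profile_receptors(m2)
  expect_equal(p1$class, p2$class)
  expect_equal(p1$n_above, p2$n_above)
  expect_equal(p1$max_hc, p2$max_hc)
})

test_that("responder counting treats the threshold strictly", {
  m <- response_matrix(matrix(c(0, 0, 30, 0), 2, 2,
                              dimnames = list(c("R1", "R2"), c("A", "B"))))
  expect_equal(count_responding_receptors(m), 0)
  m2 <- response_matrix(matrix(c(0, 0, 30.1, 0), 2, 2,
                               dimnames = list(c("R1", "R2"), c("A", "B"))))
  expect_equal(count_responding_receptors(m2), 1)
})

test_that("most efficacious ligand is the argmax with alphabetical tie-break", {
  expect_equal(most_efficacious_ligand(c(C28 = 87.5, C27 = 2)),
               list(hc_name = "C28", mean_delta = 87.5))
  expect_equal(most_efficacious_ligand(c(C30 = 30, C28 = 30))$hc_name, "C28")
  expect_equal(most_efficacious_ligand(c(C35 = 12))$hc_name, "C35")
  expect_equal(most_efficacious_ligand(c(A = NA, B = 5))$hc_name, "B")
  expect_error(most_efficacious_ligand(c(A = NA_real_)), "missing")
})

test_that("Hill fitting recovers exact data and reports degeneracy", {
  doses <- c(0.2, 2, 20, 200)
  y <- 90 * doses^2 / (20^2 + doses^2)
  f <- fit_dose_response(doses, y)
  expect_true(f$converged)
  expect_lt(f$rmse, 1e-4)
  expect_equal(f$max_delta, 90, tolerance = 1e-3)
  expect_equal(f$ec50_nmol, 20, tolerance = 1e-3)
  expect_equal(f$hill_slope, 2, tolerance = 1e-3)

  flat <- fit_dose_response(doses, rep(0, 4))
  expect_false(flat$converged)
  expect_true(is.na(flat$ec50_nmol))

  expect_error(fit_dose_response(c(2, 20), c(1, 2)), "3 distinct")
  expect_error(fit_dose_response(c(0, 2, 20), c(1, 2, 3)), "> 0")
})

test_that("low-dose silence check flags violators and handles vacuous input", {
  rec <- tibble::tibble(
    receptor = c("R1", "R1", "R2"),
    hydrocarbon = c("C28", "C28", "C30"),
    dose_nmol = c(2, 20, 2),
    mean_delta = c(12, 80, 4)
  )
  res <- check_low_dose_silence(rec)
  expect_false(res$ok)
  expect_equal(nrow(res$violations), 1)
  expect_equal(res$violations$receptor, "R1")
  expect_equal(res$violations$dose_nmol, 2)

  ok <- check_low_dose_silence(rec[rec$mean_delta < 10, ])
  expect_true(ok$ok)

  high_only <- rec[rec$dose_nmol > 2, ]
  expect_warning(vac <- check_low_dose_silence(high_only), "vacuous")
  expect_true(vac$ok)
})
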