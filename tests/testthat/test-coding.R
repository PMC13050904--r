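# Brute-force loop oracles used to cross-check the aggregation operations.
oracle_subfamily_sum <- function(m, map) {
  groups <- sort(unique(map$subfamily), method = "radix")
  out <- matrix(NA_real_, length(groups), ncol(m$mean),
                dimnames = list(groups, colnames(m$mean)))
  for (g in groups) for (hc in colnames(m$mean)) {
    members <- map$receptor[map$subfamily == g]
    vals <- c()
    for (r in members) {
      v <- m$mean[r, hc]
      if (!is.na(v)) vals <- c(vals, v)
    }
    if (length(vals) > 0) out[g, hc] <- sum(vals)
  }
  out
}

oracle_mean_per_hc <- function(grid) {
  vapply(colnames(grid), function(hc) {
    vals <- c()
    for (r in rownames(grid)) {
      if (!is.na(grid[r, hc])) vals <- c(vals, grid[r, hc])
    }
    if (length(vals) == 0) NA_real_ else sum(vals) / length(vals)
  }, numeric(1))
}

test_that("subfamily sums match hand-built cases", {
  m <- response_matrix(matrix(c(10, 20, 5, NA, 7, 7), 3, 2,
                              dimnames = list(c("R1", "R2", "R3"),
                                              c("C28", "C30"))))
  map <- tibble::tibble(receptor = c("R1", "R2", "R3"),
                        subfamily = c("V", "V", "M"))
  s <- subfamily_sum(m, map)
  expect_equal(s["V", "C28"], 30)          # 10 + 20
  expect_equal(s["V", "C30"], 7)           # missing member eliminated
  expect_equal(s["M", "C28"], 5)           # single-member identity
  expect_equal(attr(s, "members")[["V"]], 2L)
  expect_error(subfamily_sum(m, map[1:2, ]), "R3")
})

test_that("per-HC means divide by tested receptors only", {
  m <- response_matrix(matrix(c(10, 20, NA, NA, NA, NA), 3, 2,
                              dimnames = list(paste0("R", 1:3),
                                              c("C28", "C30"))))
  s <- mean_response_per_hc(m)
  expect_equal(s$mean_response[s$hc_name == "C28"], 15)
  expect_equal(s$n_tested[s$hc_name == "C28"], 2L)
  expect_true(is.na(s$mean_response[s$hc_name == "C30"]))  # missing, not 0
  expect_equal(s$n_tested[s$hc_name == "C30"], 0L)
})

test_that("receptivity weights responses by worker FPKM and drops unmeasured receptors", {
  m <- response_matrix(matrix(c(10, -5, 40, 8), 2, 2,
                              dimnames = list(c("R1", "R2"), c("A", "B"))))
  expr <- tibble::tibble(receptor = c("R1", "R2"), worker_fpkm = c(2, NA))
  rx <- receptivity(m, expr)
  expect_equal(rx$receptivity["R1", "A"], 20)
  expect_equal(rownames(rx$receptivity), "R1")
  expect_equal(rx$excluded, "R2")
  # negative responses keep their sign; FPKM 0 zeroes the cell
  expr0 <- tibble::tibble(receptor = c("R1", "R2"), worker_fpkm = c(2, 0))
  rx0 <- receptivity(m, expr0)
  expect_equal(rx0$receptivity["R1", "B"], 80)
  expect_equal(rx0$receptivity["R2", "A"], 0)
  expect_lt(receptivity(response_matrix(matrix(-10, 1, 1,
    dimnames = list("R1", "A"))), expr)$receptivity["R1", "A"], 0)
})

test_that("mean receptivity uses post-exclusion denominators", {
  m <- response_matrix(matrix(c(20, 40, 20, NA), 2, 2,
                              dimnames = list(c("R1", "R2"), c("A", "B"))))
  expr <- tibble::tibble(receptor = c("R1", "R2"), worker_fpkm = c(1, 1))
  mr <- mean_receptivity_per_hc(receptivity(m, expr))
  expect_equal(mr$mean_receptivity[mr$hc_name == "A"], 30)
  expect_equal(mr$mean_receptivity[mr$hc_name == "B"], 20)
  # uniform FPKM f: mean receptivity == f * mean response on the same subset
  expr_f <- tibble::tibble(receptor = c("R1", "R2"), worker_fpkm = c(3, 3))
  mr3 <- mean_receptivity_per_hc(receptivity(m, expr_f))
  expect_equal(mr3$mean_receptivity, 3 * mean_response_per_hc(m)$mean_response)
})

test_that("receptivity is scale-equivariant in FPKM and rankings are unchanged", {
  m <- random_small_matrix(41)
  expr <- random_expression(m, 41, p_missing = 0)
  base <- hc_summaries(m, expr)
  expr_c <- expr; expr_c$worker_fpkm <- expr$worker_fpkm * 7
  scaled <- hc_summaries(m, expr_c)
  expect_equal(scaled$mean_receptivity, 7 * base$mean_receptivity)
  expect_equal(scaled$rank_by_receptivity, base$rank_by_receptivity)
})

test_that("per-HC tested counts never grow after FPKM exclusion", {
  for (s in 1:10) {
    m <- random_small_matrix(s + 100)
    expr <- random_expression(m, s + 100)
    summ <- hc_summaries(m, expr)
    ok <- is.na(summ$n_tested_receptivity) |
      summ$n_tested >= summ$n_tested_receptivity
    expect_true(all(ok))
  }
})

test_that("summing the subfamily grid over subfamilies equals summing receptors", {
  for (s in 1:10) {
    m <- random_small_matrix(s + 200)
    map <- random_subfamily_map(m, s + 200)
    sums <- subfamily_sum(m, map)
    expect_equal(colSums(sums, na.rm = TRUE),
                 colSums(m$mean, na.rm = TRUE))
  }
})

test_that("all aggregates match the brute-force loop oracle on small matrices", {
  for (s in 1:20) {
    m <- random_small_matrix(s + 300)
    map <- random_subfamily_map(m, s + 300)
    expr <- random_expression(m, s + 300)
    got_s <- subfamily_sum(m, map)
    attr(got_s, "members") <- NULL
    expect_equal(got_s, oracle_subfamily_sum(m, map))
    got <- mean_response_per_hc(m)
    expect_equal(setNames(got$mean_response, got$hc_name),
                 oracle_mean_per_hc(m$mean))
    rx <- receptivity(m, expr)
    gotr <- mean_receptivity_per_hc(rx)
    expect_equal(setNames(gotr$mean_receptivity, gotr$hc_name),
                 oracle_mean_per_hc(rx$receptivity))
  }
})

test_that("HC ranking is descending with alphabetical tie-break and k capping", {
  s <- tibble::tibble(hc_name = c("A", "B", "C"),
                      mean_response = c(3, 5, 4))
  top <- rank_hcs(s, by = "response", k = 2)
  expect_equal(top$hc_name, c("B", "C"))
  tie <- tibble::tibble(hc_name = c("B", "A"), mean_response = c(5, 5))
  expect_equal(rank_hcs(tie, k = 1)$hc_name, "A")
  expect_warning(all3 <- rank_hcs(s, k = 10), "available")
  expect_equal(nrow(all3), 3)
  expect_error(rank_hcs(s, by = "receptivity"), "mean_receptivity")
})
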