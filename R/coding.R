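# Combinatorial-coding aggregates: subfamily sums, per-HC means,
# FPKM-weighted receptivity, and HC rankings. Missing (untested) cells are
# eliminated from every sum and denominator — never treated as zero.

#' Sum responses by receptor subfamily
#'
#' Cell-wise sum of each hydrocarbon column over the member receptors of
#' each subfamily. Missing cells contribute nothing; a (subfamily, HC) cell
#' with no tested member at all stays missing.
#'
#' @param x a [response_matrix()].
#' @param subfamilies tibble `receptor`, `subfamily` ([load_subfamilies()]);
#'   every receptor of `x` must be mapped.
#' @return Numeric matrix, subfamilies x hydrocarbons, with a
#'   `"members"` attribute giving per-subfamily receptor counts.
#' @export
subfamily_sum <- function(x, subfamilies) {
  stopifnot(inherits(x, "response_matrix"))
  lab <- subfamilies$subfamily[match(receptors(x), subfamilies$receptor)]
  if (anyNA(lab)) {
    stop_("receptor(s) without a subfamily label: ",
          paste(receptors(x)[is.na(lab)], collapse = ", "))
  }
  groups <- sort(unique(lab), method = "radix")
  out <- matrix(NA_real_, length(groups), ncol(x$mean),
                dimnames = list(groups, hc_names(x)))
  for (g in groups) {
    block <- x$mean[lab == g, , drop = FALSE]
    tested <- colSums(!is.na(block))
    s <- colSums(block, na.rm = TRUE)
    s[tested == 0] <- NA_real_
    out[g, ] <- s
  }
  attr(out, "members") <- as.integer(table(lab)[groups])
  names(attr(out, "members")) <- groups
  out
}

#' Per-hydrocarbon mean response
#'
#' The average response to each HC: summed delta spikes/s over the receptors
#' tested on that HC, divided by the number of tested receptors (non-missing
#' cells only). An HC tested on no receptor yields a missing mean, not zero.
#'
#' @param x a [response_matrix()].
#' @return Tibble: `hc_name`, `n_tested`, `mean_response`, `rank_by_response`
#'   (1 = largest; ties broken alphabetically; missing means unranked).
#' @export
mean_response_per_hc <- function(x) {
  stopifnot(inherits(x, "response_matrix"))
  n_tested <- colSums(!is.na(x$mean))
  means <- colSums(x$mean, na.rm = TRUE) / n_tested
  means[n_tested == 0] <- NA_real_
  out <- tibble::tibble(
    hc_name = hc_names(x),
    n_tested = as.integer(n_tested),
    mean_response = as.numeric(means)
  )
  out$rank_by_response <- rank_desc(out$mean_response, out$hc_name)
  out
}

# descending dense rank with alphabetical tie-break; NA values unranked
rank_desc <- function(values, names) {
  r <- rep(NA_integer_, length(values))
  ok <- !is.na(values)
  r[ok] <- order(order(-values[ok], names[ok], method = "radix"))
  r
}

#' Expression-weighted receptivity
#'
#' Multiplies each receptor's responses by its worker-antenna expression
#' (FPKM) to give a receptivity value in arbitrary units
#' (delta spikes/s x FPKM). Receptors without a worker FPKM value are
#' *dropped entirely* — excluded from the grid and from every downstream
#' denominator, never zeroed. Negative responses keep their sign.
#'
#' @param x a [response_matrix()].
#' @param expression tibble `receptor`, `worker_fpkm` ([load_expression()]).
#' @return A `receptivity_matrix`: list with `receptivity` grid (receptors
#'   with expression data x HCs) and `excluded` (receptor ids lacking
#'   worker FPKM).
#' @export
receptivity <- function(x, expression) {
  stopifnot(inherits(x, "response_matrix"))
  fpkm <- expression$worker_fpkm[match(receptors(x), expression$receptor)]
  excluded <- receptors(x)[is.na(fpkm)]
  keep <- !is.na(fpkm)
  grid <- x$mean[keep, , drop = FALSE] * fpkm[keep]
  structure(list(receptivity = grid, excluded = excluded),
            class = "receptivity_matrix")
}

#' @export
print.receptivity_matrix <- function(x, ...) {
  cat("<receptivity_matrix>", nrow(x$receptivity), "receptor(s) x",
      ncol(x$receptivity), "hydrocarbon(s)\n")
  if (length(x$excluded) > 0) {
    cat("  excluded (no worker FPKM):", paste(x$excluded, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Per-hydrocarbon mean receptivity
#'
#' Summed receptivity to each HC divided by the number of tested receptors
#' within the receptivity matrix (i.e. after FPKM exclusion).
#'
#' @param rx a `receptivity_matrix` from [receptivity()].
#' @return Tibble: `hc_name`, `n_tested`, `mean_receptivity`,
#'   `rank_by_receptivity`.
#' @export
mean_receptivity_per_hc <- function(rx) {
  stopifnot(inherits(rx, "receptivity_matrix"))
  g <- rx$receptivity
  n_tested <- colSums(!is.na(g))
  means <- colSums(g, na.rm = TRUE) / n_tested
  means[n_tested == 0] <- NA_real_
  out <- tibble::tibble(
    hc_name = colnames(g),
    n_tested = as.integer(n_tested),
    mean_receptivity = as.numeric(means)
  )
  out$rank_by_receptivity <- rank_desc(out$mean_receptivity, out$hc_name)
  out
}

#' Rank hydrocarbons by mean response or receptivity
#'
#' @param summaries output of [mean_response_per_hc()] or
#'   [mean_receptivity_per_hc()] (or a joined table holding both columns).
#' @param by `"response"` or `"receptivity"`.
#' @param k number of top HCs to return; if fewer are available all are
#'   returned with a warning.
#' @return Tibble of the top `k` HCs in descending order of the chosen
#'   statistic (ties broken alphabetically): `hc_name`, `value`, `rank`.
#' @export
rank_hcs <- function(summaries, by = c("response", "receptivity"), k = 6) {
  by <- match.arg(by)
  col <- paste0("mean_", by)
  if (!col %in% names(summaries)) {
    stop_("summaries lack a ", col, " column")
  }
  avail <- summaries[!is.na(summaries[[col]]), ]
  if (k > nrow(avail)) {
    warning("only ", nrow(avail), " ranked hydrocarbons available; k = ", k,
            call. = FALSE)
    k <- nrow(avail)
  }
  ord <- order(-avail[[col]], avail$hc_name, method = "radix")
  top <- avail[ord[seq_len(k)], ]
  tibble::tibble(hc_name = top$hc_name, value = top[[col]],
                 rank = seq_len(k))
}

#' Per-hydrocarbon summaries (response and receptivity)
#'
#' Joins [mean_response_per_hc()] and [mean_receptivity_per_hc()] into one
#' table of per-HC summaries with both rankings.
#'
#' @inheritParams receptivity
#' @return Tibble: `hc_name`, `n_tested`, `mean_response`,
#'   `rank_by_response`, `n_tested_receptivity`, `mean_receptivity`,
#'   `rank_by_receptivity`.
#' @export
hc_summaries <- function(x, expression) {
  resp <- mean_response_per_hc(x)
  rec <- mean_receptivity_per_hc(receptivity(x, expression))
  names(rec)[names(rec) == "n_tested"] <- "n_tested_receptivity"
  dplyr::left_join(resp, rec, by = "hc_name")
}
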