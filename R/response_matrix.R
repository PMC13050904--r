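#' Receptor x hydrocarbon response matrices
#'
#' The central exchange object of the pipeline: mean solvent-corrected
#' responses in delta spikes/s for each tested (receptor, HC) pair, with
#' untested pairs held as `NA` — explicitly distinguishable from a measured
#' zero — and optional matching SEM and replicate-count grids.
#'
#' @param mean numeric matrix (receptors in rows, HCs in columns) with
#'   dimnames; `NA` marks an untested pair.
#' @param sem optional matrix of standard errors, same shape; values `>= 0`.
#' @param n optional integer matrix of replicate counts, same shape.
#' @return A `response_matrix` object.
#' @examples
#' m <- response_matrix(matrix(c(87.5, 2, NA, 1), 2, 2,
#'                             dimnames = list(c("R1", "R2"), c("C28", "C27"))))
#' receptors(m)
#' hc_names(m)
#' @export
response_matrix <- function(mean, sem = NULL, n = NULL) {
  if (!is.matrix(mean) || !is.numeric(mean)) {
    stop_("mean must be a numeric matrix")
  }
  if (is.null(rownames(mean)) || is.null(colnames(mean))) {
    stop_("mean must have receptor rownames and hydrocarbon colnames")
  }
  if (anyDuplicated(rownames(mean))) stop_("duplicate receptor ids")
  if (anyDuplicated(colnames(mean))) stop_("duplicate hydrocarbon names")
  check_grid <- function(g, what) {
    if (is.null(g)) return(NULL)
    if (!is.matrix(g) || !all(dim(g) == dim(mean))) {
      stop_(what, " grid must match the dimensions of mean")
    }
    dimnames(g) <- dimnames(mean)
    g
  }
  sem <- check_grid(sem, "sem")
  n <- check_grid(n, "n")
  if (!is.null(sem) && any(sem < 0, na.rm = TRUE)) {
    stop_("sem values must be >= 0")
  }
  structure(list(mean = mean, sem = sem, n = n), class = "response_matrix")
}

#' @rdname response_matrix
#' @param x a `response_matrix`.
#' @export
receptors <- function(x) rownames(x$mean)

#' @rdname response_matrix
#' @export
hc_names <- function(x) colnames(x$mean)

#' @export
dim.response_matrix <- function(x) dim(x$mean)

#' @export
print.response_matrix <- function(x, ...) {
  d <- dim(x$mean)
  n_miss <- sum(is.na(x$mean))
  cat(sprintf(
    "<response_matrix> %d receptor(s) x %d hydrocarbon(s), %d tested pair(s), %d missing\n",
    d[1], d[2], prod(d) - n_miss, n_miss))
  cat("  grids:", paste(c("mean", if (!is.null(x$sem)) "sem",
                          if (!is.null(x$n)) "n"), collapse = ", "), "\n")
  invisible(x)
}

#' Convert a response matrix to / from a long tibble
#'
#' The long form has one row per (receptor, hydrocarbon) cell including
#' missing cells (`mean_delta = NA`), which keeps the full grid through
#' round-trips.
#'
#' @param x a `response_matrix`.
#' @param drop_missing drop untested cells from the output.
#' @return A tibble with columns `receptor`, `hydrocarbon`, `mean_delta` and,
#'   when present, `sem` and `n`.
#' @export
response_matrix_to_long <- function(x, drop_missing = FALSE) {
  stopifnot(inherits(x, "response_matrix"))
  grid <- expand.grid(receptor = receptors(x), hydrocarbon = hc_names(x),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- tibble::as_tibble(grid)
  idx <- cbind(match(out$receptor, receptors(x)),
               match(out$hydrocarbon, hc_names(x)))
  out$mean_delta <- x$mean[idx]
  if (!is.null(x$sem)) out$sem <- x$sem[idx]
  if (!is.null(x$n)) out$n <- as.integer(x$n[idx])
  out <- out[order(match(out$receptor, receptors(x)),
                   match(out$hydrocarbon, hc_names(x))), ]
  if (drop_missing) out <- out[!is.na(out$mean_delta), ]
  tibble::as_tibble(out)
}

#' @rdname response_matrix_to_long
#' @param long a data frame with columns `receptor`, `hydrocarbon`,
#'   `mean_delta` and optionally `sem`, `n`.
#' @export
long_to_response_matrix <- function(long) {
  long <- tibble::as_tibble(long)
  required <- c("receptor", "hydrocarbon", "mean_delta")
  if (!all(required %in% names(long))) {
    stop_("long table needs columns: ", paste(required, collapse = ", "))
  }
  key <- paste(long$receptor, long$hydrocarbon, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- long[duplicated(key), c("receptor", "hydrocarbon")][1, ]
    stop_("duplicate (receptor, hydrocarbon) pair: (",
          dup$receptor, ", ", dup$hydrocarbon, ")")
  }
  rids <- unique(long$receptor)
  hcs <- unique(long$hydrocarbon)
  shape <- function(values) {
    g <- matrix(NA_real_, length(rids), length(hcs),
                dimnames = list(rids, hcs))
    g[cbind(match(long$receptor, rids), match(long$hydrocarbon, hcs))] <- values
    g
  }
  response_matrix(
    mean = shape(as.numeric(long$mean_delta)),
    sem = if ("sem" %in% names(long)) shape(as.numeric(long$sem)),
    n = if ("n" %in% names(long)) shape(as.numeric(long$n))
  )
}
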