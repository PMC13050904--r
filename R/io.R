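#' Read and write response matrices
#'
#' Long-format CSV is the canonical serialization (columns `receptor`,
#' `hydrocarbon`, `mean_delta`, and optionally `sem`, `n`): one row per cell
#' of the grid, with missing (untested) cells written as empty fields so the
#' full grid survives a round-trip. Wide format (receptors as rows, HCs as
#' columns, mean only) is a convenience view. Files are pure ASCII; the
#' delta spikes/s unit is implied by the `mean_delta` header.
#'
#' @param path file path.
#' @param dialect `"long"` (canonical) or `"wide"`.
#' @return [read_response_matrix()] returns a [response_matrix()];
#'   [write_response_matrix()] returns `path` invisibly.
#' @seealso [read_response_records()] for dose-resolved long tables.
#' @export
read_response_matrix <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_("file not found: ", path)
  if (dialect == "long") {
    df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character", na.strings = character(0))
    if (nrow(df) == 0) stop_("no data rows in '", path, "'")
    mean_col <- intersect(c("mean_delta", "mean", "delta_spikes_per_s"),
                          names(df))[1]
    if (is.na(mean_col) || !all(c("receptor", "hydrocarbon") %in% names(df))) {
      stop_("long dialect needs columns receptor, hydrocarbon, mean_delta")
    }
    if ("dose_nmol" %in% names(df)) {
      doses <- unique(df$dose_nmol[!is.na(df$dose_nmol) & nzchar(df$dose_nmol)])
      if (length(doses) > 1) {
        stop_("file holds ", length(doses), " doses; use read_response_records()",
              " and filter to one dose before building a matrix")
      }
    }
    long <- tibble::tibble(receptor = df$receptor, hydrocarbon = df$hydrocarbon,
                           mean_delta = parse_numeric(df[[mean_col]], mean_col))
    if ("sem" %in% names(df)) long$sem <- parse_numeric(df$sem, "sem")
    if ("n" %in% names(df)) long$n <- parse_numeric(df$n, "n")
    long_to_response_matrix(long)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("", "NA"))
    if (nrow(df) == 0 || ncol(df) < 2) stop_("no data in '", path, "'")
    rids <- as.character(df[[1]])
    if (anyDuplicated(rids)) {
      stop_("duplicate (receptor, hydrocarbon) pair: receptor ",
            rids[duplicated(rids)][1], " appears twice")
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- rids
    response_matrix(m)
  }
}

# strict numeric parser: "" / "NA" -> NA, anything else non-numeric is an
# error naming the offending row.
parse_numeric <- function(x, what) {
  x <- trimws(x)
  out <- rep(NA_real_, length(x))
  filled <- nzchar(x) & x != "NA"
  suppressWarnings(out[filled] <- as.numeric(x[filled]))
  bad <- filled & is.na(out)
  if (any(bad)) {
    stop_("non-numeric ", what, " value '", x[which(bad)[1]],
          "' at data row ", which(bad)[1])
  }
  out
}

#' @rdname read_response_matrix
#' @param x a [response_matrix()].
#' @export
write_response_matrix <- function(x, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "response_matrix"))
  if (dialect == "long") {
    long <- response_matrix_to_long(x, drop_missing = FALSE)
    write.csv(long, path, row.names = FALSE, na = "")
  } else {
    df <- data.frame(receptor = receptors(x), x$mean, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read a dose-resolved long response table
#'
#' Like the long dialect of [read_response_matrix()], but keeps the
#' `dose_nmol` column and returns the long tibble directly (one row per
#' receptor x hydrocarbon x dose), as written by the `quantify` stage.
#'
#' @inheritParams read_response_matrix
#' @return A tibble with columns `receptor`, `hydrocarbon`, `dose_nmol`,
#'   `mean_delta` and, when present in the file, `sem`, `n`.
#' @export
read_response_records <- function(path) {
  if (!file.exists(path)) stop_("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 colClasses = "character", na.strings = character(0))
  if (nrow(df) == 0) stop_("no data rows in '", path, "'")
  mean_col <- intersect(c("mean_delta", "mean", "delta_spikes_per_s"),
                        names(df))[1]
  if (is.na(mean_col)) stop_("no mean_delta column in '", path, "'")
  out <- tibble::tibble(
    receptor = df$receptor,
    hydrocarbon = df$hydrocarbon,
    dose_nmol = if ("dose_nmol" %in% names(df))
      parse_numeric(df$dose_nmol, "dose_nmol") else NA_real_,
    mean_delta = parse_numeric(df[[mean_col]], mean_col)
  )
  if ("sem" %in% names(df)) out$sem <- parse_numeric(df$sem, "sem")
  if ("n" %in% names(df)) out$n <- parse_numeric(df$n, "n")
  key <- paste(out$receptor, out$hydrocarbon, out$dose_nmol, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- out[duplicated(key), ][1, ]
    stop_("duplicate (receptor, hydrocarbon, dose) row: (", dup$receptor,
          ", ", dup$hydrocarbon, ", ", dup$dose_nmol, ")")
  }
  out
}

#' Gene-name harmonization maps
#'
#' The packaged map carries the printed annotation-update list for the
#' *HsOr* family (19 renames plus one swapped pair flagged `swap`). The map
#' is applied *simultaneously* over the whole vocabulary — every old name is
#' looked up against the input as it was, so chained entries (an old name
#' that is also some other entry's new name) and swapped pairs resolve
#' atomically rather than sequentially.
#'
#' @param path TSV with columns `old_name`, `new_name`, `swap`; defaults to
#'   the packaged map.
#' @return [load_rename_map()]: a tibble with those columns.
#' @examples
#' m <- load_rename_map()
#' apply_rename_map(c("HsOr307.1", "LOC105187615", "HsOr999"), m)
#' apply_rename_map(c("HsOr378", "HsOr379"), m)  # swapped
#' @export
load_rename_map <- function(path = system.file("extdata", "rename_map.tsv",
                                               package = "orscreen")) {
  df <- read_tsv_strict(path)
  if (!all(c("old_name", "new_name", "swap") %in% names(df))) {
    stop_("rename map needs columns old_name, new_name, swap")
  }
  df$swap <- as.logical(df$swap)
  validate_rename_map(df)
  df
}

validate_rename_map <- function(map) {
  if (anyDuplicated(map$old_name)) {
    stop_("rename map lists old name twice: ",
          map$old_name[duplicated(map$old_name)][1])
  }
  sw <- map[map$swap, , drop = FALSE]
  if (nrow(sw) > 0) {
    # every swap row's counterpart (new -> old) must also be present
    ok <- paste(sw$new_name, sw$old_name) %in% paste(sw$old_name, sw$new_name)
    if (!all(ok)) {
      stop_("swap entries must come in exchanged pairs; missing counterpart for ",
            sw$old_name[!ok][1])
    }
  }
  invisible(map)
}

#' @rdname load_rename_map
#' @param names character vector of gene names.
#' @param map a rename map as returned by [load_rename_map()].
#' @return [apply_rename_map()]: `names` with every listed old name replaced
#'   by its new name (order preserved, unlisted names untouched).
#' @export
apply_rename_map <- function(names, map) {
  validate_rename_map(map)
  idx <- match(names, map$old_name)
  out <- ifelse(is.na(idx), names, map$new_name[idx])
  if (sum(duplicated(out)) > sum(duplicated(names))) {
    dup <- setdiff(unique(out[duplicated(out)]), unique(names[duplicated(names)]))
    stop_("renaming would create duplicate name(s): ",
          paste(dup, collapse = ", "))
  }
  out
}

#' Load expression and subfamily tables
#'
#' `load_expression()` reads a receptor -> FPKM table (worker and male
#' antennae). A receptor with an empty `worker_fpkm` field is kept with `NA`
#' — such receptors are *excluded* from receptivity weighting, never zeroed.
#' `load_subfamilies()` reads a receptor -> subfamily label map.
#'
#' @param path TSV path; the packaged `*_synthetic.tsv` stand-ins cover the
#'   23-receptor screen repertoire.
#' @return A tibble (`receptor`, `worker_fpkm`, `male_fpkm`) or
#'   (`receptor`, `subfamily`).
#' @export
load_expression <- function(path = system.file("extdata",
                                               "expression_synthetic.tsv",
                                               package = "orscreen")) {
  df <- read_tsv_strict(path)
  if (!all(c("receptor", "worker_fpkm") %in% names(df))) {
    stop_("expression table needs columns receptor, worker_fpkm")
  }
  if (!"male_fpkm" %in% names(df)) df$male_fpkm <- NA_real_
  df$worker_fpkm <- as.numeric(df$worker_fpkm)
  df$male_fpkm <- as.numeric(df$male_fpkm)
  if (any(df$worker_fpkm < 0, na.rm = TRUE) ||
      any(df$male_fpkm < 0, na.rm = TRUE)) {
    stop_("FPKM values must be >= 0")
  }
  if (anyDuplicated(df$receptor)) {
    stop_("duplicate receptor in expression table: ",
          df$receptor[duplicated(df$receptor)][1])
  }
  df[, c("receptor", "worker_fpkm", "male_fpkm")]
}

#' @rdname load_expression
#' @export
load_subfamilies <- function(path = system.file("extdata",
                                                "subfamilies_synthetic.tsv",
                                                package = "orscreen")) {
  df <- read_tsv_strict(path)
  if (!all(c("receptor", "subfamily") %in% names(df))) {
    stop_("subfamily table needs columns receptor, subfamily")
  }
  if (anyDuplicated(df$receptor)) {
    stop_("duplicate receptor in subfamily table: ",
          df$receptor[duplicated(df$receptor)][1])
  }
  df[, c("receptor", "subfamily")]
}

#' Read and write trial tables
#'
#' Trials are serialized as a long CSV with one row per recording:
#' `receptor`, `stimulus`, `dose_nmol`, `replicate`, `window_start`,
#' `window_end`, and `spike_times` as semicolon-joined seconds relative to
#' stimulus onset.
#'
#' @param trials a trials tibble as produced by [generate_experiment()].
#' @param path file path.
#' @export
write_trials <- function(trials, path) {
  df <- data.frame(
    receptor = trials$receptor,
    stimulus = trials$stimulus,
    dose_nmol = trials$dose_nmol,
    replicate = trials$replicate,
    window_start = trials$window_start,
    window_end = trials$window_end,
    spike_times = vapply(trials$spike_times,
                         function(x) paste(format(x, digits = 10, trim = TRUE,
                                                  scientific = FALSE),
                                           collapse = ";"),
                         character(1)),
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop_("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 na.strings = c("", "NA"))
  needed <- c("receptor", "stimulus", "dose_nmol", "replicate",
              "window_start", "window_end", "spike_times")
  if (!all(needed %in% names(df))) {
    stop_("trials file needs columns: ", paste(needed, collapse = ", "))
  }
  df$spike_times[is.na(df$spike_times)] <- ""
  tibble::tibble(
    receptor = as.character(df$receptor),
    stimulus = as.character(df$stimulus),
    dose_nmol = as.numeric(df$dose_nmol),
    replicate = as.integer(df$replicate),
    spike_times = lapply(strsplit(df$spike_times, ";", fixed = TRUE),
                         function(x) as.numeric(x[nzchar(x)])),
    window_start = as.numeric(df$window_start),
    window_end = as.numeric(df$window_end)
  )
}

#' Export the three-tab response database tables
#'
#' Writes the combined response values joined with SEM as three CSV views —
#' by receptor, by hydrocarbon, and by subfamily — the input tables of a
#' response-database browser.
#'
#' @param x a [response_matrix()].
#' @param subfamilies receptor -> subfamily tibble ([load_subfamilies()]).
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
export_response_tabs <- function(x, subfamilies, dir) {
  stopifnot(inherits(x, "response_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  long <- response_matrix_to_long(x, drop_missing = TRUE)
  long$subfamily <- subfamilies$subfamily[match(long$receptor,
                                                subfamilies$receptor)]
  paths <- file.path(dir, c("responses_by_receptor.csv",
                            "responses_by_hydrocarbon.csv",
                            "responses_by_subfamily.csv"))
  write.csv(long[order(long$receptor), ], paths[1], row.names = FALSE, na = "")
  write.csv(long[order(long$hydrocarbon), ], paths[2], row.names = FALSE, na = "")
  write.csv(long[order(long$subfamily, long$receptor), ], paths[3],
            row.names = FALSE, na = "")
  invisible(paths)
}
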