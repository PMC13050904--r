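#' Stimulus panels of hydrocarbons
#'
#' A stimulus panel is a tibble of hydrocarbons (one row per HC) carrying the
#' chemical annotation used throughout the pipeline, plus the solvent name and
#' the screening dose as attributes. The packaged default panel
#' ([default_panel()]) holds 39 HCs spanning n-alkanes (C10-C35),
#' methyl-branched alkanes, dimethyl alkanes and (Z)-9 alkenes, of which 17
#' are flagged as occurring in *Harpegnathos saltator* cuticular extracts.
#'
#' @param hydrocarbons data frame with columns `name`, `chain_length`,
#'   `hc_class` (one of `"n-alkane"`, `"monomethyl"`, `"dimethyl"`,
#'   `"alkene"`), `methyl_positions` (comma-joined integers, `""`/`NA` for
#'   none), `double_bond_position` (integer or `NA`),
#'   `double_bond_geometry` (`"Z"`/`"E"` or `NA`), `on_cuticle` (logical).
#' @param solvent_name solvent control stimulus name (not a panel member).
#' @param default_dose_nmol screening dose in nmol per cartridge.
#' @return A `stimulus_panel`: a tibble with attributes `solvent_name` and
#'   `default_dose_nmol`.
#' @examples
#' p <- default_panel()
#' nrow(p)                 # 39
#' sum(p$on_cuticle)       # 17
#' solvent_name(p)         # "pentane"
#' @export
stimulus_panel <- function(hydrocarbons, solvent_name = "pentane",
                           default_dose_nmol = 20) {
  hc <- tibble::as_tibble(hydrocarbons)
  required <- c("name", "chain_length", "hc_class", "on_cuticle")
  missing_cols <- setdiff(required, names(hc))
  if (length(missing_cols) > 0) {
    stop_("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(hc) == 0) stop_("panel has no hydrocarbons")
  if (!"methyl_positions" %in% names(hc)) hc$methyl_positions <- ""
  if (!"double_bond_position" %in% names(hc)) hc$double_bond_position <- NA_integer_
  if (!"double_bond_geometry" %in% names(hc)) hc$double_bond_geometry <- NA_character_
  hc$methyl_positions <- ifelse(is.na(hc$methyl_positions), "",
                                as.character(hc$methyl_positions))
  hc$chain_length <- as.integer(hc$chain_length)
  hc$on_cuticle <- as.logical(hc$on_cuticle)

  if (anyDuplicated(hc$name)) {
    stop_("duplicate hydrocarbon name(s): ",
          paste(unique(hc$name[duplicated(hc$name)]), collapse = ", "))
  }
  if (solvent_name %in% hc$name) {
    stop_("solvent '", solvent_name, "' must not be a panel member")
  }
  if (any(is.na(hc$chain_length)) || any(hc$chain_length < 1)) {
    stop_("chain_length must be a positive integer for every hydrocarbon")
  }
  classes <- c("n-alkane", "monomethyl", "dimethyl", "alkene")
  bad <- setdiff(unique(hc$hc_class), classes)
  if (length(bad) > 0) stop_("unknown hc_class: ", paste(bad, collapse = ", "))

  n_methyl <- vapply(strsplit(hc$methyl_positions, ","),
                     function(x) length(x[nzchar(trimws(x))]), integer(1))
  has_db <- !is.na(hc$double_bond_position)
  expected <- c("n-alkane" = 0L, "monomethyl" = 1L, "dimethyl" = 2L,
                "alkene" = 0L)
  wrong <- n_methyl != expected[hc$hc_class] |
    (hc$hc_class == "alkene") != has_db
  if (any(wrong)) {
    stop_("hc_class inconsistent with methyl/double-bond annotation for: ",
          paste(hc$name[wrong], collapse = ", "))
  }

  structure(hc,
            solvent_name = solvent_name,
            default_dose_nmol = default_dose_nmol,
            class = c("stimulus_panel", class(hc)))
}

#' @rdname stimulus_panel
#' @param panel a `stimulus_panel`.
#' @export
solvent_name <- function(panel) attr(panel, "solvent_name")

#' @rdname stimulus_panel
#' @export
default_dose <- function(panel) attr(panel, "default_dose_nmol")

#' Load a stimulus panel from a TSV file
#'
#' The file is tab-separated with `#` comment lines and the columns documented
#' in [stimulus_panel()].
#'
#' @param path path to a panel TSV; defaults to the packaged 39-HC panel.
#' @inheritParams stimulus_panel
#' @return A `stimulus_panel`.
#' @export
load_panel <- function(path = system.file("extdata", "hc_panel.tsv",
                                          package = "orscreen"),
                       solvent_name = "pentane", default_dose_nmol = 20) {
  df <- read_tsv_strict(path)
  stimulus_panel(df, solvent_name = solvent_name,
                 default_dose_nmol = default_dose_nmol)
}

#' @rdname load_panel
#' @export
default_panel <- function() {
  load_panel()
}

# Shared strict TSV reader: '#' comments, tab-separated, header required,
# empty file is an error.
read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop_("file not found: ", path)
  df <- tryCatch(
    read.delim(path, comment.char = "#", sep = "\t", header = TRUE,
               stringsAsFactors = FALSE, check.names = FALSE,
               na.strings = c("NA", "")),
    error = function(e) stop_("cannot read '", path, "': ", conditionMessage(e))
  )
  if (nrow(df) == 0) stop_("no data rows in '", path, "'")
  tibble::as_tibble(df)
}
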