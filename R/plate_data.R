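#' combiscreen: miRNA/drug combination viability screen analysis
#'
#' Pipeline stages: plate-data I/O ([read_viability_table()]), single-agent
#' MAD screening ([summarize_ratios()], [call_hits()], [select_candidates()]),
#' dose-response fitting ([fit_four_pl()], [working_concentration()]),
#' rank-test interaction calling ([call_interaction()],
#' [run_interaction_family()]), expression association
#' ([spearman_screen()], [lentiviral_concordance()]), and seeded synthetic
#' data generators ([simulate_mts_screen()] and friends).
#'
#' @keywords internal
"_PACKAGE"

# Required columns of the well-level viability table, in canonical order.
VIABILITY_COLUMNS <- c("cell_line", "mirna", "drug", "dose", "dose_unit",
                       "repeat_id", "well_id", "assay", "signal")

.dose_unit_factor <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)

#' Convert a dose to molar units
#'
#' @param dose numeric vector of concentrations.
#' @param unit character vector of units, one of `"M"`, `"mM"`, `"uM"`,
#'   `"nM"`, `"pM"` (micro may also be written `"µM"`).
#' @return numeric vector of concentrations in molar.
#' @export
dose_to_molar <- function(dose, unit) {
  unit <- gsub("µ", "u", unit)
  fac <- .dose_unit_factor[unit]
  if (anyNA(fac)) {
    bad <- unique(unit[is.na(fac)])
    stop("unknown dose_unit: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(dose * fac)
}

#' Read a well-level viability table
#'
#' Parses a long-format CSV/TSV of viability wells into a validated
#' data frame of records. Expected columns (exact names):
#' `cell_line, mirna, drug, dose, dose_unit, repeat_id, well_id, assay,
#' signal`. An empty string in `mirna` or `drug` means no agent; the special
#' value `NEG_CONTROL` in `mirna` marks a negative-control transfection.
#' Doses are converted to molar on load using `dose_unit`.
#'
#' @param path path to a CSV (default) or TSV file.
#' @param assay if non-`NULL`, restrict to one assay (`"MTS"` or `"ALAMAR"`)
#'   and error if the file contains none of it.
#' @param sep field separator; inferred from the file extension when `NULL`
#'   (`.tsv`/`.txt` implies tab).
#' @return a `data.frame` with columns `cell_line`, `mirna`, `drug`
#'   (character, `NA` for none), `dose` (molar), `repeat_id`, `well_id`
#'   (integer), `assay`, `signal`. Row order follows the file.
#' @export
read_viability_table <- function(path, assay = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"")
  missing_cols <- setdiff(VIABILITY_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rec <- data.frame(
    cell_line = raw$cell_line,
    mirna = ifelse(raw$mirna == "", NA_character_, raw$mirna),
    drug = ifelse(raw$drug == "", NA_character_, raw$drug),
    dose = suppressWarnings(as.numeric(raw$dose)),
    repeat_id = suppressWarnings(as.integer(raw$repeat_id)),
    well_id = suppressWarnings(as.integer(raw$well_id)),
    assay = raw$assay,
    signal = suppressWarnings(as.numeric(raw$signal)),
    stringsAsFactors = FALSE
  )
  has_dose <- !is.na(rec$dose) & rec$dose > 0
  if (any(has_dose)) {
    rec$dose[has_dose] <- dose_to_molar(rec$dose[has_dose],
                                        raw$dose_unit[has_dose])
  }
  if (!is.null(assay)) {
    rec <- rec[rec$assay == assay, , drop = FALSE]
    if (nrow(rec) == 0) stop("no rows with assay = ", assay, call. = FALSE)
    rownames(rec) <- NULL
  }
  validate_viability(rec)
  rec
}

#' Validate a viability record table
#'
#' Checks the invariants of well-level records: finite non-negative signal
#' and dose, a drug present wherever dose > 0, known assay codes, and
#' uniqueness of the (cell_line, mirna, drug, dose, repeat_id, well_id,
#' assay) key. Errors cite 1-based row numbers.
#'
#' @param records data frame as returned by [read_viability_table()].
#' @return `records`, invisibly, if valid.
#' @export
validate_viability <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("cell_line", "mirna", "drug", "dose", "repeat_id", "well_id",
            "assay", "signal")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(records$signal) | records$signal < 0)
  if (length(bad) > 0) {
    stop("validation error: negative or non-numeric signal on row ",
         bad[1], call. = FALSE)
  }
  bad <- which(!is.finite(records$dose) | records$dose < 0)
  if (length(bad) > 0) {
    stop("validation error: negative or non-numeric dose on row ",
         bad[1], call. = FALSE)
  }
  bad <- which(records$dose > 0 & is.na(records$drug))
  if (length(bad) > 0) {
    stop("validation error: dose > 0 without a drug on row ",
         bad[1], call. = FALSE)
  }
  bad <- which(!records$assay %in% c("MTS", "ALAMAR"))
  if (length(bad) > 0) {
    stop("validation error: unknown assay '", records$assay[bad[1]],
         "' on row ", bad[1], call. = FALSE)
  }
  key <- paste(records$cell_line, records$mirna, records$drug, records$dose,
               records$repeat_id, records$well_id, records$assay, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("validation error: duplicate well key on row ", dup[1],
         call. = FALSE)
  }
  invisible(records)
}

#' Write a viability table
#'
#' Inverse of [read_viability_table()]: writes records with doses expressed
#' in the requested unit so that a read round-trips all fields.
#'
#' @param records validated record data frame.
#' @param path output file; `.tsv` extension selects tab separation.
#' @param dose_unit unit to express doses in (`"M"` writes them unscaled).
#' @return `path`, invisibly.
#' @export
write_viability_table <- function(records, path, dose_unit = "M") {
  validate_viability(records)
  fac <- .dose_unit_factor[[dose_unit]]
  if (is.null(fac)) stop("unknown dose_unit: ", dose_unit, call. = FALSE)
  out <- data.frame(
    cell_line = records$cell_line,
    mirna = ifelse(is.na(records$mirna), "", records$mirna),
    drug = ifelse(is.na(records$drug), "", records$drug),
    dose = records$dose / fac,
    dose_unit = dose_unit,
    repeat_id = records$repeat_id,
    well_id = records$well_id,
    assay = records$assay,
    signal = records$signal,
    stringsAsFactors = FALSE
  )
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Group wells of one cell line into treatment arms
#'
#' Pools all wells of a cell line by (mirna, drug) arm, ignoring
#' `repeat_id`/`well_id`: each well is one observation, so duplicates
#' across three experiment repeats give n = 6 per arm.
#'
#' @param records validated record data frame.
#' @param cell_line cell line identifier to extract.
#' @param assay optional assay restriction.
#' @return named list of numeric signal vectors; names are
#'   `"<mirna>|<drug>"` with `NONE` for an absent agent.
#' @export
group_arms <- function(records, cell_line, assay = NULL) {
  validate_viability(records)
  sel <- records$cell_line == cell_line
  if (!is.null(assay)) sel <- sel & records$assay == assay
  if (!any(sel)) {
    stop("lookup error: no records for cell line '", cell_line, "'",
         call. = FALSE)
  }
  sub <- records[sel, , drop = FALSE]
  arm <- paste(ifelse(is.na(sub$mirna), "NONE", sub$mirna),
               ifelse(is.na(sub$drug), "NONE", sub$drug), sep = "|")
  split(sub$signal, arm)
}

#' Describe an interaction experiment's comparison family
#'
#' Records the per-cell-line lists of miRNAs and drugs tested together;
#' the number of drug comparisons sets the family alpha for the three-way
#' interaction tests and the number of miRNA comparisons sets the alpha
#' for single-agent miRNA tests.
#'
#' @param cell_line cell line identifier.
#' @param mirnas character vector of miRNA identifiers.
#' @param drugs character vector of drug identifiers.
#' @return an object of class `experiment_design`.
#' @export
experiment_design <- function(cell_line, mirnas, drugs) {
  stopifnot(length(mirnas) >= 1, length(drugs) >= 1)
  structure(
    list(cell_line = cell_line,
         mirnas = as.character(mirnas),
         drugs = as.character(drugs),
         n_drug_comparisons = length(drugs),
         n_mirna_comparisons = length(mirnas)),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Experiment design for", x$cell_line, "\n")
  cat("  miRNAs (", x$n_mirna_comparisons, "): ",
      paste(x$mirnas, collapse = ", "), "\n", sep = "")
  cat("  drugs  (", x$n_drug_comparisons, "): ",
      paste(x$drugs, collapse = ", "), "\n", sep = "")
  invisible(x)
}
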