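# Pure-compound melting temperatures of membrane fatty acids. The shipped
# defaults come from standard physical-chemistry references (CRC Handbook and
# lipid handbooks); each entry records its provenance so users can audit or
# override individual values. All WAMT claims based on the default table are
# ordering claims, not absolute-value claims.

#' Default melting-point reference table
#'
#' A table of pure-compound melting temperatures (degrees Celsius) covering
#' the fatty acids observed in cold-grown food-spoilage yeasts and filamentous
#' fungi. Keys are canonical shorthand labels (see [parse_fatty_acid()]).
#' Within each chain length the temperature decreases strictly as the
#' double-bond count increases.
#'
#' @param include_hydroxy If `FALSE`, hydroxylated acids (e.g. `C18:0 3OH`)
#'   are dropped so that they never enter a weighted average; their literature
#'   melting points are less certain than those of the plain acids.
#'
#' @return A tibble with columns `canonical_label`, `melting_temp_c` and
#'   `source_note`.
#' @export
default_melting_table <- function(include_hydroxy = TRUE) {
  tbl <- tibble::tribble(
    ~canonical_label,        ~melting_temp_c, ~source_note,
    "C14:0",                 53.9,  "myristic acid; CRC Handbook of Chemistry and Physics",
    "C16:0",                 62.9,  "palmitic acid; CRC Handbook of Chemistry and Physics",
    "C16:1 cis 9",           -0.1,  "palmitoleic acid; lipid handbook value",
    "C18:0",                 69.3,  "stearic acid; CRC Handbook of Chemistry and Physics",
    "C18:1 cis 9",           13.4,  "oleic acid; CRC Handbook of Chemistry and Physics",
    "C18:1 cis 11",          14.5,  "cis-vaccenic acid; lipid handbook value",
    "C18:2 cis 9, 12",       -6.9,  "linoleic acid; CRC Handbook of Chemistry and Physics",
    "C18:3 cis 9, 12, 15",   -11.0, "alpha-linolenic acid; lipid handbook value",
    "C18:3 cis 6, 9, 12",    -14.4, "gamma-linolenic acid; lipid handbook value",
    "C18:0 3OH",             84.5,  "3-hydroxystearic acid; literature value, low confidence"
  )
  if (!include_hydroxy) {
    hydroxy <- vapply(tbl$canonical_label, function(l) {
      length(parse_fatty_acid(l)$hydroxyl_positions) > 0L
    }, logical(1))
    tbl <- tbl[!hydroxy, ]
  }
  validate_melting_table(tbl)
}

#' Validate a melting-point table
#'
#' Checks the contract of a melting-point reference table: required columns,
#' parseable and unique canonical labels, and temperatures within the
#' physically plausible window of -60 to +100 degrees Celsius. Labels are
#' canonicalized, so spelling variants collapse onto one key.
#'
#' @param tbl A data frame with columns `canonical_label`, `melting_temp_c`
#'   and optionally `source_note`.
#' @return The validated tibble (labels canonicalized).
#' @export
validate_melting_table <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  required <- c("canonical_label", "melting_temp_c")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0L) {
    stop("Melting-point table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"source_note" %in% names(tbl)) tbl$source_note <- NA_character_
  tbl$canonical_label <- canonical_fa_label(tbl$canonical_label)
  tbl$melting_temp_c <- as.numeric(tbl$melting_temp_c)
  if (anyNA(tbl$melting_temp_c)) {
    stop("Melting-point table contains non-numeric temperatures.",
         call. = FALSE)
  }
  if (any(tbl$melting_temp_c < -60 | tbl$melting_temp_c > 100)) {
    bad <- tbl$canonical_label[tbl$melting_temp_c < -60 |
                                 tbl$melting_temp_c > 100][1]
    stop("Melting temperature for '", bad,
         "' is outside the plausible range [-60, 100] degrees C.",
         call. = FALSE)
  }
  if (anyDuplicated(tbl$canonical_label)) {
    dup <- tbl$canonical_label[duplicated(tbl$canonical_label)][1]
    stop("Duplicate melting-point entry for '", dup, "'.", call. = FALSE)
  }
  tbl[, c("canonical_label", "melting_temp_c", "source_note")]
}

#' Look up the melting temperature of a fatty acid
#'
#' Exact-identity lookup: double-bond positions and geometry matter, so the
#' `C18:3 cis 6, 9, 12` and `C18:3 cis 9, 12, 15` isomers resolve to
#' different entries. Absence from the table is a value (`NA`), not an error;
#' callers decide how to renormalize over covered acids.
#'
#' @param fa A `fatty_acid` object or character vector of labels.
#' @param table A melting-point table (default [default_melting_table()]).
#' @return Numeric vector of temperatures in degrees Celsius, `NA` where the
#'   acid has no entry.
#' @export
melting_temperature <- function(fa, table = default_melting_table()) {
  table <- validate_melting_table(table)
  labels <- if (inherits(fa, "fatty_acid")) fa$label else canonical_fa_label(fa)
  table$melting_temp_c[match(labels, table$canonical_label)]
}

#' Read a melting-point table from a TSV file
#'
#' Expects two or three tab-separated columns: `canonical_label`,
#' `melting_temp_c` and optionally `source_note`.
#'
#' @param path Path to the TSV file.
#' @return A validated melting-point tibble.
#' @export
read_melting_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           canonical_label = readr::col_character(),
                           melting_temp_c = readr::col_double(),
                           .default = readr::col_character()
                         ))
  validate_melting_table(tbl)
}

#' Write a melting-point table to a TSV file
#'
#' @param tbl A melting-point table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_melting_table <- function(tbl, path) {
  tbl <- validate_melting_table(tbl)
  readr::write_tsv(tbl, path)
  invisible(path)
}
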