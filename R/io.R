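# Profile-table file dialects.
#
# Wide format: one row per (organism, condition); columns = fatty-acid
# labels; cells "mean ± sd" (the separator may be "±" or "+/-"), "nd",
# "<1", or empty (treated as not detected); optional column n_replicates.
# Long format: columns organism, condition, fatty_acid, status, mean, sd,
# n_replicates, censor_threshold.
# TSV or CSV is chosen from the file extension. Decimal separators must be
# "."; decimal commas are rejected with a clear message.

parse_profile_cell <- function(x) {
  x <- trimws(ifelse(is.na(x), "", x))
  x_low <- tolower(x)
  status <- character(length(x))
  mean_v <- rep(NA_real_, length(x))
  sd_v <- rep(NA_real_, length(x))
  thr <- rep(NA_real_, length(x))

  parse_num <- function(s, context) {
    s <- trimws(s)
    if (grepl(",", s)) {
      stop("Cell '", context, "' contains a comma; decimal commas are not ",
           "supported - use '.' as the decimal separator.", call. = FALSE)
    }
    if (startsWith(s, "<")) {
      # censored standard deviation such as "<0.1": use half the bound
      return(as.numeric(substring(s, 2)) / 2)
    }
    out <- suppressWarnings(as.numeric(s))
    if (is.na(out)) {
      stop("Cannot parse numeric value '", s, "' in cell '", context, "'.",
           call. = FALSE)
    }
    out
  }

  for (i in seq_along(x)) {
    if (x_low[i] == "" || x_low[i] == "nd" || x_low[i] == "na") {
      status[i] <- "not_detected"
    } else if (grepl("^<\\s*[0-9.]+$", x[i])) {
      status[i] <- "censored_below"
      thr[i] <- as.numeric(sub("^<\\s*", "", x[i]))
    } else {
      status[i] <- "quantified"
      parts <- strsplit(x[i], "±|\\+/-")[[1]]
      if (length(parts) > 2L) {
        stop("Cannot parse cell '", x[i], "'.", call. = FALSE)
      }
      mean_v[i] <- parse_num(parts[1], x[i])
      if (length(parts) == 2L) sd_v[i] <- parse_num(parts[2], x[i])
    }
  }
  tibble::tibble(status = status, mean = mean_v, sd = sd_v,
                 censor_threshold = thr)
}

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read fatty-acid profiles from a TSV or CSV file
#'
#' Supports the wide dialect (one row per organism and condition, fatty-acid
#' labels as columns, cells `"mean ± sd"` / `"nd"` / `"<1"`) and the tidy
#' long dialect (columns `organism`, `condition`, `fatty_acid`, `status`,
#' `mean`, `sd`, `n_replicates`). The `"±"` separator may also be written
#' `"+/-"`. An empty file yields an empty profile set with a warning.
#'
#' @param path Path to the file (`.tsv` or `.csv`).
#' @param format `"auto"` (default: long if a `fatty_acid` column is
#'   present), `"wide"` or `"long"`.
#' @param n_replicates Default replicate count for wide files without an
#'   `n_replicates` column (default 3, the usual biological-triplicate
#'   design).
#' @return A [profile_set()].
#' @export
read_profiles <- function(path, format = c("auto", "wide", "long"),
                          n_replicates = 3) {
  format <- match.arg(format)
  raw <- readr::read_delim(path, delim = delim_for(path),
                           col_types = readr::cols(.default = "c"),
                           comment = "#", show_col_types = FALSE,
                           progress = FALSE)
  if (format == "auto") {
    format <- if ("fatty_acid" %in% names(raw)) "long" else "wide"
  }
  if (nrow(raw) == 0L) {
    warning("Profile file '", path, "' has no data rows; ",
            "returning an empty profile set.", call. = FALSE)
    return(profile_set(tibble::tibble(
      organism = character(0), condition = character(0),
      fatty_acid = character(0), status = character(0), mean = numeric(0),
      sd = numeric(0), n_replicates = integer(0)
    )))
  }

  if (format == "long") {
    needed <- c("organism", "condition", "fatty_acid", "status")
    missing_cols <- setdiff(needed, names(raw))
    if (length(missing_cols) > 0L) {
      stop("Long-format profile file is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    out <- tibble::tibble(
      organism = raw$organism,
      condition = raw$condition,
      fatty_acid = raw$fatty_acid,
      status = raw$status,
      mean = as.numeric(raw$mean),
      sd = if ("sd" %in% names(raw)) as.numeric(raw$sd) else NA_real_,
      n_replicates = if ("n_replicates" %in% names(raw)) {
        as.integer(raw$n_replicates)
      } else {
        as.integer(n_replicates)
      },
      censor_threshold = if ("censor_threshold" %in% names(raw)) {
        as.numeric(raw$censor_threshold)
      } else {
        NA_real_
      }
    )
    return(profile_set(out))
  }

  id_cols <- intersect(c("organism", "condition", "n_replicates"),
                       names(raw))
  if (!all(c("organism", "condition") %in% id_cols)) {
    stop("Wide-format profile file needs 'organism' and 'condition' ",
         "columns.", call. = FALSE)
  }
  acid_cols <- setdiff(names(raw), id_cols)
  canonical_fa_label(acid_cols)  # validates every header; errors name the label

  key <- paste(raw$organism, raw$condition, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- raw[duplicated(key), ][1, ]
    stop("Duplicate profile for organism '", dup$organism,
         "', condition '", dup$condition, "'.", call. = FALSE)
  }

  long <- tidyr::pivot_longer(raw, dplyr::all_of(acid_cols),
                              names_to = "fatty_acid", values_to = "cell")
  parsed <- parse_profile_cell(long$cell)
  out <- tibble::tibble(
    organism = long$organism,
    condition = long$condition,
    fatty_acid = long$fatty_acid,
    status = parsed$status,
    mean = parsed$mean,
    sd = parsed$sd,
    n_replicates = if ("n_replicates" %in% names(long)) {
      as.integer(long$n_replicates)
    } else {
      as.integer(n_replicates)
    },
    censor_threshold = parsed$censor_threshold
  )
  profile_set(out)
}

# Shortest decimal representation that survives a read/write round trip.
format_number <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    s <- as.character(v)
    if (as.numeric(s) == v) s else sprintf("%.17g", v)
  }, character(1))
}

#' Write fatty-acid profiles to a TSV or CSV file
#'
#' Inverse of [read_profiles()]: writes either the wide dialect (cells
#' `"mean ± sd"`, `"nd"`, `"<1"`) or the tidy long dialect. Numbers are
#' written with enough digits for an exact round trip.
#'
#' @param profiles A [profile_set()].
#' @param path Output path (`.tsv` or `.csv`).
#' @param format `"wide"` (default) or `"long"`.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, format = c("wide", "long")) {
  format <- match.arg(format)
  stopifnot(inherits(profiles, "profile_set"))
  delim <- delim_for(path)
  if (format == "long") {
    out <- tibble::as_tibble(profiles)[
      , c("organism", "condition", "fatty_acid", "status", "mean", "sd",
          "n_replicates", "censor_threshold")]
    readr::write_delim(out, path, delim = delim, na = "")
    return(invisible(path))
  }
  cells <- dplyr::mutate(
    tibble::as_tibble(profiles),
    cell = dplyr::case_when(
      status == "not_detected" ~ "nd",
      status == "censored_below" ~ paste0("<", format_number(censor_threshold)),
      is.na(sd) ~ format_number(mean),
      TRUE ~ paste0(format_number(mean), " ± ", format_number(sd))
    )
  )
  acid_order <- sort_acids(unique(cells$fatty_acid))
  wide <- tidyr::pivot_wider(
    cells[, c("organism", "condition", "n_replicates", "fatty_acid", "cell")],
    names_from = "fatty_acid", values_from = "cell"
  )
  wide <- wide[, c("organism", "condition", "n_replicates", acid_order)]
  readr::write_delim(wide, path, delim = delim, na = "nd")
  invisible(path)
}
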