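# Fatty-acid shorthand nomenclature: "C<chain>:<n_db>[ cis|trans p1[, p2 ...]][ <p>OH ...]"
# e.g. "C18:2 cis 9, 12", "C16:0", "C18:0 3OH". Geometry defaults to cis when
# positions are listed without a cis/trans token (all tabulated unsaturated
# acids in food-spoilage fungi are cis).

#' Parse a fatty-acid shorthand label
#'
#' Parses labels of the form `"C<chain>:<n_db>"` optionally followed by
#' double-bond positions with geometry (`"cis 9, 12"`, `"trans 11"`) and
#' hydroxyl positions (`"3OH"`). Whitespace and comma spacing are flexible and
#' matching is case-insensitive; `"cis 9,12"` and `"cis 9, 12"` parse
#' identically.
#'
#' @param label A single character string in shorthand notation.
#'
#' @return An object of class `fatty_acid`: a list with elements
#'   `chain_length` (integer), `double_bonds` (tibble with columns `position`
#'   and `geometry`; positions may be `NA` when the label declares bonds
#'   without positions), `hydroxyl_positions` (integer vector) and `label`
#'   (the canonical label, see [format_fatty_acid()]).
#'
#' @details The declared double-bond count must match the number of listed
#'   positions (when positions are given), every position must be smaller than
#'   the chain length, and duplicate positions are rejected. Positions are
#'   stored sorted ascending. At most six double bonds are supported.
#'
#' @examples
#' parse_fatty_acid("C18:3 cis 9, 12, 15")
#' parse_fatty_acid("C18:0 3OH")
#' @export
parse_fatty_acid <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label) ||
      !nzchar(trimws(label))) {
    stop("`label` must be a single non-empty character string.", call. = FALSE)
  }
  x <- tolower(gsub("\\s+", " ", trimws(label)))

  head_match <- regmatches(x, regexec("^c ?([0-9]+) ?: ?([0-9]+)", x))[[1]]
  if (length(head_match) == 0L) {
    stop("Malformed fatty-acid label '", label,
         "': expected leading 'C<chain>:<double bonds>'.", call. = FALSE)
  }
  chain <- as.integer(head_match[[2]])
  n_db <- as.integer(head_match[[3]])
  if (chain < 2L) {
    stop("Malformed fatty-acid label '", label,
         "': chain length must be at least 2.", call. = FALSE)
  }
  if (n_db > 6L) {
    stop("Malformed fatty-acid label '", label,
         "': at most 6 double bonds are supported.", call. = FALSE)
  }

  rest <- trimws(substr(x, nchar(head_match[[1]]) + 1L, nchar(x)))
  tokens <- character(0)
  if (nzchar(rest)) {
    tokens <- strsplit(rest, "[ ,]+")[[1]]
    tokens <- tokens[nzchar(tokens)]
  }

  positions <- integer(0)
  geometries <- character(0)
  hydroxyls <- integer(0)
  geometry <- "cis"  # default when positions are listed without a token
  for (tok in tokens) {
    if (tok %in% c("cis", "trans")) {
      geometry <- tok
    } else if (grepl("^[0-9]+oh$", tok)) {
      hydroxyls <- c(hydroxyls, as.integer(sub("oh$", "", tok)))
    } else if (grepl("^[0-9]+$", tok)) {
      positions <- c(positions, as.integer(tok))
      geometries <- c(geometries, geometry)
    } else {
      stop("Malformed fatty-acid label '", label, "': unexpected token '",
           tok, "'.", call. = FALSE)
    }
  }

  if (length(positions) > 0L && length(positions) != n_db) {
    stop("Malformed fatty-acid label '", label, "': ", length(positions),
         " double-bond position(s) listed but ", n_db, " declared.",
         call. = FALSE)
  }
  if (anyDuplicated(positions)) {
    stop("Malformed fatty-acid label '", label,
         "': duplicate double-bond position.", call. = FALSE)
  }
  if (any(positions >= chain)) {
    stop("Malformed fatty-acid label '", label, "': position ",
         positions[which(positions >= chain)[1]],
         " is not smaller than the chain length ", chain, ".", call. = FALSE)
  }
  if (any(hydroxyls >= chain)) {
    stop("Malformed fatty-acid label '", label, "': hydroxyl position ",
         hydroxyls[which(hydroxyls >= chain)[1]],
         " is not smaller than the chain length ", chain, ".", call. = FALSE)
  }

  if (length(positions) > 0L) {
    ord <- order(positions)
    bonds <- tibble::tibble(position = positions[ord],
                            geometry = geometries[ord])
  } else if (n_db > 0L) {
    bonds <- tibble::tibble(position = rep(NA_integer_, n_db),
                            geometry = rep(NA_character_, n_db))
  } else {
    bonds <- tibble::tibble(position = integer(0), geometry = character(0))
  }

  fa <- structure(
    list(chain_length = chain,
         double_bonds = bonds,
         hydroxyl_positions = sort(unique(hydroxyls)),
         label = NA_character_),
    class = "fatty_acid"
  )
  fa$label <- format_fatty_acid(fa)
  fa
}

#' Format a fatty acid as its canonical shorthand label
#'
#' The canonical form is `"C<chain>:<n_db>"` followed, when double-bond
#' positions are known, by runs of positions grouped by geometry
#' (`"cis 9, 12"`), and by hydroxyl positions as `"<p>OH"`. Parsing the
#' canonical label reproduces an identical [fatty_acid][parse_fatty_acid()].
#'
#' @param fa A `fatty_acid` object.
#' @return A character scalar.
#' @export
format_fatty_acid <- function(fa) {
  stopifnot(inherits(fa, "fatty_acid"))
  out <- sprintf("C%d:%d", fa$chain_length, nrow(fa$double_bonds))
  bonds <- fa$double_bonds
  if (nrow(bonds) > 0L && !anyNA(bonds$position)) {
    run <- rle(bonds$geometry)
    idx <- 1L
    parts <- character(0)
    for (k in seq_along(run$lengths)) {
      pos <- bonds$position[idx:(idx + run$lengths[k] - 1L)]
      parts <- c(parts, paste(run$values[k], paste(pos, collapse = ", ")))
      idx <- idx + run$lengths[k]
    }
    out <- paste(out, paste(parts, collapse = " "))
  }
  if (length(fa$hydroxyl_positions) > 0L) {
    out <- paste(out, paste0(fa$hydroxyl_positions, "OH", collapse = " "))
  }
  out
}

#' @export
format.fatty_acid <- function(x, ...) x$label

#' @export
print.fatty_acid <- function(x, ...) {
  cat("<fatty_acid> ", x$label, "\n", sep = "")
  cat("  chain length: ", x$chain_length, "\n", sep = "")
  cat("  double bonds: ", nrow(x$double_bonds), "\n", sep = "")
  if (length(x$hydroxyl_positions)) {
    cat("  hydroxyls at: ", paste(x$hydroxyl_positions, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
`==.fatty_acid` <- function(e1, e2) {
  identical(e1$label, e2$label)
}

#' Canonicalize fatty-acid labels
#'
#' Vectorised convenience wrapper: parses each label and returns its canonical
#' form, so that spelling variants map to a single table key.
#'
#' @param labels Character vector of shorthand labels.
#' @return Character vector of canonical labels.
#' @export
canonical_fa_label <- function(labels) {
  vapply(labels, function(l) parse_fatty_acid(l)$label, character(1),
         USE.NAMES = FALSE)
}

#' Number of double bonds of a fatty acid
#'
#' @param x A `fatty_acid` object or a character vector of labels.
#' @return Integer vector of double-bond counts.
#' @export
n_double_bonds <- function(x) {
  if (inherits(x, "fatty_acid")) return(nrow(x$double_bonds))
  vapply(x, function(l) nrow(parse_fatty_acid(l)$double_bonds), integer(1),
         USE.NAMES = FALSE)
}

#' Unsaturation class of a fatty acid
#'
#' Classifies acids by double-bond count alone (hydroxylation is ignored):
#' 0 bonds `"saturated"`, 1 `"monoene"`, 2 `"diene"`, 3 `"triene"`, 4 or more
#' `"polyene_4plus"`. These classes carry the per-acid weights of the degree
#' of unsaturation.
#'
#' @inheritParams n_double_bonds
#' @return Character vector of class names.
#' @export
unsaturation_class <- function(x) {
  k <- n_double_bonds(x)
  dplyr::case_when(
    k == 0L ~ "saturated",
    k == 1L ~ "monoene",
    k == 2L ~ "diene",
    k == 3L ~ "triene",
    TRUE ~ "polyene_4plus"
  )
}
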