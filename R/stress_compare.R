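# Condition contrasts: per-acid composition changes between growth
# conditions (e.g. 20% CO2 at 10 C versus normal atmosphere at 10 C),
# per-organism normalisation for heatmap display, Welch tests on replicate
# summary statistics, and a per-organism classification of the membrane
# response as fluidization or solidification.

#' Per-acid condition differences for every organism
#'
#' Builds the organisms-by-fatty-acids matrix of composition changes between
#' two growth conditions. Cell values are differences of mean percentages
#' (condition_a minus condition_b, so positive = higher under
#' `condition_a`), with censored cells resolved by the zero policy. An acid
#' is `NA` (not applicable) when it is censored or undetected in *both*
#' conditions — it is a trace component with no interpretable change; an
#' acid quantified in only one condition keeps a real change from or to
#' trace level.
#'
#' @param profiles A [profile_set()].
#' @param contrast Character vector of two condition labels
#'   `c(condition_a, condition_b)`.
#' @param censor_policy Passed to the percentage resolution; default
#'   `"zero"`.
#'
#' @return A `delta_matrix`: a numeric matrix with organisms as rows and
#'   canonical fatty-acid labels as columns (ordered by chain length, then
#'   double-bond count, then first position), with attributes `contrast` and
#'   `normalized = FALSE`. Organisms missing either condition are dropped
#'   with a warning.
#' @export
delta_matrix <- function(profiles, contrast = c("co2_10C", "control_10C"),
                         censor_policy = c("zero", "midpoint")) {
  censor_policy <- match.arg(censor_policy)
  stopifnot(inherits(profiles, "profile_set"), length(contrast) == 2L)
  available <- unique(profiles$condition)
  unknown <- setdiff(contrast, available)
  if (length(unknown) > 0L) {
    stop("Unknown condition '", unknown[1], "'; available conditions: ",
         paste(sort(available), collapse = ", "), call. = FALSE)
  }

  sub <- profiles[profiles$condition %in% contrast, , drop = FALSE]
  has_both <- tapply(sub$condition, sub$organism,
                     function(cc) all(contrast %in% cc))
  dropped <- names(has_both)[!has_both]
  if (length(dropped) > 0L) {
    warning("Dropping organism(s) without both contrast conditions: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(unique(sub$organism), dropped)
  sub <- sub[sub$organism %in% keep, , drop = FALSE]

  acids <- sort_acids(unique(sub$fatty_acid))
  organisms <- unique(sub$organism)

  cell <- function(org, acid, cond) {
    row <- sub[sub$organism == org & sub$fatty_acid == acid &
                 sub$condition == cond, , drop = FALSE]
    if (nrow(row) == 0L) {
      list(pct = 0, quantified = FALSE)
    } else {
      list(pct = resolve_percentages(row$status, row$mean,
                                     row$censor_threshold, censor_policy),
           quantified = row$status == "quantified")
    }
  }

  m <- matrix(NA_real_, nrow = length(organisms), ncol = length(acids),
              dimnames = list(organisms, acids))
  for (org in organisms) {
    for (acid in acids) {
      a <- cell(org, acid, contrast[1])
      b <- cell(org, acid, contrast[2])
      if (a$quantified || b$quantified) {
        m[org, acid] <- a$pct - b$pct
      }
    }
  }
  structure(m, contrast = contrast, normalized = FALSE,
            class = c("delta_matrix", "matrix", "array"))
}

# Order acid labels by chain length, then double-bond count, then first
# double-bond position (so the two C18:3 isomers sit side by side).
sort_acids <- function(labels) {
  parsed <- lapply(labels, parse_fatty_acid)
  chain <- vapply(parsed, function(f) f$chain_length, integer(1))
  ndb <- vapply(parsed, function(f) nrow(f$double_bonds), integer(1))
  first_pos <- vapply(parsed, function(f) {
    p <- f$double_bonds$position
    if (length(p) == 0L || anyNA(p)) 0L else p[1]
  }, integer(1))
  n_oh <- vapply(parsed, function(f) length(f$hydroxyl_positions), integer(1))
  labels[order(chain, ndb, first_pos, n_oh)]
}

#' Normalize a delta matrix per organism
#'
#' Divides every organism's row by its maximum absolute applicable delta, so
#' each organism's strongest change has magnitude 1 and organisms with small
#' absolute shifts remain comparable on a heatmap (the `"zscore"` variant
#' centres and scales each row instead). All-zero rows and `NA` cells are
#' left unchanged; normalizing an already normalized matrix is a no-op.
#'
#' @param m A `delta_matrix` from [delta_matrix()].
#' @param method `"max-abs"` (default) or `"zscore"`.
#' @return The normalized `delta_matrix` (attribute `normalized = TRUE`).
#' @export
normalize_deltas <- function(m, method = c("max-abs", "zscore")) {
  method <- match.arg(method)
  stopifnot(inherits(m, "delta_matrix"))
  if (isTRUE(attr(m, "normalized"))) {
    return(m)
  }
  out <- m
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    if (all(is.na(row))) next
    if (method == "max-abs") {
      scale <- max(abs(row), na.rm = TRUE)
      if (scale > 0) out[i, ] <- row / scale
    } else {
      mu <- mean(row, na.rm = TRUE)
      sdev <- stats::sd(row, na.rm = TRUE)
      if (!is.na(sdev) && sdev > 0) out[i, ] <- (row - mu) / sdev
    }
  }
  attr(out, "normalized") <- TRUE
  attr(out, "normalization") <- method
  out
}

#' @export
print.delta_matrix <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat("<delta_matrix> ", ct[1], " - ", ct[2],
      if (isTRUE(attr(x, "normalized"))) " (normalized)" else "",
      ": ", nrow(x), " organism(s) x ", ncol(x), " fatty acid(s)\n", sep = "")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Convert a delta matrix to a tidy tibble
#'
#' @param m A `delta_matrix`.
#' @return A tibble with columns `organism`, `fatty_acid`, `delta`
#'   (`NA` = not applicable).
#' @export
delta_to_long <- function(m) {
  stopifnot(inherits(m, "delta_matrix"))
  tibble::tibble(
    organism = rep(rownames(m), times = ncol(m)),
    fatty_acid = rep(colnames(m), each = nrow(m)),
    delta = as.vector(m)
  )
}

#' Write a delta matrix to CSV
#'
#' @param m A `delta_matrix`.
#' @param path Output path.
#' @param format `"wide"` (organisms x acids, `NA` for not applicable) or
#'   `"long"` (tidy).
#' @return `path`, invisibly.
#' @export
write_delta_matrix <- function(m, path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "wide") {
    df <- tibble::as_tibble(unclass(m), rownames = "organism")
    readr::write_csv(df, path, na = "NA")
  } else {
    readr::write_csv(delta_to_long(m), path, na = "NA")
  }
  invisible(path)
}

#' Welch's t-test from replicate summary statistics
#'
#' Two-sided unequal-variance t-test computed directly from per-group mean,
#' standard deviation and replicate count — the form in which biological
#' triplicate measurements are reported. Identical groups give p = 1.
#'
#' @param mean_a,sd_a,n_a Summary statistics of group A.
#' @param mean_b,sd_b,n_b Summary statistics of group B.
#' @return An object of class `htest` with elements `statistic` (t),
#'   `parameter` (Welch-Satterthwaite degrees of freedom) and `p.value`.
#' @export
replicate_test <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (any(c(n_a, n_b) < 2)) {
    stop("Welch test needs at least 2 replicates per group.", call. = FALSE)
  }
  if (any(c(sd_a, sd_b) < 0) || anyNA(c(sd_a, sd_b))) {
    stop("Standard deviations must be non-negative numbers.", call. = FALSE)
  }
  if (sd_a == 0 && sd_b == 0) {
    stop("Degenerate groups: both standard deviations are zero.",
         call. = FALSE)
  }
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  tstat <- (mean_a - mean_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(
    list(statistic = c(t = tstat), parameter = c(df = df), p.value = p,
         method = "Welch two-sample t-test from summary statistics",
         data.name = sprintf("group A (n=%d) vs group B (n=%d)", n_a, n_b),
         estimate = c(`mean difference` = mean_a - mean_b),
         alternative = "two.sided"),
    class = "htest"
  )
}

#' Per-organism summary of membrane adaptation under a condition contrast
#'
#' For every organism with both contrast conditions, computes the change in
#' the degree of unsaturation (`delta_du`) and in the weighted average
#' melting temperature (`delta_wamt`, degrees C), classifies the response
#' direction, and runs per-acid Welch tests on the replicate summary
#' statistics of all acids quantified in both conditions.
#'
#' Direction: `delta_wamt < -tol` is `"fluidization"` (the membrane shifted
#' toward lower-melting acids), `delta_wamt > tol` is `"solidification"`,
#' otherwise `"unchanged"`.
#'
#' @inheritParams delta_matrix
#' @param table Melting-point table used for WAMT.
#' @param alpha Significance level for counting significant acids
#'   (default 0.05).
#' @param tol Dead band (degrees C) around zero for the direction call
#'   (default 0.05).
#' @param p_adjust `"none"` (default; per-acid tests are reported
#'   uncorrected, matching common practice for per-acid claims) or any
#'   method of [stats::p.adjust()] such as `"BH"`.
#'
#' @return A tibble with one row per organism: `organism`, `delta_du`,
#'   `delta_wamt`, `direction`, `n_significant`, and a list column `tests`
#'   (per-acid tibble of `fatty_acid`, `delta`, `p_value`).
#' @export
adaptation_summary <- function(profiles,
                               contrast = c("co2_10C", "control_10C"),
                               table = default_melting_table(),
                               alpha = 0.05, tol = 0.05,
                               censor_policy = c("zero", "midpoint"),
                               p_adjust = "none") {
  censor_policy <- match.arg(censor_policy)
  stopifnot(inherits(profiles, "profile_set"), length(contrast) == 2L)
  stats_tbl <- summarize_profiles(profiles, table, censor_policy)
  sub <- stats_tbl[stats_tbl$condition %in% contrast, ]
  wide_du <- tidyr::pivot_wider(sub[, c("organism", "condition", "du")],
                                names_from = "condition",
                                values_from = "du")
  wide_wamt <- tidyr::pivot_wider(sub[, c("organism", "condition", "wamt")],
                                  names_from = "condition",
                                  values_from = "wamt")
  keep <- stats::complete.cases(wide_du[, contrast])
  organisms <- wide_du$organism[keep]

  tests_per_org <- lapply(organisms, function(org) {
    a <- profiles[profiles$organism == org &
                    profiles$condition == contrast[1], ]
    b <- profiles[profiles$organism == org &
                    profiles$condition == contrast[2], ]
    both <- merge(
      a[a$status == "quantified",
        c("fatty_acid", "mean", "sd", "n_replicates")],
      b[b$status == "quantified",
        c("fatty_acid", "mean", "sd", "n_replicates")],
      by = "fatty_acid", suffixes = c("_a", "_b")
    )
    testable <- !is.na(both$sd_a) & !is.na(both$sd_b) &
      (both$sd_a > 0 | both$sd_b > 0) &
      !is.na(both$n_replicates_a) & both$n_replicates_a >= 2 &
      !is.na(both$n_replicates_b) & both$n_replicates_b >= 2
    both <- both[testable, , drop = FALSE]
    p <- vapply(seq_len(nrow(both)), function(i) {
      replicate_test(both$mean_a[i], both$sd_a[i], both$n_replicates_a[i],
                     both$mean_b[i], both$sd_b[i],
                     both$n_replicates_b[i])$p.value
    }, numeric(1))
    tibble::tibble(fatty_acid = both$fatty_acid,
                   delta = both$mean_a - both$mean_b,
                   p_value = stats::p.adjust(p, method = p_adjust))
  })

  delta_du <- wide_du[[contrast[1]]][keep] - wide_du[[contrast[2]]][keep]
  delta_wamt <- wide_wamt[[contrast[1]]][match(organisms,
                                               wide_wamt$organism)] -
    wide_wamt[[contrast[2]]][match(organisms, wide_wamt$organism)]
  tibble::tibble(
    organism = organisms,
    delta_du = delta_du,
    delta_wamt = delta_wamt,
    direction = dplyr::case_when(
      delta_wamt < -tol ~ "fluidization",
      delta_wamt > tol ~ "solidification",
      TRUE ~ "unchanged"
    ),
    n_significant = vapply(tests_per_org,
                           function(t) sum(t$p_value < alpha), integer(1)),
    tests = tests_per_org
  ) |>
    dplyr::arrange(.data$organism)
}
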