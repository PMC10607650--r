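# Synthetic replicate fatty-acid profiles with known condition effects.
# The generator emulates the design of the packaged study: three growth
# conditions (20% CO2 at 10 C, control at 10 C, control at 25 C), three
# biological replicates, compositions closed to 100%, per-acid noise on the
# percentage-point scale seen in real GC-FID tables (0.1-8 points). The CO2
# effect moves mass from oleic and palmitic acid toward linoleic and
# linolenic acid; the warm-temperature effect is the reverse.

DEFAULT_ACIDS <- c(
  "C14:0", "C16:0", "C16:1 cis 9", "C18:0", "C18:1 cis 9", "C18:1 cis 11",
  "C18:2 cis 9, 12", "C18:3 cis 9, 12, 15", "C18:3 cis 6, 9, 12",
  "C18:0 3OH"
)

default_baseline <- function() {
  c("C14:0" = 1, "C16:0" = 15, "C16:1 cis 9" = 8, "C18:0" = 3,
    "C18:1 cis 9" = 40, "C18:1 cis 11" = 1.5, "C18:2 cis 9, 12" = 20,
    "C18:3 cis 9, 12, 15" = 10, "C18:3 cis 6, 9, 12" = 0.5,
    "C18:0 3OH" = 1)
}

default_effect_co2 <- function() {
  eff <- stats::setNames(numeric(length(DEFAULT_ACIDS)), DEFAULT_ACIDS)
  eff["C18:3 cis 9, 12, 15"] <- 6
  eff["C18:2 cis 9, 12"] <- 4
  eff["C18:1 cis 9"] <- -7
  eff["C16:0"] <- -3
  eff
}

default_effect_temp <- function() {
  eff <- stats::setNames(numeric(length(DEFAULT_ACIDS)), DEFAULT_ACIDS)
  eff["C18:3 cis 9, 12, 15"] <- -4
  eff["C18:2 cis 9, 12"] <- -3
  eff["C18:1 cis 9"] <- 5
  eff["C16:0"] <- 2
  eff
}

#' Specification for a synthetic profile-set generator
#'
#' Defines the ground truth of a simulated experiment: a baseline
#' composition (percent, closed to 100), signed per-acid effect vectors for
#' the CO2 and warm-temperature contrasts (percentage points, each summing
#' to zero), per-acid noise scales, and the replicate count.
#'
#' @param organisms Number of organisms to simulate (default 20, the size of
#'   the packaged study).
#' @param acids Character vector of canonical fatty-acid labels.
#' @param baseline_mean Named composition vector summing to 100.
#' @param effect_co2,effect_temp Named signed shift vectors in percentage
#'   points, each summing to zero, applied to the baseline under the
#'   `co2_10C` and `control_25C` conditions respectively. `baseline + effect`
#'   must be non-negative elementwise.
#' @param noise_sd Per-acid noise scale in percentage points; the default
#'   scales with abundance and stays within the 0.1-8 point range typical of
#'   replicate GC-FID tables.
#' @param n_replicates Biological replicates per profile (default 3).
#' @param seed Master seed; per-organism random streams are derived from it
#'   so that changing the organism count does not reshuffle earlier
#'   organisms.
#'
#' @return A validated object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(organisms = 20,
                           acids = DEFAULT_ACIDS,
                           baseline_mean = default_baseline(),
                           effect_co2 = default_effect_co2(),
                           effect_temp = default_effect_temp(),
                           noise_sd = NULL,
                           n_replicates = 3,
                           seed = 1) {
  acids <- canonical_fa_label(acids)
  align <- function(v, what) {
    if (is.null(names(v))) {
      if (length(v) != length(acids)) {
        stop("`", what, "` must be named or have one value per acid.",
             call. = FALSE)
      }
      names(v) <- acids
      return(v)
    }
    names(v) <- canonical_fa_label(names(v))
    out <- stats::setNames(numeric(length(acids)), acids)
    unknown <- setdiff(names(v), acids)
    if (length(unknown) > 0L) {
      stop("`", what, "` names acid '", unknown[1],
           "' that is not in `acids`.", call. = FALSE)
    }
    out[names(v)] <- v
    out
  }
  baseline_mean <- align(baseline_mean, "baseline_mean")
  effect_co2 <- align(effect_co2, "effect_co2")
  effect_temp <- align(effect_temp, "effect_temp")
  if (is.null(noise_sd)) {
    noise_sd <- pmin(8, pmax(0.1, 0.15 * baseline_mean))
  }
  noise_sd <- align(noise_sd, "noise_sd")

  if (any(baseline_mean < 0)) {
    stop("`baseline_mean` must be non-negative.", call. = FALSE)
  }
  if (abs(sum(baseline_mean) - 100) > 1e-9) {
    stop("`baseline_mean` must sum to 100 (got ", sum(baseline_mean), ").",
         call. = FALSE)
  }
  for (eff_name in c("effect_co2", "effect_temp")) {
    eff <- get(eff_name)
    if (abs(sum(eff)) > 1e-9) {
      stop("`", eff_name, "` must sum to zero.", call. = FALSE)
    }
    if (any(baseline_mean + eff < 0)) {
      stop("`baseline_mean + ", eff_name,
           "` must be non-negative elementwise.", call. = FALSE)
    }
  }
  if (any(noise_sd <= 0)) {
    stop("`noise_sd` must be positive.", call. = FALSE)
  }
  if (organisms < 1 || n_replicates < 1) {
    stop("`organisms` and `n_replicates` must be positive.", call. = FALSE)
  }

  structure(
    list(organisms = as.integer(organisms), acids = acids,
         baseline_mean = baseline_mean, effect_co2 = effect_co2,
         effect_temp = effect_temp, noise_sd = noise_sd,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Read a synthetic-generator specification from YAML or JSON
#'
#' @param path Path to a YAML (or JSON) file whose fields match the
#'   arguments of [synthetic_spec()]; vectors may be given as named maps.
#' @return A validated `synthetic_spec`.
#' @export
read_synthetic_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  to_named <- function(x) {
    if (is.list(x)) unlist(x) else x
  }
  do.call(synthetic_spec, c(
    cfg[intersect(names(cfg), c("organisms", "n_replicates", "seed",
                                "acids"))],
    lapply(cfg[intersect(names(cfg),
                         c("baseline_mean", "effect_co2", "effect_temp",
                           "noise_sd"))], to_named)
  ))
}

# Deterministic per-organism seed derived from the master seed; kept below
# 2^31 - 1. The multiplier spreads consecutive organisms far apart.
organism_seed <- function(seed, i) {
  as.integer((as.double(seed) + 7919 * as.double(i)) %% 2147483647)
}

#' Generate a synthetic profile set with known ground truth
#'
#' For each organism and condition, draws `n_replicates` compositions by
#' perturbing the condition mean (baseline plus the applicable effect
#' vector) with independent per-acid Gaussian noise, clipping negative
#' intermediate draws to zero (trace acids can vanish, mirroring "nd"
#' cells), and closing each replicate to exactly 100%. The generation is
#' deterministic for a fixed seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements:
#'   * `profiles`: a [profile_set()] with replicate-level data (list column
#'     `replicates`), conditions `co2_10C`, `control_10C`, `control_25C`;
#'   * `truth`: tibble of true effect signs per organism, acid and contrast
#'     (`co2_10C-control_10C`, `control_25C-control_10C`);
#'   * `delta_du`: the analytic DU shift implied by each effect vector.
#' @export
generate_profiles <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  acids <- spec$acids
  bonds <- n_double_bonds(acids)
  cond_means <- list(
    co2_10C = spec$baseline_mean + spec$effect_co2,
    control_10C = spec$baseline_mean,
    control_25C = spec$baseline_mean + spec$effect_temp
  )
  org_names <- sprintf("org%02d", seq_len(spec$organisms))

  rows <- vector("list", spec$organisms)
  for (i in seq_len(spec$organisms)) {
    set.seed(organism_seed(spec$seed, i))
    per_cond <- lapply(names(cond_means), function(cond) {
      mu <- cond_means[[cond]]
      reps <- vapply(seq_len(spec$n_replicates), function(r) {
        x <- pmax(0, stats::rnorm(length(acids), mu, spec$noise_sd))
        100 * x / sum(x)
      }, numeric(length(acids)))
      # reps: acids x replicates
      means <- rowMeans(reps)
      sds <- apply(reps, 1, stats::sd)
      tibble::tibble(
        organism = org_names[i],
        condition = cond,
        fatty_acid = acids,
        status = ifelse(means > 0, "quantified", "not_detected"),
        mean = ifelse(means > 0, means, NA_real_),
        sd = ifelse(means > 0, sds, NA_real_),
        n_replicates = spec$n_replicates,
        replicates = lapply(seq_along(acids), function(k) reps[k, ])
      )
    })
    rows[[i]] <- dplyr::bind_rows(per_cond)
  }
  profiles <- profile_set(dplyr::bind_rows(rows))

  truth <- dplyr::bind_rows(lapply(
    c(co2 = "co2_10C", temp = "control_25C"),
    function(cond) {
      eff <- if (cond == "co2_10C") spec$effect_co2 else spec$effect_temp
      tidyr::expand_grid(organism = org_names, fatty_acid = acids) |>
        dplyr::mutate(
          contrast = paste0(cond, "-control_10C"),
          effect = eff[.data$fatty_acid],
          effect_sign = sign(.data$effect)
        )
    }
  ))
  delta_du <- c(
    `co2_10C-control_10C` = sum(bonds * spec$effect_co2) / 100,
    `control_25C-control_10C` = sum(bonds * spec$effect_temp) / 100
  )
  list(profiles = profiles, truth = truth, delta_du = delta_du)
}

#' Sign-recovery and false-positive rates of the per-acid Welch test
#'
#' Runs [replicate_test()] on every (organism, acid) cell of a synthetic set
#' under one contrast and scores it against the generator's ground truth:
#' the *recovery rate* is the fraction of truly shifted cells that are both
#' significant at `alpha` and of the true sign; the *false-positive rate* is
#' the rejection rate among truly null cells.
#'
#' @param profiles A [profile_set()] generated by [generate_profiles()].
#' @param truth The matching ground-truth tibble.
#' @param alpha Significance level (default 0.05).
#' @param contrast Two condition labels (default CO2 versus 10 C control).
#' @return A list with `recovery_rate`, `false_positive_rate`,
#'   `n_effect_cells`, `n_null_cells` and the per-cell tibble `cells`.
#'   A warning is issued when fewer than 3 replicates are available (the
#'   test is valid but severely under-powered).
#' @export
sign_recovery_rate <- function(profiles, truth, alpha = 0.05,
                               contrast = c("co2_10C", "control_10C")) {
  stopifnot(inherits(profiles, "profile_set"))
  contrast_id <- paste0(contrast[1], "-", contrast[2])
  tr <- truth[truth$contrast == contrast_id, ]
  if (nrow(tr) == 0L) {
    stop("Ground truth has no rows for contrast '", contrast_id, "'.",
         call. = FALSE)
  }
  if (any(profiles$n_replicates < 3, na.rm = TRUE)) {
    warning("Fewer than 3 replicates in some profiles; ",
            "sign-recovery rates will be low-powered.", call. = FALSE)
  }

  get_cells <- function(cond) {
    sub <- profiles[profiles$condition == cond, ]
    stats::setNames(
      sub[, c("organism", "fatty_acid", "status", "mean", "sd",
              "n_replicates")],
      c("organism", "fatty_acid", paste0(c("status", "mean", "sd", "n"),
                                         "_", cond))
    )
  }
  cells <- merge(get_cells(contrast[1]), get_cells(contrast[2]),
                 by = c("organism", "fatty_acid"))
  cells <- merge(cells, tr[, c("organism", "fatty_acid", "effect_sign")],
                 by = c("organism", "fatty_acid"))
  sa <- cells[[paste0("sd_", contrast[1])]]
  sb <- cells[[paste0("sd_", contrast[2])]]
  ma <- cells[[paste0("mean_", contrast[1])]]
  mb <- cells[[paste0("mean_", contrast[2])]]
  na_ <- cells[[paste0("n_", contrast[1])]]
  nb_ <- cells[[paste0("n_", contrast[2])]]
  testable <- !is.na(sa) & !is.na(sb) & (sa > 0 | sb > 0) &
    na_ >= 2 & nb_ >= 2
  p <- rep(NA_real_, nrow(cells))
  p[testable] <- vapply(which(testable), function(i) {
    replicate_test(ma[i], sa[i], na_[i], mb[i], sb[i], nb_[i])$p.value
  }, numeric(1))
  obs_sign <- sign(ifelse(is.na(ma), 0, ma) - ifelse(is.na(mb), 0, mb))

  out <- tibble::tibble(
    organism = cells$organism, fatty_acid = cells$fatty_acid,
    effect_sign = cells$effect_sign, observed_sign = obs_sign, p_value = p
  )
  effect_cells <- out[out$effect_sign != 0, ]
  null_cells <- out[out$effect_sign == 0, ]
  hit <- !is.na(effect_cells$p_value) & effect_cells$p_value < alpha &
    effect_cells$observed_sign == effect_cells$effect_sign
  fp <- !is.na(null_cells$p_value) & null_cells$p_value < alpha
  list(
    recovery_rate = if (nrow(effect_cells) > 0) mean(hit) else NA_real_,
    false_positive_rate = if (nrow(null_cells) > 0) mean(fp) else NA_real_,
    n_effect_cells = nrow(effect_cells),
    n_null_cells = nrow(null_cells),
    cells = out
  )
}
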