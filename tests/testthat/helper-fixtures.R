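# In-code fixtures and independent oracles shared across test files.

# Build a profile_set for a single organism/condition from a named vector of
# quantified mean percentages (sd defaults to 0.5, n to 3).
make_profile <- function(pcts, organism = "orgA", condition = "control_10C",
                         sd = 0.5, n = 3, check_sums = FALSE) {
  profile_set(tibble::tibble(
    organism = organism, condition = condition,
    fatty_acid = names(pcts), status = "quantified",
    mean = unname(pcts), sd = sd, n_replicates = n
  ), check_sums = check_sums)
}

# Random valid shorthand label (chain, bonds with positions/geometry,
# optional hydroxyl), for parser round-trip properties.
random_fa_label <- function() {
  chain <- sample(12:24, 1)
  ndb <- sample(0:6, 1)
  lbl <- sprintf("C%d:%d", chain, ndb)
  if (ndb > 0) {
    pos <- sort(sample(2:(chain - 1), ndb))
    geom <- sample(c("cis", "trans"), 1)
    lbl <- paste0(lbl, " ", geom, " ", paste(pos, collapse = ", "))
  }
  if (stats::runif(1) < 0.2) lbl <- paste0(lbl, " 3OH")
  lbl
}

# Independent DU oracle: bond counts read straight off the label text (the
# declared count after the colon), never through the package parser.
brute_force_du <- function(labels, pcts) {
  counts <- as.integer(sub("^[Cc]\\s*[0-9]+\\s*:\\s*([0-9]+).*$", "\\1",
                           labels))
  sum(counts * pcts) / 100
}

# Independent Welch oracle: three data points {m, m - s, m + s} have sample
# mean m and sample sd s exactly, so stats::t.test on reconstructed triples
# reproduces the summary-statistic Welch test for n = 3.
welch_oracle_p <- function(mean_a, sd_a, mean_b, sd_b) {
  x <- c(mean_a, mean_a - sd_a, mean_a + sd_a)
  y <- c(mean_b, mean_b - sd_b, mean_b + sd_b)
  stats::t.test(x, y)$p.value
}

fixture_profiles <- function() load_fungal_profiles()
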