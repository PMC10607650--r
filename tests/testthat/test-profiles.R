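test_that("degree of unsaturation reproduces published worked examples", {
  # C. zeylanoides LR1 under CO2 at 10 C, "<1" resolved to zero
  lr1 <- profile_set(tibble::tibble(
    organism = "LR1", condition = "co2_10C",
    fatty_acid = c("C16:0", "C16:1 cis 9", "C18:0", "C18:1 cis 9",
                   "C18:2 cis 9, 12", "C18:3 cis 9, 12, 15"),
    status = c("quantified", "quantified", "censored_below", "quantified",
               "quantified", "quantified"),
    mean = c(10.4, 8.9, NA, 38.7, 24.8, 17.3),
    sd = c(0.5, 1.8, NA, 3.1, 1.9, 2.6),
    n_replicates = 3
  ))
  expect_equal(round(degree_of_unsaturation(lr1)$du, 2), 1.49)

  # P. rubens DSM 1075 under CO2 at 10 C
  dsm <- make_profile(c("C16:0" = 8.9, "C18:0" = 6.8, "C18:1 cis 9" = 4.2,
                        "C18:2 cis 9, 12" = 47.3,
                        "C18:3 cis 9, 12, 15" = 32.8))
  expect_equal(round(degree_of_unsaturation(dsm)$du, 2), 1.97)

  # fully saturated profile
  sat <- make_profile(c("C14:0" = 30, "C16:0" = 50, "C18:0" = 20))
  expect_equal(degree_of_unsaturation(sat)$du, 0)
})

test_that("DU equals the brute-force bond-count sum on random profiles", {
  set.seed(11)
  acids <- c("C14:0", "C16:1 cis 9", "C18:1 cis 11", "C18:2 cis 9, 12",
             "C18:3 cis 6, 9, 12", "C20:4 5, 8, 11, 14", "C18:0 3OH")
  for (i in 1:25) {
    k <- sample(3:length(acids), 1)
    labels <- sample(acids, k)
    pct <- as.numeric(stats::rmultinom(1, 1000, rep(1, k))) / 10
    labels <- labels[pct > 0]; pct <- pct[pct > 0]
    prof <- make_profile(stats::setNames(pct, labels))
    expect_equal(degree_of_unsaturation(prof)$du,
                 brute_force_du(labels, pct), tolerance = 1e-12)
  }
})

test_that("DU is linear in composition shifts and respects censor policy", {
  base <- c("C16:0" = 40, "C18:3 cis 9, 12, 15" = 10, "C18:1 cis 9" = 50)
  shifted <- base + c(-5, 5, 0)
  du0 <- degree_of_unsaturation(make_profile(base))$du
  du1 <- degree_of_unsaturation(make_profile(shifted))$du
  expect_equal(du1 - du0, 3 * 5 / 100, tolerance = 1e-12)

  censored <- profile_set(tibble::tibble(
    organism = "x", condition = "c",
    fatty_acid = c("C16:0", "C18:3 cis 9, 12, 15"),
    status = c("quantified", "censored_below"),
    mean = c(99, NA), sd = 0.1, n_replicates = 3
  ))
  expect_equal(degree_of_unsaturation(censored, "zero")$du, 0)
  expect_equal(degree_of_unsaturation(censored, "midpoint")$du, 3 * 0.5 / 100)
})

test_that("WAMT collapses, averages and stays within covered-acid bounds", {
  tbl <- default_melting_table()
  single <- make_profile(c("C16:0" = 100))
  w <- wamt(single, tbl)
  expect_equal(w$wamt, melting_temperature("C16:0", tbl))
  expect_equal(w$wamt_coverage, 1.0)

  pair <- make_profile(c("C16:0" = 50, "C18:1 cis 9" = 50))
  expect_equal(wamt(pair, tbl)$wamt,
               mean(melting_temperature(c("C16:0", "C18:1 cis 9"), tbl)))

  set.seed(21)
  for (i in 1:10) {
    k <- sample(2:8, 1)
    labels <- sample(tbl$canonical_label, k)
    pct <- as.numeric(stats::rmultinom(1, 1000, rep(1, k))) / 10
    labels <- labels[pct > 0]; pct <- pct[pct > 0]
    w <- wamt(make_profile(stats::setNames(pct, labels)), tbl)
    temps <- melting_temperature(labels, tbl)
    expect_gte(w$wamt, min(temps))
    expect_lte(w$wamt, max(temps))
  }
})

test_that("replacing a saturated acid by a lower-melting one lowers WAMT", {
  tbl <- default_melting_table()
  for (target in c("C16:1 cis 9", "C18:1 cis 9", "C18:2 cis 9, 12",
                   "C18:3 cis 9, 12, 15")) {
    before <- make_profile(stats::setNames(c(60, 40), c("C16:0", target)))
    after <- make_profile(stats::setNames(c(50, 50), c("C16:0", target)))
    expect_lt(wamt(after, tbl)$wamt, wamt(before, tbl)$wamt)
  }
})

test_that("WAMT renormalizes over covered acids and reports coverage", {
  tbl <- default_melting_table()
  prof <- make_profile(c("C16:0" = 50, "C22:0" = 50))  # C22:0 not in table
  w <- wamt(prof, tbl)
  expect_equal(w$wamt, melting_temperature("C16:0", tbl))
  expect_equal(w$wamt_coverage, 0.5)

  uncovered <- make_profile(c("C22:0" = 100))
  expect_error(wamt(uncovered, tbl), "No melting temperatures")
})

test_that("summarize covers the packaged study and empty sets", {
  profiles <- fixture_profiles()
  s <- summarize_profiles(profiles)
  expect_equal(nrow(s), 60L)
  expect_equal(length(unique(s$organism)), 20L)
  expect_true(all(s$wamt_coverage == 1))
  expect_true(all(s$du >= 0 & s$du <= 3))

  empty <- profile_set(tibble::tibble(
    organism = character(0), condition = character(0),
    fatty_acid = character(0), status = character(0), mean = numeric(0),
    sd = numeric(0), n_replicates = integer(0)))
  expect_equal(nrow(summarize_profiles(empty)), 0L)
})

test_that("profile validation enforces the compositional contract", {
  bad_mean <- tibble::tibble(
    organism = "x", condition = "c", fatty_acid = "C16:0",
    status = "quantified", mean = 120, sd = 1, n_replicates = 3)
  expect_error(profile_set(bad_mean), "\\(0, 100\\]")

  dup <- tibble::tibble(
    organism = "x", condition = "c", fatty_acid = c("C16:0", "c16:0"),
    status = "quantified", mean = c(50, 50), sd = 1, n_replicates = 3)
  expect_error(profile_set(dup), "Duplicate")

  low_sum <- tibble::tibble(
    organism = "x", condition = "c", fatty_acid = "C16:0",
    status = "quantified", mean = 50, sd = 1, n_replicates = 3)
  expect_error(profile_set(low_sum), "sum")
  expect_s3_class(profile_set(low_sum, check_sums = FALSE), "profile_set")

  bad_reps <- tibble::tibble(
    organism = "x", condition = "c", fatty_acid = c("C16:0", "C18:0"),
    status = "quantified", mean = c(60, 40), sd = 1, n_replicates = 3,
    replicates = list(c(60, 60, 60), c(45, 45, 45)))
  expect_error(profile_set(bad_reps), "0.05 percentage points")
})
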