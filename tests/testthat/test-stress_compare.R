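test_that("delta matrix reproduces published per-acid changes", {
  profiles <- fixture_profiles()
  dm <- delta_matrix(profiles, c("co2_10C", "control_10C"))
  expect_equal(dm["LR1", "C18:2 cis 9, 12"], -1.0, tolerance = 1e-12)
  expect_equal(dm["M3", "C18:2 cis 9, 12"], 18.2, tolerance = 1e-12)
  expect_equal(nrow(dm), 20L)
  # columns ordered by chain length then bond count
  expect_equal(colnames(dm)[1:2], c("C14:0", "C16:0"))
})

test_that("identical profiles give an all-zero row; unknown conditions error", {
  same <- dplyr::bind_rows(
    make_profile(c("C16:0" = 50, "C18:2 cis 9, 12" = 50), condition = "a"),
    make_profile(c("C16:0" = 50, "C18:2 cis 9, 12" = 50), condition = "b"))
  dm <- delta_matrix(profile_set(same, check_sums = FALSE), c("a", "b"))
  expect_true(all(dm == 0))

  expect_error(delta_matrix(fixture_profiles(), c("co2_10C", "nope")),
               "available conditions")
})

test_that("acids are not applicable exactly when censored in both conditions", {
  profiles <- fixture_profiles()
  dm <- delta_matrix(profiles, c("co2_10C", "control_10C"))
  # LR1: C18:1 cis 11 is "nd" under both conditions -> grey cell
  expect_true(is.na(dm["LR1", "C18:1 cis 11"]))
  # LR1: C18:0 is "<1" under CO2 and absent in the control -> grey cell
  expect_true(is.na(dm["LR1", "C18:0"]))
  # WT2: C18:0 quantified in both -> a real change
  expect_equal(dm["WT2", "C18:0"], 0.5 - 1.0, tolerance = 1e-12)
  # molds have no C14:0 column at all -> not applicable
  expect_true(is.na(dm["KR3", "C14:0"]))
})

test_that("organisms missing a contrast condition are dropped with a warning", {
  partial <- profile_set(dplyr::bind_rows(
    tibble::as_tibble(make_profile(c("C16:0" = 100), organism = "one",
                                   condition = "co2_10C")),
    tibble::as_tibble(make_profile(c("C16:0" = 100), organism = "one",
                                   condition = "control_10C")),
    tibble::as_tibble(make_profile(c("C16:0" = 100), organism = "two",
                                   condition = "co2_10C"))
  ), check_sums = FALSE)
  expect_warning(dm <- delta_matrix(partial, c("co2_10C", "control_10C")),
                 "two")
  expect_equal(rownames(dm), "one")
})

test_that("delta matrices are antisymmetric in the contrast", {
  profiles <- fixture_profiles()
  ab <- delta_matrix(profiles, c("co2_10C", "control_10C"))
  ba <- delta_matrix(profiles, c("control_10C", "co2_10C"))
  expect_equal(unclass(ab)[, ], -unclass(ba)[rownames(ab), colnames(ab)],
               tolerance = 1e-12)
})

test_that("max-abs normalization scales rows to unit maximum and is idempotent", {
  profiles <- fixture_profiles()
  dm <- delta_matrix(profiles, c("co2_10C", "control_10C"))
  nm <- normalize_deltas(dm)
  row_max <- apply(abs(nm), 1, max, na.rm = TRUE)
  expect_equal(unname(row_max), rep(1, nrow(nm)), tolerance = 1e-12)
  expect_equal(normalize_deltas(nm), nm)

  # worked example: scaling preserves sign and ratios
  toy <- structure(matrix(c(-1, 2, 4), nrow = 1,
                          dimnames = list("o", c("C16:0", "C18:0", "C18:1 cis 9"))),
                   contrast = c("a", "b"), normalized = FALSE,
                   class = c("delta_matrix", "matrix", "array"))
  expect_equal(as.vector(normalize_deltas(toy)), c(-0.25, 0.5, 1))

  zero <- structure(matrix(0, nrow = 1, ncol = 3,
                           dimnames = list("o", c("C16:0", "C18:0", "C18:1 cis 9"))),
                    contrast = c("a", "b"), normalized = FALSE,
                    class = c("delta_matrix", "matrix", "array"))
  expect_equal(as.vector(normalize_deltas(zero)), c(0, 0, 0))
})

test_that("Welch test matches an independent oracle and is symmetric", {
  # identical groups: no evidence of change
  expect_equal(replicate_test(10, 1, 3, 10, 1, 3)$p.value, 1.0)

  cases <- list(c(24.8, 1.9, 25.8, 0.5), c(47.2, 4.2, 22.9, 3.0),
                c(5, 2, 5.5, 0.1), c(0.3, 0.1, 0.8, 0.1))
  for (cs in cases) {
    p_pkg <- replicate_test(cs[1], cs[2], 3, cs[3], cs[4], 3)$p.value
    expect_equal(p_pkg, welch_oracle_p(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-6)
    # exchanging group labels leaves the p-value unchanged
    expect_equal(replicate_test(cs[3], cs[4], 3, cs[1], cs[2], 3)$p.value,
                 p_pkg, tolerance = 1e-12)
  }
  # a large standardized difference is significant
  expect_lt(replicate_test(47.2, 4.2, 3, 22.9, 3.0, 3)$p.value, 0.05)
})

test_that("Welch test rejects degenerate inputs", {
  expect_error(replicate_test(1, 0, 3, 2, 0, 3), "Degenerate")
  expect_error(replicate_test(1, 1, 1, 2, 1, 3), "at least 2 replicates")
  expect_error(replicate_test(1, -1, 3, 2, 1, 3), "non-negative")
})

test_that("adaptation summary recovers the study's headline pattern", {
  profiles <- fixture_profiles()
  ad <- adaptation_summary(profiles)
  expect_equal(nrow(ad), 20L)

  # unsaturation rose under CO2 for every strain (WR1 at equality)
  expect_true(all(ad$delta_du >= -0.005))
  expect_gte(sum(ad$delta_du > 0), 19L)

  # membranes fluidized in every strain except WR1
  expect_equal(sort(ad$organism[ad$direction == "fluidization"]),
               sort(setdiff(ad$organism, "WR1")))
  expect_false(ad$direction[ad$organism == "WR1"] == "fluidization")

  # per-acid tests exist only for acids quantified under both conditions
  lr1 <- ad$tests[[which(ad$organism == "LR1")]]
  expect_false("C18:0" %in% lr1$fatty_acid)
  expect_true(all(lr1$p_value > 0 & lr1$p_value <= 1))
})

test_that("delta_du from summaries matches DU linearity on synthetic pairs", {
  base <- c("C16:0" = 30, "C18:1 cis 9" = 50, "C18:3 cis 9, 12, 15" = 20)
  shift <- c(-6, 2, 4)
  pair <- profile_set(dplyr::bind_rows(
    tibble::as_tibble(make_profile(base, condition = "control_10C")),
    tibble::as_tibble(make_profile(base + shift, condition = "co2_10C"))))
  ad <- adaptation_summary(pair)
  analytic <- sum(n_double_bonds(names(base)) * shift) / 100
  expect_equal(ad$delta_du, analytic, tolerance = 1e-12)
})
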