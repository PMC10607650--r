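test_that("spec validation rejects inconsistent generator parameters", {
  expect_error(synthetic_spec(baseline_mean = c("C16:0" = 50)), "sum to 100")
  expect_error(synthetic_spec(effect_co2 = c("C16:0" = 5)), "sum to zero")
  expect_error(synthetic_spec(effect_co2 = c("C14:0" = -2, "C16:0" = 2)),
               "non-negative")
  expect_error(synthetic_spec(noise_sd = rep(0, 10)), "positive")
  expect_error(synthetic_spec(effect_co2 = c("C99:0" = 0)), "Malformed|not in")
})

test_that("generation is deterministic and closed to 100 percent", {
  spec <- synthetic_spec(organisms = 4, seed = 42)
  g1 <- generate_profiles(spec)
  g2 <- generate_profiles(spec)
  expect_identical(g1$profiles, g2$profiles)

  sums <- vapply(split(
    ifelse(g1$profiles$status == "quantified", g1$profiles$mean, 0),
    paste(g1$profiles$organism, g1$profiles$condition)), sum, numeric(1))
  expect_equal(unname(sums), rep(100, length(sums)), tolerance = 1e-9)
  reps <- unlist(g1$profiles$replicates)
  expect_true(all(reps >= 0))

  # organism streams are stable under a larger organism count
  g_more <- generate_profiles(synthetic_spec(organisms = 6, seed = 42))
  first4 <- g_more$profiles[g_more$profiles$organism %in%
                              sprintf("org%02d", 1:4), ]
  expect_equal(tibble::as_tibble(first4), tibble::as_tibble(g1$profiles))
})

test_that("vanishing noise recovers the analytic condition means and DU shift", {
  spec <- synthetic_spec(organisms = 2, noise_sd = rep(1e-9, 10), seed = 1)
  g <- generate_profiles(spec)
  s <- summarize_profiles(g$profiles)
  du_co2 <- s$du[s$condition == "co2_10C"]
  du_ctl <- s$du[s$condition == "control_10C"]
  # default CO2 effect: +6 trienes, +4 dienes, -7 monoenes, -3 saturated
  expect_equal(du_co2 - du_ctl, rep(0.19, 2), tolerance = 1e-6)
  expect_equal(g$delta_du[["co2_10C-control_10C"]], 0.19, tolerance = 1e-12)

  co2_means <- g$profiles$mean[g$profiles$organism == "org01" &
                                 g$profiles$condition == "co2_10C"]
  expect_equal(co2_means, unname(spec$baseline_mean + spec$effect_co2),
               tolerance = 1e-6)
})

test_that("sample means converge to condition means as replicates grow", {
  for (n in c(30, 120)) {
    spec <- synthetic_spec(organisms = 1, n_replicates = n, seed = 5)
    g <- generate_profiles(spec)
    ctl <- g$profiles[g$profiles$condition == "control_10C", ]
    resolved <- ifelse(ctl$status == "quantified", ctl$mean, 0)
    err <- abs(resolved - unname(spec$baseline_mean))
    expect_true(all(err < 4 * spec$noise_sd / sqrt(n)),
                label = paste("n =", n))
  }
})

test_that("sign recovery is near-perfect for strong effects and replication", {
  spec <- synthetic_spec(organisms = 25, noise_sd = rep(0.5, 10),
                         n_replicates = 10, seed = 9)
  g <- generate_profiles(spec)
  r <- sign_recovery_rate(g$profiles, g$truth)
  expect_equal(r$n_effect_cells, 25 * 4)
  expect_gte(r$recovery_rate, 0.9)

  # boundary case: n = 2 still runs, with a low-power warning
  tiny <- synthetic_spec(organisms = 2, n_replicates = 2, seed = 3)
  gt <- generate_profiles(tiny)
  expect_warning(rt <- sign_recovery_rate(gt$profiles, gt$truth),
                 "low-powered")
  expect_true(is.finite(rt$recovery_rate))
})

test_that("specs round-trip through YAML and drive the generic reader", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    organisms = 3, n_replicates = 4, seed = 11,
    acids = c("C16:0", "C18:1 cis 9", "C18:3 cis 9, 12, 15"),
    baseline_mean = list("C16:0" = 30, "C18:1 cis 9" = 50,
                         "C18:3 cis 9, 12, 15" = 20),
    effect_co2 = list("C18:3 cis 9, 12, 15" = 5, "C18:1 cis 9" = -5),
    effect_temp = list("C18:3 cis 9, 12, 15" = -3, "C18:1 cis 9" = 3),
    noise_sd = list("C16:0" = 1, "C18:1 cis 9" = 1,
                    "C18:3 cis 9, 12, 15" = 1)
  ), path)
  spec <- read_synthetic_spec(path)
  expect_s3_class(spec, "synthetic_spec")
  expect_equal(spec$organisms, 3L)
  g <- generate_profiles(spec)
  expect_equal(nrow(g$profiles), 3L * 3L * 3L)
})
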