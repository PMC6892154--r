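test_that("generation is a pure function of seed and configuration", {
  aus <- load_builtin_model("final_australia")
  a <- generate_factor_items(aus, 50, seed = 9)
  b <- generate_factor_items(aus, 50, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, generate_factor_items(aus, 50, seed = 10)))
  pr <- small_profiles()
  expect_identical(generate_full_cohort(pr, seed = 3, items = TRUE),
                   generate_full_cohort(pr, seed = 3, items = TRUE))
})

test_that("zero residual variance makes items exactly proportional to their factor", {
  spec <- one_factor_spec(3, loadings = c(1, 1, -1))
  dat <- generate_factor_items(spec, 200, seed = 2)
  cc <- cor(dat)
  expect_equal(abs(cc[upper.tri(cc)]), rep(1, 3), tolerance = 1e-10)
  expect_true(all(sign(cc["x1", "x3"]) == -1))
})

test_that("within-factor item correlations match the product of configured loadings", {
  aus <- load_builtin_model("final_australia")
  dat <- generate_factor_items(aus, 20000, seed = 31)
  # no residual covariance on (AE1, AE2): cor = 0.90 * 0.88
  expect_equal(cor(dat$AE1, dat$AE2), 0.90 * 0.88, tolerance = 0.02)
  # a second within-factor pair
  expect_equal(cor(dat$CR1, dat$CR2), 0.72 * 0.73, tolerance = 0.02)
  # items are marginally standardized
  expect_equal(unname(apply(dat, 2, sd)), rep(1, 18), tolerance = 0.03)
})

test_that("likert discretization attenuates correlations relative to continuous items", {
  aus <- load_builtin_model("final_australia")
  cont <- generate_factor_items(aus, 8000, seed = 12, mode = "continuous")
  lik <- generate_factor_items(aus, 8000, seed = 12, mode = "likert")
  expect_true(all(unlist(lik[, 1:3]) %in% 1:4))
  expect_lt(abs(cor(lik$AE1, lik$AE2)), abs(cor(cont$AE1, cont$AE2)))
  expect_lt(abs(cor(lik$CR2, lik$CR3)), abs(cor(cont$CR2, cont$CR3)))
})

test_that("subscale cohorts recover configured country moments with clustering", {
  pr <- small_profiles(c("hongkong", "usa"))
  co <- generate_subscale_cohort(pr, seed = 21)
  expect_identical(nrow(co), sum(pr$n))
  for (i in seq_len(nrow(pr))) {
    rows <- co$country == pr$country[i]
    for (sub in c("residential_density", "aesthetics")) {
      m <- pr[[paste0(sub, "_mean")]][i]
      s <- pr[[paste0(sub, "_sd")]][i]
      expect_equal(mean(co[[sub]][rows]), m, tolerance = 5 * s / sqrt(pr$n[i]))
      expect_equal(sd(co[[sub]][rows]), s, tolerance = 0.15 * s)
    }
  }
  # units are nested in countries and balanced round-robin
  expect_true(all(table(co$country, substr(co$unit_id, 1, 3)) %in%
                    c(0, table(co$country))))
  expect_lte(diff(range(table(co$unit_id[co$country == "usa"]))), 1)
})

test_that("full cohorts carry balanced unit-level exposures, covariates and effects", {
  pr <- small_profiles()
  co <- generate_full_cohort(pr, seed = 14)
  # each unit has exactly one exposure pair
  per_unit <- unique(co[, c("unit_id", "ses_high", "walk_high")])
  expect_identical(nrow(per_unit), length(unique(co$unit_id)))
  for (cty in pr$country) {
    sel <- co$country == cty
    expect_equal(mean(co$ses_high[sel]), 0.5, tolerance = 0.1)
    expect_equal(mean(co$walk_high[sel]), 0.5, tolerance = 0.1)
  }
  expect_true(all(co$age >= 11 & co$age <= 19))
  expect_true(all(co$sex %in% 0:1))
  # configured walkability effect shifts the accessibility score
  eff <- exposure_effects()
  shift <- mean(co$accessibility_walking[co$walk_high == 1]) -
    mean(co$accessibility_walking[co$walk_high == 0])
  expect_equal(shift, eff$walk[["accessibility_walking"]], tolerance = 0.08)
  # item channel joins per-country measurement models
  co2 <- generate_full_cohort(small_profiles("australia"), seed = 5, items = TRUE)
  expect_true(all(paste0("CR", 1:4) %in% names(co2)))
  expect_true(all(unlist(co2[, paste0("AW", 1:5)]) %in% 1:4))
})
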