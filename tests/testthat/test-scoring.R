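test_that("residential density is the weighted sum with the printed weights", {
  expect_equal(score_residential_density(rep(0, 6)), 0)
  expect_equal(score_residential_density(rep(4, 6)), 4 * (1 + 11 + 25 + 50 + 75 + 100))  # 1048
  expect_equal(score_residential_density(c(1, 1, 0, 0, 0, 0)), 12)
  expect_equal(score_residential_density(rep(4, 5), variant = "no_item6"), 648)
  expect_true(is.na(score_residential_density(c(1, NA, 0, 0, 0, 0))))
  expect_error(score_residential_density(c(5, 0, 0, 0, 0, 0)), "\\[0, 4\\]")
  expect_error(score_residential_density(rep(0, 5)), "expected 6")
})

test_that("destination-proximity subscales are plain means over the fixed item count", {
  expect_equal(score_destination_mix(rep(5, 13), 13), 5)
  expect_equal(score_destination_mix(rep(1, 9), 9), 1)
  expect_equal(score_destination_mix(c(5, 4, 3, 2, 1, 5, 4, 3, 2), 9),
               mean(c(5, 4, 3, 2, 1, 5, 4, 3, 2)))  # 3.222...
  expect_error(score_destination_mix(rep(3, 8), 9), "expected 9")
  expect_error(score_destination_mix(c(rep(3, 12), 6), 13), "\\[1, 5\\]")
})

test_that("reverse coding is a strictly decreasing involution of the scale", {
  expect_equal(reverse_code(1), 4)
  expect_equal(reverse_code(3), 2)
  for (x in 1:4) expect_equal(reverse_code(reverse_code(x)), x)
  expect_true(all(diff(reverse_code(1:4)) < 0))
  expect_equal(reverse_code(0:4, scale_min = 0, scale_max = 4), 4:0)
  expect_error(reverse_code(5), "\\[1, 4\\]")
})

test_that("Likert subscales reverse the declared set before averaging", {
  ts <- c(TS1 = 1, TS2 = 4, TS3 = 1)
  expect_equal(score_likert_subscale(ts, reverse = c("TS1", "TS3")), 4)
  cr <- c(CR1 = 4, CR2 = 4, CR3 = 4, CR4 = 4)
  expect_equal(score_likert_subscale(cr, reverse = names(cr)), 1)
  expect_equal(score_likert_subscale(c(AE1 = 2, AE2 = 2, AE3 = 2)), 2)
  expect_true(is.na(score_likert_subscale(c(AE1 = 2, AE2 = NA, AE3 = 2))))
  expect_equal(score_likert_subscale(c(AE1 = 2, AE2 = NA, AE3 = 4),
                                     min_prop = 0.5), 3)
})

test_that("scores are monotone, range-bounded and permutation invariant", {
  set.seed(81)
  proto <- scoring_protocol()
  for (rep in 1:25) {
    dens <- sample(0:4, 6, replace = TRUE)
    s0 <- score_residential_density(dens)
    i <- sample(6, 1)
    if (dens[i] < 4) {
      dens2 <- dens; dens2[i] <- dens2[i] + 1
      expect_gte(score_residential_density(dens2), s0)
    }
    expect_gte(s0, 0); expect_lte(s0, 1048)

    lik <- sample(1:4, 5, replace = TRUE)
    names(lik) <- paste0("AW", 1:5)
    sc <- score_likert_subscale(lik, reverse = "AW1")
    expect_gte(sc, 1); expect_lte(sc, 4)
    j <- sample(2:5, 1)  # positively scored item
    if (lik[j] < 4) {
      lik2 <- lik; lik2[j] <- lik2[j] + 1
      expect_gte(score_likert_subscale(lik2, reverse = "AW1"), sc)
    }
    prox <- sample(1:5, 13, replace = TRUE)
    expect_equal(score_destination_mix(prox, 13),
                 score_destination_mix(sample(prox), 13))
  }
})

test_that("cohort scoring applies country variants and carries identifiers through", {
  items <- news_items()
  lik <- items$item_id[items$block == "likert"][1:18]
  tab <- data.frame(country = c("denmark", "nigeria", "usa"),
                    unit_id = c("u1", "u2", "u3"),
                    density_variant = c("no_item6", "standard", "standard"),
                    recreation_variant = c("standard", "first6", "standard"))
  for (id in paste0("RD", 1:6)) tab[[id]] <- 4
  for (id in sprintf("D%02d", 1:13)) tab[[id]] <- 1
  for (id in paste0("R", 1:9)) tab[[id]] <- c(2, 2, 5)
  for (id in paste0("AW", 1:5)) tab[[id]] <- 1
  scored <- score_cohort(tab)
  expect_equal(scored$residential_density_score, c(648, 1048, 1048))  # Denmark variant drops item 6
  expect_equal(scored$land_use_mix_diversity_score, rep(1, 3))
  expect_equal(scored$recreational_facilities_score, c(2, 2, 5))
  # AW all-1 with AW1 reversed: (4 + 1 + 1 + 1 + 1)/5
  expect_equal(scored$accessibility_walking_score, rep(8 / 5, 3))
  expect_identical(scored$unit_id, tab$unit_id)
  tab$density_variant[1] <- "odd"
  expect_error(score_cohort(tab), "unknown density_variant")
})

test_that("a zero-variance generated cohort scores at the configured country means", {
  pr <- small_profiles("australia")
  for (col in grep("_sd$", names(pr))) pr[[col]] <- 0
  co <- generate_subscale_cohort(pr, seed = 4)
  for (sub in news_subscales())
    expect_equal(unique(round(co[[sub]], 10)), pr[[paste0(sub, "_mean")]])
})
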