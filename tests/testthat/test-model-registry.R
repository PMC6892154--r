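test_that("degrees of freedom match the published fit table for every builtin model", {
  expect_identical(model_df(load_builtin_model("apriori")), 194L)
  expect_identical(model_df(load_builtin_model("final_common")), 125L)
  published <- c(australia = 124L, belgium = 125L, brazil = 126L,
                 hongkong = 128L, india = 129L, malaysia = 125L,
                 newzealand = 128L, nigeria = 133L, spain = 126L, usa = 129L)
  for (cty in names(published))
    expect_identical(model_df(load_builtin_model(paste0("final_", cty))),
                     published[[cty]])
})

test_that("free-parameter tallies follow the identification rule", {
  apriori_m <- load_builtin_model("apriori", scaling = "marker")
  tally <- count_free_parameters(apriori_m)
  expect_identical(tally$loadings, 16L)           # 22 items - 6 markers
  expect_identical(tally$factor_variances, 6L)
  expect_identical(tally$factor_covariances, 15L)
  expect_identical(tally$error_variances, 22L)
  expect_identical(tally$total, 59L)

  common <- load_builtin_model("final_common")    # unit-variance scaling
  expect_identical(count_free_parameters(common)$total, 46L)  # 18 + 10 + 18

  triad <- one_factor_spec(3)
  expect_identical(count_free_parameters(triad)$total, 6L)
  expect_identical(model_df(triad), 0L)
})

test_that("df is invariant to the identification rule and counts removed parameters one-for-one", {
  for (key in c("apriori", "final_common", "final_australia", "final_malaysia")) {
    expect_identical(model_df(load_builtin_model(key)),
                     model_df(load_builtin_model(key, scaling = "marker")))
  }
  aus <- load_builtin_model("final_australia")
  # drop one residual pair -> one fewer free parameter -> df + 1
  fewer <- measurement_model("aus2", aus$loadings, free_cov = aus$free_cov,
                             residual_pairs = aus$residual_pairs[-1, , drop = FALSE],
                             target_loadings = aus$target_loadings)
  expect_identical(model_df(fewer), model_df(aus) + 1L)
  # fix one more factor covariance to zero -> df + 1 again
  fewer2 <- measurement_model("aus3", aus$loadings,
                              free_cov = aus$free_cov[-1, , drop = FALSE],
                              residual_pairs = aus$residual_pairs,
                              target_loadings = aus$target_loadings)
  expect_identical(model_df(fewer2), model_df(aus) + 1L)
})

test_that("invalid specifications are rejected", {
  expect_error(load_builtin_model("nope"), "available")
  # 2 items, 1 factor: 3 moments < 4 free parameters
  expect_error(measurement_model("tiny", c(a = "F", b = "F")),
               "not identified")
  expect_error(
    measurement_model("dup", c(a = "F", b = "F", c = "F"),
                      residual_pairs = rbind(c("a", "b"), c("b", "a"))),
    "duplicate")
  expect_error(
    measurement_model("bad", c(a = "F", b = "F", c = "F"),
                      residual_pairs = rbind(c("a", "z"))),
    "unknown item pair")
})

test_that("model specs round-trip through JSON and YAML", {
  for (ext in c("json", "yaml")) {
    path <- tempfile(fileext = paste0(".", ext))
    spec <- load_builtin_model("final_malaysia")
    write_model(spec, path)
    back <- read_model(path)
    expect_identical(back$items, spec$items)
    expect_identical(back$loadings, spec$loadings)
    expect_equal(back$target_loadings, spec$target_loadings)
    expect_identical(unname(back$free_cov), unname(spec$free_cov))
    expect_identical(unname(back$residual_pairs), unname(spec$residual_pairs))
    expect_identical(model_df(back), model_df(spec))
    unlink(path)
  }
})

test_that("builtin catalog matches the published model structure", {
  ap <- load_builtin_model("apriori")
  expect_length(ap$items, 22)
  expect_length(ap$factors, 6)
  expect_identical(nrow(ap$free_cov), 15L)
  expect_identical(nrow(ap$residual_pairs), 0L)
  # a priori item allocation: 2 + 6 + 5 + 4 + 3 + 2
  expect_identical(as.vector(table(ap$loadings)[c("LU", "PA", "CR", "AE", "WC", "SC")]),
                   c(2L, 6L, 5L, 4L, 3L, 2L))
  common <- load_builtin_model("final_common")
  expect_length(common$items, 18)
  expect_length(common$factors, 5)
  nz <- load_builtin_model("final_newzealand")
  expect_identical(nrow(nz$residual_pairs), 0L)
  pairs <- c(australia = 3L, belgium = 3L, brazil = 1L, hongkong = 1L,
             india = 2L, malaysia = 4L, newzealand = 0L, nigeria = 0L,
             spain = 0L, usa = 1L)
  for (cty in names(pairs))
    expect_identical(nrow(load_builtin_model(paste0("final_", cty))$residual_pairs),
                     pairs[[cty]])
})
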