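test_that("pooled within-cluster covariance matches the brute-force estimator", {
  set.seed(71)
  # two clusters identical up to a mean shift: shift must not matter
  base <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("a", "b")))
  x <- rbind(base, sweep(base, 2, c(10, -5), "+"))
  cl <- rep(c("g1", "g2"), each = 4)
  mom <- pooled_within_covariance(x, cl)
  expect_equal(mom$S, 2 * cov(base) * 3 / 6, tolerance = 1e-12)
  expect_identical(mom$n_effective, 6L)

  # 6 x 2 fixture against the double-loop oracle
  x2 <- matrix(c(1, 2, 4, 0, 3, 5, 2, 1, 0, 4, 4, 1), 6, 2,
               dimnames = list(NULL, c("u", "v")))
  cl2 <- c("p", "p", "p", "q", "q", "q")
  expect_equal(pooled_within_covariance(x2, cl2)$S,
               pooled_within_bruteforce(x2, cl2), tolerance = 1e-12)

  # one cluster reduces to the ordinary N-1 covariance
  one <- pooled_within_covariance(base, rep("g", 4))
  expect_equal(one$S, cov(base), tolerance = 1e-12)
  expect_identical(one$n_effective, 3L)

  # singletons are dropped with a count; all-singleton input errors
  mixed <- pooled_within_covariance(rbind(base, base[1, ]),
                                    c(rep("g", 4), "solo"))
  expect_identical(mixed$dropped_singletons, 1L)
  expect_equal(mixed$S, cov(base), tolerance = 1e-12)
  expect_error(pooled_within_covariance(base, paste0("s", 1:4)), "singleton")
})

test_that("the one-factor triad reproduces the closed-form loadings", {
  S <- triad_cov(0.72, 0.63, 0.56)
  fit <- fit_ml(sample_moments(S, 499), one_factor_spec(3))
  expect_equal(unname(fit$standardized$loadings), c(0.9, 0.8, 0.7),
               tolerance = 1e-5)
  expect_identical(fit$df, 0L)
  expect_lt(fit$chi2, 1e-6)        # just-identified: exact reproduction
  expect_true(fit$rmsea_undefined)
  # generic closed form on a second triad
  r <- c(r12 = 0.48, r13 = 0.42, r23 = 0.56)
  fit2 <- fit_ml(sample_moments(triad_cov(r[1], r[2], r[3]), 999),
                 one_factor_spec(3))
  lam1 <- sqrt(r[["r12"]] * r[["r13"]] / r[["r23"]])
  expect_equal(unname(fit2$standardized$loadings),
               unname(c(lam1, r[["r12"]] / lam1, r[["r13"]] / lam1)),
               tolerance = 1e-5)
})

test_that("a model fitted to its own implied covariance recovers the generating parameters", {
  aus <- load_builtin_model("final_australia")
  Sigma0 <- newsyipen:::implied_sigma(aus, residual_cor = 0.15)
  fit <- fit_ml(sample_moments(Sigma0, 999), aus)
  expect_true(fit$converged)
  expect_lt(fit$F_min, 1e-9)
  expect_lt(fit$chi2, 1e-5)
  expect_equal(fit$cfi, 1)
  expect_equal(fit$rmsea, 0)
  expect_lt(fit$srmr, 1e-5)
  expect_equal(unname(fit$standardized$loadings),
               unname(aus$target_loadings), tolerance = 1e-4)
  # free inter-factor correlations recovered at the generation value
  fc <- fit$standardized$factor_cor
  for (i in seq_len(nrow(aus$free_cov)))
    expect_equal(fc[aus$free_cov[i, 1], aus$free_cov[i, 2]], 0.29,
                 tolerance = 1e-4)
})

test_that("chi-square and loadings agree with an independent ML factor-analysis oracle", {
  set.seed(42)
  for (r in 1:20) {
    p <- sample(4:6, 1)
    n <- sample(200:800, 1)
    lam <- runif(p, 0.4, 0.9) * sample(c(-1, 1), p, replace = TRUE)
    spec <- one_factor_spec(p, loadings = lam, name = paste0("rand", r))
    S <- cor(generate_factor_items(spec, n))
    fit <- fit_ml(sample_moments(S, n - 1), spec)
    oracle <- stats::factanal(covmat = S, factors = 1, n.obs = n)
    expect_equal(fit$F_min, oracle$criteria[["objective"]], tolerance = 1e-5)
    expect_equal(abs(unname(fit$standardized$loadings)),
                 abs(unname(oracle$loadings[, 1])), tolerance = 1e-3)
  }
})

test_that("fit statistics are invariant to item rescaling", {
  aus <- load_builtin_model("final_australia")
  dat <- generate_factor_items(aus, 1500, seed = 77)
  f1 <- fit_ml(moments_from_data(dat), aus)
  dat2 <- dat
  dat2$AE1 <- dat2$AE1 * 7.3
  dat2$CR2 <- dat2$CR2 * 0.2
  f2 <- fit_ml(moments_from_data(dat2), aus)
  expect_equal(f1$chi2, f2$chi2, tolerance = 1e-4)
  expect_equal(f1$cfi, f2$cfi, tolerance = 1e-6)
  expect_equal(f1$rmsea, f2$rmsea, tolerance = 1e-6)
  expect_equal(f1$srmr, f2$srmr, tolerance = 1e-6)
  expect_equal(f1$standardized$loadings, f2$standardized$loadings,
               tolerance = 1e-4)
})

test_that("marker and unit-variance identifications give the same fit and standardized solution", {
  aus <- load_builtin_model("final_australia")
  ausm <- load_builtin_model("final_australia", scaling = "marker")
  m <- moments_from_data(generate_factor_items(aus, 2000, seed = 3))
  f1 <- fit_ml(m, aus)
  f2 <- fit_ml(m, ausm)
  expect_equal(f1$chi2, f2$chi2, tolerance = 1e-4)
  expect_identical(f1$df, f2$df)
  l1 <- f1$standardized$loadings
  l2 <- f2$standardized$loadings
  fac <- aus$loadings[aus$items]
  for (f in unique(fac)) {   # factor orientation is arbitrary
    i <- fac == f
    if (sum(l1[i] * l2[i]) < 0) l2[i] <- -l2[i]
  }
  expect_equal(l1, l2, tolerance = 1e-4)
})

test_that("baseline model has closed-form behavior and bounds the structured chi-square", {
  set.seed(10)
  d <- diag(c(2, 1, 0.5, 3))
  dimnames(d) <- list(paste0("x", 1:4), paste0("x", 1:4))
  bl <- baseline_chi_square(sample_moments(d, 200))
  expect_equal(bl$chi2, 0, tolerance = 1e-10)
  expect_equal(bl$df, 6)
  expect_equal(baseline_chi_square(sample_moments(diag(22) + 0, 100,
                                                  items = paste0("i", 1:22)))$df, 231)
  spec <- one_factor_spec(4)
  dat <- generate_factor_items(one_factor_spec(4, loadings = rep(0.7, 4)), 300,
                               seed = 6)
  mom <- moments_from_data(dat)
  fit <- fit_ml(mom, spec)
  expect_gte(baseline_chi_square(mom)$chi2, fit$chi2)
})

test_that("fit indices follow their definitions", {
  fi <- fit_indices(200, 100, 2000, 231, 1000)
  expect_equal(fi$rmsea, sqrt(100 / 100000), tolerance = 1e-12)  # 0.0316
  expect_equal(fi$cfi, 1 - 100 / (2000 - 231), tolerance = 1e-12)
  expect_true(fi$rmsea_ci95[1] < fi$rmsea & fi$rmsea < fi$rmsea_ci95[2])
  central <- fit_indices(100, 100, 500, 120, 800)
  expect_equal(central$rmsea, 0)
  expect_equal(central$cfi, 1)
  expect_equal(central$rmsea_ci95[1], 0)
  saturated <- fit_indices(0, 0, 50, 10, 100)
  expect_true(saturated$rmsea_undefined)
  expect_equal(saturated$rmsea, 0)
  # SRMR: zero at equality, tracks a single perturbed cell
  S <- triad_cov(0.5, 0.4, 0.3)
  expect_equal(fit_indices(10, 2, 50, 3, 99, S = S, Sigma = S)$srmr, 0)
  S2 <- S; S2["x1", "x2"] <- S2["x2", "x1"] <- 0.6
  res <- std_residuals(S2, S)
  expect_equal(res["x1", "x2"], 0.1, tolerance = 1e-12)
  expect_equal(res, t(res))
  top <- residual_diagnostics(S2, S, k = 1)
  expect_identical(sort(c(top$item_1, top$item_2)), c("x1", "x2"))
})

test_that("Wald statistics and significance behave as expected", {
  # plain arithmetic on a fitted table
  aus <- load_builtin_model("final_australia")
  dat <- generate_factor_items(aus, 20000, seed = 55)
  fit <- fit_ml(moments_from_data(dat), aus)
  w <- wald_tests(fit)
  expect_equal(w$z, w$estimate / w$se, tolerance = 1e-12)
  # in a well-powered recovery run every loading is significant at 0.001
  expect_true(all(w$p[w$type == "lambda"] < 0.001))
  expect_false(any(w$flagged[w$type == "lambda"]))
})

test_that("a Heywood-bound solution is flagged rather than thrown", {
  # implied lambda1^2 = r12*r13/r23 > 1 pushes an error variance to its bound
  S <- triad_cov(0.9, 0.9, 0.7)
  fit <- fit_ml(sample_moments(S, 499), one_factor_spec(3))
  expect_true(fit$heywood)
})

test_that("modification indices point at a truly freed parameter", {
  # 5 heterogeneous items break the equivalence between alternative
  # residual-pair placements that exists in a 4-item one-factor model
  spec0 <- one_factor_spec(5, loadings = c(0.8, 0.7, 0.6, 0.5, 0.4),
                           name = "gen")
  gen <- measurement_model("gen_res", spec0$loadings,
                           residual_pairs = rbind(c("x1", "x2")),
                           target_loadings = spec0$target_loadings)
  Sigma0 <- newsyipen:::implied_sigma(gen, residual_cor = 0.5)
  fit <- fit_ml(sample_moments(Sigma0, 999), one_factor_spec(5, name = "fit"))
  mi <- modification_indices(fit, k = 3)
  top <- mi[mi$type == "theta_od", ][1, ]
  expect_identical(sort(c(top$row, top$col)), c("x1", "x2"))
})

test_that("every loading of a published-profile model is recovered at n = 20000", {
  aus <- load_builtin_model("final_australia")
  dat <- generate_factor_items(aus, 20000, seed = 1, mode = "continuous")
  fit <- fit_ml(moments_from_data(dat), aus)
  expect_true(all(abs(fit$standardized$loadings - aus$target_loadings) <= 0.03))
})
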