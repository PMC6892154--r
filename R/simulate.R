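# Synthetic multi-country cohort generation: item-level draws from a factor
# model with configured standardized loadings, and subscale-level draws with
# country means/SDs, administrative-unit clustering, stratified binary
# exposures and covariates.

# Symmetric PSD square root (tolerates exactly-singular Theta, e.g. residual
# variances forced to 0).
psd_sqrt <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  vals <- e$values
  if (any(vals < -1e-8 * max(abs(vals), 1)))
    stop("matrix is not positive semi-definite")
  vals[vals < 0] <- 0
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

build_phi <- function(spec, factor_cor) {
  m <- length(spec$factors)
  phi <- diag(m)
  dimnames(phi) <- list(spec$factors, spec$factors)
  if (is.matrix(factor_cor)) {
    stopifnot(all(dim(factor_cor) == m))
    phi[] <- factor_cor
    diag(phi) <- 1
  } else if (nrow(spec$free_cov) > 0) {
    for (i in seq_len(nrow(spec$free_cov))) {
      pr <- spec$free_cov[i, ]
      phi[pr[1], pr[2]] <- phi[pr[2], pr[1]] <- factor_cor
    }
  }
  if (min(eigen(phi, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("inter-factor correlation matrix is not positive definite")
  phi
}

build_lambda <- function(spec, loadings) {
  p <- length(spec$items); m <- length(spec$factors)
  lambda <- matrix(0, p, m, dimnames = list(spec$items, spec$factors))
  lambda[cbind(spec$items, spec$loadings[spec$items])] <- loadings[spec$items]
  lambda
}

build_theta <- function(spec, loadings, residual_cor) {
  p <- length(spec$items)
  v <- 1 - loadings[spec$items]^2
  if (any(v < -1e-12)) stop("|loading| > 1 leaves negative residual variance")
  v <- pmax(v, 0)
  theta <- diag(v, p)
  dimnames(theta) <- list(spec$items, spec$items)
  if (nrow(spec$residual_pairs) > 0 && residual_cor != 0) {
    for (i in seq_len(nrow(spec$residual_pairs))) {
      pr <- spec$residual_pairs[i, ]
      cv <- residual_cor * sqrt(v[pr[1]] * v[pr[2]])
      theta[pr[1], pr[2]] <- theta[pr[2], pr[1]] <- cv
    }
    if (min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values) < 0)
      stop("residual covariances make the error covariance non-positive-definite")
  }
  theta
}

# Model-implied covariance of a generation configuration (also used by tests
# and perfect-fit checks).
implied_sigma <- function(spec, loadings = spec$target_loadings,
                          factor_cor = spec$gen_factor_cor %||% 0,
                          residual_cor = 0) {
  lambda <- build_lambda(spec, loadings)
  phi <- build_phi(spec, factor_cor)
  theta <- build_theta(spec, loadings, residual_cor)
  sigma <- lambda %*% phi %*% t(lambda) + theta
  dimnames(sigma) <- list(spec$items, spec$items)
  sigma
}

#' Generate item responses from a measurement model
#'
#' Draws latent factors from a zero-mean multivariate normal with unit
#' variances and the configured inter-factor correlations, then forms each
#' item as `loading * factor + residual` with residual variance
#' `1 - loading^2` (plus any configured residual correlation on the model's
#' correlated-error pairs), so every item is marginally standard normal.
#' `mode = "likert"` discretizes into 1..4 at the equal-probability normal
#' cut points; discretization attenuates observed correlations relative to
#' the continuous mode.
#'
#' @param spec A `newsy_model` carrying `target_loadings` (or pass
#'   `loadings`).
#' @param n Number of respondents.
#' @param seed Optional integer seed; identical `(seed, configuration)`
#'   yields identical output.
#' @param mode `"continuous"` or `"likert"`.
#' @param loadings Optional named signed standardized loadings overriding the
#'   spec's reference values.
#' @param factor_cor Scalar correlation applied uniformly to the model's free
#'   factor pairs (fixed-to-zero pairs stay 0), or a full correlation matrix;
#'   default the spec's generation default.
#' @param residual_cor Residual correlation applied to the model's
#'   correlated-error pairs; default 0.
#' @return Data frame of item responses, columns in spec item order.
#' @export
generate_factor_items <- function(spec, n, seed = NULL,
                                  mode = c("continuous", "likert"),
                                  loadings = NULL, factor_cor = NULL,
                                  residual_cor = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "newsy_model"), n >= 1)
  loadings <- loadings %||% spec$target_loadings
  if (is.null(loadings)) stop("no loadings available for generation")
  factor_cor <- factor_cor %||% spec$gen_factor_cor %||% 0
  lambda <- build_lambda(spec, loadings)
  phi <- build_phi(spec, factor_cor)
  theta <- build_theta(spec, loadings, residual_cor)
  if (!is.null(seed)) set.seed(seed)
  f <- matrix(stats::rnorm(n * ncol(phi)), n) %*% psd_sqrt(phi)
  e <- matrix(stats::rnorm(n * nrow(theta)), n) %*% psd_sqrt(theta)
  y <- f %*% t(lambda) + e
  colnames(y) <- spec$items
  if (mode == "likert") {
    cuts <- stats::qnorm(c(.25, .5, .75))
    y[] <- findInterval(y, cuts) + 1L
  }
  as.data.frame(y)
}

unit_labels <- function(country, n, n_units) {
  sprintf("%s_u%02d", country, 1L + (seq_len(n) - 1L) %% n_units)
}

#' Generate a clustered multi-country subscale-score cohort
#'
#' For each country profile, each respondent's score on each subscale is
#' `country mean + unit intercept + residual`, with the unit intercept
#' variance `unit_icc * SD^2` and residual variance `(1 - unit_icc) * SD^2`,
#' so the total within-country variance matches the profile SD. Respondents
#' are allocated to administrative units round-robin (balanced cluster
#' sizes) and to schools in contiguous blocks.
#'
#' @param profiles Data frame as returned by [country_profiles()] (any
#'   subset/edit with the same columns).
#' @param seed Optional integer seed.
#' @param subscales Subscales to generate; default all eight.
#' @return Data frame with `country`, `unit_id`, `school_id`, variant flags
#'   and one column per subscale.
#' @export
generate_subscale_cohort <- function(profiles = country_profiles(),
                                     seed = NULL,
                                     subscales = news_subscales()) {
  stopifnot(nrow(profiles) >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    pr <- profiles[i, ]
    n <- pr$n
    units <- unit_labels(pr$country, n, pr$n_units)
    schools <- sprintf("%s_s%02d", pr$country,
                       ceiling(seq_len(n) / (n / pr$n_schools)))
    out <- data.frame(country = pr$country, unit_id = units,
                      school_id = schools,
                      density_variant = pr$density_variant,
                      recreation_variant = pr$recreation_variant)
    for (sub in subscales) {
      m <- pr[[paste0(sub, "_mean")]]
      s <- pr[[paste0(sub, "_sd")]]
      icc <- pr$unit_icc
      u <- stats::rnorm(pr$n_units, 0, sqrt(icc) * s)
      names(u) <- sort(unique(units))
      e <- stats::rnorm(n, 0, sqrt(1 - icc) * s)
      out[[sub]] <- m + u[units] + e
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate the full synthetic cohort
#'
#' Composes the subscale-score generator with unit-level binary exposures,
#' respondent covariates, exposure effects and (optionally) item-level
#' responses. Exposures are assigned at the administrative-unit level,
#' cycling units through the four SES-by-walkability strata so each country
#' is approximately balanced 50/50 on both labels, mirroring the stratified
#' recruitment design. Exposure and covariate effects from `effects` are
#' added to the subscale scores (age is centered at 15 before applying its
#' effect). Item responses, when requested, are drawn from the country's
#' final measurement model (`final_common` for countries without one) in
#' Likert mode; they share the factor structure of the instrument but are
#' standardized draws, not calibrated to the subscale-score channel.
#'
#' @param profiles Country profiles; default [country_profiles()].
#' @param effects Effect configuration from [exposure_effects()].
#' @param seed Optional integer seed.
#' @param items `TRUE` to attach item-level responses for the 18
#'   factor-analyzable items.
#' @param age_range Recruitment age range in years; ages are uniform on it.
#' @return Data frame with identifiers, covariates (`age`, `sex`; sex is 1 =
#'   male with the country's published percentage), exposures (`ses_high`,
#'   `walk_high`), subscale scores and optional item columns.
#' @export
generate_full_cohort <- function(profiles = country_profiles(),
                                 effects = exposure_effects(),
                                 seed = NULL, items = FALSE,
                                 age_range = c(11, 19)) {
  if (!is.null(seed)) set.seed(seed)
  base <- generate_subscale_cohort(profiles, seed = NULL)
  subs <- intersect(news_subscales(), names(base))
  # unit-level stratified exposures: cycle units through the 4 strata
  all_units <- unique(base$unit_id)
  strata <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), ncol = 2, byrow = TRUE)
  unit_stratum <- strata[1L + (seq_along(all_units) - 1L) %% 4L, , drop = FALSE]
  rownames(unit_stratum) <- all_units
  base$ses_high <- unit_stratum[base$unit_id, 1]
  base$walk_high <- unit_stratum[base$unit_id, 2]
  base$age <- stats::runif(nrow(base), age_range[1], age_range[2])
  pct <- profiles$pct_male[match(base$country, profiles$country)]
  base$sex <- stats::rbinom(nrow(base), 1, pct / 100)
  for (sub in subs) {
    base[[sub]] <- base[[sub]] +
      effects$ses[[sub]] * base$ses_high +
      effects$walk[[sub]] * base$walk_high +
      effects$age * (base$age - 15) +
      effects$sex * base$sex
  }
  if (items) {
    item_blocks <- lapply(unique(base$country), function(cty) {
      model_name <- if (cty %in% cfa_countries()) paste0("final_", cty)
                    else "final_common"
      spec <- load_builtin_model(model_name)
      generate_factor_items(spec, sum(base$country == cty), mode = "likert")
    })
    base <- cbind(base, do.call(rbind, item_blocks))
  }
  rownames(base) <- NULL
  base
}
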