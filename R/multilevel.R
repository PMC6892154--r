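# Empty (intercept-only) multilevel models partitioning subscale variance
# between countries (and optionally administrative units within country).

#' Variance decomposition from an empty multilevel model
#'
#' Fits the intercept-only random-intercept model by REML (default; ML
#' available) with a country random intercept and, when `unit` is supplied,
#' an administrative-unit intercept nested within country, and returns the
#' estimated variance components with the percentage of total variance
#' attributable to between-country differences,
#' `100 * sigma2_country / (sigma2_country + sigma2_unit + sigma2_residual)`.
#' Degenerate inputs (zero within-country variance) are resolved in closed
#' form rather than through the optimizer.
#'
#' @param y Numeric response (subscale scores).
#' @param country Country identifier, length `length(y)`; at least 2
#'   distinct values.
#' @param unit Optional administrative-unit identifier (nested in country).
#' @param method `"reml"` or `"ml"`.
#' @return Object of class `newsy_varcomp`: `sigma2_country`, `sigma2_unit`
#'   (`NA` if no unit level), `sigma2_residual`, `pct_between_country`,
#'   `pct_by_level`, `converged`, `messages`.
#' @export
fit_empty_multilevel <- function(y, country, unit = NULL,
                                 method = c("reml", "ml")) {
  method <- match.arg(method)
  keep <- is.finite(y)
  y <- y[keep]; country <- factor(country[keep])
  if (!is.null(unit)) unit <- factor(unit[keep])
  if (nlevels(country) < 2)
    stop("variance decomposition requires at least 2 countries")
  within_var <- stats::ave(y, country, FUN = function(v) stats::var(v))
  within_var[is.na(within_var)] <- 0
  comp <- list(sigma2_country = NA_real_, sigma2_unit = NA_real_,
               sigma2_residual = NA_real_, converged = TRUE,
               messages = character())
  if (max(within_var) < 1e-12) {
    # all variance is between country means (possibly none at all)
    comp$sigma2_country <- stats::var(tapply(y, country, mean))
    comp$sigma2_residual <- 0
    if (!is.null(unit)) comp$sigma2_unit <- 0
  } else {
    fml <- if (is.null(unit)) y ~ 1 + (1 | country)
           else y ~ 1 + (1 | country) + (1 | unit)
    dat <- data.frame(y = y, country = country)
    if (!is.null(unit)) dat$unit <- factor(paste(country, unit, sep = ":"))
    fit <- withCallingHandlers(
      lme4::lmer(fml, data = dat, REML = (method == "reml")),
      message = function(m) {
        comp$messages <<- c(comp$messages, conditionMessage(m))
        invokeRestart("muffleMessage")
      },
      warning = function(w) {
        comp$messages <<- c(comp$messages, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    vc <- as.data.frame(lme4::VarCorr(fit))
    comp$sigma2_country <- vc$vcov[vc$grp == "country"]
    comp$sigma2_residual <- vc$vcov[vc$grp == "Residual"]
    if (!is.null(unit)) comp$sigma2_unit <- vc$vcov[vc$grp == "unit"]
    comp$converged <- length(fit@optinfo$conv$lme4) == 0
  }
  tot <- sum(comp$sigma2_country, comp$sigma2_unit, comp$sigma2_residual,
             na.rm = TRUE)
  shares <- c(country = comp$sigma2_country,
              unit = if (!is.null(unit)) comp$sigma2_unit,
              residual = comp$sigma2_residual)
  comp$pct_by_level <- if (tot > 0) 100 * shares / tot else shares * 0
  comp$pct_between_country <- unname(comp$pct_by_level["country"])
  comp$method <- method
  class(comp) <- "newsy_varcomp"
  comp
}

#' @exportS3Method base::print
print.newsy_varcomp <- function(x, ...) {
  cat("Empty multilevel model (", toupper(x$method), ")\n", sep = "")
  cat(sprintf("  sigma2: country %.4g, unit %s, residual %.4g\n",
              x$sigma2_country,
              if (is.na(x$sigma2_unit)) "-" else sprintf("%.4g", x$sigma2_unit),
              x$sigma2_residual))
  cat(sprintf("  %% variance between countries: %.1f\n", x$pct_between_country))
  invisible(x)
}

#' Between-country variance share for every subscale
#'
#' Applies [fit_empty_multilevel()] to each subscale of a scored cohort,
#' producing the percentage of total variance attributable to between-country
#' differences per subscale.
#'
#' @param scores Data frame with a `country` column and per-subscale score
#'   columns (either `<subscale>` or `<subscale>_score`).
#' @param subscales Subscales to decompose; default all present.
#' @param unit Optional column name holding the administrative-unit id.
#' @param method `"reml"` or `"ml"`.
#' @return Data frame `subscale`, `pct_between_country`, `sigma2_country`,
#'   `sigma2_unit`, `sigma2_residual`, `converged`.
#' @export
variance_share_table <- function(scores, subscales = news_subscales(),
                                 unit = NULL, method = "reml") {
  stopifnot("country" %in% names(scores))
  pick <- function(sub) {
    for (cand in c(sub, paste0(sub, "_score")))
      if (cand %in% names(scores)) return(cand)
    NA_character_
  }
  cols <- vapply(subscales, pick, character(1))
  subscales <- subscales[!is.na(cols)]
  cols <- cols[!is.na(cols)]
  rows <- lapply(seq_along(subscales), function(i) {
    vc <- fit_empty_multilevel(scores[[cols[i]]], scores$country,
                               unit = if (!is.null(unit)) scores[[unit]],
                               method = method)
    data.frame(subscale = subscales[i],
               pct_between_country = vc$pct_between_country,
               sigma2_country = vc$sigma2_country,
               sigma2_unit = vc$sigma2_unit,
               sigma2_residual = vc$sigma2_residual,
               converged = vc$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
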