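# Construct-validity stage: random-intercept linear mixed models of subscale
# scores on binary area-level SES and walkability, adjusted for age, sex and
# country, with Wald confidence intervals, plus evaluation of the a priori
# convergent/divergent hypotheses.

#' Construct-validity linear mixed model for one subscale
#'
#' REML fit of an identity-link linear mixed model of a subscale score on
#' the binary exposures, with country as fixed dummies ("adjusted for
#' country") and random intercepts for the supplied cluster factors (school
#' and/or administrative unit). Confidence intervals and p-values for the
#' fixed effects use the Wald normal approximation `b +/- 1.96 se` (no
#' Satterthwaite-type degrees-of-freedom correction; see the methods
#' vignette).
#'
#' @param data Cohort data frame (scored).
#' @param outcome Name of the score column.
#' @param exposures Exposure columns (binary 0/1); default `ses_high` and
#'   `walk_high`.
#' @param adjust Covariate columns; `"country"` enters as a factor.
#' @param clusters Random-intercept grouping columns; default `unit_id`.
#' @param exclude_countries Optional countries to drop (sensitivity
#'   analysis, e.g. the sites that classified areas by expert opinion).
#' @param reml Use REML (default) or ML.
#' @return Object of class `newsy_validity`: a data frame of
#'   `FixedEffectEstimate` rows (`term`, `b`, `se`, `lo95`, `hi95`, `z`,
#'   `p`) with the fitted model and convergence flag as attributes.
#' @export
fit_validity_lmm <- function(data, outcome,
                             exposures = c("ses_high", "walk_high"),
                             adjust = c("age", "sex", "country"),
                             clusters = "unit_id",
                             exclude_countries = NULL, reml = TRUE) {
  stopifnot(outcome %in% names(data))
  if (!is.null(exclude_countries))
    data <- data[!data$country %in% exclude_countries, ]
  for (e in exposures)
    if (!all(stats::na.omit(data[[e]]) %in% 0:1))
      stop("exposure '", e, "' must be binary 0/1")
  fixed <- c(exposures, adjust)
  rhs <- paste(c(ifelse(fixed == "country", "factor(country)", fixed),
                 sprintf("(1 | %s)", clusters)), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  # check the fixed design for rank deficiency, naming the collinear columns
  X <- stats::model.matrix(
    stats::as.formula(paste(outcome, "~",
      paste(ifelse(fixed == "country", "factor(country)", fixed),
            collapse = " + "))), data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = data, REML = reml),
    message = function(m) {msgs <<- c(msgs, conditionMessage(m));
                           invokeRestart("muffleMessage")},
    warning = function(w) {msgs <<- c(msgs, conditionMessage(w));
                           invokeRestart("muffleWarning")})
  sm <- summary(fit)$coefficients
  out <- data.frame(term = rownames(sm), b = sm[, "Estimate"],
                    se = sm[, "Std. Error"])
  out$lo95 <- out$b - 1.96 * out$se
  out$hi95 <- out$b + 1.96 * out$se
  out$z <- out$b / out$se
  out$p <- 2 * stats::pnorm(-abs(out$z))
  rownames(out) <- NULL
  attr(out, "outcome") <- outcome
  attr(out, "model") <- fit
  attr(out, "converged") <- length(fit@optinfo$conv$lme4) == 0
  attr(out, "messages") <- msgs
  class(out) <- c("newsy_validity", "data.frame")
  out
}

#' Evaluate construct-validity hypotheses
#'
#' Compares estimated exposure effects against the a priori expectations.
#' For a `"+"` hypothesis: `confirmed` when the estimate is significantly
#' positive at `alpha`, `contradicted` when significantly negative,
#' otherwise `not_confirmed`. For a `"0"` hypothesis: `upheld` when the
#' estimate is not significant, `unexpected` when a significant association
#' appears where none was hypothesized. Hypothesized terms missing from the
#' estimates are reported as `untested`.
#'
#' @param estimates Data frame with columns `subscale`, `exposure`, `b`,
#'   `lo95`, `hi95`, `p` (one row per subscale-exposure pair, e.g. built by
#'   [run_pipeline()]'s validity stage).
#' @param hypotheses Data frame as from [validity_hypotheses()].
#' @param alpha Significance level; default 0.05.
#' @return The hypotheses table with appended estimate columns and a
#'   `status` column.
#' @export
hypothesis_evaluation <- function(estimates, hypotheses = validity_hypotheses(),
                                  alpha = 0.05) {
  out <- hypotheses
  out$b <- out$lo95 <- out$hi95 <- out$p <- NA_real_
  out$status <- "untested"
  for (i in seq_len(nrow(out))) {
    hit <- estimates$subscale == out$subscale[i] &
      estimates$exposure == out$exposure[i]
    if (!any(hit)) next
    e <- estimates[which(hit)[1], ]
    out$b[i] <- e$b; out$lo95[i] <- e$lo95; out$hi95[i] <- e$hi95
    out$p[i] <- e$p
    sig <- is.finite(e$p) && e$p < alpha
    out$status[i] <- if (out$expected[i] == "+") {
      if (sig && e$b > 0) "confirmed"
      else if (sig && e$b < 0) "contradicted"
      else "not_confirmed"
    } else {
      if (sig) "unexpected" else "upheld"
    }
  }
  out
}
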