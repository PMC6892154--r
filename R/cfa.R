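# Normal-theory maximum-likelihood confirmatory factor analysis: minimizes
# the ML discrepancy F(theta) = log|Sigma| + tr(S Sigma^-1) - log|S| - p
# over the free parameters of a measurement-model specification, with
# analytic gradients, observed-information standard errors, baseline model,
# CFI / RMSEA (noncentral chi-square CI) / SRMR, standardized solution, Wald
# tests, standardized residuals and univariate modification indices.

# --- parameter template -----------------------------------------------------

# One row per free parameter. 'trans' marks log-parameterized variances
# (keeps error and factor variances positive; soft lower bound 1e-6 guards
# Heywood collapse).
par_template <- function(spec) {
  items <- spec$items; factors <- spec$factors
  sign0 <- rep(1, length(items)); names(sign0) <- items
  if (!is.null(spec$target_loadings))
    sign0 <- ifelse(spec$target_loadings[items] < 0, -1, 1)
  marker <- spec$scaling == "marker"
  markers <- vapply(factors, function(f) items[spec$loadings[items] == f][1],
                    character(1))
  rows <- list()
  add <- function(type, row, col, start, lower = -Inf, upper = Inf,
                  trans = "id")
    rows[[length(rows) + 1]] <<- data.frame(type = type, row = row, col = col,
                                            start = start, lower = lower,
                                            upper = upper, trans = trans)
  # starts correspond to standardized loadings 0.7*sign, error variances
  # 0.51, factor correlations 0.2; under marker scaling they are translated
  # into the marker parameterization (factor SD = |marker loading|, other
  # loadings relative to the marker, covariances on the factor-variance
  # scale) so both rules start at the same implied covariance matrix
  msign <- sign0[unname(markers)]; names(msign) <- names(markers)
  for (it in items) {
    f <- spec$loadings[[it]]
    if (marker && it == markers[[f]]) next  # fixed at 1
    start <- if (marker) sign0[[it]] / msign[[f]] else 0.7 * sign0[[it]]
    add("lambda", it, f, start)
  }
  if (marker)
    for (f in factors) add("phi_d", f, f, log(0.49), trans = "log")
  if (nrow(spec$free_cov) > 0)
    for (i in seq_len(nrow(spec$free_cov))) {
      pr <- spec$free_cov[i, ]
      if (marker) add("phi_od", pr[1], pr[2],
                      0.2 * 0.49 * msign[[pr[1]]] * msign[[pr[2]]])
      else add("phi_od", pr[1], pr[2], 0.2, lower = -0.999, upper = 0.999)
    }
  for (it in items)
    add("theta_d", it, it, log(0.51), lower = log(1e-6), trans = "log")
  if (nrow(spec$residual_pairs) > 0)
    for (i in seq_len(nrow(spec$residual_pairs))) {
      pr <- spec$residual_pairs[i, ]
      add("theta_od", pr[1], pr[2], 0)
    }
  tpl <- do.call(rbind, rows)
  attr(tpl, "markers") <- markers
  tpl
}

# Assemble Lambda, Phi, Theta from a working parameter vector.
par_matrices <- function(par, spec, tpl) {
  items <- spec$items; factors <- spec$factors
  lambda <- matrix(0, length(items), length(factors),
                   dimnames = list(items, factors))
  if (spec$scaling == "marker") {
    markers <- attr(tpl, "markers")
    lambda[cbind(unname(markers), names(markers))] <- 1
  }
  phi <- diag(length(factors))
  dimnames(phi) <- list(factors, factors)
  theta <- matrix(0, length(items), length(items),
                  dimnames = list(items, items))
  raw <- ifelse(tpl$trans == "log", exp(par), par)
  for (k in seq_len(nrow(tpl))) {
    ty <- tpl$type[k]; i <- tpl$row[k]; j <- tpl$col[k]; v <- raw[k]
    if (ty == "lambda") lambda[i, j] <- v
    else if (ty == "phi_d") phi[i, i] <- v
    else if (ty == "phi_od") phi[i, j] <- phi[j, i] <- v
    else if (ty == "theta_d") theta[i, i] <- v
    else theta[i, j] <- theta[j, i] <- v
  }
  list(lambda = lambda, phi = phi, theta = theta,
       sigma = lambda %*% phi %*% t(lambda) + theta)
}

ml_discrepancy <- function(S, sigma, logdet_s) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  inv <- chol2inv(ch)
  2 * sum(log(diag(ch))) + sum(inv * S) - logdet_s - nrow(S)
}

# Gradient of F wrt the working parameters, using
# E = Sigma^-1 (Sigma - S) Sigma^-1. ml_gradient_mats takes pre-built
# matrices (possibly with perturbed fixed cells, as the score tests need);
# ml_gradient is the optimizer-facing wrapper.
ml_gradient <- function(par, spec, tpl, S, logdet_s) {
  mats <- par_matrices(par, spec, tpl)
  raw <- ifelse(tpl$trans == "log", exp(par), par)
  ml_gradient_mats(mats, raw, spec, tpl, S)
}

ml_gradient_mats <- function(mats, raw, spec, tpl, S) {
  sigma <- mats$sigma
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    # ridge the infeasible iterate enough to get a usable descent direction
    ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
    sigma <- sigma + diag(abs(ev) + 1e-6, nrow(sigma))
    ch <- chol(sigma)
  }
  inv <- chol2inv(ch)
  E <- inv - inv %*% S %*% inv
  dimnames(E) <- dimnames(sigma)
  elp <- E %*% mats$lambda %*% mats$phi
  rownames(elp) <- spec$items
  lel <- t(mats$lambda) %*% E %*% mats$lambda
  g <- numeric(nrow(tpl))
  for (k in seq_len(nrow(tpl))) {
    ty <- tpl$type[k]; i <- tpl$row[k]; j <- tpl$col[k]
    g[k] <- switch(ty,
      lambda = 2 * elp[i, j],
      phi_d = lel[i, i] * raw[k],          # chain rule through log
      phi_od = 2 * lel[i, j],
      theta_d = E[i, i] * raw[k],
      theta_od = 2 * E[i, j])
  }
  g
}

# --- fitting ----------------------------------------------------------------

#' Fit a measurement model by maximum likelihood
#'
#' Minimizes the normal-theory discrepancy
#' `F = log|Sigma(theta)| + tr(S Sigma(theta)^-1) - log|S| - p` with a
#' quasi-Newton optimizer (analytic gradient; variance parameters on the log
#' scale with a soft lower bound of 1e-6 guarding Heywood collapse). The
#' chi-square statistic is `n_effective * F_min`; standard errors come from
#' the inverse observed information `(n_effective/2) H(F)`. Non-convergence
#' and Heywood cases are flagged on the result, not raised as errors.
#'
#' @param moments A `newsy_moments` (see [moments_from_data()],
#'   [pooled_within_covariance()], [sample_moments()]).
#' @param spec A `newsy_model` whose items are all present in the moments.
#' @param start Optional numeric start vector on the working scale
#'   (advanced).
#' @param se Compute standard errors (numerical Hessian); default `TRUE`.
#' @param control Passed to [stats::optim()] (method `"L-BFGS-B"`).
#' @return Object of class `newsy_fit`: parameter table (`estimates`),
#'   fitted matrices, `F_min`, `chi2`, `df`, baseline chi-square, `cfi`,
#'   `rmsea` (+ 95% CI), `srmr`, `standardized` solution, convergence and
#'   Heywood flags.
#' @export
fit_ml <- function(moments, spec, start = NULL, se = TRUE, control = list()) {
  stopifnot(inherits(moments, "newsy_moments"), inherits(spec, "newsy_model"))
  if (!all(spec$items %in% moments$items))
    stop("moments do not cover all model items")
  S <- moments$S[spec$items, spec$items]
  n_eff <- moments$n_effective
  df <- model_df(spec)
  p <- length(spec$items)
  ridged <- FALSE
  ch_s <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch_s) || min(diag(ch_s)) < 1e-10) {
    S <- S + diag(1e-6 * mean(diag(S)), p)  # ridge fallback, flagged
    ch_s <- chol(S)
    ridged <- TRUE
  }
  logdet_s <- 2 * sum(log(diag(ch_s)))
  tpl <- par_template(spec)
  par0 <- start %||% tpl$start
  fn <- function(par) {
    f <- ml_discrepancy(S, par_matrices(par, spec, tpl)$sigma, logdet_s)
    if (!is.finite(f)) 1e10 else f
  }
  gr <- function(par) ml_gradient(par, spec, tpl, S, logdet_s)
  ctrl <- utils::modifyList(list(maxit = 1000L, factr = 1e3), control)
  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      lower = tpl$lower, upper = tpl$upper, control = ctrl)
  # polish until the gradient criterion is met or no further progress
  for (k in 1:2) {
    if (max(abs(gr(opt$par))) < 1e-6) break
    opt2 <- stats::optim(opt$par, fn, gr, method = "L-BFGS-B",
                         lower = tpl$lower, upper = tpl$upper,
                         control = utils::modifyList(ctrl, list(factr = 10)))
    if (opt2$value > opt$value - 1e-12) {opt <- opt2; break}
    opt <- opt2
  }
  f_min <- max(opt$value, 0)
  max_grad <- max(abs(gr(opt$par)))
  converged <- opt$convergence == 0 && max_grad < 1e-3
  mats <- par_matrices(opt$par, spec, tpl)
  heywood <- any(diag(mats$theta) <= 1.5e-6)

  raw <- ifelse(tpl$trans == "log", exp(opt$par), opt$par)
  est <- data.frame(type = tpl$type, row = tpl$row, col = tpl$col,
                    estimate = raw, se = NA_real_)
  if (se) {
    H <- tryCatch(stats::optimHess(opt$par, fn, gr), error = function(e) NULL)
    if (!is.null(H)) {
      acov <- tryCatch(solve(0.5 * n_eff * H), error = function(e) NULL)
      if (!is.null(acov)) {
        sev <- sqrt(pmax(diag(acov), 0))
        # delta method back to the raw scale for log-parameterized variances
        est$se <- ifelse(tpl$trans == "log", sev * raw, sev)
      }
    }
  }
  est$z <- est$estimate / est$se
  est$p <- 2 * stats::pnorm(-abs(est$z))

  chi2 <- n_eff * f_min
  bl <- baseline_chi_square(sample_moments(S, n_eff, spec$items))
  fi <- fit_indices(chi2, df, bl$chi2, bl$df, n_eff, S = S,
                    Sigma = mats$sigma)
  fit <- structure(
    list(spec = spec, items = spec$items, n_effective = n_eff, S = S,
         estimates = est, lambda = mats$lambda, phi = mats$phi,
         theta = mats$theta, sigma = mats$sigma,
         F_min = f_min, chi2 = chi2, df = df,
         chi2_baseline = bl$chi2, df_baseline = bl$df,
         cfi = fi$cfi, rmsea = fi$rmsea, rmsea_ci95 = fi$rmsea_ci95,
         rmsea_undefined = fi$rmsea_undefined, srmr = fi$srmr,
         converged = converged, iterations = opt$counts[["function"]],
         max_gradient = max_grad, heywood = heywood, s_ridged = ridged,
         par = opt$par, tpl = tpl),
    class = "newsy_fit")
  fit$standardized <- standardized_solution(fit)
  fit
}

#' Baseline (independence) model chi-square
#'
#' The ML solution of the diagonal model is `Sigma = diag(S)` in closed
#' form, so `chi2_b = n_effective * (sum(log(diag(S))) - log|S|)` with
#' `df_b = p(p-1)/2`.
#'
#' @param moments A `newsy_moments`.
#' @return List with `chi2` and `df`.
#' @export
baseline_chi_square <- function(moments) {
  S <- moments$S
  p <- nrow(S)
  f_b <- sum(log(diag(S))) - determinant(S, logarithm = TRUE)$modulus[1]
  list(chi2 = max(moments$n_effective * f_b, 0), df = p * (p - 1) / 2)
}

# --- fit indices ------------------------------------------------------------

rmsea_ncp_ci <- function(chi2, df, level = 0.95, tol = 1e-8) {
  lo_q <- (1 + level) / 2; hi_q <- (1 - level) / 2
  bound <- function(target) {
    # pchisq(chi2, df, ncp) is decreasing in ncp; bisection on [0, hi]
    if (stats::pchisq(chi2, df, ncp = 0) < target) return(0)
    hi <- max(chi2, 1)
    while (stats::pchisq(chi2, df, ncp = hi) > target) hi <- hi * 2
    lo <- 0
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (stats::pchisq(chi2, df, ncp = mid) > target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  c(bound(lo_q), bound(hi_q))
}

#' Model fit indices
#'
#' `CFI = 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0)` (clamped
#' to `[0, 1]`); `RMSEA = sqrt(max(chi2 - df, 0) / (df * n_effective))` with
#' a 95% confidence interval obtained by inverting the noncentral chi-square
#' distribution in its noncentrality parameter (bisection to 1e-8); SRMR is
#' the root mean square of the standardized residuals over all
#' `p(p+1)/2` unique elements, diagonal included. Good-fit benchmarks used
#' in reports: CFI >= 0.95 (0.90 acceptable when the other two pass),
#' SRMR <= 0.08, RMSEA <= 0.06.
#'
#' @param chi2,df Model chi-square and degrees of freedom.
#' @param chi2_b,df_b Baseline chi-square and degrees of freedom.
#' @param n_effective Effective sample size.
#' @param S,Sigma Sample and model-implied covariance (for SRMR); optional.
#' @return List with `cfi`, `rmsea`, `rmsea_ci95`, `rmsea_undefined`,
#'   `srmr` (`NA` when `S`/`Sigma` not supplied).
#' @export
fit_indices <- function(chi2, df, chi2_b, df_b, n_effective,
                        S = NULL, Sigma = NULL) {
  stopifnot(df >= 0, df_b >= df)
  num <- max(chi2 - df, 0)
  den <- max(chi2_b - df_b, chi2 - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  cfi <- min(max(cfi, 0), 1)
  if (df == 0) {
    rmsea <- 0; ci <- c(0, 0); undef <- TRUE
  } else {
    rmsea <- sqrt(num / (df * n_effective))
    ci <- sqrt(rmsea_ncp_ci(chi2, df) / (df * n_effective))
    undef <- FALSE
  }
  srmr <- if (is.null(S) || is.null(Sigma)) NA_real_
          else sqrt(mean(std_residuals(S, Sigma)[upper.tri(S, diag = TRUE)]^2))
  list(cfi = cfi, rmsea = rmsea, rmsea_ci95 = ci, rmsea_undefined = undef,
       srmr = srmr)
}

#' Standardized residual matrix
#'
#' Element-wise difference between the sample and model-implied matrices on
#' the correlation scale, `s_ij/sqrt(s_ii s_jj) - sigma_ij/sqrt(sigma_ii
#' sigma_jj)` — the quantity whose root mean square is the SRMR.
#'
#' @param S Sample covariance.
#' @param Sigma Model-implied covariance (same dimension/order).
#' @return Symmetric residual matrix.
#' @export
std_residuals <- function(S, Sigma) {
  stopifnot(all(dim(S) == dim(Sigma)))
  ds <- sqrt(diag(S)); dm <- sqrt(diag(Sigma))
  S / tcrossprod(ds) - Sigma / tcrossprod(dm)
}

#' Largest standardized residuals
#'
#' Reporting helper listing the largest-|value| standardized residuals.
#'
#' @param S,Sigma As in [std_residuals()].
#' @param k Number of entries to report.
#' @return Data frame `item_1`, `item_2`, `residual`, sorted by
#'   absolute value.
#' @export
residual_diagnostics <- function(S, Sigma, k = 10) {
  r <- std_residuals(S, Sigma)
  idx <- which(upper.tri(r, diag = TRUE), arr.ind = TRUE)
  out <- data.frame(item_1 = rownames(r)[idx[, 1]],
                    item_2 = colnames(r)[idx[, 2]],
                    residual = r[idx])
  out <- out[order(-abs(out$residual)), ]
  utils::head(out, k)
}

# --- solution post-processing ----------------------------------------------

#' Standardized solution of a fitted model
#'
#' Rescales loadings to unit item and factor variances (using the fitted
#' model-implied item variances) and factor covariances to correlations.
#' Under unit-variance scaling on standardized input this reproduces the raw
#' estimates; a marker-scaled fit of the same data yields the identical
#' standardized solution.
#'
#' @param fit A `newsy_fit`.
#' @return List with `loadings` (named signed vector), `factor_cor`
#'   (correlation matrix) and `flagged` (items with non-positive fitted
#'   variance, if any).
#' @export
standardized_solution <- function(fit) {
  sd_item <- sqrt(diag(fit$sigma))
  sd_fac <- sqrt(diag(fit$phi))
  flagged <- names(sd_item)[!is.finite(sd_item) | sd_item <= 0]
  lam_std <- sweep(sweep(fit$lambda, 1, sd_item, "/"), 2, sd_fac, "*")
  loads <- lam_std[cbind(fit$items, fit$spec$loadings[fit$items])]
  names(loads) <- fit$items
  list(loadings = loads, factor_cor = stats::cov2cor(fit$phi),
       flagged = flagged)
}

#' Wald tests for free parameters
#'
#' `z = estimate / SE` with two-sided normal p-values; entries with missing
#' or non-positive SE are flagged rather than dropped.
#'
#' @param fit A `newsy_fit`.
#' @return Data frame of parameter rows with `z`, `p` and `flagged`.
#' @export
wald_tests <- function(fit) {
  est <- fit$estimates
  est$flagged <- !is.finite(est$se) | est$se <= 0
  est$z[est$flagged] <- NA_real_
  est$p[est$flagged] <- NA_real_
  est
}

#' Univariate modification indices
#'
#' Score (Lagrange-multiplier) statistics for parameters fixed to zero in
#' the specification: cross-loadings, fixed-to-zero inter-factor covariances
#' and unfreed error covariances. For a candidate direction `c` the index is
#' the score statistic `n g_c^2 / (2 (h_cc - h_cf H_ff^-1 h_fc))`: the
#' curvature of the discrepancy in the candidate direction is corrected by
#' its interaction with the free parameters (Schur complement against the
#' free-parameter Hessian), so the index approximates the chi-square drop a
#' full refit with that one parameter freed would achieve. Reporting only;
#' the package performs no automated re-specification.
#'
#' @param fit A `newsy_fit`.
#' @param k Number of rows to report.
#' @return Data frame `type`, `row`, `col`, `mi`, sorted decreasing.
#' @export
modification_indices <- function(fit, k = 10) {
  spec <- fit$spec; tpl <- fit$tpl
  S <- fit$S
  logdet_s <- determinant(S, logarithm = TRUE)$modulus[1]
  candidates <- list()
  for (it in spec$items)
    for (f in setdiff(spec$factors, spec$loadings[[it]]))
      candidates[[length(candidates) + 1]] <- c("lambda", it, f)
  if (nrow(spec$fixed_zero_cov) > 0)
    for (i in seq_len(nrow(spec$fixed_zero_cov)))
      candidates[[length(candidates) + 1]] <- c("phi_od",
                                                spec$fixed_zero_cov[i, 1],
                                                spec$fixed_zero_cov[i, 2])
  free_res <- pair_key(spec$residual_pairs)
  univ <- item_pairs_universe(spec$items)
  for (i in seq_len(nrow(univ)))
    if (!pair_key(univ[i, , drop = FALSE]) %in% free_res)
      candidates[[length(candidates) + 1]] <- c("theta_od", univ[i, 1], univ[i, 2])
  n <- fit$n_effective
  raw <- ifelse(tpl$trans == "log", exp(fit$par), fit$par)
  fn <- function(par) ml_discrepancy(S, par_matrices(par, spec, tpl)$sigma,
                                     logdet_s)
  gr <- function(par) ml_gradient(par, spec, tpl, S, logdet_s)
  H_ff <- stats::optimHess(fit$par, fn, gr)
  H_ff_inv <- tryCatch(solve(H_ff), error = function(e) NULL)
  perturbed_mats <- function(type, i, j, d) {
    mats <- list(lambda = fit$lambda, phi = fit$phi, theta = fit$theta)
    if (type == "lambda") mats$lambda[i, j] <- mats$lambda[i, j] + d
    else if (type == "phi_od") mats$phi[i, j] <- mats$phi[j, i] <- mats$phi[i, j] + d
    else mats$theta[i, j] <- mats$theta[j, i] <- mats$theta[i, j] + d
    mats$sigma <- mats$lambda %*% mats$phi %*% t(mats$lambda) + mats$theta
    mats
  }
  mi_one <- function(type, i, j) {
    delta <- 1e-4
    f_of <- function(d) ml_discrepancy(S, perturbed_mats(type, i, j, d)$sigma,
                                       logdet_s)
    f0 <- f_of(0); fp <- f_of(delta); fm <- f_of(-delta)
    g_c <- (fp - fm) / (2 * delta)
    h_cc <- (fp - 2 * f0 + fm) / delta^2
    # mixed curvature: change of the free-parameter gradient along c
    g_free <- function(d) ml_gradient_mats(perturbed_mats(type, i, j, d), raw,
                                           spec, tpl, S)
    h_cf <- (g_free(delta) - g_free(-delta)) / (2 * delta)
    h_eff <- if (is.null(H_ff_inv)) h_cc
             else h_cc - drop(h_cf %*% H_ff_inv %*% h_cf)
    if (!is.finite(h_eff) || h_eff <= 1e-12) return(NA_real_)
    n * g_c^2 / (2 * h_eff)
  }
  out <- do.call(rbind, lapply(candidates, function(cc)
    data.frame(type = cc[1], row = cc[2], col = cc[3],
               mi = mi_one(cc[1], cc[2], cc[3]))))
  out <- out[order(-out$mi), ]
  utils::head(out, k)
}

#' @exportS3Method base::print
print.newsy_fit <- function(x, ...) {
  cat("ML CFA fit: '", x$spec$name, "', ", length(x$items), " items, n_eff = ",
      x$n_effective, "\n", sep = "")
  cat(sprintf("  chi2 = %.1f (df = %d), CFI = %.3f, RMSEA = %.3f (%.3f, %.3f), SRMR = %.3f\n",
              x$chi2, x$df, x$cfi, x$rmsea, x$rmsea_ci95[1], x$rmsea_ci95[2],
              x$srmr))
  if (!x$converged) cat("  warning: convergence flag not met (max |grad| ",
                        format(x$max_gradient), ")\n", sep = "")
  if (x$heywood) cat("  warning: Heywood case (error variance at bound)\n")
  invisible(x)
}
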