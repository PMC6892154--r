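# Shared fixtures built in code.

# Correlation matrix of a one-factor triad with the given correlations.
triad_cov <- function(r12, r13, r23, names = c("x1", "x2", "x3")) {
  S <- diag(3)
  S[1, 2] <- S[2, 1] <- r12
  S[1, 3] <- S[3, 1] <- r13
  S[2, 3] <- S[3, 2] <- r23
  dimnames(S) <- list(names, names)
  S
}

one_factor_spec <- function(p = 3, loadings = NULL, name = "one") {
  items <- paste0("x", seq_len(p))
  measurement_model(name, stats::setNames(rep("F", p), items),
                    target_loadings = if (!is.null(loadings))
                      stats::setNames(loadings, items))
}

# Brute-force pooled within-cluster covariance: double loop over clusters
# and element pairs, divisor N - G (the independent oracle for
# pooled_within_covariance()).
pooled_within_bruteforce <- function(x, cluster) {
  x <- as.matrix(x)
  keep <- cluster %in% names(which(table(cluster) >= 2))
  x <- x[keep, , drop = FALSE]; cluster <- cluster[keep]
  p <- ncol(x)
  acc <- matrix(0, p, p, dimnames = list(colnames(x), colnames(x)))
  for (g in unique(cluster)) {
    xg <- x[cluster == g, , drop = FALSE]
    ctr <- colMeans(xg)
    for (r in seq_len(nrow(xg)))
      for (i in 1:p) for (j in 1:p)
        acc[i, j] <- acc[i, j] + (xg[r, i] - ctr[i]) * (xg[r, j] - ctr[j])
  }
  acc / (nrow(x) - length(unique(cluster)))
}

# Small three-country profile table for fast cohort tests (published
# structure, reduced country set).
small_profiles <- function(countries = c("australia", "nigeria", "usa")) {
  pr <- country_profiles()
  pr[pr$country %in% countries, ]
}
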