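# Sample-moment containers for the CFA engine: raw-data covariance and the
# pooled within-cluster covariance used when respondents are nested in
# schools/administrative areas.

#' Construct a sample-moments object
#'
#' @param S Symmetric positive semi-definite covariance matrix with item
#'   names.
#' @param n_effective Effective sample size carried into the chi-square
#'   multiplier: `N - 1` for raw data, `N - G` for a pooled within-cluster
#'   matrix over `G` clusters.
#' @param items Item order; defaults to `colnames(S)`.
#' @param dropped_singletons Number of singleton clusters removed upstream.
#' @return Object of class `newsy_moments`.
#' @export
sample_moments <- function(S, n_effective, items = colnames(S),
                           dropped_singletons = 0L) {
  S <- as.matrix(S)
  if (is.null(items)) stop("item names are required")
  if (!isSymmetric(unname(S), tol = 1e-8))
    stop("covariance matrix must be symmetric")
  S <- (S + t(S)) / 2
  dimnames(S) <- list(items, items)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("covariance matrix must be positive semi-definite")
  structure(list(S = S, n_effective = n_effective, items = items,
                 dropped_singletons = dropped_singletons),
            class = "newsy_moments")
}

#' Sample moments from a raw item table
#'
#' Ordinary sample covariance with divisor `N - 1`; `n_effective = N - 1`.
#'
#' @param data Data frame or matrix of item responses.
#' @param items Columns to use; default all numeric columns.
#' @return A `newsy_moments`.
#' @export
moments_from_data <- function(data, items = NULL) {
  if (is.null(items)) items <- colnames(data)
  x <- as.matrix(data[, items, drop = FALSE])
  if (anyNA(x)) stop("raw-data moments require complete data")
  sample_moments(stats::cov(x), n_effective = nrow(x) - 1L, items = items)
}

#' Pooled within-cluster covariance matrix
#'
#' Covariance of deviations about cluster means with divisor `N - G`,
#' estimating individual-level item relationships net of area-level mean
#' differences. Clusters with fewer than two members carry no within-cluster
#' information and are dropped (count recorded on the result). With a single
#' cluster this reduces to the ordinary `N - 1` sample covariance.
#'
#' @param data Data frame or matrix of item responses.
#' @param cluster Cluster identifier vector, length `nrow(data)`.
#' @param items Columns to use; default all columns of `data`.
#' @return A `newsy_moments` with `n_effective = N - G`.
#' @export
pooled_within_covariance <- function(data, cluster, items = NULL) {
  if (is.null(items)) items <- colnames(data)
  x <- as.matrix(data[, items, drop = FALSE])
  stopifnot(length(cluster) == nrow(x))
  if (anyNA(x)) stop("pooled within-cluster moments require complete data")
  cluster <- as.character(cluster)
  sizes <- table(cluster)
  keep <- names(sizes)[sizes >= 2]
  dropped <- sum(sizes < 2)
  if (length(keep) == 0)
    stop("all clusters are singletons; no within-cluster information")
  sel <- cluster %in% keep
  x <- x[sel, , drop = FALSE]
  cluster <- cluster[sel]
  centered <- x - rowsum(x, cluster)[as.character(cluster), ] /
    as.vector(table(cluster)[as.character(cluster)])
  n <- nrow(x)
  g <- length(unique(cluster))
  sample_moments(crossprod(centered) / (n - g), n_effective = n - g,
                 items = items, dropped_singletons = dropped)
}
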