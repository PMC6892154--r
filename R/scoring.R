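# NEWS-Y-IPEN scoring protocol: weighted residential-density sum, proximity
# averages, reverse coding and Likert subscale means, and cohort-level
# application with country variants.

check_ordinal <- function(x, lo, hi, what) {
  bad <- !is.na(x) & (x < lo | x > hi | x != round(x))
  if (any(bad))
    stop(what, " responses must be integers in [", lo, ", ", hi, "]; got ",
         paste(utils::head(x[bad], 3), collapse = ", "))
  invisible(x)
}

#' Residential density score
#'
#' Weighted sum of the six housing-type frequency ratings (each 0 = none to
#' 4 = all) with weights 1, 11, 25, 50, 75 and 100 reflecting the estimated
#' number of dwelling units per building type. The `no_item6` variant (used
#' where >20-story buildings do not occur, i.e. Denmark) sums the first five
#' weighted items. Any missing response yields a missing score; no
#' imputation.
#'
#' @param responses Numeric vector of 6 ordinal responses (5 for
#'   `no_item6`), each in 0..4.
#' @param variant `"standard"` or `"no_item6"`.
#' @return Nonnegative number, or `NA` if any response is missing.
#' @export
score_residential_density <- function(responses,
                                      variant = c("standard", "no_item6")) {
  variant <- match.arg(variant)
  w <- c(1, 11, 25, 50, 75, 100)
  if (variant == "no_item6") w <- w[1:5]
  if (length(responses) != length(w))
    stop("expected ", length(w), " density responses, got ", length(responses))
  check_ordinal(responses, 0, 4, "density")
  if (anyNA(responses)) return(NA_real_)
  sum(w * responses)
}

#' Destination-proximity subscale score
#'
#' Arithmetic mean of walking-proximity ratings (1 = more than 30 minutes,
#' 5 = within 5 minutes) over a fixed destination list: 13 items for land
#' use mix -- diversity, 9 (standard) or 6 (Nigeria variant) for recreational
#' facilities.
#'
#' @param responses Ordinal responses in 1..5.
#' @param expected_k Required item count.
#' @return Mean in `[1, 5]`, or `NA` if any response is missing.
#' @export
score_destination_mix <- function(responses, expected_k) {
  if (length(responses) != expected_k)
    stop("expected ", expected_k, " proximity responses, got ", length(responses))
  check_ordinal(responses, 1, 5, "proximity")
  if (anyNA(responses)) return(NA_real_)
  mean(responses)
}

#' Reverse-code an ordinal response
#'
#' Maps `x` to `(scale_min + scale_max) - x` (sum 5 for the 1--4 Likert
#' items), so the coded direction is consistent with higher walkability and
#' safety. The map is a strictly decreasing involution of the scale.
#'
#' @param x Ordinal response(s).
#' @param scale_min,scale_max Scale endpoints; default the 1--4 Likert scale.
#' @return Reverse-coded value(s).
#' @export
reverse_code <- function(x, scale_min = 1, scale_max = 4) {
  check_ordinal(x, scale_min, scale_max, "item")
  (scale_min + scale_max) - x
}

#' Likert subscale score
#'
#' Mean of 4-point Likert responses after reverse-coding the items in
#' `reverse`; listwise missing rule (any missing item yields a missing
#' score) unless `min_prop` allows a mean over a sufficient fraction of
#' answered items.
#'
#' @param responses Named numeric vector (names = item ids) of responses in
#'   1..4.
#' @param reverse Character vector of item ids to reverse-code.
#' @param min_prop Minimum proportion of answered items required; default 1
#'   (listwise).
#' @return Mean in `[1, 4]`, or `NA` under the missing rule.
#' @export
score_likert_subscale <- function(responses, reverse = character(),
                                  min_prop = 1) {
  check_ordinal(responses, 1, 4, "Likert")
  if (length(reverse)) {
    if (is.null(names(responses)))
      stop("responses must be named when a reverse set is supplied")
    if (!all(reverse %in% names(responses)))
      stop("reverse set contains items not in the response vector")
    responses[reverse] <- 5 - responses[reverse]
  }
  answered <- mean(!is.na(responses))
  if (answered < min_prop || answered == 0) return(NA_real_)
  mean(responses, na.rm = TRUE)
}

#' Score a cohort table
#'
#' Applies the scoring protocol row-wise to a respondent-level item table,
#' producing one `<subscale>_score` column per subscale whose items are all
#' present in the table. Per-country variants are applied when the table has
#' `density_variant` / `recreation_variant` columns (as emitted by the
#' cohort generator) or when set globally via the `protocol` argument.
#' Identifier, covariate and exposure columns are carried through.
#'
#' @param table Data frame with item columns named by `item_id`.
#' @param protocol A `newsy_protocol`; default [scoring_protocol()].
#' @param min_prop Passed to [score_likert_subscale()].
#' @return The input data frame with appended `*_score` columns.
#' @export
score_cohort <- function(table, protocol = scoring_protocol(), min_prop = 1) {
  stopifnot(is.data.frame(table), inherits(protocol, "newsy_protocol"))
  variants_ok <- function(col, allowed) {
    if (!col %in% names(table)) return(invisible())
    bad <- setdiff(unique(table[[col]]), allowed)
    if (length(bad)) stop("unknown ", col, " value: ", paste(bad, collapse = ", "))
  }
  variants_ok("density_variant", c("standard", "no_item6"))
  variants_ok("recreation_variant", c("standard", "first6"))
  n <- nrow(table)
  out <- table

  dens_variant <- if ("density_variant" %in% names(table))
    table$density_variant else rep(attr(protocol, "density_variant"), n)
  rec_variant <- if ("recreation_variant" %in% names(table))
    table$recreation_variant else rep(attr(protocol, "recreation_variant"), n)

  for (sub in names(protocol)) {
    rule <- protocol[[sub]]
    if (sub == "residential_density") {
      k6 <- paste0("RD", 1:6)
      if (!all(k6[1:5] %in% names(table))) next
      has6 <- k6[6] %in% names(table)
      out[[paste0(sub, "_score")]] <- vapply(seq_len(n), function(i) {
        v <- dens_variant[i]
        ids <- if (v == "no_item6") k6[1:5] else k6
        if (v == "standard" && !has6) return(NA_real_)
        score_residential_density(as.numeric(table[i, ids]), variant = v)
      }, numeric(1))
    } else if (sub == "recreational_facilities") {
      if (!all(paste0("R", 1:6) %in% names(table))) next
      has9 <- all(paste0("R", 1:9) %in% names(table))
      out[[paste0(sub, "_score")]] <- vapply(seq_len(n), function(i) {
        v <- rec_variant[i]
        ids <- if (v == "first6") paste0("R", 1:6) else paste0("R", 1:9)
        if (v == "standard" && !has9) return(NA_real_)
        score_destination_mix(as.numeric(table[i, ids]), length(ids))
      }, numeric(1))
    } else if (rule$rule == "mean" && identical(rule$range, c(1, 5))) {
      if (!all(rule$items %in% names(table))) next
      mat <- as.matrix(table[, rule$items, drop = FALSE])
      out[[paste0(sub, "_score")]] <- apply(mat, 1, score_destination_mix,
                                            expected_k = length(rule$items))
    } else {
      if (!all(rule$items %in% names(table))) next
      mat <- as.matrix(table[, rule$items, drop = FALSE])
      out[[paste0(sub, "_score")]] <- apply(mat, 1, function(r) {
        names(r) <- rule$items
        score_likert_subscale(r, reverse = rule$reverse, min_prop = min_prop)
      })
    }
  }
  out
}
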