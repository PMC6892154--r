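# Published reference values used to parameterize the synthetic cohorts and
# the built-in measurement models: country sample sizes and sample
# composition, per-country subscale means/SDs, and standardized loadings of
# the final country-specific measurement models.

#' Country profiles of the IPEN Adolescent samples
#'
#' One row per country with the published sample size, percentage of male
#' adolescents, and mean/SD of each of the eight NEWS-Y-IPEN subscales
#' (`<subscale>_mean`, `<subscale>_sd`). Columns `n_units`, `n_schools` and
#' `unit_icc` parameterize the clustering of the synthetic cohorts: the
#' source tables do not report administrative-unit counts or unit-level
#' intraclass correlations, so the defaults (16 units and 8 schools per
#' country, unit ICC 0.05) are package choices, documented in the methods
#' vignette and overridable by editing the returned data frame.
#' `adolescent_report` flags New Zealand, the one site where adolescents
#' rather than parents answered the survey.
#'
#' @return A data frame of class `newsy_profiles`, 15 rows.
#' @export
country_profiles <- function() {
  # columns per subscale: mean, sd (residential density; land use mix -
  # diversity; recreational facilities; accessibility & walking; traffic
  # safety; pedestrian infrastructure; safety from crime; aesthetics)
  raw <- list(
    #            n    male%  rd            lud          rf           aw           ts           pi           cr           ae
    australia   = list(238, 40.3, c(43.8, 83.8),  c(3.14, .81), c(2.77, .88), c(3.26, .48), c(2.89, .53), c(2.79, .54), c(3.15, .76), c(2.97, .76)),
    bangladesh  = list(86,  51.2, c(177.3, 84.7), c(3.35, .61), c(1.97, .73), c(2.84, .57), c(2.38, .58), c(2.47, .60), c(1.99, .87), c(1.75, .72)),
    belgium     = list(279, 41.9, c(69.2, 105.7), c(3.52, .76), c(2.77, .88), c(2.98, .57), c(2.50, .57), c(2.67, .58), c(3.11, .75), c(2.27, .68)),
    brazil      = list(491, 49.1, c(95.4, 123.4), c(3.14, .65), c(2.45, .83), c(2.91, .63), c(2.15, .77), c(2.56, .81), c(2.01, .82), c(2.37, .85)),
    czech       = list(183, 42.6, c(131.4, 105.9), c(3.28, .81), c(3.00, .89), c(3.17, .49), c(2.87, .56), c(3.01, .56), c(2.85, .71), c(2.24, .63)),
    denmark     = list(197, 57.9, c(103.9, 107.5), c(2.29, .64), c(2.62, .69), c(3.07, .46), c(2.94, .70), c(2.92, .68), c(3.67, .59), c(2.66, .75)),
    hongkong    = list(1291, 42.8, c(468.7, 203.2), c(3.47, .78), c(2.88, .88), c(2.99, .49), c(2.82, .50), c(2.95, .56), c(2.69, .87), c(2.47, .68)),
    india       = list(315, 52.4, c(65.9, 78.2),  c(3.41, .61), c(1.78, .60), c(2.58, .59), c(2.27, .68), c(2.93, .80), c(3.02, 1.11), c(1.51, .81)),
    israel      = list(109, 38.5, c(220.3, 136.6), c(3.07, .85), c(2.47, .84), c(3.13, .50), c(2.31, .72), c(2.85, .75), c(3.13, .95), c(2.39, .77)),
    malaysia    = list(348, 40.2, c(294.0, 230.0), c(2.77, .78), c(2.31, .88), c(2.77, .43), c(2.37, .53), c(2.68, .58), c(2.04, .71), c(2.52, .63)),
    newzealand  = list(400, 55.5, c(57.5, 97.6),  c(2.86, .77), c(2.69, .81), c(2.88, .49), c(2.90, .53), c(2.81, .58), c(3.67, .52), c(2.72, .68)),
    nigeria     = list(258, 55.0, c(269.4, 153.8), c(3.43, .78), c(3.08, .60), c(2.73, .66), c(2.96, .88), c(2.97, .83), c(2.73, 1.15), c(2.93, .85)),
    portugal    = list(132, 34.8, c(119.0, 91.7), c(3.58, .74), c(2.62, .93), c(3.58, .42), c(2.78, .45), c(2.89, .49), c(2.99, .53), c(2.39, .52)),
    spain       = list(465, 44.9, c(251.1, 134.7), c(4.23, .50), c(2.94, .80), c(2.96, .36), c(2.61, .72), c(3.03, .62), c(3.25, .79), c(2.25, .74)),
    usa         = list(922, 49.7, c(31.1, 47.9),  c(2.81, .87), c(2.87, .89), c(2.90, .62), c(2.58, .58), c(2.83, .65), c(3.01, .73), c(3.08, .69))
  )
  sub <- news_subscales()
  out <- data.frame(country = names(raw),
                    n = vapply(raw, function(x) as.integer(x[[1]]), integer(1)),
                    pct_male = vapply(raw, function(x) x[[2]], numeric(1)))
  for (k in seq_along(sub)) {
    out[[paste0(sub[k], "_mean")]] <- vapply(raw, function(x) x[[k + 2]][1], numeric(1))
    out[[paste0(sub[k], "_sd")]] <- vapply(raw, function(x) x[[k + 2]][2], numeric(1))
  }
  out$n_units <- 16L
  out$n_schools <- 8L
  out$unit_icc <- 0.05
  out$adolescent_report <- out$country == "newzealand"
  out$density_variant <- ifelse(out$country == "denmark", "no_item6", "standard")
  out$recreation_variant <- ifelse(out$country == "nigeria", "first6", "standard")
  rownames(out) <- NULL
  class(out) <- c("newsy_profiles", "data.frame")
  out
}

# Standardized loadings of the final five-factor country models (18 items x
# 10 CFA-eligible countries), stored signed: the crime-fear and several
# traffic/hill items load negatively because their raw direction opposes
# walkability/safety. Reversal belongs to the scoring protocol, not the CFA.
final_loading_table <- function() {
  items <- c(paste0("AW", 1:5), paste0("TS", 1:3), paste0("PI", 1:3),
             paste0("CR", 1:4), paste0("AE", 1:3))
  m <- rbind(
    #      aus    bel    bra    hk     ind    mys    nzl    nga    esp    usa
    AW1 = c(-.38, -.35, -.31, -.31, -.28, -.31, -.25, -.29, -.34, -.34),
    AW2 = c(.29,  .36,  .37,  .36,  .31,  .39,  .24,  .33,  .39,  .32),
    AW3 = c(.52,  .48,  .26,  .53,  .33,  .36,  .32,  .42,  .40,  .41),
    AW4 = c(.46,  .92,  .54,  .57,  .84,  .78,  .53,  .71,  .70,  .89),
    AW5 = c(.56,  .70,  .36,  .30,  .76,  .50,  .42,  .72,  .53,  .64),
    TS1 = c(-.68, -.73, -.55, -.40, -.85, -.47, -.43, -.49, -.60, -.55),
    TS2 = c(.34,  .34,  .41,  .38,  .44,  .34,  .32,  .58,  .63,  .47),
    TS3 = c(-.30, -.48, -.39, -.51, -.39, -.58, -.43, -.71, -.58, -.37),
    PI1 = c(.36,  .43,  .47,  .60,  .37,  .50,  .55,  .48,  .36,  .64),
    PI2 = c(.39,  .41,  .36,  .41,  .43,  .68,  .40,  .38,  .65,  .59),
    PI3 = c(.60,  .75,  .43,  .59,  .36,  .51,  .31,  .52,  .58,  .62),
    CR1 = c(-.72, -.89, -.92, -.91, -.85, -.78, -.77, -.76, -.84, -.66),
    CR2 = c(-.73, -.91, -.86, -.95, -.96, -.90, -.77, -.94, -.92, -.57),
    CR3 = c(-.98, -.95, -.47, -.94, -.77, -.87, -.84, -.95, -.97, -.94),
    CR4 = c(-.85, -.82, -.32, -.91, -.61, -.81, -.72, -.87, -.90, -.78),
    AE1 = c(.90,  .77,  .76,  .63,  .76,  .78,  .70,  .54,  .70,  .78),
    AE2 = c(.88,  .59,  .66,  .83,  .82,  .74,  .78,  .73,  .65,  .85),
    AE3 = c(.71,  .75,  .40,  .64,  .51,  .63,  .56,  .65,  .69,  .67)
  )
  colnames(m) <- cfa_countries()
  stopifnot(identical(rownames(m), items))
  m
}

#' Countries with a published country-specific measurement model
#'
#' The ten countries whose samples exceeded the n > 200 eligibility rule for
#' confirmatory factor analysis.
#'
#' @return Character vector of country keys.
#' @export
cfa_countries <- function() {
  c("australia", "belgium", "brazil", "hongkong", "india",
    "malaysia", "newzealand", "nigeria", "spain", "usa")
}

# Per-country structural metadata of the final models: number of correlated
# error pairs, number of free inter-factor covariances (pinned by
# df-consistency with the published chi-square df), the reported
# maximum-correlation factor pair, and the reported average absolute
# inter-factor correlation (used as the uniform generation default).
final_model_meta <- function() {
  data.frame(
    country = cfa_countries(),
    n_residual_pairs = c(3L, 3L, 1L, 1L, 2L, 4L, 0L, 0L, 0L, 1L),
    n_free_cov = c(8L, 7L, 8L, 6L, 4L, 6L, 7L, 2L, 9L, 5L),
    max_pair = c("TS-AE", "AW-PI", "AW-PI", "AW-PI", "AW-PI",
                 "TS-CR", "TS-PI", "PI-AE", "TS-PI", "AW-PI"),
    avg_abs_cor = c(.29, .23, .30, .20, .11, .24, .17, .11, .26, .19),
    final_df = c(124L, 125L, 126L, 128L, 129L, 125L, 128L, 133L, 126L, 129L)
  )
}

#' Default construct-validity effect configuration
#'
#' Fixed effects of binary area-level SES and walkability on each subscale
#' used by the cohort generator, taken from the published pooled
#' construct-validity coefficients (subscale-score units per exposure
#' contrast), plus adolescent age and sex effects (default 0: the published
#' models adjust for them but do not report their coefficients).
#'
#' @param null_effects If `TRUE`, all exposure effects are zero (used for
#'   calibration simulations).
#' @return A list with per-subscale numeric vectors `ses` and `walk`, and
#'   scalars `age` and `sex`.
#' @export
exposure_effects <- function(null_effects = FALSE) {
  sub <- news_subscales()
  ses <- c(-3.45, 0.01, 0.14, 0.02, 0.05, 0.00, 0.16, 0.18)
  walk <- c(50.36, 0.44, 0.16, 0.24, -0.01, 0.16, 0.01, 0.06)
  names(ses) <- names(walk) <- sub
  if (null_effects) ses[] <- walk[] <- 0
  list(ses = ses, walk = walk, age = 0, sex = 0)
}

#' Default construct-validity hypotheses
#'
#' The a priori expectations for each subscale--exposure pair: density and
#' destination-availability subscales should track area-level walkability,
#' safety and aesthetics subscales should track area-level SES, recreation
#' and pedestrian infrastructure both, and the remaining pairs should show no
#' association (the stratified design balances walkability by SES).
#'
#' @return Data frame with columns `subscale`, `exposure`, `expected`
#'   (`"+"` or `"0"`).
#' @export
validity_hypotheses <- function() {
  sub <- news_subscales()
  pos_walk <- c("residential_density", "land_use_mix_diversity",
                "recreational_facilities", "accessibility_walking",
                "pedestrian_infrastructure")
  pos_ses <- c("recreational_facilities", "traffic_safety",
               "pedestrian_infrastructure", "safety_from_crime", "aesthetics")
  out <- expand.grid(subscale = sub, exposure = c("ses", "walk"),
                     stringsAsFactors = FALSE)
  out$expected <- ifelse(
    (out$exposure == "walk" & out$subscale %in% pos_walk) |
      (out$exposure == "ses" & out$subscale %in% pos_ses), "+", "0")
  out[order(match(out$subscale, sub)), c("subscale", "exposure", "expected")]
}
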