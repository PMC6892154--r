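#' NEWS-Y-IPEN item catalogue
#'
#' Returns the definition of every NEWS-Y-IPEN item handled by the package:
#' the six weighted residential-density items (`RD1`--`RD6`, rated 0--4), the
#' thirteen land-use-mix--diversity destination items (`D01`--`D13`) and nine
#' recreational-facility items (`R1`--`R9`) rated on the 1--5 walking-proximity
#' scale, and the 22 factor-analyzable 4-point Likert items (1 = strongly
#' disagree; 4 = strongly agree). Items dropped during re-specification of the
#' measurement model (`PK1` difficult parking, `GD1` grass/dirt strip, `TR1`
#' trees along streets, `HC1` high crime rate) are retained because the a
#' priori model uses them. `reverse_coded` marks items whose raw direction is
#' opposite to "higher walkability and safety"; the destination wordings for
#' `D01`--`D13`/`R1`--`R9` are placeholders since the original supplementary
#' item lists are not distributed with the package.
#'
#' @return A data frame with columns `item_id`, `label`, `scale_min`,
#'   `scale_max`, `reverse_coded` and `block` (`density`, `diversity`,
#'   `recreation`, `likert`).
#' @export
news_items <- function() {
  likert <- function(id, label, rev = FALSE)
    data.frame(item_id = id, label = label, scale_min = 1L, scale_max = 4L,
               reverse_coded = rev, block = "likert")
  rows <- list(
    data.frame(item_id = paste0("RD", 1:6),
               label = c("Single-family residences",
                         "Multi-family houses of 1-3 stories",
                         "Multi-family houses of 1-3 stories (as printed)",
                         "Multi-family houses of 7-12 stories",
                         "Multi-family houses of 13-20 stories",
                         "Multi-family houses of over 20 stories"),
               scale_min = 0L, scale_max = 4L, reverse_coded = FALSE,
               block = "density"),
    data.frame(item_id = sprintf("D%02d", 1:13),
               label = sprintf("Destination type %d (land use mix - diversity)", 1:13),
               scale_min = 1L, scale_max = 5L, reverse_coded = FALSE,
               block = "diversity"),
    data.frame(item_id = paste0("R", 1:9),
               label = sprintf("Recreational facility type %d", 1:9),
               scale_min = 1L, scale_max = 5L, reverse_coded = FALSE,
               block = "recreation"),
    likert("AW1", "Hilly streets make it difficult to walk in the neighborhood", TRUE),
    likert("AW2", "Less cul-de-sacs in the neighborhood"),
    likert("AW3", "Many different routes for getting from place to place"),
    likert("AW4", "Presence of sidewalks on most of the streets"),
    likert("AW5", "Sidewalks separated from the road / traffic by parked cars"),
    likert("TS1", "Difficult/unpleasant to walk due to traffic in the neighborhood", TRUE),
    likert("TS2", "Speed of traffic usually slow (30 mph)"),
    likert("TS3", "Drivers drive faster than speed limit", TRUE),
    likert("PI1", "Good lighting at night"),
    likert("PI2", "Easy view of walkers / bikers from houses"),
    likert("PI3", "Crosswalks and signals to cross busy streets"),
    likert("CR1", "Fear of child being hurt by a stranger when alone outside around the home", TRUE),
    likert("CR2", "Fear of child being hurt by a stranger when with a friend outside around the home", TRUE),
    likert("CR3", "Fear of child being hurt by a stranger when walking in local streets", TRUE),
    likert("CR4", "Fear of child being hurt by a stranger in a local park", TRUE),
    likert("AE1", "Interesting things to look at"),
    likert("AE2", "Beautiful natural things to look at"),
    likert("AE3", "Buildings / homes nice to look at"),
    likert("PK1", "Parking is difficult in shopping areas", TRUE),
    likert("GD1", "Presence of grass / dirt between the streets and the sidewalks"),
    likert("TR1", "Presence of trees along the streets"),
    likert("HC1", "High crime rate", TRUE)
  )
  out <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(out$item_id), all(out$scale_min < out$scale_max))
  rownames(out) <- NULL
  out
}

#' Names of the eight NEWS-Y-IPEN subscales
#'
#' @return Character vector of subscale identifiers in instrument order.
#' @export
news_subscales <- function() {
  c("residential_density", "land_use_mix_diversity", "recreational_facilities",
    "accessibility_walking", "traffic_safety", "pedestrian_infrastructure",
    "safety_from_crime", "aesthetics")
}

#' Default NEWS-Y-IPEN scoring protocol
#'
#' Encodes the common scoring algorithm: a weighted sum for residential
#' density (weights 1, 11, 25, 50, 75, 100 per housing-type item), plain
#' averages over the 13 diversity and 9 recreation proximity items, and
#' averages of the 4-point Likert items per factor-analyzable subscale after
#' reverse-coding the items whose direction opposes walkability/safety (AW1;
#' TS1, TS3; CR1--CR4; the reversal set follows the sign of the published
#' standardized loadings). Variants: `density_variant = "no_item6"` drops the
#' sixth density item (Denmark; no >20-story buildings on site) and
#' `recreation_variant = "first6"` restricts the recreation average to the
#' first six facility items (Nigeria).
#'
#' @param density_variant `"standard"` or `"no_item6"`.
#' @param recreation_variant `"standard"` or `"first6"`.
#' @return A list of per-subscale scoring rules of class `newsy_protocol`.
#' @export
scoring_protocol <- function(density_variant = c("standard", "no_item6"),
                             recreation_variant = c("standard", "first6")) {
  density_variant <- match.arg(density_variant)
  recreation_variant <- match.arg(recreation_variant)
  rec_items <- paste0("R", 1:9)
  if (recreation_variant == "first6") rec_items <- rec_items[1:6]
  dens_items <- paste0("RD", 1:6)
  dens_w <- c(1, 11, 25, 50, 75, 100)
  if (density_variant == "no_item6") {
    dens_items <- dens_items[1:5]
    dens_w <- dens_w[1:5]
  }
  proto <- list(
    residential_density = list(items = dens_items, weights = dens_w,
                               rule = "weighted_sum", range = c(0, sum(4 * dens_w))),
    land_use_mix_diversity = list(items = sprintf("D%02d", 1:13), rule = "mean",
                                  reverse = character(), range = c(1, 5), scale_sum = 6),
    recreational_facilities = list(items = rec_items, rule = "mean",
                                   reverse = character(), range = c(1, 5), scale_sum = 6),
    accessibility_walking = list(items = paste0("AW", 1:5), rule = "mean",
                                 reverse = "AW1", range = c(1, 4), scale_sum = 5),
    traffic_safety = list(items = paste0("TS", 1:3), rule = "mean",
                          reverse = c("TS1", "TS3"), range = c(1, 4), scale_sum = 5),
    pedestrian_infrastructure = list(items = paste0("PI", 1:3), rule = "mean",
                                     reverse = character(), range = c(1, 4), scale_sum = 5),
    safety_from_crime = list(items = paste0("CR", 1:4), rule = "mean",
                             reverse = paste0("CR", 1:4), range = c(1, 4), scale_sum = 5),
    aesthetics = list(items = paste0("AE", 1:3), rule = "mean",
                      reverse = character(), range = c(1, 4), scale_sum = 5)
  )
  attr(proto, "density_variant") <- density_variant
  attr(proto, "recreation_variant") <- recreation_variant
  class(proto) <- "newsy_protocol"
  proto
}
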