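#' Global and population-level ancestry estimation
#'
#' From per-marker local-ancestry calls to individual global proportions
#' (fraction of bases assigned to each ancestry), region-weighted national
#' estimates correcting for over/under-sampled regions, demographic-zone
#' grouping, and zone comparisons by one-way ANOVA with Tukey HSD.
#'
#' @name ancestry_estimation
NULL

#' Individual global ancestry proportions
#'
#' Each marker is weighted by half the bp distance to each neighbour
#' (half-interval at chromosome ends), approximating the number of bases
#' its call represents; the proportion of an ancestry is the weighted
#' fraction of calls carrying it over both haplotypes.
#'
#' @param calls an `ancestry_calls`.
#' @return Matrix (individuals x K) of proportions; rows sum to 1.
#' @export
global_proportions <- function(calls) {
  if (!ncol(calls$labels)) stop("empty call set")
  w <- marker_bp_weights(calls$markers)
  K <- length(calls$ancestries)
  n <- n_individuals(calls)
  out <- matrix(0, n, K, dimnames = list(NULL, calls$ancestries))
  for (k in seq_len(K)) {
    wk <- (calls$labels == k) %*% w
    out[, k] <- wk[seq(1, 2 * n, 2)] + wk[seq(2, 2 * n, 2)]
  }
  out / (2 * sum(w))
}

#' Region sampling weights
#'
#' The weight of a region is the ratio of its census (population) fraction
#' to its sample fraction, so under-sampled regions count more in national
#' estimates. Fractions are taken from the printed percentage columns when
#' present, otherwise from raw sample counts.
#'
#' @param region_table data frame with `region` and either `sample_pct`
#'   and `census_pct` (percent) or `n_sample` plus `census_pct`.
#' @return The table with a `weight` column (full precision; round to 2
#'   decimals for display). Regions without a census fraction (e.g. an
#'   "Unknown" row) get weight 1.
#' @examples
#' region_weights(chile_region_table())
#' @export
region_weights <- function(region_table) {
  rt <- as.data.frame(region_table)
  if (is.null(rt$sample_pct)) {
    if (is.null(rt$n_sample)) stop("need sample_pct or n_sample")
    rt$sample_pct <- 100 * rt$n_sample / sum(rt$n_sample)
  }
  if (is.null(rt$census_pct)) stop("need census_pct")
  w <- rt$census_pct / rt$sample_pct
  bad <- !is.na(rt$census_pct) & rt$sample_pct == 0
  if (any(bad)) stop("region with census fraction but zero sample fraction: ",
                     paste(rt$region[bad], collapse = ", "))
  w[is.na(rt$census_pct)] <- 1
  rt$weight <- w
  rt
}

#' Weighted population ancestry proportions
#'
#' Weighted average of individual proportions, \eqn{\sum_i w_i p_{ik} /
#' \sum_i w_i} per ancestry k.
#'
#' @param proportions matrix (individuals x K) of global proportions.
#' @param weights per-individual non-negative weights (default all 1).
#' @return Named length-K vector.
#' @export
weighted_proportions <- function(proportions, weights = NULL) {
  proportions <- as.matrix(proportions)
  if (is.null(weights)) weights <- rep(1, nrow(proportions))
  if (length(weights) != nrow(proportions))
    stop("one weight per individual required")
  if (any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative and not all zero")
  drop(crossprod(proportions, weights)) / sum(weights)
}

#' Map per-individual regions to weights
#'
#' @param regions character vector of per-individual region names.
#' @param region_table table accepted by [region_weights()].
#' @param unknown_weight weight for individuals whose region is missing or
#'   unmapped (default 1: retained nationally).
#' @return Numeric vector of per-individual weights.
#' @export
individual_weights <- function(regions, region_table, unknown_weight = 1) {
  rw <- region_weights(region_table)
  w <- rw$weight[match(regions, rw$region)]
  w[is.na(w)] <- unknown_weight
  w
}

#' Group sampled regions into demographic zones
#'
#' @param region_table table with `region` and `n_sample`.
#' @param zone_map data frame `region`, `zone`; regions absent from the
#'   map (e.g. "Unknown") fall outside every zone.
#' @param zone_levels display order of zones.
#' @return List with `counts` (named per-zone sample counts),
#'   `membership` (region -> zone on the sampled regions) and
#'   `n_unzoned` (samples outside all zones).
#' @export
assign_zones <- function(region_table, zone_map,
                         zone_levels = c("N", "C1", "C2", "S1", "S2")) {
  rt <- as.data.frame(region_table)
  zm <- as.data.frame(zone_map)
  zone <- zm$zone[match(rt$region, zm$region)]
  unmapped <- is.na(zone) & rt$n_sample > 0 & !(rt$region %in% c("Unknown", NA))
  if (any(unmapped))
    stop("sampled region(s) not covered by the zone map: ",
         paste(rt$region[unmapped], collapse = ", "))
  zl <- intersect(zone_levels, unique(zone[!is.na(zone)]))
  counts <- vapply(zl, function(z) sum(rt$n_sample[!is.na(zone) & zone == z]),
                   numeric(1))
  list(counts = counts,
       membership = data.frame(region = rt$region, zone = zone,
                               n_sample = rt$n_sample, stringsAsFactors = FALSE),
       n_unzoned = sum(rt$n_sample[is.na(zone)]))
}

#' Compare an ancestry proportion across zones
#'
#' One-way ANOVA with Tukey HSD (studentized-range adjusted) pairwise
#' comparisons, plus box-plot summaries per zone. Zones with fewer than
#' two members are reported but excluded from the test.
#'
#' @param values numeric vector of per-individual proportions.
#' @param zones factor/character of per-individual zone labels (NA =
#'   outside all zones, dropped).
#' @param weights optional per-individual weights used for the per-zone
#'   weighted means (the test itself is unweighted).
#' @return List with `means`, `anova` (the `aov` summary), `tukey`
#'   (data frame: comparison, diff, lwr, upr, p_adj), `box_stats`
#'   (per-zone median/quartiles/whiskers) and `excluded_zones`.
#' @export
zone_comparison <- function(values, zones, weights = NULL) {
  keep <- !is.na(zones) & !is.na(values)
  values <- values[keep]
  zones <- factor(as.character(zones[keep]), levels = unique(as.character(zones[keep])))
  if (!is.null(weights)) weights <- weights[keep]
  tab <- table(zones)
  small <- names(tab)[tab < 2]
  use <- !(zones %in% small)
  zu <- droplevels(zones[use])
  if (nlevels(zu) < 2) stop("need at least two zones with >= 2 members")
  fit <- stats::aov(values[use] ~ zu)
  tk <- stats::TukeyHSD(fit)$zu
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  means <- if (is.null(weights)) {
    tapply(values, zones, mean)
  } else {
    mapply(function(v, w) sum(v * w) / sum(w),
           split(values, zones), split(weights, zones))
  }
  box_stats <- t(vapply(split(values, zones),
                        function(v) grDevices::boxplot.stats(v)$stats,
                        numeric(5)))
  colnames(box_stats) <- c("whisker_lo", "q1", "median", "q3", "whisker_hi")
  list(means = means, anova = summary(fit), tukey = tukey,
       box_stats = box_stats, excluded_zones = small)
}

#' Chilean political-region sampling table
#'
#' The 15 continental political regions (north to south) plus an Unknown
#' row: sample percentage, sample count and census (population)
#' percentage of a 313-individual nationwide cohort.
#'
#' @return Data frame `region`, `sample_pct`, `n_sample`, `census_pct`.
#' @export
chile_region_table <- function() {
  data.frame(
    region = c("Arica y Parinacota", "Tarapacá", "Antofagasta", "Atacama",
               "Coquimbo", "Valparaíso", "Metropolitana", "O'Higgins",
               "Maule", "Bio-bio", "Araucanía", "Los Ríos",
               "Los Lagos", "Aysén", "Magallanes", "Unknown"),
    sample_pct = c(0.6, 1.6, 0.6, 1.0, 1.3, 9.3, 39.6, 1.9, 2.9, 10.2, 8.3,
                   8.3, 6.7, 2.9, 1.0, 3.8),
    n_sample = c(2L, 5L, 2L, 3L, 4L, 29L, 124L, 6L, 9L, 32L, 26L, 26L, 21L,
                 9L, 3L, 12L),
    census_pct = c(1.1, 1.8, 3.4, 1.6, 4.2, 10.3, 40.3, 5.2, 5.9, 11.9, 5.7,
                   2.2, 4.9, 0.6, 0.9, NA),
    stringsAsFactors = FALSE)
}

#' North-to-south demographic zone map for the Chilean regions
#'
#' Zones: N (Arica y Parinacota to Coquimbo), C1 (Valparaiso to O'Higgins),
#' C2 (Maule, Bio-bio), S1 (Araucania to Los Lagos), S2 (Aysen,
#' Magallanes). The Unknown row belongs to no zone.
#'
#' @return Data frame `region`, `zone`.
#' @export
chile_zone_map <- function() {
  data.frame(
    region = c("Arica y Parinacota", "Tarapacá", "Antofagasta", "Atacama",
               "Coquimbo", "Valparaíso", "Metropolitana", "O'Higgins",
               "Maule", "Bio-bio", "Araucanía", "Los Ríos",
               "Los Lagos", "Aysén", "Magallanes"),
    zone = c(rep("N", 5), rep("C1", 3), rep("C2", 2), rep("S1", 3),
             rep("S2", 2)),
    stringsAsFactors = FALSE)
}
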