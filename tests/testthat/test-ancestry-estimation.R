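test_that("base-weighted global proportions match the half-interval arithmetic", {
  # 3 equally spaced markers, haplotypes (NAT,NAT,EUR) and (EUR,EUR,EUR):
  # weights 1/4, 1/2, 1/4 per haplotype -> NAT share 3/8
  calls <- manual_calls(rbind(c(1L, 1L, 2L), c(2L, 2L, 2L)))
  gp <- global_proportions(calls)
  expect_equal(unname(gp[1, "NAT"]), 3 / 8)
  expect_equal(unname(gp[1, "EUR"]), 5 / 8)

  all_eur <- manual_calls(rbind(rep(2L, 5), rep(2L, 5)))
  expect_equal(unname(global_proportions(all_eur)[1, ]), c(0, 1))
})

test_that("global proportion rows always sum to 1", {
  set.seed(61)
  labels <- matrix(sample(1:3, 20 * 40, replace = TRUE), 20, 40)
  gp <- global_proportions(manual_calls(labels,
                                        chrom = rep(c("chr1", "chr2"), each = 20)))
  expect_equal(unname(rowSums(gp)), rep(1, 10), tolerance = 1e-9)
})

test_that("region weights reproduce the census/sample ratio worked examples", {
  rw <- region_weights(chile_region_table())
  expect_equal(round(rw$weight[rw$region == "Arica y Parinacota"], 2), 1.83)
  expect_equal(round(rw$weight[rw$region == "Metropolitana"], 2), 1.02)
  expect_equal(rw$weight[rw$region == "Unknown"], 1)  # no census fraction
  eq <- region_weights(data.frame(region = "r", sample_pct = 5, n_sample = 5,
                                  census_pct = 5))
  expect_equal(eq$weight, 1)
})

test_that("weighted population proportions follow the weighted-average formula", {
  props <- rbind(c(0.4, 0.5, 0.1), c(0.6, 0.3, 0.1))
  colnames(props) <- c("NAT", "EUR", "AFR")
  expect_equal(unname(weighted_proportions(props)["NAT"]), 0.5)
  p2 <- rbind(c(0.2, 0.7, 0.1), c(0.8, 0.1, 0.1))
  expect_equal(unname(weighted_proportions(p2, c(1, 3))[1]), 0.65)
  # identical individuals: estimate equals the shared triple
  p3 <- rbind(c(0.3, 0.6, 0.1), c(0.3, 0.6, 0.1))
  expect_equal(unname(weighted_proportions(p3, c(2, 5))), c(0.3, 0.6, 0.1))
  # equal weights = unweighted mean; invariant to weight rescaling
  set.seed(62)
  p4 <- matrix(runif(30), 10, 3); p4 <- p4 / rowSums(p4)
  w <- runif(10)
  expect_equal(weighted_proportions(p4), colMeans(p4))
  expect_equal(weighted_proportions(p4, w), weighted_proportions(p4, 10 * w))
  expect_error(weighted_proportions(p4, rep(0, 10)), "not all zero")
})

test_that("zone assignment reproduces the north-to-south grouping counts", {
  za <- assign_zones(chile_region_table(), chile_zone_map())
  expect_equal(za$counts, c(N = 16, C1 = 159, C2 = 41, S1 = 73, S2 = 12))
  expect_equal(za$n_unzoned, 12)       # Unknown row outside every zone
  expect_equal(sum(chile_region_table()$n_sample), 313)
  bad_map <- chile_zone_map()[-1, ]    # drop a sampled region
  expect_error(assign_zones(chile_region_table(), bad_map), "Arica")
})

test_that("zone comparison returns k(k-1)/2 Tukey rows and sane box stats", {
  set.seed(63)
  zones <- rep(c("N", "C1", "C2", "S1", "S2"), each = 20)
  vals <- rnorm(100, mean = rep(c(4, 3, 2.5, 2, 1.5), each = 20), sd = 0.5)
  zc <- zone_comparison(vals, zones)
  expect_equal(nrow(zc$tukey), 10)
  expect_equal(colnames(zc$box_stats),
               c("whisker_lo", "q1", "median", "q3", "whisker_hi"))
  expect_equal(unname(zc$box_stats[, "median"]),
               unname(vapply(split(vals, factor(zones, unique(zones))),
                             median, numeric(1))))
  # near-constant groups: every adjusted p ~ 1 (exact ties break aov)
  const <- rep(c(1, 1 + 1e-9, 1 - 1e-9), 10) + rep(0, 30)
  zc0 <- zone_comparison(const, rep(c("a", "b"), each = 15))
  expect_true(all(zc0$tukey$p_adj > 0.999))
})

test_that("Tukey q statistics match the hand-computed studentized range", {
  # classic 3-group layout, n = 4 each
  g <- list(a = c(18, 20, 21, 22), b = c(24, 25, 27, 26), c = c(30, 31, 29, 33))
  vals <- unlist(g); zones <- rep(names(g), each = 4)
  zc <- zone_comparison(vals, zones)
  mse <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1))) / 9
  for (i in seq_len(nrow(zc$tukey))) {
    pair <- strsplit(zc$tukey$comparison[i], "-")[[1]]
    d_hand <- mean(g[[pair[1]]]) - mean(g[[pair[2]]])
    expect_equal(zc$tukey$diff[i], d_hand)
    # adjusted p from the studentized-range distribution, computed directly
    q_hand <- abs(d_hand) / sqrt(mse / 4)
    expect_equal(zc$tukey$p_adj[i], stats::ptukey(q_hand, 3, 9, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
  # a zone with < 2 members is excluded but reported
  zc2 <- zone_comparison(c(vals, 10), c(zones, "d"))
  expect_equal(zc2$excluded_zones, "d")
  expect_equal(nrow(zc2$tukey), 3)
})

test_that("a configured north-to-south AFR gradient is recovered in zone means", {
  map <- tiny_map(morgans = 2, markers = 150, seed = 71)
  panel <- tiny_panel(map, seed = 72)
  zones5 <- c("N", "C1", "C2", "S1", "S2")
  afr <- c(0.10, 0.06, 0.04, 0.025, 0.01)
  rt <- data.frame(region = zones5, n_sample = rep(50, 5))
  props <- lapply(afr, function(a) c(NAT = 0.45, EUR = 0.55 - a, AFR = a))
  names(props) <- zones5
  cfg <- sim_cohort_config(region_table = rt, region_props = props,
                           T_admix = 10, seed = 73)
  sim <- simulate_cohort(cfg, panel, map)
  gp <- global_proportions(sim$truth_calls)
  zone_means <- tapply(gp[, "AFR"], sim$regions, mean)[zones5]
  expect_equal(order(zone_means, decreasing = TRUE), 1:5)
})
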