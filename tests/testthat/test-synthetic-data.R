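test_that("Balding-Nichols panel degenerates to the base frequency at F = 0", {
  base <- function(n) rep(0.37, n)
  p <- gen_frequency_panel(50, F_st = c(A = 0, B = 0), base_freq_sampler = base,
                           seed = 1)
  expect_equal(unname(p$freqs[, 1]), rep(0.37, 50))
  expect_equal(unname(p$freqs[, 2]), rep(0.37, 50))
})

test_that("panel generation is deterministic given a seed and validates inputs", {
  a <- gen_frequency_panel(200, F_st = c(NAT = 0.2, EUR = 0.1), seed = 7)
  b <- gen_frequency_panel(200, F_st = c(NAT = 0.2, EUR = 0.1), seed = 7)
  expect_identical(a, b)
  expect_error(gen_frequency_panel(10, F_st = c(0.2, 1.0)), "F_st")
  expect_error(gen_frequency_panel(10, F_st = c(0.2, 0.2),
                                   base_freq_sampler = function(n) rep(1, n)),
               "base frequencies")
})

test_that("realized Hudson FST between two generated tracks matches the generating F", {
  p <- gen_frequency_panel(10000, F_st = c(A = 0.2, B = 0.2), seed = 21)
  haps <- gen_reference_haplotypes(p, 400, seed = 22)
  est <- fst_hudson(haps$A, haps$B, ploidy = 1)$fst
  expect_gt(est, 0.17)
  expect_lt(est, 0.23)
})

test_that("genetic map respects lengths, monotonicity and additivity", {
  m <- gen_genetic_map(c(1e6, 2e6), c(1, 2), 40, seed = 3)
  len <- map_length_morgans(m)
  expect_equal(len$total, 3)
  expect_equal(unname(len$per_chrom), c(1, 2))
  # uniform profile: cM strictly proportional to bp within a chromosome
  sub <- m[m$chrom == "chr1", ]
  expect_equal(sub$cM, (sub$bp - sub$bp[1]) / diff(range(sub$bp)) * 100)
  gaps <- marker_morgan_gaps(m)
  expect_true(all(gaps[is.finite(gaps)] >= 0))
  expect_equal(sum(gaps[is.finite(gaps)]), 3)
  expect_error(gen_genetic_map(-1, 1, 10), "positive")
})

test_that("T = 0 gives a single tract per haplotype-chromosome, pure proportions give one label", {
  map <- tiny_map(morgans = c(1, 1), markers = 20)
  cfg <- sim_cohort_config(n_individuals = 5, T_admix = 0, seed = 5)
  tr <- simulate_tracts(cfg, map)
  expect_equal(nrow(tr), 5 * 2 * 2)
  expect_equal(sum(count_switches(tr)), 0)

  cfg1 <- sim_cohort_config(n_individuals = 5, T_admix = 10,
                            proportions = c(NAT = 1, EUR = 0, AFR = 0), seed = 6)
  tr1 <- simulate_tracts(cfg1, map)
  expect_true(all(tr1$ancestry == "NAT"))
})

test_that("visible switch count matches the Poisson-thinning expectation", {
  # 1-Morgan chromosome, T = 10: junctions ~ Poisson(10) per haplotype,
  # visible with probability 1 - sum(p^2)
  map <- tiny_map(morgans = 1, markers = 2)
  p <- c(NAT = 0.5, EUR = 0.3, AFR = 0.2)
  cfg <- sim_cohort_config(n_individuals = 500, T_admix = 10,
                           proportions = p, seed = 8)
  tr <- simulate_tracts(cfg, map)
  per_ind <- count_switches(tr)  # both haplotypes
  expected <- 2 * 10 * 1 * (1 - sum(p^2))
  se <- sd(per_ind) / sqrt(length(per_ind))
  expect_lt(abs(mean(per_ind) - expected), 3 * se)
})

test_that("tract lengths follow the HI exponential limit", {
  # mean tract length for ancestry k ~ 1/(T (1 - p_k)) Morgans on a long
  # chromosome (interior tracts; censoring at ends biases short maps)
  map <- tiny_map(morgans = 50, markers = 2)
  p <- c(NAT = 0.6, EUR = 0.4)
  cfg <- sim_cohort_config(n_individuals = 60, T_admix = 10,
                           proportions = p, seed = 9)
  tr <- simulate_tracts(cfg, map)
  bp_per_morgan <- diff(range(map$bp)) / 50
  for (k in names(p)) {
    lens <- (tr$end - tr$start)[tr$ancestry == k] / bp_per_morgan
    expected <- 1 / (10 * (1 - p[[k]]))
    se <- sd(lens) / sqrt(length(lens))
    expect_lt(abs(mean(lens) - expected), 4 * se + 0.02 * expected)
  }
})

test_that("truth tracts tile every chromosome of every haplotype", {
  map <- tiny_map(morgans = c(1, 2), markers = 30)
  cfg <- sim_cohort_config(n_individuals = 8, T_admix = 12, seed = 10)
  tr <- simulate_tracts(cfg, map)
  for (ch in unique(map$chrom)) {
    ext <- range(map$bp[map$chrom == ch])
    sub <- split(tr[tr$chrom == ch, ], paste(tr$individual, tr$haplotype)[tr$chrom == ch])
    for (s in sub) {
      expect_equal(s$start[1], ext[1] - 1)
      expect_equal(s$end[nrow(s)], ext[2])
      if (nrow(s) > 1) {
        expect_equal(s$start[-1], s$end[-nrow(s)])       # no gaps/overlaps
        expect_true(all(s$ancestry[-1] != s$ancestry[-nrow(s)]))  # merged runs
      }
    }
  }
})

test_that("cohort emissions follow the panel frequencies of the truth ancestry", {
  map <- tiny_map(morgans = 1, markers = 60)
  panel <- tiny_panel(map, F_st = c(NAT = 0.4, EUR = 0.4))
  cfg <- sim_cohort_config(n_individuals = 250, T_admix = 5,
                           proportions = c(NAT = 0.5, EUR = 0.5), seed = 13)
  sim <- simulate_cohort(cfg, panel, map)
  # per-marker empirical allele frequency among haplotypes whose truth
  # ancestry is k approximates f_kj (binomial error)
  j_set <- c(5L, 30L, 55L)
  for (j in j_set) {
    for (k in 1:2) {
      rows <- sim$truth_calls$labels[, j] == k
      if (sum(rows) < 50) next
      emp <- mean(sim$haplotypes[rows, j])
      f <- panel$freqs[j, k]
      expect_lt(abs(emp - f), 4 * sqrt(f * (1 - f) / sum(rows)) + 1e-9)
    }
  }
})

test_that("deterministic emission cases and seed reproducibility hold", {
  map <- tiny_map(morgans = 1, markers = 10)
  panel <- tiny_panel(map, F_st = c(NAT = 0.3, EUR = 0.3))
  panel$freqs[, ] <- c(1, 0)[col(panel$freqs)]  # NAT fixed at 1, EUR at 0
  cfg <- sim_cohort_config(n_individuals = 4, T_admix = 3,
                           proportions = c(NAT = 0.5, EUR = 0.5), seed = 14)
  sim <- simulate_cohort(cfg, panel, map)
  expect_true(all(sim$haplotypes == (sim$truth_calls$labels == 1L)))
  sim2 <- simulate_cohort(cfg, panel, map)
  expect_identical(sim$haplotypes, sim2$haplotypes)
  expect_identical(sim$tracts, sim2$tracts)
})

test_that("marker mismatch between panel and map is rejected", {
  map <- tiny_map(morgans = 1, markers = 10)
  panel <- tiny_panel(map)
  map2 <- tiny_map(morgans = 1, markers = 10, seed = 99)
  cfg <- sim_cohort_config(n_individuals = 2, seed = 1)
  expect_error(simulate_cohort(cfg, panel, map2), "marker list")
})

test_that("per-region proportion profiles land on the configured individuals", {
  map <- tiny_map(morgans = 1, markers = 2)
  rt <- data.frame(region = c("north", "south"), n_sample = c(30, 30))
  cfg <- sim_cohort_config(region_table = rt, T_admix = 10,
                           region_props = list(
                             north = c(NAT = 0.3, EUR = 0.5, AFR = 0.2),
                             south = c(NAT = 0.5, EUR = 0.49, AFR = 0.01)),
                           seed = 15)
  tr <- simulate_tracts(cfg, map)
  regions <- rep(rt$region, rt$n_sample)
  afr_share <- sapply(split(seq_len(60), regions), function(idx) {
    sub <- tr[tr$individual %in% idx, ]
    sum((sub$end - sub$start)[sub$ancestry == "AFR"]) / sum(sub$end - sub$start)
  })
  expect_gt(afr_share[["north"]], afr_share[["south"]])
})
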