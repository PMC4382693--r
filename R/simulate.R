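#' Hybrid-isolation cohort simulation
#'
#' The simulator produces three-way admixed diploid genomes under a
#' hybrid-isolation (HI) model: all admixture happens in a single pulse T
#' generations ago, after which recombination breaks each haplotype into
#' ancestry tracts. On a chromosome of genetic length g Morgans, junctions
#' form a Poisson process of rate T per Morgan; segment labels between
#' junctions are drawn i.i.d. from the ancestry proportions p, and
#' adjacent same-label segments merge, so a junction is a visible ancestry
#' switch with probability 1 - sum(p^2).
#'
#' @name simulate
NULL

#' Cohort simulation configuration
#'
#' @param n_individuals number of admixed individuals (defaults to the sum
#'   of `region_table` sample counts if one is given).
#' @param T_admix admixture age in generations (>= 0). Default 10, a
#'   post-colonial Latin-American time depth.
#' @param proportions named ancestry proportions summing to 1
#'   (default `c(NAT = 0.45, EUR = 0.52, AFR = 0.03)`).
#' @param region_table optional data frame with columns `region` and
#'   `n_sample` (and optionally `sample_pct`, `census_pct`); individuals
#'   are assigned to regions by these counts.
#' @param region_props optional named list `region -> proportions`,
#'   overriding `proportions` per region (used to synthesise the
#'   north-to-south African-ancestry gradient).
#' @param genotype_error per-allele flip probability in `[0, 0.5)`.
#' @param missing_rate genotype missingness rate in `[0, 1)` (default 0).
#' @param seed integer seed driving all cohort randomness.
#' @return A `sim_config` list.
#' @export
sim_cohort_config <- function(n_individuals = NULL, T_admix = 10,
                              proportions = c(NAT = 0.45, EUR = 0.52, AFR = 0.03),
                              region_table = NULL, region_props = NULL,
                              genotype_error = 0, missing_rate = 0, seed = 1L) {
  if (!is.null(region_table)) {
    stopifnot(all(c("region", "n_sample") %in% names(region_table)))
    if (is.null(n_individuals)) n_individuals <- sum(region_table$n_sample)
    if (n_individuals != sum(region_table$n_sample))
      stop("n_individuals must equal the region_table sample total")
  }
  if (is.null(n_individuals) || n_individuals < 1)
    stop("n_individuals must be >= 1")
  if (T_admix < 0) stop("T_admix must be >= 0")
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  if (any(proportions < 0)) stop("proportions must be non-negative")
  if (genotype_error < 0 || genotype_error >= 0.5)
    stop("genotype_error must lie in [0, 0.5)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (!is.null(region_props)) {
    for (pr in region_props) {
      if (abs(sum(pr) - 1) > 1e-8) stop("each region proportion vector must sum to 1")
    }
  }
  structure(list(n_individuals = as.integer(n_individuals), T_admix = T_admix,
                 proportions = proportions, region_table = region_table,
                 region_props = region_props, genotype_error = genotype_error,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

region_assignment <- function(config) {
  if (is.null(config$region_table)) return(rep(NA_character_, config$n_individuals))
  rep(config$region_table$region, times = config$region_table$n_sample)
}

individual_proportions <- function(config) {
  regions <- region_assignment(config)
  K <- length(config$proportions)
  out <- matrix(rep(config$proportions, each = config$n_individuals),
                nrow = config$n_individuals, ncol = K,
                dimnames = list(NULL, names(config$proportions)))
  if (!is.null(config$region_props)) {
    for (r in names(config$region_props))
      out[regions == r & !is.na(regions), ] <-
        matrix(config$region_props[[r]], sum(regions == r, na.rm = TRUE), K, byrow = TRUE)
  }
  out
}

#' Simulate ancestry tracts under the hybrid-isolation model
#'
#' For every individual and haplotype, junctions are placed on each
#' chromosome as a Poisson process of rate `T_admix` per Morgan; segment
#' ancestries are i.i.d. draws from the individual's proportions and
#' same-label neighbours are merged. Genetic positions are mapped back to
#' bp by linear interpolation of the genetic map.
#'
#' @param config a `sim_config`.
#' @param map a `genetic_map`.
#' @return A `tract_set`: data frame `individual`, `haplotype`, `chrom`,
#'   `start`, `end` (bp, 0-based half-open), `ancestry`; tracts tile each
#'   chromosome with no gaps, and adjacent tracts on a haplotype carry
#'   different labels.
#' @export
simulate_tracts <- function(config, map) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  props <- individual_proportions(config)
  K <- ncol(props)
  ancestries <- colnames(props)
  chroms <- unique(map$chrom)
  chrom_info <- lapply(chroms, function(ch) {
    sub <- map[map$chrom == ch, ]
    list(g = (max(sub$cM) - min(sub$cM)) / 100,
         cm0 = min(sub$cM), bp = sub$bp, cM = sub$cM,
         bp_start = min(sub$bp) - 1L, bp_end = max(sub$bp))
  })
  names(chrom_info) <- chroms

  acc_ind <- list(); acc_hap <- list(); acc_chr <- list()
  acc_start <- list(); acc_end <- list(); acc_anc <- list()
  j <- 0L
  for (i in seq_len(config$n_individuals)) {
    p_i <- props[i, ]
    for (h in 1:2) {
      for (ch in chroms) {
        ci <- chrom_info[[ch]]
        n_junc <- stats::rpois(1, config$T_admix * ci$g)
        pos_m <- sort(stats::runif(n_junc, 0, ci$g))
        labs <- sample.int(K, n_junc + 1, replace = TRUE, prob = p_i)
        keep <- c(TRUE, labs[-1] != labs[-(n_junc + 1)])
        labs <- labs[keep]
        pos_m <- pos_m[keep[-1]]
        # morgan -> bp: interpolate along the chromosome's cumulative map
        if (length(pos_m)) {
          bp_cuts <- round(stats::approx(x = (ci$cM - ci$cm0) / 100, y = ci$bp,
                                         xout = pos_m, ties = "ordered")$y)
        } else bp_cuts <- numeric(0)
        starts <- c(ci$bp_start, bp_cuts)
        ends <- c(bp_cuts, ci$bp_end)
        ok <- ends > starts  # guard collisions from bp rounding
        j <- j + 1L
        acc_ind[[j]] <- rep.int(i, sum(ok)); acc_hap[[j]] <- rep.int(h, sum(ok))
        acc_chr[[j]] <- rep.int(ch, sum(ok))
        acc_start[[j]] <- starts[ok]; acc_end[[j]] <- ends[ok]
        acc_anc[[j]] <- labs[ok]
      }
    }
  }
  tr <- data.frame(individual = unlist(acc_ind), haplotype = unlist(acc_hap),
                   chrom = unlist(acc_chr), start = unlist(acc_start),
                   end = unlist(acc_end),
                   ancestry = ancestries[unlist(acc_anc)],
                   stringsAsFactors = FALSE)
  structure(tr, class = c("tract_set", "data.frame"),
            ancestries = ancestries, n_individuals = config$n_individuals)
}

#' Simulate a genotyped admixed cohort
#'
#' Simulates HI ancestry tracts, then emits phased haplotype alleles: at a
#' marker lying in a tract of ancestry k, allele 1 is drawn with
#' probability f_kj (the panel frequency), and flipped with probability
#' `genotype_error`. Genotypes are the haplotype sums with optional
#' missingness.
#'
#' @param config a `sim_config`.
#' @param panel a `freq_panel`.
#' @param map a `genetic_map` sharing the panel's marker list.
#' @return List with `haplotypes` (0/1 matrix, 2 rows per individual),
#'   `genotypes` (0/1/2/NA matrix, individuals x markers), `truth_calls`
#'   (an `ancestry_calls` of true per-marker labels), `tracts` (the truth
#'   `tract_set`), `regions` (per-individual region label), `markers`, and
#'   the `config`.
#' @export
simulate_cohort <- function(config, panel, map) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "freq_panel"))
  if (nrow(panel$freqs) != nrow(map) ||
      any(panel$markers$bp != map$bp) ||
      any(panel$markers$chrom != map$chrom))
    stop("panel and map must share an identical marker list")
  if (length(config$proportions) != length(panel$ancestries))
    stop("config proportions and panel must list the same ancestries")
  tracts <- simulate_tracts(config, map)  # seeds the RNG stream
  n <- config$n_individuals
  m <- nrow(map)
  K <- length(panel$ancestries)
  labels <- tract_labels_at_markers(tracts, map)
  haps <- matrix(0L, 2L * n, m)
  for (r in seq_len(2L * n)) {
    f <- panel$freqs[cbind(seq_len(m), labels[r, ])]
    a <- stats::rbinom(m, 1L, f)
    if (config$genotype_error > 0) {
      flip <- stats::runif(m) < config$genotype_error
      a[flip] <- 1L - a[flip]
    }
    haps[r, ] <- a
  }
  geno <- haps[seq(1, 2 * n, by = 2), , drop = FALSE] +
          haps[seq(2, 2 * n, by = 2), , drop = FALSE]
  if (config$missing_rate > 0)
    geno[matrix(stats::runif(n * m) < config$missing_rate, n, m)] <- NA_integer_
  hap_meta <- data.frame(individual = rep(seq_len(n), each = 2),
                         haplotype = rep.int(1:2, n))
  truth <- new_ancestry_calls(labels, hap_meta, panel$markers,
                              panel$ancestries, method = "truth")
  rownames(geno) <- paste0("ind", seq_len(n))
  list(haplotypes = haps, genotypes = geno, truth_calls = truth,
       tracts = tracts, regions = region_assignment(config),
       markers = panel$markers, config = config)
}

#' Per-marker truth labels from a tract set
#'
#' @param tracts a `tract_set`.
#' @param map marker table (`chrom`, `bp`).
#' @return Integer matrix (2 rows per individual, markers in columns) of
#'   ancestry indices into `attr(tracts, "ancestries")`.
#' @keywords internal
tract_labels_at_markers <- function(tracts, map) {
  ancestries <- attr(tracts, "ancestries")
  n <- attr(tracts, "n_individuals")
  m <- nrow(map)
  labels <- matrix(0L, 2L * n, m)
  anc_idx <- match(tracts$ancestry, ancestries)
  key <- paste(tracts$individual, tracts$haplotype, tracts$chrom, sep = "\r")
  groups <- split(seq_len(nrow(tracts)), key)
  chrom_cols <- split(seq_len(m), factor(map$chrom, levels = unique(map$chrom)))
  for (g in groups) {
    i <- tracts$individual[g[1]]; h <- tracts$haplotype[g[1]]
    ch <- tracts$chrom[g[1]]
    cols <- chrom_cols[[ch]]
    # markers at bp fall in tract [start, end) with start 0-based: bp > start
    idx <- findInterval(map$bp[cols] - 0.5, tracts$start[g]) # tracts sorted within group
    idx[idx < 1] <- 1L; idx[idx > length(g)] <- length(g)
    labels[2L * (i - 1L) + h, cols] <- anc_idx[g][idx]
  }
  labels
}
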