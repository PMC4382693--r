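#' Pairwise FST and permutation tests
#'
#' Multi-locus pairwise FST by Hudson's ratio-of-averages estimator with
#' sample-size correction (for a single biallelic locus this coincides
#' with the classical Slatkin/Hudson pairwise form), plus a label
#' permutation test of the null hypothesis of no differentiation, and
#' per-marker squared-frequency-difference scores used to rank
#' ancestry-informative markers.
#'
#' @name fst
NULL

fst_components <- function(g1, g2, ploidy) {
  n1 <- ploidy * colSums(!is.na(g1))
  n2 <- ploidy * colSums(!is.na(g2))
  p1 <- colSums(g1, na.rm = TRUE) / n1
  p2 <- colSums(g2, na.rm = TRUE) / n2
  ok <- n1 > 1 & n2 > 1
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num[ok], den = den[ok])
}

#' Hudson pairwise FST
#'
#' Ratio of averages over loci:
#' \eqn{\hat F_{ST} = \sum_l N_l / \sum_l D_l} with
#' \eqn{N_l = (p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)} and
#' \eqn{D_l = p_1(1-p_2) + p_2(1-p_1)}, n the allele sample sizes. The
#' estimate may be slightly negative under no differentiation; both the
#' raw and a zero-clamped copy are returned.
#'
#' @param g1,g2 genotype matrices (samples x markers): 0/1/2/NA for
#'   diploid input, 0/1/NA for haploid.
#' @param ploidy 2 (default, autosome/X-in-females style) or 1
#'   (haplotype / chromosome-Y style input).
#' @return List `fst` (unclamped), `fst_clamped`, `n_loci` (loci entering
#'   the ratio).
#' @export
fst_hudson <- function(g1, g2, ploidy = 2) {
  g1 <- as.matrix(g1); g2 <- as.matrix(g2)
  if (ncol(g1) != ncol(g2)) stop("marker sets differ between populations")
  if (nrow(g1) < 2 || nrow(g2) < 2) stop("need >= 2 samples per population")
  cmp <- fst_components(g1, g2, ploidy)
  poly <- cmp$den > 0
  if (!any(poly)) stop("no polymorphic markers: FST undefined")
  fst <- sum(cmp$num[poly]) / sum(cmp$den[poly])
  list(fst = fst, fst_clamped = max(fst, 0), n_loci = sum(poly))
}

#' Permutation test for population differentiation
#'
#' Population labels are permuted M times and Hudson FST recomputed; the
#' add-one p-value is (1 + #\{FST_perm >= FST_obs\}) / (M + 1), so p is
#' never below 1/(M+1).
#'
#' @param genotypes combined genotype matrix (samples x markers).
#' @param labels two-level vector assigning each sample to a population.
#' @param M number of permutations (default 999).
#' @param ploidy see [fst_hudson()].
#' @param seed optional integer seed.
#' @return An `fst_result` list: `fst`, `fst_clamped`, `n_loci`,
#'   `n_permutations`, `n_exceedances`, `p_value`.
#' @export
fst_permutation_test <- function(genotypes, labels, M = 999, ploidy = 2,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genotypes <- as.matrix(genotypes)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must define exactly two populations")
  if (M < 1) stop("M must be >= 1")
  idx1 <- which(labels == levels(labels)[1])
  obs <- fst_hudson(genotypes[idx1, , drop = FALSE],
                    genotypes[-idx1, , drop = FALSE], ploidy)
  n <- nrow(genotypes)
  exceed <- 0L
  for (b in seq_len(M)) {
    perm <- sample.int(n, length(idx1))
    f <- fst_hudson(genotypes[perm, , drop = FALSE],
                    genotypes[-perm, , drop = FALSE], ploidy)$fst
    if (f >= obs$fst) exceed <- exceed + 1L
  }
  structure(list(fst = obs$fst, fst_clamped = obs$fst_clamped,
                 n_loci = obs$n_loci, n_permutations = M,
                 n_exceedances = exceed, p_value = (1 + exceed) / (M + 1)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Hudson FST = %.4f (p = %.4g, %d permutations, %d loci)\n",
              x$fst, x$p_value, x$n_permutations, x$n_loci))
  invisible(x)
}

#' Per-marker differentiation scores
#'
#' Squared allele-frequency difference between two ancestral populations
#' at every marker, with a descending ranking; markers with large
#' differences are the most ancestry-informative.
#'
#' @param panel a `freq_panel`.
#' @param pop_a,pop_b ancestry names present in the panel.
#' @return Data frame `chrom`, `bp`, `score`, `rank`, sorted by
#'   decreasing score.
#' @export
marker_differentiation <- function(panel, pop_a, pop_b) {
  if (!all(c(pop_a, pop_b) %in% panel$ancestries))
    stop("both populations must be in the panel")
  score <- (panel$freqs[, pop_a] - panel$freqs[, pop_b])^2
  out <- data.frame(chrom = panel$markers$chrom, bp = panel$markers$bp,
                    score = score, stringsAsFactors = FALSE)
  out <- out[order(-out$score), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
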