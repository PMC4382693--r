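#' Time since admixture from ancestry-switch counts
#'
#' Under the hybrid-isolation model, a genome admixed T generations ago
#' carries, per diploid individual, an expected
#' E(K) = 2 T G (1 - sum_k p_k^2) visible ancestry switches over a G-Morgan
#' map with ancestry proportions p. Inverting this relation on an
#' individual's observed switch count yields a per-individual estimate of
#' T; in the two-ancestry mode with European proportion q the expectation
#' reduces to 4 T G q (1 - q).
#'
#' @name admixture_time
NULL

#' Count ancestry switches per individual
#'
#' Label changes between adjacent markers (or adjacent tracts), summed
#' over both haplotypes and all chromosomes; chromosome boundaries are
#' never counted. Marker-wise counting on a call set equals
#' tract-boundary counting after run merging.
#'
#' @param x an `ancestry_calls` or a `tract_set`.
#' @return Integer vector, one switch count per individual.
#' @export
count_switches <- function(x) {
  if (inherits(x, "ancestry_calls")) {
    chrom <- factor(x$markers$chrom, levels = unique(x$markers$chrom))
    per_hap <- numeric(nrow(x$labels))
    for (cols in split(seq_len(ncol(x$labels)), chrom)) {
      if (length(cols) < 2) next
      sub <- x$labels[, cols, drop = FALSE]
      per_hap <- per_hap +
        rowSums(sub[, -1, drop = FALSE] != sub[, -length(cols), drop = FALSE])
    }
    return(as.integer(tapply(per_hap, x$hap_meta$individual, sum)))
  }
  if (inherits(x, "tract_set")) {
    n_tracts <- table(factor(x$individual), paste(x$haplotype, x$chrom))
    return(as.integer(rowSums(pmax(n_tracts - 1, 0))))
  }
  stop("x must be ancestry_calls or a tract_set")
}

#' Expected switch count under the hybrid-isolation model
#'
#' @param T_admix generations since admixture (>= 0).
#' @param p ancestry proportions (three-way mode), or ignored when `q` is
#'   given.
#' @param G total genetic map length in Morgans.
#' @param q optional European-style focal proportion: two-way mode with
#'   p = (q, 1-q), E(K) = 4 T G q (1 - q).
#' @return Expected number of visible switches per diploid individual.
#' @export
expected_switches <- function(T_admix, p = NULL, G, q = NULL) {
  if (T_admix < 0) stop("T_admix must be >= 0")
  if (G <= 0) stop("G must be positive")
  het <- if (!is.null(q)) 2 * q * (1 - q) else {
    if (is.null(p)) stop("supply p or q")
    1 - sum(p^2)
  }
  2 * T_admix * G * het
}

#' Estimate time since admixture from switch counts
#'
#' Per-individual inversion of the HI expectation,
#' \eqn{\hat T = K / (2 G (1 - \sum_k p_k^2))}; switch counts are summed
#' over both haplotypes of each individual. Individuals with degenerate
#' proportions (a single ancestry) have no defined estimate and are
#' flagged.
#'
#' @param K_switches per-individual switch counts.
#' @param proportions matrix (individuals x K) of global proportions, or
#'   a vector of two-way focal proportions `q`.
#' @param G total map length (Morgans).
#' @param mode `"three-way"` (1 - sum p^2) or `"two-way"` (2 q (1 - q),
#'   with q the first/only column).
#' @return Data frame `individual`, `q_focal`, `K`, `T_hat`, `degenerate`,
#'   with the sample mean of the defined estimates as attribute
#'   `"mean_T"`.
#' @export
estimate_admixture_time <- function(K_switches, proportions, G,
                                    mode = c("three-way", "two-way")) {
  mode <- match.arg(mode)
  proportions <- as.matrix(proportions)
  if (nrow(proportions) != length(K_switches))
    stop("one proportion row per switch count required")
  if (G <= 0) stop("G must be positive")
  het <- if (mode == "three-way") 1 - rowSums(proportions^2)
         else 2 * proportions[, 1] * (1 - proportions[, 1])
  degenerate <- het <= 0
  T_hat <- ifelse(degenerate, NA_real_, K_switches / (2 * G * het))
  out <- data.frame(individual = seq_along(K_switches),
                    q_focal = proportions[, 1], K = K_switches,
                    T_hat = T_hat, degenerate = degenerate)
  attr(out, "mean_T") <- mean(T_hat[!degenerate])
  attr(out, "switch_convention") <- "switches counted per haplotype and summed over the two haplotypes"
  out
}
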