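#' Array-style SNP and sample quality control
#'
#' Filters mirror standard admixture-cohort array QC: sample missingness,
#' SNP call rate, minor allele frequency, an exact Hardy-Weinberg test,
#' removal of strand-ambiguous (A/T, C/G) SNPs, and exclusion of the HLA
#' region, whose unusual LD biases local-ancestry inference.
#'
#' @name qc
NULL

#' QC thresholds
#'
#' @param maf_min minimum minor allele frequency (exclusive). Default 0.01.
#' @param hwe_p_min minimum HWE exact p-value (exclusive). Default 1e-5.
#' @param snp_call_rate_min minimum SNP call rate (exclusive). Default 0.95.
#' @param sample_missing_max maximum per-sample missingness. Default 0.10.
#' @param drop_ambiguous drop A/T and C/G SNPs. Default TRUE.
#' @param hla_region list(chrom, start, end) in bp; default
#'   chr6:25e6-35e6 (GRCh37 convention).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(maf_min = 0.01, hwe_p_min = 1e-5,
                          snp_call_rate_min = 0.95, sample_missing_max = 0.10,
                          drop_ambiguous = TRUE,
                          hla_region = list(chrom = "chr6", start = 25e6, end = 35e6)) {
  rates <- c(maf_min, hwe_p_min, snp_call_rate_min, sample_missing_max)
  if (any(rates < 0 | rates > 1)) stop("thresholds must lie in [0, 1]")
  structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                 snp_call_rate_min = snp_call_rate_min,
                 sample_missing_max = sample_missing_max,
                 drop_ambiguous = drop_ambiguous, hla_region = hla_region),
            class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test: given the allele counts, the probability of
#' every possible heterozygote count is computed by enumeration and the
#' two-sided p-value is the total mass of configurations no more probable
#' than the observed one.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative integers).
#' @return p-value in (0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25)  # modal configuration: p = 1
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("at least one genotyped sample required")
  nA <- 2 * n_AA + n_Aa
  if (nA == 0 || nA == 2 * n) return(1)  # monomorphic: single configuration
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  # log P(h | nA, n) up to a constant: conditional distribution under HWE
  logp <- h_logprob(hets, nA, n)
  logp <- logp - max(logp)
  p <- exp(logp); p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= obs + 1e-12]))
}

h_logprob <- function(h, nA, n) {
  na <- 2 * n - nA
  lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((na - h) / 2) + h * log(2)
}

#' Apply the QC filter cascade
#'
#' Rules run in a fixed order so reports are reproducible:
#' sample missingness, then — on the reduced sample set — SNP call rate,
#' MAF, HWE, ambiguous alleles, HLA region. MAF and HWE use non-missing
#' calls only.
#'
#' @param genotypes 0/1/2/NA matrix, samples x markers.
#' @param markers marker table with `chrom`, `bp`, `ref`, `alt`.
#' @param thresholds a `qc_thresholds`.
#' @return List with `genotypes`, `markers` (survivors), `samples_kept`
#'   (row indices), `report` (data frame rule / n_removed, in application
#'   order) and `excluded` (marker-level exclusion table with the first
#'   rule that removed each marker).
#' @export
qc_filter <- function(genotypes, markers, thresholds = qc_thresholds()) {
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) != nrow(markers))
    stop("genotypes must have one column per marker")
  th <- thresholds

  sample_miss <- rowMeans(is.na(genotypes))
  samples_kept <- which(sample_miss <= th$sample_missing_max)
  n_sample_removed <- nrow(genotypes) - length(samples_kept)
  g <- genotypes[samples_kept, , drop = FALSE]

  n_used <- colSums(!is.na(g))
  call_rate <- n_used / nrow(g)
  af <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    x <- g[, j]; x <- x[!is.na(x)]
    if (!length(x)) return(1)
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  pair <- paste0(pmin(markers$ref, markers$alt), pmax(markers$ref, markers$alt))
  ambiguous <- th$drop_ambiguous & pair %in% c("AT", "CG")
  in_hla <- !is.null(th$hla_region) &
    markers$chrom == th$hla_region$chrom &
    markers$bp >= th$hla_region$start & markers$bp <= th$hla_region$end

  fail <- list(
    call_rate = !(call_rate > th$snp_call_rate_min),
    maf = !(maf > th$maf_min),
    hwe = !(hwe_p > th$hwe_p_min),
    ambiguous_alleles = ambiguous,
    hla_region = in_hla)
  # attribute each removed marker to the first rule that caught it
  first_rule <- rep(NA_character_, ncol(g))
  for (rule in names(fail))
    first_rule[is.na(first_rule) & fail[[rule]]] <- rule
  keep <- is.na(first_rule)
  report <- data.frame(
    rule = c("sample_missingness", names(fail)),
    n_removed = c(n_sample_removed,
                  vapply(names(fail), function(r) sum(first_rule == r, na.rm = TRUE),
                         numeric(1))),
    stringsAsFactors = FALSE)
  if (!any(keep) || !length(samples_kept))
    warning("QC removed all markers or all samples")
  excluded <- data.frame(chrom = markers$chrom[!keep], bp = markers$bp[!keep],
                         rule = first_rule[!keep], stringsAsFactors = FALSE)
  list(genotypes = g[, keep, drop = FALSE],
       markers = markers[keep, , drop = FALSE],
       samples_kept = samples_kept, report = report, excluded = excluded)
}
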