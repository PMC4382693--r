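# Independent oracle for the exact HWE test: condition the multinomial
# HWE genotype distribution (at the allele-count MLE) on the observed
# allele counts, enumerating every heterozygote configuration.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  if (nA == 0 || nA == 2 * n) return(1)
  p <- nA / (2 * n)
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  probs <- vapply(hets, function(h)
    stats::dmultinom(c((nA - h) / 2, h, (2 * n - nA - h) / 2),
                     prob = c(p^2, 2 * p * (1 - p), (1 - p)^2)),
    numeric(1))
  probs <- probs / sum(probs)
  sum(probs[probs <= probs[match(n_Aa, hets)] + 1e-12])
}

test_that("exact HWE test matches enumeration and handles edge configurations", {
  expect_equal(hwe_exact_test(25, 50, 25), 1.0)   # modal HWE configuration
  expect_equal(hwe_exact_test(100, 0, 0), 1.0)    # monomorphic
  cases <- list(c(0, 100, 0), c(10, 5, 10), c(3, 1, 17), c(0, 2, 8),
                c(12, 30, 8), c(1, 1, 1))
  for (cs in cases)
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 hwe_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-12)
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

# 8 markers x 6 samples; one violation each, worked out by hand:
#   m1 clean | m2 low call rate (2/6 missing) | m3 MAF 0 | m4 HWE (3 AA/3 aa)
#   m5 A/T ambiguous | m6 C/G ambiguous | m7 in HLA window | m8 clean
qc_fixture <- function() {
  g <- rbind(c(0, 1, 0, 0, 0, 0, 1, 2),
             c(1, NA, 0, 0, 1, 1, 0, 1),
             c(1, NA, 0, 2, 0, 0, 1, 0),
             c(0, 0, 0, 2, 1, 1, 2, 1),
             c(1, 1, 0, 2, 0, 0, 0, 0),
             c(2, 0, 0, 0, 1, 1, 1, 1))
  mk <- data.frame(
    chrom = c(rep("chr1", 6), "chr6", "chr2"),
    bp = c(1e5, 2e5, 3e5, 4e5, 5e5, 6e5, 30e6, 1e5),
    ref = c("A", "C", "A", "G", "A", "C", "A", "T"),
    alt = c("G", "T", "G", "A", "T", "G", "C", "C"),
    stringsAsFactors = FALSE)
  list(g = g, mk = mk)
}

test_that("the QC cascade removes exactly the hand-derived violations, in order", {
  fx <- qc_fixture()
  # m4 (3 AA / 0 Aa / 3 aa) has exact p ~ 0.022: raise the HWE floor just
  # above it; relax sample missingness so the two single-NA samples stay
  p_m4 <- hwe_oracle(3, 0, 3)
  th <- qc_thresholds(hwe_p_min = p_m4 + 1e-6, sample_missing_max = 0.3)
  res <- qc_filter(fx$g, fx$mk, th)
  expect_equal(res$markers$bp, c(1e5, 1e5))          # only m1 and m8 survive
  expect_equal(res$markers$chrom, c("chr1", "chr2"))
  rep_counts <- setNames(res$report$n_removed, res$report$rule)
  expect_equal(unname(rep_counts[c("sample_missingness", "call_rate", "maf",
                                   "hwe", "ambiguous_alleles", "hla_region")]),
               c(0, 1, 1, 1, 2, 1))
  expect_equal(res$report$rule[1], "sample_missingness")  # fixed application order
})

test_that("QC is idempotent and removal counts sum to the total removed", {
  fx <- qc_fixture()
  res <- qc_filter(fx$g, fx$mk)
  res2 <- qc_filter(res$genotypes, res$markers)
  expect_equal(res2$genotypes, res$genotypes)
  expect_equal(sum(res2$report$n_removed), 0)
  expect_equal(sum(res$report$n_removed[-1]), ncol(fx$g) - ncol(res$genotypes))
})

test_that("markers passing a threshold also pass any laxer threshold", {
  set.seed(31)
  n <- 40; m <- 60
  g <- matrix(rbinom(n * m, 2, runif(m, 0.02, 0.5)[col(matrix(0, n, m))]), n, m)
  g[runif(n * m) < 0.03] <- NA
  mk <- data.frame(chrom = "chr1", bp = seq_len(m) * 1e4, ref = "A", alt = "G")
  strict <- qc_filter(g, mk, qc_thresholds(maf_min = 0.05, hwe_p_min = 1e-3,
                                           snp_call_rate_min = 0.97))
  lax <- qc_filter(g, mk, qc_thresholds(maf_min = 0.01, hwe_p_min = 1e-5,
                                        snp_call_rate_min = 0.90))
  expect_true(all(strict$markers$bp %in% lax$markers$bp))
})

test_that("sample missingness removes samples before marker rules run", {
  fx <- qc_fixture()
  g <- fx$g
  g[1, ] <- NA  # sample 1: 100% missing
  res <- qc_filter(g, fx$mk, qc_thresholds(sample_missing_max = 0.3))
  expect_equal(res$samples_kept, 2:6)
  expect_equal(res$report$n_removed[res$report$rule == "sample_missingness"], 1)
})

test_that("removing everything warns instead of failing silently", {
  g <- matrix(c(0L, 0L, 0L, 0L), 2, 2)
  mk <- data.frame(chrom = "chr1", bp = c(1e5, 2e5), ref = "A", alt = "G")
  expect_warning(qc_filter(g, mk), "removed all")
})
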