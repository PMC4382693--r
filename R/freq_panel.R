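#' Ancestral allele-frequency panels
#'
#' A `freq_panel` holds, for each of K ancestral populations, the
#' alternate-allele frequency at every marker of a shared marker list. It
#' is the emission model of the local-ancestry HMM and the generating
#' object of the cohort simulator.
#'
#' @name freq_panel
NULL

new_freq_panel <- function(markers, freqs, ancestries) {
  freqs <- as.matrix(freqs)
  if (nrow(freqs) != nrow(markers))
    stop("freqs must have one row per marker")
  if (ncol(freqs) < 2) stop("a frequency panel needs K >= 2 ancestries")
  if (any(freqs < 0 | freqs > 1)) stop("allele frequencies must lie in [0, 1]")
  colnames(freqs) <- ancestries
  structure(list(markers = markers, freqs = freqs, ancestries = ancestries),
            class = "freq_panel")
}

#' @export
print.freq_panel <- function(x, ...) {
  cat("Allele-frequency panel:", nrow(x$freqs), "markers x",
      ncol(x$freqs), "ancestries (", paste(x$ancestries, collapse = ", "), ")\n")
  invisible(x)
}

#' Generate ancestral allele frequencies under the Balding-Nichols model
#'
#' Draws a shared ancestral frequency p_j per marker from
#' `base_freq_sampler`, then for each population k draws
#' f_kj ~ Beta(p_j (1-F_k)/F_k, (1-p_j)(1-F_k)/F_k), so that population k
#' has differentiation F_k from the common ancestor. `F_k = 0` degenerates
#' to f_kj = p_j exactly.
#'
#' @param n_markers number of markers (ignored when `markers` is given).
#' @param F_st per-ancestry differentiation, each in `[0, 1)`. Names are
#'   used as ancestry labels; unnamed vectors default to NAT/EUR/AFR (or
#'   pop1..popK for K > 3).
#' @param base_freq_sampler function(n) returning n ancestral frequencies
#'   in (0, 1); default Uniform(0.05, 0.95).
#' @param markers optional marker table (`chrom`, `bp`) shared with a
#'   genetic map; by default markers are laid uniformly on one chromosome.
#' @param seed optional integer seed.
#' @return A `freq_panel`.
#' @examples
#' p <- gen_frequency_panel(100, F_st = c(NAT = 0.2, EUR = 0.15, AFR = 0.1), seed = 1)
#' @export
gen_frequency_panel <- function(n_markers = NULL, F_st,
                                base_freq_sampler = NULL,
                                markers = NULL, seed = NULL) {
  if (is.null(base_freq_sampler))
    base_freq_sampler <- function(n) stats::runif(n, 0.05, 0.95)
  if (any(F_st < 0 | F_st >= 1)) stop("each F_st must lie in [0, 1)")
  if (is.null(markers)) {
    if (is.null(n_markers) || n_markers < 1) stop("n_markers must be >= 1")
    markers <- data.frame(chrom = "chr1",
                          bp = seq(10000L, by = 10000L, length.out = n_markers),
                          ref = "A", alt = "G", stringsAsFactors = FALSE)
  } else {
    markers <- as.data.frame(markers)
    if (is.null(markers$ref)) markers$ref <- "A"
    if (is.null(markers$alt)) markers$alt <- "G"
  }
  n <- nrow(markers)
  K <- length(F_st)
  ancestries <- names(F_st)
  if (is.null(ancestries))
    ancestries <- if (K <= 3) c("NAT", "EUR", "AFR")[seq_len(K)] else paste0("pop", seq_len(K))
  if (!is.null(seed)) set.seed(seed)
  p <- base_freq_sampler(n)
  if (any(p <= 0 | p >= 1)) stop("base frequencies must lie in (0, 1)")
  freqs <- matrix(0, n, K)
  for (k in seq_len(K)) {
    Fk <- F_st[k]
    if (Fk == 0) {
      freqs[, k] <- p
    } else {
      lambda <- (1 - Fk) / Fk
      freqs[, k] <- stats::rbeta(n, p * lambda, (1 - p) * lambda)
    }
  }
  new_freq_panel(markers, freqs, ancestries)
}

#' Sample reference haplotypes from a frequency panel
#'
#' Draws haploid 0/1 reference panels per ancestry, marker alleles
#' independent Bernoulli(f_kj). Used by the sensitivity sweeps, which
#' subsample these haplotypes and refit emission frequencies.
#'
#' @param panel a `freq_panel`.
#' @param n_haplotypes haplotypes per ancestry (scalar or named vector).
#' @param seed optional integer seed.
#' @return Named list of 0/1 matrices (haplotypes x markers), one per
#'   ancestry.
#' @export
gen_reference_haplotypes <- function(panel, n_haplotypes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(panel$ancestries)
  n_haplotypes <- rep_len(n_haplotypes, K)
  out <- vector("list", K)
  names(out) <- panel$ancestries
  m <- nrow(panel$freqs)
  for (k in seq_len(K)) {
    nh <- n_haplotypes[k]
    out[[k]] <- matrix(stats::rbinom(nh * m, 1L, rep(panel$freqs[, k], each = nh)),
                       nrow = nh, ncol = m)
  }
  out
}

#' Empirical frequency panel from reference haplotypes
#'
#' @param haps named list of 0/1 haplotype matrices (haplotypes x markers).
#' @param markers marker table to attach.
#' @return A `freq_panel` of per-ancestry empirical alternate-allele
#'   frequencies.
#' @export
panel_from_haplotypes <- function(haps, markers) {
  freqs <- vapply(haps, colMeans, numeric(ncol(haps[[1]])))
  new_freq_panel(as.data.frame(markers), freqs, names(haps))
}
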