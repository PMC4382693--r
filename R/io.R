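#' Shared readers and writers
#'
#' Coordinate dialects: VCF and genetic-map files are 1-based; BED tract
#' files are 0-based half-open. Every writer states the convention in a
#' header comment.
#'
#' @name io
NULL

#' Write phased haplotypes as VCF
#'
#' Minimal VCFv4.2 with a phased GT field ("0|1" separators).
#'
#' @param haplotypes 0/1 matrix, two consecutive rows per individual.
#' @param markers marker table (`chrom`, `bp`, `ref`, `alt`).
#' @param path output path.
#' @param sample_names optional; default ind1..indN.
#' @export
write_vcf <- function(haplotypes, markers, path, sample_names = NULL) {
  n <- nrow(haplotypes) / 2
  if (is.null(sample_names)) sample_names <- paste0("ind", seq_len(n))
  h1 <- haplotypes[seq(1, 2 * n, 2), , drop = FALSE]
  h2 <- haplotypes[seq(2, 2 * n, 2), , drop = FALSE]
  gt <- matrix(paste0(t(h1), "|", t(h2)), nrow = ncol(haplotypes))
  ref <- if (is.null(markers$ref)) "A" else markers$ref
  alt <- if (is.null(markers$alt)) "G" else markers$alt
  body <- cbind(markers$chrom, markers$bp, paste0("snp", seq_len(nrow(markers))),
                ref, alt, ".", "PASS", ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=laikit",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Phased genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sample_names), collapse = "\t")), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read phased haplotypes from a VCF
#'
#' Requires a phased GT field; unphased records ("/" separators) are an
#' error because local-ancestry calling runs on haplotypes.
#'
#' @param path VCF path.
#' @return List with `haplotypes` (0/1 matrix, two rows per individual),
#'   `genotypes` (0/1/2/NA), `markers` and `samples`.
#' @export
read_vcf_haplotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE), na.rm = TRUE))
    stop("unphased genotypes in ", path, ": phased GT ('|') required")
  fx <- vcfR::getFIX(v)
  markers <- data.frame(chrom = fx[, "CHROM"], bp = as.integer(fx[, "POS"]),
                        ref = fx[, "REF"], alt = fx[, "ALT"],
                        stringsAsFactors = FALSE)
  m <- nrow(gt); n <- ncol(gt)
  a1 <- suppressWarnings(matrix(as.integer(substr(gt, 1, 1)), m, n))
  a2 <- suppressWarnings(matrix(as.integer(substr(gt, 3, 3)), m, n))
  haps <- matrix(0L, 2 * n, m)
  haps[seq(1, 2 * n, 2), ] <- t(a1)
  haps[seq(2, 2 * n, 2), ] <- t(a2)
  geno <- t(a1) + t(a2)
  rownames(geno) <- colnames(gt)
  list(haplotypes = haps, genotypes = geno, markers = markers,
       samples = colnames(gt))
}

#' Read a region table / zone map from TSV
#'
#' Region table columns: `region`, `sample_pct`, `n_sample`, `census_pct`
#' (missing census fractions allowed, e.g. for an Unknown row). Zone map
#' columns: `region`, `zone`.
#'
#' @param path TSV path.
#' @export
read_region_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("region", "n_sample") %in% names(df)))
  df
}

#' @rdname read_region_table
#' @export
read_zone_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("region", "zone") %in% names(df)))
  df
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
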