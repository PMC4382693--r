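#' Per-marker local-ancestry call sets
#'
#' An `ancestry_calls` object stores one ancestry label per individual,
#' haplotype and marker: an integer matrix with two rows per individual
#' (haplotypes 1 and 2) and one column per marker, plus the marker table,
#' the ancestry labels the integers index, and a provenance tag naming the
#' method that produced the calls.
#'
#' @name ancestry_calls
NULL

new_ancestry_calls <- function(labels, hap_meta, markers, ancestries, method) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (nrow(labels) != nrow(hap_meta))
    stop("labels must have one row per haplotype")
  if (ncol(labels) != nrow(markers))
    stop("labels must have one column per marker")
  if (any(labels < 1L | labels > length(ancestries)))
    stop("ancestry labels out of range")
  structure(list(labels = labels, hap_meta = hap_meta, markers = markers,
                 ancestries = ancestries, method = method),
            class = "ancestry_calls")
}

#' @export
print.ancestry_calls <- function(x, ...) {
  cat("Ancestry calls [", x$method, "]: ",
      nrow(x$labels) / 2, " individuals x ", ncol(x$labels), " markers (",
      paste(x$ancestries, collapse = "/"), ")\n", sep = "")
  invisible(x)
}

#' Number of individuals in a call set
#' @param calls an `ancestry_calls`.
#' @export
n_individuals <- function(calls) nrow(calls$labels) / 2L

#' Merge per-marker calls into ancestry tracts
#'
#' Runs of identical labels become tracts; boundaries between differing
#' adjacent markers are placed at the bp midpoint, and chromosome ends at
#' the terminal marker positions (0-based half-open intervals).
#'
#' @param calls an `ancestry_calls`.
#' @return A `tract_set` data frame.
#' @export
calls_to_tracts <- function(calls) {
  mk <- calls$markers
  chroms <- unique(mk$chrom)
  res <- vector("list", 0)
  for (r in seq_len(nrow(calls$labels))) {
    i <- calls$hap_meta$individual[r]; h <- calls$hap_meta$haplotype[r]
    for (ch in chroms) {
      cols <- which(mk$chrom == ch)
      bp <- mk$bp[cols]
      lab <- calls$labels[r, cols]
      runs <- rle(lab)
      ends_idx <- cumsum(runs$lengths)
      starts_idx <- c(1L, head(ends_idx, -1L) + 1L)
      mid <- function(a, b) floor((bp[a] + bp[b]) / 2)
      starts <- c(bp[1] - 1L,
                  if (length(ends_idx) > 1)
                    mapply(mid, ends_idx[-length(ends_idx)], starts_idx[-1]))
      ends <- c(if (length(ends_idx) > 1)
                  mapply(mid, ends_idx[-length(ends_idx)], starts_idx[-1]),
                bp[length(bp)])
      res[[length(res) + 1L]] <- data.frame(
        individual = i, haplotype = h, chrom = ch,
        start = starts, end = ends,
        ancestry = calls$ancestries[runs$values], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  structure(out, class = c("tract_set", "data.frame"),
            ancestries = calls$ancestries,
            n_individuals = n_individuals(calls))
}

#' Write / read per-marker calls as TSV
#'
#' Long format with columns `individual`, `haplotype`, `chrom`, `bp`,
#' `ancestry`; the reader accepts the same layout so externally produced
#' call sets (LAMP-LD/RFMix-style exports) can enter the pipeline.
#'
#' @param calls an `ancestry_calls`.
#' @param path file path.
#' @param method provenance tag recorded on read.
#' @export
write_calls_tsv <- function(calls, path) {
  mk <- calls$markers
  long <- data.frame(
    individual = rep(calls$hap_meta$individual, each = ncol(calls$labels)),
    haplotype = rep(calls$hap_meta$haplotype, each = ncol(calls$labels)),
    chrom = rep(mk$chrom, nrow(calls$labels)),
    bp = rep(mk$bp, nrow(calls$labels)),
    ancestry = calls$ancestries[as.integer(t(calls$labels))],
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# per-marker ancestry calls; method=", calls$method,
                    "; ancestries=", paste(calls$ancestries, collapse = ","),
                    "; bp is 1-based"), con)
  utils::write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path, method = "external") {
  first <- readLines(path, n = 1)
  long <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                            stringsAsFactors = FALSE, comment.char = "#")
  mk <- unique(long[long$individual == long$individual[1] &
                    long$haplotype == long$haplotype[1], c("chrom", "bp")])
  ancestries <- if (grepl("ancestries=", first)) {
    strsplit(sub(".*ancestries=([^;]*).*", "\\1", first), ",")[[1]]
  } else sort(unique(long$ancestry))
  ord <- order(long$individual, long$haplotype)
  long <- long[ord, ]
  n_hap <- nrow(long) / nrow(mk)
  labels <- matrix(match(long$ancestry, ancestries), nrow = n_hap,
                   ncol = nrow(mk), byrow = TRUE)
  hap_meta <- unique(long[, c("individual", "haplotype")])
  rownames(hap_meta) <- NULL
  new_ancestry_calls(labels, hap_meta, mk, ancestries, method)
}

#' Write a tract set as BED
#'
#' Columns: chrom, start, end (0-based half-open), sample, haplotype,
#' ancestry.
#'
#' @param tracts a `tract_set`.
#' @param path file path.
#' @export
write_tracts_bed <- function(tracts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# ancestry tracts; BED coordinates: 0-based, half-open", con)
  utils::write.table(tracts[, c("chrom", "start", "end", "individual",
                                "haplotype", "ancestry")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_tracts_bed
#' @export
read_tracts_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "#",
                          col.names = c("chrom", "start", "end", "individual",
                                        "haplotype", "ancestry"))
  df <- df[, c("individual", "haplotype", "chrom", "start", "end", "ancestry")]
  structure(df, class = c("tract_set", "data.frame"),
            ancestries = sort(unique(df$ancestry)),
            n_individuals = length(unique(df$individual)))
}
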