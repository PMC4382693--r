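#' Genetic maps
#'
#' A genetic map is a data frame with one row per marker and columns
#' `chrom`, `bp` (1-based physical position) and `cM` (cumulative genetic
#' position within the chromosome, centiMorgans). Physical positions are
#' strictly increasing and genetic positions non-decreasing within each
#' chromosome.
#'
#' @name genetic_map
NULL

new_genetic_map <- function(df) {
  stopifnot(all(c("chrom", "bp", "cM") %in% names(df)))
  df$chrom <- as.character(df$chrom)
  validate_genetic_map(df)
  structure(df, class = c("genetic_map", "data.frame"))
}

validate_genetic_map <- function(df) {
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (any(diff(sub$bp) <= 0))
      stop("genetic map: bp must be strictly increasing within chromosome ", ch)
    if (any(diff(sub$cM) < 0))
      stop("genetic map: cM must be non-decreasing within chromosome ", ch)
  }
  invisible(df)
}

#' Generate a synthetic genetic map
#'
#' Lays `markers_per_chrom` markers on each chromosome and assigns genetic
#' positions so that each chromosome spans the requested number of Morgans.
#' With `rate_profile = "uniform"` the cM position is proportional to bp;
#' with `"variable"` per-interval recombination rates are drawn from a
#' Gamma distribution (shape `rate_shape`) and rescaled so the chromosome
#' keeps its requested total Morgan length, emulating the rate
#' heterogeneity of pedigree-based human maps.
#'
#' @param chrom_lengths_bp numeric vector of chromosome lengths in bp.
#' @param morgans_per_chrom genetic length of each chromosome (Morgans).
#' @param markers_per_chrom integer (scalar or per-chromosome), >= 2.
#' @param rate_profile `"uniform"` or `"variable"`.
#' @param rate_shape Gamma shape for the variable profile; smaller values
#'   give spikier rate landscapes. Default 0.6.
#' @param seed optional integer seed.
#' @return A `genetic_map` data frame (`chrom`, `bp`, `cM`).
#' @examples
#' m <- gen_genetic_map(c(1e6, 2e6), c(1, 2), 50, seed = 1)
#' map_length_morgans(m)  # total G = 3
#' @export
gen_genetic_map <- function(chrom_lengths_bp, morgans_per_chrom,
                            markers_per_chrom, rate_profile = c("uniform", "variable"),
                            rate_shape = 0.6, seed = NULL) {
  rate_profile <- match.arg(rate_profile)
  if (any(chrom_lengths_bp <= 0)) stop("chromosome lengths must be positive")
  if (any(morgans_per_chrom <= 0)) stop("morgans_per_chrom must be positive")
  n_chrom <- length(chrom_lengths_bp)
  markers_per_chrom <- rep_len(as.integer(markers_per_chrom), n_chrom)
  if (any(markers_per_chrom < 2)) stop("markers_per_chrom must be >= 2")
  morgans_per_chrom <- rep_len(morgans_per_chrom, n_chrom)
  if (!is.null(seed)) set.seed(seed)

  pieces <- vector("list", n_chrom)
  for (c_i in seq_len(n_chrom)) {
    m <- markers_per_chrom[c_i]
    L <- chrom_lengths_bp[c_i]
    bp <- sort(sample.int(L, m))
    if (rate_profile == "uniform") {
      cM <- (bp - bp[1]) / (bp[m] - bp[1]) * morgans_per_chrom[c_i] * 100
    } else {
      w <- stats::rgamma(m - 1, shape = rate_shape, rate = 1)
      w <- w / sum(w)
      cM <- c(0, cumsum(w)) * morgans_per_chrom[c_i] * 100
    }
    pieces[[c_i]] <- data.frame(chrom = paste0("chr", c_i), bp = bp, cM = cM,
                                stringsAsFactors = FALSE)
  }
  new_genetic_map(do.call(rbind, pieces))
}

#' Genetic length of a map
#'
#' @param map a `genetic_map`.
#' @return List with `per_chrom` (named vector of Morgan lengths) and
#'   `total` (G, Morgans).
#' @export
map_length_morgans <- function(map) {
  per <- vapply(split(map$cM, map$chrom), function(x) (max(x) - min(x)) / 100,
                numeric(1))
  per <- per[unique(map$chrom)]
  list(per_chrom = per, total = sum(per))
}

#' Inter-marker Morgan distances
#'
#' Distances between consecutive markers within each chromosome; the first
#' marker of each chromosome gets distance `Inf` (used by the HMM to reset
#' to the prior at chromosome starts).
#'
#' @param map a `genetic_map`.
#' @return Numeric vector, one entry per marker.
#' @export
marker_morgan_gaps <- function(map) {
  unlist(lapply(split(seq_len(nrow(map)), factor(map$chrom, levels = unique(map$chrom))),
                function(idx) c(Inf, diff(map$cM[idx]) / 100)),
         use.names = FALSE)
}

#' Per-marker local recombination rate
#'
#' Rate over each marker's half-open interval neighbourhood: the Morgan
#' span between the midpoints to the two flanking markers divided by the
#' corresponding bp span (chromosome ends use the single flanking
#' half-interval). Units: Morgans per bp.
#'
#' @param map a `genetic_map`.
#' @return Numeric vector, one rate per marker.
#' @export
marker_recomb_rate <- function(map) {
  out <- numeric(nrow(map))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    bp <- map$bp[idx]; cm <- map$cM[idx]
    n <- length(idx)
    if (n == 1) { out[idx] <- 0; next }
    bp_lo <- c(bp[1], (bp[-n] + bp[-1]) / 2)
    bp_hi <- c((bp[-n] + bp[-1]) / 2, bp[n])
    cm_lo <- c(cm[1], (cm[-n] + cm[-1]) / 2)
    cm_hi <- c((cm[-n] + cm[-1]) / 2, cm[n])
    span_bp <- pmax(bp_hi - bp_lo, 1)
    out[idx] <- ((cm_hi - cm_lo) / 100) / span_bp
  }
  out
}

#' Half-interval bp weights per marker
#'
#' Each marker is weighted by half the bp distance to each neighbour, with
#' a single half-interval at chromosome ends. These weights approximate the
#' number of bases a marker's ancestry call represents.
#'
#' @param map a data frame with `chrom` and `bp` columns (e.g. a
#'   `genetic_map` or a marker table).
#' @return Numeric vector of bp weights.
#' @export
marker_bp_weights <- function(map) {
  out <- numeric(nrow(map))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    bp <- map$bp[idx]
    n <- length(idx)
    if (n == 1) { out[idx] <- 1; next }
    d <- diff(bp)
    # interior marker j gets (d[j-1]+d[j])/2; ends get a single half-interval
    w <- numeric(n)
    w[1] <- d[1] / 2
    if (n > 2) w[2:(n - 1)] <- (d[-(n - 1)] + d[-1]) / 2
    w[n] <- d[n - 1] / 2
    out[idx] <- w
  }
  out
}

#' Read / write a 3-column genetic map file
#'
#' Plain whitespace-separated text with a header line: `chrom bp cM`
#' (1-based physical positions).
#'
#' @param path file path.
#' @return `read_genetic_map` returns a `genetic_map`.
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "bp", "cM")
  new_genetic_map(df)
}

#' @rdname read_genetic_map
#' @param map a `genetic_map` to write.
#' @export
write_genetic_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# genetic map; bp is 1-based; cM cumulative within chromosome", con)
  utils::write.table(as.data.frame(map)[, c("chrom", "bp", "cM")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
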