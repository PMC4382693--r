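#' Sensitivity of global ancestry to panel size and SNP density
#'
#' Resampling sweeps quantifying how stable individual global-ancestry
#' estimates are as the reference panels grow or as the marker density
#' increases: at each axis value the reference material is randomly
#' subsampled, the local-ancestry caller re-run, and the per-individual
#' standard deviation of the global proportions across replicates
#' summarised by its cohort median.
#'
#' @name sensitivity
NULL

sweep_seed <- function(seed, axis_index, rep) {
  as.integer((as.double(seed) * 7919 + axis_index * 104729 + rep * 31L) %% 2147483629)
}

summarise_sweep <- function(records, axis_name, reps, seed) {
  long <- do.call(rbind, records)
  agg_mean <- stats::aggregate(value ~ axis + individual + ancestry, long, mean)
  agg_sd <- stats::aggregate(value ~ axis + individual + ancestry, long, stats::sd)
  names(agg_mean)[4] <- "mean"
  agg_mean$sd <- agg_sd$value
  med <- stats::aggregate(sd ~ axis + ancestry, agg_mean, stats::median)
  names(med)[3] <- "median_sd"
  structure(list(axis_name = axis_name, axis = sort(unique(long$axis)),
                 long = agg_mean, median_sd = med,
                 n_replicates = reps, seed = seed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Sensitivity sweep over", x$axis_name, "(", length(x$axis),
      "values x", x$n_replicates, "replicates )\n")
  print(stats::reshape(x$median_sd, idvar = "axis", timevar = "ancestry",
                       direction = "wide"), row.names = FALSE)
  invisible(x)
}

#' Reference-panel-size sweep
#'
#' For each panel size and replicate, the chosen reference panel(s) are
#' subsampled without replacement to that many haplotypes (other panels
#' stay at full size), emission frequencies re-estimated, the HMM caller
#' re-run on the cohort and global proportions recorded. Replicate
#' subsamples are reproducible from (seed, size index, replicate).
#'
#' @param ref_haps named list of reference 0/1 haplotype matrices
#'   (haplotypes x markers), one per ancestry.
#' @param haplotypes cohort haplotypes to call (two rows per individual).
#' @param map a `genetic_map` on the shared marker list.
#' @param sizes panel sizes to visit (e.g. `seq(10, 100, by = 10)`).
#' @param which_panel ancestry name to vary, or `"all"` to subsample every
#'   panel simultaneously.
#' @param reps replicates per size (default 10).
#' @param config an `hmm_config`.
#' @param mode decode mode passed to [decode_calls()].
#' @param seed integer seed.
#' @param caller optional plug-in: `function(haplotypes, panel, map)`
#'   returning an `ancestry_calls`, substituting the built-in HMM so
#'   external callers can be swept.
#' @return A `sweep_result`.
#' @export
panel_size_sweep <- function(ref_haps, haplotypes, map, sizes,
                             which_panel = "all", reps = 10,
                             config = hmm_config(), mode = "viterbi",
                             seed = 1L, caller = NULL) {
  if (reps < 2) stop("reps must be >= 2")
  vary <- if (identical(which_panel, "all")) names(ref_haps) else which_panel
  if (!all(vary %in% names(ref_haps))) stop("unknown panel: ", which_panel)
  for (v in vary) if (max(sizes) > nrow(ref_haps[[v]]))
    stop("size exceeds available haplotypes in panel ", v)
  markers <- data.frame(chrom = map$chrom, bp = map$bp)
  records <- list()
  for (s_i in seq_along(sizes)) {
    for (b in seq_len(reps)) {
      set.seed(sweep_seed(seed, s_i, b))
      sub <- ref_haps
      for (v in vary)
        sub[[v]] <- sub[[v]][sample.int(nrow(sub[[v]]), sizes[s_i]), , drop = FALSE]
      panel <- panel_from_haplotypes(sub, markers)
      calls <- if (is.null(caller)) decode_calls(haplotypes, panel, map, config, mode)
               else caller(haplotypes, panel, map)
      gp <- global_proportions(calls)
      records[[length(records) + 1L]] <- data.frame(
        axis = sizes[s_i], rep = b,
        individual = rep(seq_len(nrow(gp)), ncol(gp)),
        ancestry = rep(colnames(gp), each = nrow(gp)),
        value = as.vector(gp), stringsAsFactors = FALSE)
    }
  }
  summarise_sweep(records, "panel_size", reps, seed)
}

#' SNP-density sweep
#'
#' For each density and replicate, a random marker subset of that size is
#' drawn, the caller re-run on the subset and global proportions
#' recorded.
#'
#' @inheritParams panel_size_sweep
#' @param panel a `freq_panel` (full marker list).
#' @param densities marker-subset sizes to visit.
#' @return A `sweep_result`.
#' @export
snp_density_sweep <- function(haplotypes, panel, map, densities, reps = 10,
                              config = hmm_config(), mode = "viterbi",
                              seed = 1L, caller = NULL) {
  if (reps < 2) stop("reps must be >= 2")
  m <- nrow(map)
  if (max(densities) > m) stop("density exceeds available marker count")
  records <- list()
  for (d_i in seq_along(densities)) {
    for (b in seq_len(reps)) {
      set.seed(sweep_seed(seed, d_i, b))
      cols <- sort(sample.int(m, densities[d_i]))
      sub_map <- structure(as.data.frame(map)[cols, ],
                           class = c("genetic_map", "data.frame"))
      sub_panel <- new_freq_panel(panel$markers[cols, , drop = FALSE],
                                  panel$freqs[cols, , drop = FALSE],
                                  panel$ancestries)
      sub_haps <- haplotypes[, cols, drop = FALSE]
      calls <- if (is.null(caller)) decode_calls(sub_haps, sub_panel, sub_map, config, mode)
               else caller(sub_haps, sub_panel, sub_map)
      gp <- global_proportions(calls)
      records[[length(records) + 1L]] <- data.frame(
        axis = densities[d_i], rep = b,
        individual = rep(seq_len(nrow(gp)), ncol(gp)),
        ancestry = rep(colnames(gp), each = nrow(gp)),
        value = as.vector(gp), stringsAsFactors = FALSE)
    }
  }
  summarise_sweep(records, "snp_density", reps, seed)
}

#' Select a stable axis value from a sweep
#'
#' `"min-median"` returns the axis value minimising the median s.d.
#' (smallest value on ties). `"kink"` finds the elbow of the decay curve:
#' the interior axis value s maximising the drop ratio
#' (m(s - 1 step) - m(s)) / max(m(s) - m(s + 1 step), floor) — large when
#' the curve drops steeply into s and flattens after it.
#'
#' @param sweep a `sweep_result`.
#' @param ancestry ancestry whose median-s.d. curve is used.
#' @param rule `"min-median"` or `"kink"`.
#' @param floor denominator floor for the kink ratio (default 1e-12).
#' @return The chosen axis value.
#' @export
select_stable_size <- function(sweep, ancestry, rule = c("min-median", "kink"),
                               floor = 1e-12) {
  rule <- match.arg(rule)
  med <- sweep$median_sd[sweep$median_sd$ancestry == ancestry, ]
  if (!nrow(med)) stop("ancestry not present in sweep: ", ancestry)
  med <- med[order(med$axis), ]
  m <- med$median_sd
  if (rule == "min-median") return(med$axis[which.min(m)])
  if (length(m) < 3) stop("kink rule needs at least 3 axis values")
  interior <- 2:(length(m) - 1)
  ratio <- (m[interior - 1] - m[interior]) /
    pmax(m[interior] - m[interior + 1], floor)
  med$axis[interior[which.max(ratio)]]
}

#' Write a sweep result as TSV
#'
#' Long table (axis, individual, ancestry, mean, sd) plus a summary table
#' (axis, ancestry, median_sd) side by side in two files.
#'
#' @param sweep a `sweep_result`.
#' @param path base path; `<path>_long.tsv` and `<path>_summary.tsv` are
#'   written.
#' @export
write_sweep_tsv <- function(sweep, path) {
  utils::write.table(sweep$long, paste0(path, "_long.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sweep$median_sd, paste0(path, "_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
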