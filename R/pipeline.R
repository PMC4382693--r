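#' End-to-end analysis pipeline
#'
#' Chains the stages of an admixed-cohort study on simulated or supplied
#' data: QC, local-ancestry calling with two decoders, global and
#' region-weighted population proportions, zone comparisons, time since
#' admixture, decoder concordance, and pairwise FST against the ancestral
#' panels. Stage outputs are written as TSV under an output directory
#' together with a run manifest.
#'
#' @param sim output of [simulate_cohort()] (or an equivalent list with
#'   `haplotypes`, `genotypes`, `markers`, `regions`).
#' @param panel a `freq_panel`.
#' @param map a `genetic_map`.
#' @param region_table,zone_map tables for the weighting and zone stages;
#'   `zone_map = NULL` skips the zone stage with a warning.
#' @param hmm an `hmm_config`.
#' @param fst_permutations permutations for the FST stage (0 skips it).
#' @param out_dir output directory (created); `NULL` writes nothing.
#' @param seed integer seed for the FST permutations.
#' @return List of stage results: `qc_report`, `calls` (viterbi),
#'   `proportions`, `national`, `zones`, `time`, `concordance`, `fst`,
#'   `manifest`.
#' @export
run_pipeline <- function(sim, panel, map, region_table = NULL,
                         zone_map = NULL, hmm = hmm_config(),
                         fst_permutations = 199, out_dir = NULL, seed = 1L) {
  t0 <- Sys.time()
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                    paste(..., collapse = " ")))
  }

  log_stage("qc", "markers in:", nrow(sim$markers))
  qc <- qc_filter(sim$genotypes, sim$markers)
  keep <- !paste(sim$markers$chrom, sim$markers$bp) %in%
    paste(qc$excluded$chrom, qc$excluded$bp)
  sub_map <- structure(as.data.frame(map)[keep, ],
                       class = c("genetic_map", "data.frame"))
  sub_panel <- new_freq_panel(panel$markers[keep, , drop = FALSE],
                              panel$freqs[keep, , drop = FALSE],
                              panel$ancestries)
  haps <- sim$haplotypes[, keep, drop = FALSE]
  log_stage("qc", "markers kept:", sum(keep))

  log_stage("lai", "decoding", nrow(haps), "haplotypes")
  calls_v <- decode_calls(haps, sub_panel, sub_map, hmm, "viterbi")
  calls_mp <- decode_calls(haps, sub_panel, sub_map, hmm, "max-posterior")

  props <- global_proportions(calls_v)
  w <- if (!is.null(region_table)) individual_weights(sim$regions, region_table)
       else rep(1, nrow(props))
  national <- weighted_proportions(props, w)
  log_stage("global", "national estimate:",
            paste(sprintf("%s=%.2f%%", names(national), 100 * national),
                  collapse = " "))

  zones <- NULL
  if (!is.null(zone_map) && !is.null(region_table)) {
    za <- assign_zones(region_table, zone_map)
    ind_zone <- za$membership$zone[match(sim$regions, za$membership$region)]
    zones <- list(assignment = za,
                  comparisons = lapply(stats::setNames(colnames(props), colnames(props)),
                    function(k) zone_comparison(props[, k], ind_zone, w)))
    log_stage("zones", "zone counts:",
              paste(names(za$counts), za$counts, sep = "=", collapse = " "))
  } else {
    warning("zone stage skipped: no zone map supplied")
  }

  G <- map_length_morgans(sub_map)$total
  K_sw <- count_switches(calls_v)
  time_est <- estimate_admixture_time(K_sw, props, G)
  log_stage("time", sprintf("mean T-hat = %.2f over G = %.2f Morgans",
                            attr(time_est, "mean_T"), G))

  conc <- local_concordance(calls_v, calls_mp)
  log_stage("concordance", sprintf("decoder coincidence = %.2f%%",
                                   conc$coincidence_pct))

  fst <- NULL
  if (fst_permutations > 0) {
    ref <- gen_reference_haplotypes(sub_panel, 40, seed = seed)
    fst <- lapply(stats::setNames(sub_panel$ancestries, sub_panel$ancestries),
      function(k) {
        ref_geno <- ref[[k]][seq(1, 39, 2), ] + ref[[k]][seq(2, 40, 2), ]
        fst_permutation_test(rbind(qc$genotypes, ref_geno),
                             rep(c("cohort", k), c(nrow(qc$genotypes), 20)),
                             M = fst_permutations, seed = seed)
      })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("laikit")),
    seed = seed, hmm = unclass(hmm),
    n_individuals = nrow(sim$genotypes),
    n_markers_in = nrow(sim$markers), n_markers_kept = sum(keep),
    map_morgans = G, elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_with_header(qc$report, file.path(out_dir, "qc_report.tsv"),
                          "QC removals per rule, in application order")
    write_tsv_with_header(
      data.frame(individual = seq_len(nrow(props)), props,
                 weight = w, check.names = FALSE),
      file.path(out_dir, "global_proportions.tsv"),
      "per-individual global ancestry proportions (base-weighted)")
    write_tsv_with_header(time_est, file.path(out_dir, "admixture_time.tsv"),
                          "per-individual switch counts and T estimates")
    write_calls_tsv(calls_v, file.path(out_dir, "calls_viterbi.tsv"))
    utils::write.table(conc$crosstab, file.path(out_dir, "concordance_crosstab.tsv"),
                       sep = "\t", quote = FALSE)
    writeLines(paste(names(manifest),
                     vapply(manifest, function(x) paste(unlist(x), collapse = ","),
                            character(1)),
                     sep = "\t"),
               file.path(out_dir, "manifest.tsv"))
  }

  list(qc_report = qc$report, calls = calls_v, calls_posterior = calls_mp,
       proportions = props, weights = w, national = national, zones = zones,
       time = time_est, concordance = conc, fst = fst, manifest = manifest)
}
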