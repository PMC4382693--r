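# Small builders shared across test files.

# Uniform-rate map: one value per chromosome Morgan length.
tiny_map <- function(morgans = 1, markers = 100, seed = 11,
                     rate_profile = "uniform") {
  gen_genetic_map(rep(5e7, length(morgans)), morgans,
                  markers, rate_profile = rate_profile, seed = seed)
}

tiny_panel <- function(map, F_st = c(NAT = 0.3, EUR = 0.3, AFR = 0.3), seed = 12) {
  gen_frequency_panel(markers = data.frame(chrom = map$chrom, bp = map$bp),
                      F_st = F_st, seed = seed)
}

# Hand-built ancestry_calls: labels is a matrix (haplotypes x markers) of
# integer ancestry indices; markers equally spaced unless bp given.
manual_calls <- function(labels, chrom = NULL, bp = NULL,
                         ancestries = c("NAT", "EUR", "AFR")) {
  labels <- as.matrix(labels)
  m <- ncol(labels)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(bp)) bp <- ave(seq_len(m), chrom, FUN = seq_along) * 1000L
  hap_meta <- data.frame(individual = rep(seq_len(nrow(labels) / 2), each = 2),
                         haplotype = rep.int(1:2, nrow(labels) / 2))
  laikit:::new_ancestry_calls(labels, hap_meta,
                              data.frame(chrom = chrom, bp = bp,
                                         ref = "A", alt = "G",
                                         stringsAsFactors = FALSE),
                              ancestries[seq_len(max(labels))], "manual")
}

# Random small HMM instance for oracle-equivalence checks.
random_instance <- function(m, K, seed) {
  set.seed(seed)
  map <- structure(data.frame(chrom = "chr1", bp = sort(sample.int(1e6, m)),
                              cM = cumsum(c(0, runif(m - 1, 0, 5)))),
                   class = c("genetic_map", "data.frame"))
  freqs <- matrix(runif(m * K), m, K)
  panel <- laikit:::new_freq_panel(
    data.frame(chrom = map$chrom, bp = map$bp, ref = "A", alt = "G"),
    freqs, paste0("pop", seq_len(K)))
  hap <- rbinom(m, 1, 0.5)
  cfg <- hmm_config(T_switch = runif(1, 1, 15), eps = runif(1, 0.005, 0.1))
  list(map = map, panel = panel, hap = hap, cfg = cfg)
}

# Exhaustive-path HMM oracle: joint probability of every ancestry path,
# computed directly from the model definition (prior, stay/redraw
# transition kernel, clamped Bernoulli emissions). Independent of the
# forward-backward / Viterbi recursions under test.
enumerate_hmm <- function(hap, panel, map, config) {
  m <- length(hap)
  K <- ncol(panel$freqs)
  f <- pmin(pmax(panel$freqs, config$eps), 1 - config$eps)
  E <- hap * f + (1 - hap) * (1 - f)
  pr <- rep(1 / K, K)
  stay <- exp(-config$T_switch * marker_morgan_gaps(map))
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), m)))
  probs <- apply(paths, 1, function(z) {
    p <- pr[z[1]] * E[1, z[1]]
    if (m > 1) for (j in 2:m) {
      tr <- (1 - stay[j]) * pr[z[j]] + if (z[j] == z[j - 1]) stay[j] else 0
      p <- p * tr * E[j, z[j]]
    }
    p
  })
  post <- matrix(0, m, K)
  for (j in seq_len(m)) for (k in seq_len(K))
    post[j, k] <- sum(probs[paths[, j] == k])
  lik <- sum(probs)
  list(posterior = post / lik, loglik = log(lik),
       best_path = paths[which.max(probs), ], best_logp = log(max(probs)))
}

# bp-weighted per-individual ancestry proportions from a truth tract set.
tract_proportions <- function(tracts) {
  len <- tracts$end - tracts$start
  tot <- tapply(len, tracts$individual, sum)
  ancestries <- attr(tracts, "ancestries")
  out <- sapply(ancestries, function(a) {
    x <- tapply(len * (tracts$ancestry == a), tracts$individual, sum)
    x / tot
  })
  matrix(out, ncol = length(ancestries),
         dimnames = list(NULL, ancestries))
}
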