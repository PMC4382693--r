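#' Admixture hidden Markov model for local-ancestry calling
#'
#' A minimal haplotype-level admixture HMM. The hidden state at marker j
#' is the ancestry of the haplotype there; over a gap of d Morgans the
#' chain stays put with weight exp(-T d) and otherwise redraws the state
#' from the prior proportions (so chromosome starts, at infinite gap,
#' reset to the prior). Emissions are Bernoulli in the panel frequency
#' f_kj, clamped away from 0/1 so no marker has zero likelihood.
#'
#' @name hmm
NULL

#' HMM configuration
#'
#' @param T_switch switch-rate parameter in generations (> 0). Default 8,
#'   the usual setting for Latin-American cohorts admixed since colonial
#'   times.
#' @param eps emission clamp / error rate in (0, 0.5); panel frequencies
#'   are clamped to `[eps, 1 - eps]`. Default 0.01.
#' @param priors ancestry prior proportions (default uniform 1/K).
#' @return An `hmm_config` list.
#' @export
hmm_config <- function(T_switch = 8, eps = 0.01, priors = NULL) {
  if (T_switch <= 0) stop("T_switch must be > 0")
  if (eps <= 0 || eps >= 0.5) stop("eps must lie in (0, 0.5)")
  structure(list(T_switch = T_switch, eps = eps, priors = priors),
            class = "hmm_config")
}

hmm_emissions <- function(hap, panel, eps) {
  f <- pmin(pmax(panel$freqs, eps), 1 - eps)
  hap * f + (1 - hap) * (1 - f)  # markers x K
}

hmm_priors <- function(config, K) {
  pr <- config$priors
  if (is.null(pr)) pr <- rep(1 / K, K)
  if (length(pr) != K || abs(sum(pr) - 1) > 1e-8)
    stop("priors must be a length-K probability vector")
  pr
}

#' Posterior ancestry probabilities for one haplotype
#'
#' Scaled forward-backward over the admixture HMM.
#'
#' @param hap 0/1 allele vector over the panel's markers.
#' @param panel a `freq_panel`.
#' @param map a `genetic_map` on the same marker list.
#' @param config an `hmm_config`.
#' @return List with `posterior` (markers x K, rows sum to 1) and
#'   `loglik` (marginal log-likelihood of the haplotype).
#' @export
ancestry_posteriors <- function(hap, panel, map, config = hmm_config()) {
  m <- length(hap)
  if (m != nrow(panel$freqs) || m != nrow(map))
    stop("haplotype, panel and map must share one marker list")
  K <- ncol(panel$freqs)
  E <- hmm_emissions(hap, panel, config$eps)
  pr <- hmm_priors(config, K)
  stay <- exp(-config$T_switch * marker_morgan_gaps(map))

  alpha <- matrix(0, m, K)
  scal <- numeric(m)
  a <- pr * E[1, ]
  scal[1] <- sum(a); alpha[1, ] <- a / scal[1]
  if (m > 1) for (j in 2:m) {
    pred <- stay[j] * alpha[j - 1, ] + (1 - stay[j]) * pr
    a <- pred * E[j, ]
    scal[j] <- sum(a)
    alpha[j, ] <- a / scal[j]
  }
  beta <- matrix(0, m, K)
  beta[m, ] <- 1
  if (m > 1) for (j in (m - 1):1) {
    nb <- E[j + 1, ] * beta[j + 1, ]
    beta[j, ] <- (stay[j + 1] * nb + (1 - stay[j + 1]) * sum(pr * nb)) / scal[j + 1]
  }
  post <- alpha * beta
  post <- post / rowSums(post)
  list(posterior = post, loglik = sum(log(scal)))
}

#' Viterbi path for one haplotype
#'
#' Most probable joint ancestry path; ties resolved to the lowest
#' ancestry index.
#'
#' @inheritParams ancestry_posteriors
#' @return List with `path` (integer ancestry indices) and `logp` (joint
#'   log-probability of the path).
#' @export
viterbi_path <- function(hap, panel, map, config = hmm_config()) {
  m <- length(hap)
  K <- ncol(panel$freqs)
  logE <- log(hmm_emissions(hap, panel, config$eps))
  pr <- hmm_priors(config, K)
  stay <- exp(-config$T_switch * marker_morgan_gaps(map))

  delta <- log(pr) + logE[1, ]
  back <- matrix(0L, m, K)
  if (m > 1) for (j in 2:m) {
    # trans[k, l] = P(l at j | k at j-1)
    trans <- (1 - stay[j]) * matrix(pr, K, K, byrow = TRUE)
    diag(trans) <- diag(trans) + stay[j]
    cand <- delta + log(trans)  # K x K: row k -> col l
    back[j, ] <- max.col(t(cand), ties.method = "first")
    delta <- cand[cbind(back[j, ], seq_len(K))] + logE[j, ]
  }
  path <- integer(m)
  path[m] <- which.max(delta)
  if (m > 1) for (j in m:2) path[j - 1] <- back[j, path[j]]
  list(path = path, logp = max(delta))
}

#' Decode local-ancestry calls for a set of haplotypes
#'
#' Runs the admixture HMM on every haplotype and returns per-marker
#' ancestry labels, either as the Viterbi joint path or the per-marker
#' posterior mode (ties to the lowest ancestry index). The two modes act
#' as two distinct callers for concordance analysis.
#'
#' @param haplotypes 0/1 matrix, two consecutive rows per individual.
#' @param panel a `freq_panel`.
#' @param map a `genetic_map` on the same marker list.
#' @param config an `hmm_config`.
#' @param mode `"viterbi"` or `"max-posterior"`.
#' @return An `ancestry_calls` with `method` set to the decode mode.
#' @export
decode_calls <- function(haplotypes, panel, map, config = hmm_config(),
                         mode = c("viterbi", "max-posterior")) {
  mode <- match.arg(mode)
  haplotypes <- as.matrix(haplotypes)
  nh <- nrow(haplotypes)
  if (nh %% 2L != 0L) stop("haplotypes must come in pairs (two rows per individual)")
  labels <- matrix(0L, nh, ncol(haplotypes))
  for (r in seq_len(nh)) {
    labels[r, ] <- if (mode == "viterbi") {
      viterbi_path(haplotypes[r, ], panel, map, config)$path
    } else {
      post <- ancestry_posteriors(haplotypes[r, ], panel, map, config)$posterior
      max.col(post, ties.method = "first")
    }
  }
  hap_meta <- data.frame(individual = rep(seq_len(nh / 2L), each = 2),
                         haplotype = rep.int(1:2, nh / 2L))
  new_ancestry_calls(labels, hap_meta, panel$markers, panel$ancestries,
                     method = mode)
}
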