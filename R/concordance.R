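#' Concordance between two local-ancestry call sets
#'
#' Agreement measures between two callers on the same cohort: the exact
#' per-call coincidence percentage with a K x K cross-tabulation of label
#' pairs, band counts of global-proportion differences, and Pearson
#' correlation tests relating per-marker disagreement to local
#' recombination rate and to ancestral allele-frequency differentiation.
#'
#' @name concordance
NULL

#' Local (per-call) concordance
#'
#' Calls are compared over every individual x haplotype x marker cell.
#' Because phase is not identifiable between independent callers,
#' haplotype label pairs are compared per individual-marker as unordered
#' pairs: if swapping the two haplotypes of one caller matches more calls
#' at a marker, the swapped orientation is used there.
#'
#' @param a,b two `ancestry_calls` on identical individuals and markers.
#' @param match_phase compare unordered haplotype pairs (default TRUE).
#' @return A `concordance_report`: list with `coincidence_pct`,
#'   `crosstab` (K x K counts, rows = `a`, cols = `b`),
#'   `marker_inconsistency` (per-marker count of disagreeing calls) and
#'   `n_total`.
#' @export
local_concordance <- function(a, b, match_phase = TRUE) {
  if (!identical(dim(a$labels), dim(b$labels)))
    stop("call sets have different dimensions")
  if (!identical(a$ancestries, b$ancestries))
    stop("call sets label different ancestries")
  la <- a$labels; lb <- b$labels
  n <- nrow(la) / 2L
  if (match_phase && n >= 1) {
    for (i in seq_len(n)) {
      r <- c(2L * i - 1L, 2L * i)
      direct <- (la[r[1], ] == lb[r[1], ]) + (la[r[2], ] == lb[r[2], ])
      swapped <- (la[r[1], ] == lb[r[2], ]) + (la[r[2], ] == lb[r[1], ])
      sw <- swapped > direct
      if (any(sw)) {
        tmp <- lb[r[1], sw]
        lb[r[1], sw] <- lb[r[2], sw]
        lb[r[2], sw] <- tmp
      }
    }
  }
  K <- length(a$ancestries)
  crosstab <- table(factor(la, levels = seq_len(K), labels = a$ancestries),
                    factor(lb, levels = seq_len(K), labels = a$ancestries))
  total <- length(la)
  structure(list(coincidence_pct = 100 * sum(diag(crosstab)) / total,
                 crosstab = unclass(crosstab),
                 marker_inconsistency = colSums(la != lb),
                 n_total = total),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Local concordance: %.2f%% of %d calls coincide\n",
              x$coincidence_pct, x$n_total))
  print(x$crosstab)
  invisible(x)
}

#' Global-proportion agreement bands
#'
#' Counts, per ancestry, the individuals whose global proportions from
#' two methods differ by less than each threshold, and the per-ancestry
#' Pearson correlation between the two proportion sets.
#'
#' @param props_a,props_b matrices (individuals x K) of global
#'   proportions from two methods.
#' @param thresholds difference bands in percent (default
#'   0.1, 0.5, 1, 3, 6).
#' @return List with `bands` (threshold x ancestry counts, non-decreasing
#'   down the thresholds) and `correlation` (per-ancestry Pearson r).
#' @export
global_concordance_bands <- function(props_a, props_b,
                                     thresholds = c(0.1, 0.5, 1, 3, 6)) {
  props_a <- as.matrix(props_a); props_b <- as.matrix(props_b)
  if (!identical(dim(props_a), dim(props_b)))
    stop("proportion sets have different dimensions")
  d_pct <- abs(props_a - props_b) * 100
  bands <- t(vapply(thresholds, function(t) colSums(d_pct < t),
                    numeric(ncol(props_a))))
  rownames(bands) <- paste0("<", thresholds, "%")
  corr <- vapply(seq_len(ncol(props_a)), function(k) {
    if (stats::sd(props_a[, k]) == 0 || stats::sd(props_b[, k]) == 0)
      return(NA_real_)  # degenerate: correlation undefined
    stats::cor(props_a[, k], props_b[, k])
  }, numeric(1))
  names(corr) <- colnames(props_a)
  list(bands = bands, correlation = corr)
}

#' Pearson correlation test
#'
#' Computes r, the t statistic \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on
#' n - 2 degrees of freedom, and the two-sided p-value.
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant).
#' @return List `r`, `t`, `df`, `p`.
#' @export
correlation_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  df <- n - 2
  t <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), df)
  list(r = r, t = t, df = df, p = p)
}
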