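---
title: "Local-ancestry pipelines for recently admixed cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local-ancestry pipelines for recently admixed cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laikit)
```

## The problem

Cohorts from Latin America typically carry chromosomes that are mosaics of
Native-American (NAT), European (EUR) and African (AFR) segments, the
product of admixture beginning a handful of centuries — some ten
generations — ago. `laikit` provides the full analysis chain such a cohort
needs once phased genotypes exist: per-marker local-ancestry calls, global
ancestry per individual, population-level estimates that correct for
geographically uneven sampling, an estimate of when admixture happened,
agreement diagnostics between callers, sensitivity analyses for reference
panels and marker density, and permutation-tested FST for questions such as
sex-biased admixture.

Because each stage is statistical, the package ships a cohort simulator
whose ground truth exercises every stage; all claims the test suite makes
are claims about these synthetic conditions.

## The hybrid-isolation model

The simulator and the time-since-admixture estimator share one model.
Admixture happens in a single pulse $T$ generations ago ("hybrid
isolation"); afterwards recombination alone reshuffles ancestry. On a
chromosome of genetic length $g$ Morgans, each haplotype then carries
junctions laid down as a Poisson process of rate $T$ per Morgan. Segment
ancestries between junctions are drawn i.i.d. from the admixture
proportions $p = (p_{NAT}, p_{EUR}, p_{AFR})$ — the standard Markov
approximation to the underlying pedigree process — and a junction is a
*visible* switch only when the labels on both sides differ, which happens
with probability $1 - \sum_k p_k^2$. Summing over a diploid genome of total
map length $G = \sum_c g_c$:

$$E[K] \;=\; 2\,T\,G\,\bigl(1 - \textstyle\sum_k p_k^2\bigr),$$

and in the two-ancestry view with European share $q$,
$E[K] = 4TGq(1-q)$. We use the rate-$T$ convention (not $T-1$); simulator
and estimator share it, so parameter recovery is exact in expectation. The
estimator inverts the formula per individual,
$\hat T = K / (2G(1-\sum_k p_k^2))$, using that individual's own estimated
proportions, and is undefined (and flagged) for single-ancestry genomes.
Two caveats are inherited from the model: under continuous gene flow
$\hat T$ is a gene-flow-weighted average age, and calls decoded by an HMM
are smoother than the truth, so $\hat T$ from decoded calls is biased
downward relative to truth tracts — the tests measure this rather than
assume it away. Mean tract lengths follow the HI limit
$1/(T(1-p_k))$ Morgans, which the suite checks on long chromosomes; on
short chromosomes end-censoring shortens observed tracts.

Switches are counted per haplotype between adjacent markers (equivalently
tract boundaries after merging runs — the two representations are asserted
equal), never across chromosome boundaries, and summed over the two
haplotypes; output metadata records this convention.

## Synthetic data: what it does and does not emulate

`gen_frequency_panel()` draws ancestral allele frequencies under the
Balding–Nichols model: marker $j$ gets an ancestral frequency $p_j$ (by
default Uniform(0.05, 0.95)), and population $k$ draws
$f_{kj} \sim \mathrm{Beta}(p_j\lambda_k, (1-p_j)\lambda_k)$ with
$\lambda_k = (1-F_k)/F_k$, so $F_k$ controls differentiation; two tracks
generated at $F$ show realized pairwise Hudson FST $\approx F$. Default
differentiation 0.3 in the test cohorts gives per-marker informativeness
comparable to well-separated continental panels. `gen_genetic_map()` lays
markers with either uniform recombination or Gamma-distributed per-interval
rates (shape 0.6), the latter a crude but sufficient stand-in for hotspot
heterogeneity in pedigree maps. `simulate_cohort()` emits haplotype alleles
Bernoulli($f_{kj}$) given the truth tract, with an optional per-allele flip
error and missingness to exercise QC, and assigns individuals to regions by
a configurable sampling table, with per-region proportion profiles to
synthesise a north-to-south minority-ancestry gradient.

Real data differ in ways the simulator deliberately ignores: linkage
disequilibrium *within* ancestral populations (emissions are
conditionally independent given ancestry), phasing error, genotyping batch
structure, and continuous or multi-pulse gene flow. Passing tests therefore
validate the estimators under their stated model, not the hardness of real
LAMP-LD/RFMix calling on array data.

## Quality control

Filters run in a fixed order so reports are reproducible: sample
missingness (> 10% removes the sample), then on the reduced matrix SNP
call rate (≤ 95% removes), minor allele frequency (≤ 0.01), an exact
Hardy–Weinberg test (p ≤ 10⁻⁵), strand-ambiguous A/T and C/G SNPs, and the
HLA region, whose extreme LD biases local-ancestry models. The HWE test is
the conditional exact test by full enumeration of heterozygote counts
(two-sided by probability mass) — the field default for array QC; MAF and
HWE use non-missing calls only. The HLA window defaults to
chr6:25–35 Mb (GRCh37 convention) and is overridable since no universal
coordinates exist. Each removed marker is attributed to the first rule
that caught it, so rule counts sum to the total removed.

## The local-ancestry HMM

The caller is a haplotype-level admixture HMM: the hidden state at a
marker is that haplotype's ancestry. Over a gap of $d$ Morgans the chain
stays with weight $e^{-T_{hmm} d}$ and otherwise redraws from the prior
proportions (uniform $1/K$ by default; estimating them is out of scope),
so an infinite gap — a chromosome start — resets to the prior. Emissions
are Bernoulli in the panel frequency clamped to $[\epsilon, 1-\epsilon]$
($\epsilon = 0.01$), which both models genotype error and guarantees no
marker has zero likelihood. $T_{hmm}$ defaults to 8 generations, the usual
setting for post-colonial Latin-American cohorts; it need not equal the
simulated age, and the mismatch is part of what the concordance tests
probe. Decoding is either the Viterbi joint path or the per-marker
posterior mode (forward–backward with per-marker scaling); ties break to
the lowest ancestry index. The two decoders double as two distinct
"methods" for concordance analysis. The suite verifies both decoders
against exhaustive path enumeration on small instances at $10^{-9}$
tolerance.

Unphased diploid input is out of scope by design: phasing happens
upstream (the simulator emits phase), avoiding a $K^2$-state diploid HMM.

## Global, weighted and zonal ancestry

"Proportion of bases assigned to each ancestry" is computed with
half-interval weights: each marker represents half the bp distance to each
neighbour (single half-interval at chromosome ends). This approximates
base coverage and reduces to plain call averaging on uniformly spaced
markers. Population-level estimates correct uneven geographic sampling by
weighting every individual from region $r$ with
$w_r = \text{census fraction}_r / \text{sample fraction}_r$ and averaging
$\sum_i w_i p_{ik} / \sum_i w_i$. Weights use the printed percentage
fractions when available (matching two-decimal display like 1.83 for a
1.1%/0.6% region), else raw counts; individuals of unknown region get
weight 1 so they stay in the national estimate despite having no census
fraction. Zone analyses group regions into five north-to-south zones and
compare an ancestry's per-individual proportions across zones by one-way
ANOVA with Tukey HSD on the untransformed proportions, plus box-plot
summaries. Within-zone means reuse the same region weights; pass
`weights = NULL` to disable. Zones with fewer than two members are
reported and excluded from the test.

## Concordance and its correlates

Local concordance is the percentage of exactly coinciding calls over
individual × haplotype × marker, with a $K \times K$ cross-tabulation to
localise directional confusions. Because phase is not identifiable between
independent callers, haplotype pairs are compared unordered per
individual-marker. Global agreement is summarised by band counts
(differences below 0.1/0.5/1/3/6 percentage points) and per-ancestry
Pearson correlations. Per-marker disagreement counts are correlated
(Pearson, $t = r\sqrt{(n-2)/(1-r^2)}$) against the local recombination
rate — the Morgan span of the marker's half-interval divided by its bp
span — and against the squared NAT–EUR frequency difference. On simulated
cohorts the signs reproduce the expected pattern: more disagreement where
recombination is fast (callers must decide whether to switch), less where
markers are ancestry-informative.

## Sensitivity sweeps

Both sweeps repeat the full call-and-summarise cycle over replicates
(default 10) and report, per axis value, each individual's across-replicate
standard deviation and its cohort median. The panel sweep subsamples
reference haplotypes without replacement (one panel or all panels; others
fixed) and refits emission frequencies; the density sweep subsamples
markers. Subsamples are reproducible from (seed, axis index, replicate).
Stable-size selection offers `min-median` (argmin of the median s.d.,
smallest size on ties) and a `kink` rule: the interior point maximising the
drop ratio $(m(s_{-1})-m(s)) / \max(m(s)-m(s_{+1}), \delta)$, i.e. where
the decay curve flattens; the kink formula is this package's own
reconstruction of the elbow idea and is flagged in output metadata. A
plug-in `caller` hook lets external LAI tools be swept through the same
machinery.

## FST

Pairwise differentiation uses Hudson's ratio-of-averages estimator with
sample-size correction, $\sum_l N_l / \sum_l D_l$ with
$N_l = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1}$
and $D_l = p_1(1-p_2) + p_2(1-p_1)$ — for a single biallelic locus this
coincides with the classical Slatkin/Hudson pairwise form. The estimate is
reported unclamped (slightly negative values are informative under no
differentiation) alongside a zero-clamped copy. A `ploidy` flag supports
haploid input (chromosome-Y-style male haplotypes) next to diploid
(autosomes, X in females), so sex-chromosome contrasts are a matter of
configuration. Significance comes from label permutations with the add-one
estimator $p = (1 + \#\{F_{perm} \ge F_{obs}\})/(M+1)$, bounded below by
$1/(M+1)$; the suite verifies calibration (type-I error near 5% at
$\alpha = 0.05$) and recovery of generating $F \in \{0.01, 0.1, 0.3\}$
within Monte-Carlo error.

## Numerical and design notes

* All randomness flows from named integer seeds; identical seeds give
  bit-identical outputs, including TSV files.
* Forward–backward uses per-marker scaling, never raw products; posteriors
  renormalise to 1 within $10^{-9}$.
* Junction bp positions come from linear interpolation of the cumulative
  map and are rounded; zero-length tracts that rounding could create are
  dropped.
* Problem sizes in tests and in the acceptance script (hundreds of markers,
  tens of individuals, hundreds of replicates) were chosen as the smallest
  scales at which the Monte-Carlo checks are sharp; the statistical
  machinery is identical at larger scale.
* Coordinates: BED tract output is 0-based half-open; VCF and map files are
  1-based. Every writer states its convention in a header comment.

## Known limitations

No coalescent-level realism (no within-ancestry LD, no drift since
admixture); no continuous-gene-flow or multi-pulse time inference; no
relatedness/IBD QC; no unphased-input mode; the two built-in "methods" for
concordance are two decoders of one HMM, not two independent model
families. These are boundaries, not bugs: each mirrors an explicit scope
decision described above.
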