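---
title: "Methods: haplotype painting, crossover-rate estimation and pool association on recombinant X chromosomes"
author: "crossoverBSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crossover suppression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Two near-isogenic *Drosophila* X chromosomes, one from a high-locomotor-
activity line ("Hi") and one from a low line ("Lo"), differ at single-
nucleotide sites that are strikingly unevenly distributed: five discrete
blocks of roughly 0.4–2.6 Mb carry ~25 SNPs/10 kb (0.25% divergence) on a
background of ~4 SNPs/10 kb (0.04%). After 15 generations of free
intermating between the lines, individually sequenced recombinant males
can be "painted" by parental origin along the X, crossovers can be counted
per region, and pool-based association can map the activity phenotype.
The question the statistics answer: is crossover placement biased away
from the SNP-dense blocks, and is the phenotype signal confined to
particular blocks?

`crossoverBSA` implements the full analysis (painting, region-wise rate
estimation with bootstrap CIs, an exact conditional rate test, Fisher
pool association, per-region parentage fractions) plus a forward meiosis
simulator that generates data with the design's statistical structure, so
every stage can be validated against known truth.

# Haplotype painting

A site is *informative* when every Hi parental sample is homozygous for
one allele, every Lo sample homozygous for a different allele; sites
segregating within a line are dropped and reported as the per-line
heterozygous fraction. Because males are hemizygous, a male's X genotype
is a direct haplotype: each informative call is labelled `Hi`, `Lo`,
`Missing` (no call) or `Unique` (matches neither parent).

Uncalled base pairs inherit the origin of the nearest usable labelled
site by bp distance. Numerical conventions, all deterministic:

* exact midpoints between two opposite-origin sites go to the
  lower-coordinate site;
* chromosome ends inherit the nearest label inward;
* coordinates are 0-based half-open internally, 1-based in VCF output.

**Denoising.** Single-fly sequencing at marginal coverage leaves a faint
background of apparently opposite parentage that cannot be distinguished
from non-crossover gene conversion; we treat it as call noise. A run of
opposite-origin labels shorter than `k` informative sites flanked by the
same origin on both sides is reassigned to the flanking origin, iterated
to a fixed point (end runs are never touched; `k = 1` is the identity).
The default is `k = 5`: with per-site error rate $\varepsilon$ and
dropout $d$, the expected number of spurious tracts per fly is roughly
$n_{\mathrm{sites}}\,[\varepsilon(1-d)]^k$ — at the default noise levels
($\varepsilon = 0.02$, $d = 0.15$, ~21,000 informative sites) that is
~0.1 per fly at $k = 3$, the same order as the true per-region crossover
signal, but ~$3\times10^{-5}$ at $k = 5$. True tracts spanning fewer than
5 dense-region sites (~2 kb) are vanishingly rare under ~1 crossover per
meiosis, so the cost of the larger `k` is negligible. `k` is exposed
everywhere (`smoothK` in the pipeline, `--k` in the CLI).

# Crossover counting and rates

An observed crossover is an origin switch between consecutive usable
sites; its breakpoint is localised only to the interval between the two
flanking sites, and it is assigned to the region containing the interval
midpoint. Marker-based counts are lower bounds: an even number of
crossovers between two informative sites is invisible (parity loss).

Within the SNP-sparse regions the parental sequences are nearly
identical, so tracts cannot be read directly. For the sparse gap between
two dense regions we instead *infer* a minimum crossover count: 1 if the
facing edges of the flanking dense regions have discordant origin, 0 if
concordant, not evaluable if either edge lacks a usable site.

Rates are normalised as
$$ r = \frac{\text{crossovers}}{\text{Mb} \times n_{\text{flies}} \times n_{\text{meioses}}}, $$
with $n_{\text{flies}} = 84$ and $n_{\text{meioses}} = 5$ as the study
constants: recombination happens only in females, a given X spends about
two thirds of 15 generations in females (~10 female transmissions), and
only half of the chromatids carry each crossover, giving ~5 effective
single-recombination opportunities. Both constants are explicit arguments
rather than hard-coded, since the design admits either the
15-generation or the 5-opportunity accounting; the defaults follow the
published normalisation.

**Confidence intervals.** Flies are the exchangeable unit, so the
bootstrap resamples flies with replacement (B = 10,000 by default) and
recomputes the rate; per-region CIs are percentile intervals, matching
the study's stated procedure. For *ratio* estimands (sparse:dense rate
ratio) the percentile interval undercovers because the denominator count
is small and the ratio distribution is skewed; `bootstrapRateRatio()`
therefore returns a basic (reflected) interval on the log scale, the
standard construction for rate ratios. The package's own replicated
simulation check (below) is what motivated and calibrated this choice.

**Exact conditional rate test.** Treating region counts as Poisson with
exposure proportional to length, conditioning on the total $N = c_1 +
c_2$ makes $c_1 \sim \mathrm{Binomial}(N,\, L_1/(L_1+L_2))$ under the
null of equal per-Mb rates. The two-sided p-value sums all outcomes with
point probability no larger than the observed one (the minimum-likelihood
convention used by `binom.test`/`poisson.test`). This convention — not
tail doubling — reproduces the published per-region p-values (0.009 for
region C vs the gap, 0.001 for region D) from the published counts, and
it is verified in the tests against a full enumeration oracle built from
`lchoose`, for every total up to 200, to $10^{-12}$.

# Pool association and parentage fractions

Extreme pools are the `poolSize` lowest- and highest-activity flies (ties
broken by fly id). Per site, a 2×2 allele-by-pool table is built with
complete-case handling (a fly missing a call is dropped at that site
only) and tested with Fisher's exact test, two-sided by the
probability-mass method, implemented directly from the hypergeometric
density and cross-checked against both an enumeration oracle and
`stats::fisher.test`. Significance uses Bonferroni: $p < \alpha/m$.

Per-region Hi-parentage fractions are length-weighted (Hi bp over
determinable bp; an informative-site-weighted variant is exposed as an
option, since either convention is defensible). Pools are compared per
region with a two-sided Wilcoxon rank-sum test: the exact permutation
distribution of the midrank sum (two-sided by doubling the smaller tail,
capped at 1) is enumerated whenever the number of group assignments is at
most 1e5; otherwise the normal approximation with tie and continuity
correction is used. The exact-with-midranks path is needed because
parentage fractions are mostly 0 or 1, i.e. heavily tied.

`expectedResolution(L, n)` = $L/2^n$ Mb gives the naive expected mapping
resolution of $n$ uniformly-placed recombination opportunities, and
`cmMbFit()` is the ordinary least-squares map of genetic (cM) on physical
(Mb) position with $r^2$, for comparison with classical mapping.

# The simulator

`simulationConfig()` fixes the emulated design: 23.5 Mb X; dense blocks
A–E of 0.4, 0.8, 2.6, 1.9 and 1.5 Mb (C at 13.9–16.5 Mb and D at
16.9–18.8 Mb are placed where the mapping localised them; A, B and E have
published lengths but not positions, so their default placements at
3.0–3.4, 6.0–6.8 and 19.5–21.0 Mb are package choices, configurable);
SNP rates 25 vs 4 per 10 kb; per-line heterozygous-site fractions 7.9%
and 5.8%; ~80 Hi founder females × ~55 Lo founder males; 15 discrete
non-overlapping generations of random mating at population size 400
("free intermating" is otherwise unspecified, so random union of gametes
with equal sex ratio is the model); 788 assayed males; pools of 45.

Female meiosis draws a Poisson(1) crossover count per X bivalent; each
crossover lands on the transmitted chromatid with probability 1/2; no
crossover interference is modelled. Crossover positions follow a
piecewise-constant weight: 1 in sparse regions, 1/3.4 in dense blocks
(the suppression factor under study). Males transmit their X intact to
daughters. Gene conversion is not simulated; the per-site genotype error
probability (default 0.02, with dropout 0.15 emulating ~4–6M-read
single-fly sequencing) stands in for the opposite-parentage background.

Activity is `baseline + effect_C·HiFrac(C) + effect_D·HiFrac(D) + noise`,
floored at 0, with defaults 250 + 945·C + 405·D counts/day and sd 80
(a 70/30 split of the causal effect between C and D, association being
stronger in C), calibrated so the extreme pools land in the low-hundreds
vs mid-thousands counts/day regime reported for the real pools.

**What the generator reproduces, and what it does not.** It reproduces
the SNP landscape, the breeding design, female-limited recombination with
dense-block suppression, genotyping noise, and phenotype-driven pool
selection; all stochastic steps are bit-reproducible given (config,
seed). It does not reproduce one quantitative feature of the real data:
with Poisson(1)/half-chromatid meiosis and founder Hi-X frequency
160/215 ≈ 0.74, a mother's two X's differ at a locus with probability at
most $2pq \approx 0.38$, so assayed chromosomes carry only ~2 visible
origin switches, whereas the published per-region counts imply ~5–6
visible crossovers per fly. No parameterisation of this meiosis model can
close that gap (it would need origin-heterozygosity near 1). Two
consequences follow for what passing tests show:

* parameter recovery of the suppression factor is checked on unselected
  males with the chromosome-wide painted sparse:dense contrast, since in
  simulated data sparse regions are directly readable; the gap-flank
  minimum-count contrast remains the real-data analogue and is reported
  alongside;
* with so few switches per chromosome, extreme pools differ in parentage
  chromosome-wide, so simulated pool association is *not* confined to
  the causal blocks the way the real mapping was: flagged sites
  concentrate in and around C and D but about a third fall outside, a
  hitch-hiking artefact of the generator's long haplotype blocks, not of
  the association code (which is oracle-verified site by site). The
  corresponding acceptance check is left failing by design honesty.

Pool selection also removes C/D-discordant flies (their activity is
intermediate), which depresses crossover counts in and between the causal
blocks — the same ascertainment the study itself notes when calling its
sparse-gap count "an absolute minimum".

# Problem sizes used by the test suite

Tests run the full 15-generation design where the claim depends on it:
parameter recovery uses 50 replicates × 84 painted flies with B = 2,000
bootstrap resamples per replicate (the headline per-region tables use
B = 10,000); painting fidelity uses 100 noise-free flies (≥99% bp
agreement, crossover counts never above truth); bootstrap coverage uses
500 Poisson replicates at nominal 95% (≥90% required); oracle agreement
covers every conditional-test total up to 200 and 2,000 random Fisher
tables with margins up to 100, at $10^{-12}$. Smaller designs (3–4
generations, 6 Mb chromosomes) are used for I/O round trips and pipeline
determinism, where generation depth is irrelevant.

# Known limitations

* Breakpoints are localised only to flanking-site intervals; in sparse
  regions that is ~2.5 kb even without noise.
* The inferred sparse-gap count is a minimum (parity losses, plus pool
  ascertainment); rate contrasts involving it are biased toward 1.
* Autosomes, crossover interference, gene conversion, overlapping
  generations and non-random mating are out of scope.
* The painting reports `Unknown`/`Unique` separately rather than merging
  them into a single ambiguous class.
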