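---
title: "QTL mapping from graded-pool sequencing: model, statistics and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QTL mapping from graded-pool sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradedpool)
```

## The experimental design

Bulked-segregant analysis (BSA) maps quantitative trait loci by pooling DNA
from phenotypically extreme individuals and comparing pooled allele
frequencies. The graded-pool variant implemented here generalises the two
phenotypic tails to *k* ordered bulks: an F2 population segregating for a
quantitative trait is ranked by phenotype, split into k graded pools
(grade 1 = highest phenotypic class), and each pool is sequenced as one
sample. At a SNP linked to a causal locus, the frequency of the high-parent
allele declines monotonically from grade 1 to grade k; at an unlinked SNP
every pool shows the same allele ratio (about 50/50 when both parents
contribute one allele). The analysis therefore reduces, per SNP, to a
2 x k contingency table — reference and alternate read counts across the
ordered grades — and the mapping question becomes: where along the genome
do these tables show an allele-by-grade association?

## Variant filtering

Pooled read counts only carry signal at sites that segregate between the
parents and are sequenced adequately. Four staged filters run before
testing:

1. **Quality** — drop variants below a Phred-scaled QUAL floor
   (`min_qual`, default 30, the conventional floor for GATK-called SNPs;
   the threshold is configurable because calling pipelines differ).
2. **Depth** — per pool, keep a variant only if its depth lies within
   `[0.5, 2] x` that pool's median depth (closed interval, medians taken
   over the post-quality table). A median-relative window was chosen over
   absolute bounds because pools are sequenced on different lanes at
   different total coverage; halving and doubling brackets the bulk of a
   Poisson-like depth distribution while excluding collapsed repeats and
   dropout sites.
3. **Parent informativeness** — keep sites where the two parental lines
   are homozygous for different alleles. When parents were not sequenced
   (or in parent-free simulated runs) this stage is skipped.
4. **Fixed non-reference sites** — drop sites where no pool contains a
   single reference read; such sites are reference-assembly differences
   shared by both parents and carry no segregation signal. The mirrored
   all-reference case is only dropped under an optional flag (default
   off), keeping the default behaviour exactly at the published criterion.

Stages run in the order above. Because depth medians are computed on the
table a stage receives, filtering is not formally idempotent in
pathological cases, although in practice a second pass removes nothing;
the per-stage counts are reported in a `FilterReport` tibble.

Only biallelic SNPs enter the table at all: multiallelic records and
indels are excluded at VCF parsing (a flag admits biallelic indels), and
per-sample AD allele depths are the single source of counts — records
lacking AD are dropped, never imputed from DP or PL.

## The ridit test

With reads as observations, each SNP is a 2 x k table: `n_1j` reference
reads and `n_2j` alternate reads in grade j, column totals `N_j`, total N.
The package's default statistic is a ridit analysis with the combined
sample as the reference distribution. The ridit of grade j,

\[ r_j = \frac{\sum_{i<j} N_i + N_j/2}{N}, \]

is the probability that a random observation from the reference
distribution falls below grade j, counting half of grade j itself; the
count-weighted mean ridit is exactly 0.5. The mean ridit of the
reference-read group, \(\bar R_1 = \sum_j n_{1j} r_j / n_1\), estimates
the probability that a reference read sits in a higher grade than a random
read. Because `N r_j + 0.5` is precisely the midrank of grade j, the
two-group comparison of mean ridits is algebraically a Wilcoxon rank-sum
test on heavily tied data, and the package computes it in that form:

\[ W_1 = \sum_j n_{1j} (N r_j + 0.5), \quad
   \mathrm{E}[W_1] = \frac{n_1 (N+1)}{2}, \]
\[ \mathrm{Var}(W_1) = \frac{n_1 n_2}{12}\left[(N+1) -
   \frac{\sum_j (N_j^3 - N_j)}{N (N-1)}\right], \qquad
   z = \frac{W_1 - \mathrm{E}[W_1]}{\sqrt{\mathrm{Var}(W_1)}}, \]

with a two-sided p from the standard normal. The tie correction is
essential here: with only k grade categories virtually every observation
is tied, which shrinks the true rank variance by roughly the factor
`1 - sum(N_j^3 - N_j) / (N^3 - N)`; omitting the correction (as in the
classical no-ties approximation, available via `variance = "bross"`)
understates the evidence accordingly. The test-suite
property checks assert exact (1e-12) agreement between this closed form
and a brute-force expansion of the table into N ranked observations, and
agreement with `stats::wilcox.test(correct = FALSE)`.

Conventions for degenerate tables are fixed rather than erroring
mid-genome: an empty allele group, or all mass in a single grade (zero
rank variance), yields z = 0 and p = 1 with a `degenerate` flag. p-values
are floored at the smallest positive double before `-ln(p)` so the track
is always finite. Swapping the two allele rows negates z and leaves p
unchanged; the reported sign convention is that group 1 is the
reference-allele reads.

Two comparator statistics are available through the same interface:
a tie-corrected Kruskal–Wallis H (grades as groups, allele as a binary
response; for k = 2 the identity \(H = z^2\) with the ridit z holds
exactly) and a Pearson chi-square on the 2 x k table (no continuity
correction, zero-depth grades dropped with df reduced). The chi-square
ignores grade ordering, which is exactly why the ordinal tests outperform
it on monotone allele-frequency gradients.

**Reads as independent observations.** The test treats every read as an
independent draw. In reality reads within a pool share the finite set of
pooled individuals, so pooled allele frequencies carry an extra
between-bulk variance component of roughly \(S^2 / (4 n_b)\) (dosage
variance \(S^2 = 0.5\) in an F2, bulk size \(n_b\)) on top of the
read-sampling variance \(f(1-f)/D\). At 300 individuals per bulk and
about 210x pool depth this inflates the z variance by a factor around
1.5, i.e. the per-SNP test is anti-conservative under the full pooling
process even though it is exactly calibrated against read-level binomial
noise (both facts are asserted in the test suite, the former as an
expected failure of the read-only calibration band). The default keeps
the uncorrected statistic — the genome scan's ratio statistic absorbs a
uniform inflation, since it compares windows against each other — and an
optional effective-count scaling (`effective_size = c`, counts multiplied
by c ≤ 1) is available when calibrated per-SNP p-values are wanted; in
the conditions above c ≈ 0.6 restores the nominal 5% rate.

## Noise reduction and interval calling

A single small p-value does not localise a QTL: distant crosses produce
abundant spurious SNP calls, and isolated significant SNPs are scattered
genome-wide. The noise-reduction scheme scores non-overlapping windows
(default 400 kb, tiling each chromosome from coordinate 0, half-open
0-based internally; SNP at 1-based position p belongs to window
`floor((p-1)/window_bp)`) by the *fraction* of their SNPs with p below a
threshold `alpha`. Windows with fewer than 10 SNPs are skipped — too few
SNPs to estimate a fraction. True QTL regions show *clusters* of
significant SNPs, so their windows approach ratio 1 while background
windows stay near the per-SNP false-positive rate.

`alpha` defaults to 0.001. Nothing in the scan depends delicately on it —
any monotone transformation of the p-values that preserves the alpha cut
leaves the ratio track unchanged (a tested invariant) — but it sets the
background level and is therefore exposed prominently.

Interval calling ranks unskipped windows by ratio, breaking ties by
significant-SNP count and then genome order, selects windows by rank
(`top_n`) and/or ratio floor (`min_ratio`), and by default merges
adjacent selected windows into one interval carrying the peak ratio.
Merging matters under strong signal: a QTL of half a phenotypic SD
sequenced at 200x spreads p < 0.001 SNPs over several megabases of linked
sequence, so single-window ratios saturate at 1.0 across the peak and the
argmax window alone is arbitrary within the plateau. The merged interval
is the honest statement of what the scan resolves. Single-window calls
are exactly `window_bp` wide by construction — the scheme's resolution is
structural, not empirical.

## The F2 simulator

`simulate_f2()` and friends emulate the full experiment for power and
false-positive studies:

- **Meiosis** — per chromosome and gamete, crossover count
  ~ Poisson(map length in Morgans), breakpoints uniform, no interference
  (Haldane). The map is uniform at `cM_per_Mb` (default 4) — adequate for
  a power harness; real genomes modulate recombination locally.
- **Genome** — rice-like defaults: 12 chromosomes x 30 Mb, 2,000 evenly
  spaced SNPs per chromosome (one per 15 kb, so a 400-kb window holds
  about 26 SNPs, comfortably above the 10-SNP skip rule).
- **Phenotype** — `y = sum_q [a_q (dosage_q - 1) + d_q 1(dosage_q = 1)]
  + N(0, env_sd^2)`. The helper `effect_for_sd_fraction()` converts "an
  additive effect of x phenotypic SDs" into trait units; the default QTL
  is additive at 0.5 phenotypic SD.
- **Grading** — rank and split by `bulk_fractions` (default three equal
  thirds, mirroring the published three-pool design where the largest
  pool held 33.56% of 1,046 plants), or by explicit phenotype cut points.
  Misclassification swaps `floor(m n_b)` random members of a target bulk
  with uniformly chosen outsiders — a symmetric mechanism chosen because
  only the rate ("20% wrong classification in a certain bulk") is
  specified by the experiment being emulated.
- **Reads** — pool depth ~ Poisson(bulk size x per-individual coverage;
  default 0.7x per individual, within the recommended 0.5–1x), allele
  reads binomial at the bulk's true frequency perturbed by a symmetric
  sequencing error (default 0.001, a post-filtering Illumina-like
  substitution rate). Equal DNA mass per individual is assumed.

All randomness derives from one seed fanned out to named substreams
(meiosis, grading, read sampling), so the same configuration and seed
give bit-identical variant tables while components stay independently
reproducible.

What the simulator does *not* model: SNP-calling artefacts, mapping bias,
unequal DNA contributions, segregation distortion, linked or epistatic
QTLs beyond those listed, and crossover interference. Passing power
checks on simulated data therefore demonstrate the statistical machinery
under the stated sampling model, not performance on any particular real
cross.

## The acceptance experiments and their sizes

The test suite runs four simulation experiments, sized to be decisive yet
quick on a single CPU:

- **Null calibration**: one no-QTL genome (12 chr x 2,000 SNPs, 3 bulks
  of 300, 0.7x/individual). Expected per-SNP behaviour is discussed
  above; the scan-level check is that no interval reaches ratio 0.5.
- **Localization**: 100 replicates of the default single-QTL
  configuration; the rank-1 interval (windows with ratio ≥ 0.5, adjacent
  windows merged) must cover the QTL within ±1 window in at least 80% of
  replicates.
- **Monotonicity**: power compared across coverage 0.25x vs 1x, pool
  size 100 vs 300, bulk count 2 vs 3, and misclassification 0 vs 0.2, on
  a two-chromosome genome with 100 common-random-number replicates per
  level. The bulk-count and misclassification axes run at 0.4x
  per-individual coverage: at 0.7x both levels sit at the power ceiling
  and the comparison would be a degenerate equality; 0.4x places the base
  condition on the steep part of the power curve. This choice was made
  from a pilot run and then frozen.
- **Conservation**: window SNP totals must equal the tested-SNP count and
  ratios stay in [0, 1], on a two-chromosome scan.

The mid-distribution of the ridit p-values under the null is visibly
discrete (the midrank z on k = 3 categories takes a lumpy set of values),
so uniformity is asserted at the tail thresholds the scan actually uses
rather than with a whole-range Kolmogorov–Smirnov statistic.

## Heterosis arithmetic

For a near-isogenic line (NIL) carrying one introgressed locus, the
heterosis contribution rate

\[ \mathrm{rate} = \frac{Y_{\mathrm{NIL}} - Y_{\mathrm{parent}}}
                        {Y_{\mathrm{F1}} - Y_{\mathrm{parent}}} \]

measures the share of the hybrid–parent gap the locus recovers. It is
invariant to shifting or rescaling all three means. Applied to the
grain-yield summaries shipped in the examples (parent 42.644 g, NIL
46.615 g, hybrid 56.878 g per plant) the rate is 27.90%, which the
package reports as 27.9% at one decimal; published figures derived from
unrounded raw data can differ in the last digit, so
`contribution_rate()` also reports the rate recomputed from means rounded
to one decimal. `pairwise_differences()` reproduces comparison tables
from per-line summaries alone: pooled MSE across all groups, difference
SEs under the one-way layout, and optionally an approximate Tukey HSD
p-value from the studentized range (flagged approximate because it is
computed from summaries with unequal n). Percentages are rounded half
away from zero, matching how such tables are conventionally printed.

## Known limitations

- Per-SNP p-values are anti-conservative under pooled sampling unless
  `effective_size` is used (see above); interval ranking is unaffected.
- The ridit/rank-sum orientation assumes a monotone allele-frequency
  gradient; overdominant loci, whose heterozygotes differ from both
  homozygotes, produce weak gradients and low power by construction.
- The normal approximation of the rank-sum is excellent at sequencing
  depths (hundreds of reads) but mildly anti-conservative for tiny
  tables (N below ~60), where the permutation comparison in the test
  suite quantifies the gap.
- Interval width under strong signal reflects linkage disequilibrium,
  not method resolution; reported merged intervals can span many
  windows.
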