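---
title: "Models and methods for sweetness meta-genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for sweetness meta-genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweetqtl)
```

sweetqtl connects four layers of the genetic analysis of a quantitative
fruit trait such as melon sweetness (total soluble solids, °Brix): hybrid
mode-of-inheritance statistics on half-diallel panels, bulk-segregant
QTL-seq scans on inbred-line tails, marker-level QTL quantification, and
cross-study QTL integration. This vignette is the package's account of the
underlying models, the tunable parameters and their defaults, what the
simulators do and do not emulate, and the numerical choices made where the
methods literature leaves room.

## Mode of inheritance in a half-diallel

A half-diallel crosses `p` inbred parents in all unordered combinations
(no reciprocals), giving `choose(p, 2)` F1 hybrids; with 20 parents, 190
hybrids. For each *hybrid group* — an F1 with its two parents — the package
computes, on genotype means:

* mid-parent `m = (P1 + P2) / 2`;
* additive effect `a = |P1 − P2| / 2`, defined non-negative so that the
  high parent fixes the orientation;
* dominance effect `d = F1 − m`, signed positive toward the high parent;
* degree of dominance `d / a`, undefined (`NA`) when `a = 0`; `|d/a| > 1`
  is over- or under-dominance.

The sign convention for `d` is a genuine choice: plots of dominance
deviations "toward the high parent" versus "toward the low parent" only
reproduce if `d` is oriented by the high parent, so that is the package's
convention, and swapping the parent labels of a group changes neither `a`
nor `d`. `dominance_distribution()` restricts to differential groups
(`a > a_min`, default 2 °Brix — with near-equal parents, `d/a` explodes and
`d` is mostly noise) and reports a one-sample t-test of mean `d` against
zero. `build_diallel_matrix()` orders both axes of the genotype-mean matrix
by general combining ability, a parent's mean over its 19 crosses, so the
additive structure appears as a monotone color gradient in `autoplot()`.

Broad-sense heritability is estimated per experiment from the one-way
random-effects ANOVA on plot values:

$$\hat\sigma^2_G = \frac{MS_{genotype} - MS_{error}}{\bar r}, \qquad
  \hat H^2 = \frac{\hat\sigma^2_G}{\hat\sigma^2_G + MS_{error}},$$

with $\bar r$ the harmonic mean of per-genotype replicate numbers — the
standard plug-in that stays nearly unbiased under unbalance. Negative
$\hat\sigma^2_G$ is clamped to zero and flagged (`clamped = TRUE`) rather
than silently hidden. The denominator is the *plot-level* phenotypic
variance; an experiment with $\sigma^2_G = \sigma^2_E = 1$ therefore has
$H^2 = 0.5$, not the genotype-mean repeatability $1/(1 + 1/r)$. Whether
single plants or plot means enter the ANOVA is an upstream choice; the
package assumes its input records are the experimental units (plot means).
All cross-trait correlations (`trait_correlation()`) are computed on
genotype means within experiment, because plot-level correlations mix
genetic and residual covariance.

## The QTL-seq scan

For each polymorphic site, within each bulk, the SNP-index is the fraction
of reads carrying the reference allele, and `Δ = idx_high − idx_low`.
Away from trait loci both tails sample the same allele frequencies and
`E[Δ] = 0`; at a QTL with complete tail separation `|Δ| → 1`.

Parameters, defaults, and why:

* `min_depth = 20` (reads): sites must exceed this **in each bulk**. A
  "total depth > 20" rule could also be read as the summed depth; the
  per-bulk reading is stricter and avoids sites where one bulk is
  essentially unobserved.
* `window_size = 1e6` bp, `step = 1e5` bp: at ~30× and realistic SNP
  densities, 1 Mb windows average enough sites to suppress binomial read
  noise while following the linkage-scale signal; the 100 kb step gives a
  smooth trend line. Both are configurable.
* `threshold = 0.4` on the **windowed** |Δ|: the conventional fixed cutoff
  for tail-bulk designs. The raw site-level Δ is far too noisy at 30× for
  a fixed cutoff, so the trend line is what is thresholded.
* `merge_gap = 2` windows: same-sign threshold excursions separated by at
  most two sub-threshold windows are one region, absorbing single-window
  dropouts.
* Region sign is kept (`"high"`/`"low"`): a negative-Δ region means the
  low-trait parent donates the trait-increasing allele, a configuration
  that real populations do produce, so negative excursions are regions,
  not artifacts.
* Peak = window of maximal |Δ|, leftmost on ties; region bounds are the
  outermost window bounds tightened to the covered sites; coordinates are
  1-based inclusive in all tables, windows half-open internally.

A practical caveat that the simulation makes quantitative: with bulks of
~30 lines drawn from ~200, the windowed null Δ has standard deviation
around 0.13 — not from read depth (which window-averaging suppresses) but
from *which lines* enter each bulk, a sampling layer shared by all linked
sites. The 0.4 cutoff is therefore only about 3σ, and occasional coherent
false excursions over it are expected in a genome-wide scan; they shrink
with larger bulks, not with more sites or depth. Confidence envelopes for
Δ are deliberately out of scope; the fixed cutoff is the method being
provided.

## Marker-level QTL quantification

`marker_scan()` tests each marker by one-way ANOVA of line means between
the two homozygote classes. Heterozygous and missing lines are excluded by
default — in F5/F6 material residual heterozygotes are few (3.1% expected
at F6) and their inclusion as a third class mostly costs degrees of
freedom; the class tables make the exclusion visible. The genome-wide
threshold at level α is the α-quantile of the per-permutation *minimum*
p-value across markers (phenotypes permuted over lines), the standard
family-wise construction; with `n_perm = 1000` the smallest attainable
permutation p-value is 1/1001. Benjamini–Hochberg q-values are reported
alongside, monotone in the raw p-values.

`allelic_effect()` reports `effect = mean(A) − mean(B)` (sign = donor of
the increasing allele), `PVE = 100·SS_between/SS_total`, and the ANOVA p;
on extreme-tail material both effect and PVE are inflated by construction,
which is a property of the design, not the estimator. `pair_interaction()`
fits the two-way ANOVA with interaction on the four double-homozygote
classes and labels class means with a Tukey HSD compact letter display at
α = 0.05 (via multcomp), the usual all-pairs display; the reported
interaction estimate is the sum-to-zero cell contrast
`(m_AA + m_BB − m_AB − m_BA)/4`. An empty class yields a flagged
missing-class result rather than a silent drop. `stack_analysis()` groups
fully homozygous lines by their favorable-allele count; the headline
contrast is full-stack minus null-stack, absolute and as percent of the
null-stack mean. `expected_vs_observed()` regresses observed pair effects
(double-favorable minus double-unfavorable class means — the same scale on
which expected = sum of singles lives) on expected ones and tests
slope = 1; a slope below 1 is the signature of general less-than-additive
epistasis.

## Pan-QTLome binning

`bin_counts()` tiles each chromosome with fixed 5 Mb bins (terminal bins
truncated), drops intervals longer than 15 Mb (length `end − start + 1`;
such intervals would blanket several bins with little positional
information), and assigns each remaining QTL to every bin its interval
overlaps. "Falls within" is ambiguous for intervals straddling a bin
boundary, so a `midpoint` mode (exactly one bin per QTL) is provided; the
two rules genuinely differ in hotspot counts and the choice is surfaced as
a parameter rather than hidden. Per-bin support counts *distinct studies*,
not QTL records — a study with two QTLs in one bin supports it once —
and `classify_bins()` calls a bin a hotspot at support ≥ 6 by default.
Point associations (e.g. GWAS markers without intervals) are representable
as 1 bp intervals and behave correctly under both assignment rules.

## What the simulators emulate

`simulate_diallel()` draws plot values around genetic values composed of
fixed parental values and per-pair dominance deviations, with i.i.d.
Gaussian plot noise — years are exchangeable replicates (no genotype ×
year interaction, no spatial field structure).

`simulate_biparental()` builds single-seed-descent lines: every line
starts as an F1 and is selfed `generation − 1` times, each meiosis placing
one uniformly positioned crossover per chromosome (a map-distance proxy
that needs no genetic map; analyses here depend on allele-frequency
contrasts, not map accuracy). Residual heterozygosity halves per
generation, `(1/2)^(g−1)`. One artifact of the obligate single crossover
is worth knowing: loci separated by more than half a chromosome recombine
at more than 50% per meiosis, so weak *repulsion* can appear between a
selected QTL and the far end of its chromosome; it does not affect
unlinked chromosomes. Phenotypes are `baseline + Σ signed QTL effects +
noise`, where a QTL's `effect` is the difference between its homozygote
class means. The noise variance is set from the **realized** genetic
variance of the simulated lines so the target plot-level `h2` is met in
each draw exactly, rather than only in expectation across draws.

`simulate_bulk_reads()` pools the selected tail lines equimolarly (the
pooling model is not observable from read data; equimolar is the neutral
assumption), computes the bulk reference-allele frequency as the mean
dosage (hom 1, het 0.5; missing calls leave the denominator), then draws
`depth ~ Poisson(mean)` and `ref reads ~ Binomial(depth, freq)` per site
and bulk. `simulate_qtl_studies()` emits, per study and hotspot bin, an
interval with the stated probability — centered at the bin midpoint with a
drawn length, so deterministic-regime hotspot recovery is exact — plus
Poisson background QTLs placed uniformly.

Not emulated, by design: sequence-level reads (FASTQ), genotyping error,
multi-allelic sites, selection during SSD, segregation distortion, and
genotype × environment structure. Passing tests on this generator
therefore certify the statistical machinery — index arithmetic, windowing,
calling, ANOVA decompositions, binning — under clean sampling assumptions;
they do not certify robustness to alignment artifacts or allele-specific
sequencing bias in real data.

All generators take an explicit `seed` and restore the caller's RNG state:
there is no hidden global randomness, and equal seeds give byte-identical
outputs.

## Problem sizes and numerical conventions

The package's end-to-end checks run the QTL-seq pipeline at the design
scale of a typical tail-sequencing experiment — 200 F6 lines, 30 + 30
tails, 10,000 polymorphic sites at 30×, over 100 seeded replicates — and
the diallel machinery at 20 parents × 3 years × 3 replicates; these sizes
exercise every code path at realistic dimensions while keeping a full run
in the minutes range. Exact-equality checks (variance components, BH
q-values, window means, two-way sums of squares, bin summaries) compare
against independent brute-force enumerations on small instances at 1e-9 or
tighter.

Conventions worth restating: ties in tail selection and in scan peaks
break deterministically (lexical line id; leftmost window); degenerate
inputs error early with the reason (`a = 0` gives `NA` degree, not an
error; zero phenotypic variance, empty bulks, monomorphic markers do
error); negative variance components clamp to zero with a flag; and the
"reference" allele in all bulk tables is the parent-A (high-parent) allele
unless the VCF metadata says otherwise.

## Limitations

Heritability uses the ANOVA moment estimator, not REML, and a full
Griffing GCA/SCA decomposition is out of scope. The scan offers no
confidence intervals on Δ. Interval mapping, kinship-corrected association
models, and linkage-map estimation are deliberately not provided — the
package quantifies and integrates QTLs found by contrast-based designs
rather than re-implementing mapping frameworks.
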