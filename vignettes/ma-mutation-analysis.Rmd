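---
title: "Estimating mutation rates and spectra from mutation-accumulation lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mutation rates and spectra from mutation-accumulation lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mamutspec)
library(dplyr)
```

## The problem

Mutation-accumulation (MA) experiments propagate replicate lines through
extreme population bottlenecks so that selection is nearly powerless and new
mutations fix essentially at the rate they arise. Sequencing the descendant
lines against their ancestor then gives a direct view of the spontaneous
mutational process. `mamutspec` implements the analysis stack for such an
experiment in a mismatch-repair-impaired, obligately outcrossing
*Caenorhabditis elegans* setting: cross-line verification of candidate
variant calls, repeat and sequence-complexity annotation, partitioned
mutation-rate and spectrum estimation, heteroplasmy-weighted mitochondrial
rates, and a penalized logistic model of site mutability. A synthetic-data
module simulates whole experiments with known ground truth, so every stage
is testable without touching the original sequencing data.

## Rate model

All rates are per site per generation. For line $i$,

$$\mu_i = \frac{F_i}{G_i \, B},$$

where $F_i$ is the number of accepted mutations in the queried partition,
$G_i$ that line's realised MA generations (a first-class input, since lines
rarely share an identical generation count), and $B$ the callable bases of
the genome or genomic subdivision. Experiment-level rates average the
line-specific rates, $\bar\mu = \tfrac1n \sum_i \mu_i$, and 95% confidence
intervals use the $t$ distribution over lines. Pooled statistics always
weight by line; `line_rates()` fills explicit zero counts so that
zero-mutation lines enter every average.

## Variant acceptance

Candidate calls carry their read support: $K$ reads calling the variant out
of $N$ quality reads at the position. Acceptance is two-staged.

**Hard thresholds** (`apply_hard_filters()`): RMS mapping quality $\ge 30$
(SNPs) or $\ge 40$ (indels); $K \ge 3$ (SNPs) or $\ge 5$ (indels);
$K/N \ge 0.80$; at least two independent callers; and no supporting read in
the ancestral control at the same position and allele — ancestral presence,
however weak, removes the candidate. Each rejection is logged under the
first failing rule.

**Cross-line binomial verification** (`consensus_filter()`): for each
surviving position the per-read chance of calling the variant by noise is
estimated across *all* sequenced lines, carriers included,

$$P = \frac{\sum_{\text{lines}} K}{\sum_{\text{lines}} N},$$

and each carrier call is scored with the binomial point mass
$\binom{N}{K} P^K (1-P)^{N-K}$, evaluated in log space so depths up to
$10^5$ are safe. A Holm–Bonferroni step-down over all candidate variants
(experiment-wide, $\alpha = 0.05$ by default) decides retention:
a *significant* probability means the observed support is inconsistent with
noise shared across lines, so the variant is kept. Three choices here were
genuinely open and are worth stating:

* The verification statistic is implemented as the point mass, which is the
  natural reading of the formula-based procedure; a conventional upper-tail
  $P(X \ge K)$ is available via `upper_tail = TRUE` and the mode is flagged
  in the output. For fixed variants ($K \approx N$) at realistic error
  rates the two are practically indistinguishable.
* Retention polarity: "significant after correction" *retains* the
  variant. The test exists to rule out shared sequencing or alignment
  error; a systematic artifact receives roughly its noise share of reads in
  every line, yielding a large point probability and removal, while a real
  fixed variant in one line is wildly improbable under the pooled noise
  rate.
* The correction is applied experiment-wide (all lines jointly), which is
  the stricter reading; a per-line mode would only relax the threshold.
* $\alpha$ is configurable because no canonical value exists for this
  procedure; 0.05 is the default.

Positions where $P$ is undefined (no coverage in any line) go to a
quarantine table rather than being silently dropped.

## Repeats and sequence complexity

The repeat catalog (`detect_repeats()`) holds maximal perfect tandem runs:
homopolymers of at least 6 bp, di- and tri-nucleotide repeats of at least 4
copies, and tetra- to hexa-nucleotide repeats of at least 3 copies. A run is
attributed to its smallest period (poly-A is never an (AA)$_n$ repeat), the
motif is canonicalised to its smallest rotation, and an interruption — a
mismatch or an N — splits a candidate into independently judged perfect
sub-runs. A trailing partial unit is not part of the catalogued interval.
Variants associate with the catalog by overlap of their affected bases
(`map_variant_to_repeat()`): `in_repeat`, `adjacent` within a configurable
flank (default 1 bp, since no numeric adjacency rule is canonical), or
`complex` otherwise, with ties resolved toward the longest run.

Sequence complexity of a window $a$ of length $n$ counts the $l = n-2$
overlapping triplets, $c_t(a)$ occurrences of triplet $t$, and scores

$$S(a) = \sum_t \frac{c_t (c_t - 1)}{2(l-1)}.$$

Note the polarity: $S$ counts *pairs of identical triplets*, so it is 0
exactly when all triplets are distinct and is maximised by homopolymers —
larger $S$ means more repetitive sequence, yet the field's phrasing is that
repetitive DNA has "lower complexity". Reports therefore also expose the
normalised complement $1 - \sum_t c_t(c_t-1) / (l(l-1))$, which decreases
with repetitiveness, so directional statements can be tested either way;
raw $S$ is always retained. Windows are 41 bp centred on the site (20 bp
each flank), truncated at contig edges, flagged instead of scored below
21 bp or when containing N.

## Spectrum and partitions

Substitutions collapse over strand into six classes (`A/T->G/C`,
`A/T->T/A`, `A/T->C/G`, `G/C->A/T`, `G/C->T/A`, `G/C->C/G`); the first and
fourth are the transitions. Trinucleotide contexts collapse a triplet and
its reverse complement onto one of 32 keys, written `AAT/ATT`-style.
Coding effects come from codon translation against the gene models;
exonic indels are frameshifts unless their length is a multiple of 3.
Synonymous/nonsynonymous site counts use Nei–Gojobori-style fractional
counting (each codon position contributes the fraction of its three
possible changes that preserve the amino acid); the method is isolated
behind `synonymous_site_counts()` so it can be swapped, since no single
convention is universal.

The composition-normalised AT bias divides the AT-ward and GC-ward counts
by the genomic fraction of G:C and A:T sites respectively before forming
the fraction; with uniform composition it reduces exactly to the raw count
fraction. The genomic G+C fraction used for normalisation is a parameter
(genome-wide by default) because callable-site and genome-wide composition
differ slightly.

Indels are assigned to partitions by their left-aligned VCF-style anchor
base; an indel spanning a boundary follows its anchor. Homopolymer and
dinucleotide indel dynamics normalise event counts per catalogued run:
$\text{rate} = \text{events} / (n_{\text{runs}} \times \sum_i G_i)$, i.e.
events per run per generation, with run-length-resolved tables for
homopolymers and family-resolved tables (`AT/TA`, `AC/GT`, `AG/CT`,
`CG/GC`) for dinucleotides.

Mitochondrial variants are typically heteroplasmic, so each contributes its
intracellular frequency $f$ (fraction of quality reads) rather than a unit
count: line rates are $\sum_v f_v / (L_{mt} G_i)$ and the experiment rate
averages over *all* lines, including the zero-mutation ones. $L_{mt}$
defaults to 13,794 bp (the *C. elegans* mitochondrial genome) and should be
overridden with a callable-site count when one is available — the printed
rate depends directly on this denominator.

## Site mutability

`fit_penalized_logistic()` regresses mutation presence (1 for an observed
substitution site, 0 for a uniformly drawn non-mutated callable site) on
chromosome, functional class, collapsed trinucleotide context,
recombination rate, 41-bp G+C and complexity, germline expression, repeat
membership, chromatin state and A/T-cluster membership, with categorical
predictors expanded one-hot. The elastic-net mixing parameter defaults to
$\alpha = 0.01$ (near ridge, shrinking correlated predictors together) and
$\lambda$ is chosen by 10-fold cross-validated deviance minimisation unless
fixed; the historical value $6.83 \times 10^{-5}$ is a sensible fixed
default at $10^5$-site scale but is dataset-specific, which is why
re-selection is the default on new data. The large class imbalance of the
training set is deliberately *not* reweighted: predicted probabilities are
meaningful relative to the training prevalence, and the analysis only ever
uses relative mutability. Odds ratios are $e^c$ per coefficient.
`bin_rates()` calibrates predictions against realised mutation rates in
bins of width 0.015 over $[0, 0.12)$ — eight bins — and reports the Pearson
regression of bin rate on bin midpoint.

## The synthetic-data generator

The generator is the package's test bed and defines the study conditions it
emulates: 19–20 lines, a nominal 50-generation design with realised
per-line generations near 40, 30x read depth, and a mutational spectrum
whose defaults follow the study's observed structure — a total substitution
rate of $4.22 \times 10^{-8}$/site/generation split across the six classes
in the observed proportions (pooled Ts/Tv $\approx 1.12$), deletion and
insertion rates of $1.47 \times 10^{-7}$ and $7.59 \times 10^{-8}$ (about
2:1), homopolymer indel multipliers peaking at 11 bp for A/T runs and 8 bp
for G/C runs, and dinucleotide families with an insertion bias in `AT/TA`
and deletions only in `CG/GC`. Where the emulated study fixes no number we
chose once: background G+C 0.36 (the *C. elegans* value), tip/arm/core
domain proportions 10/30/60% per chromosome, gene density 120/Mb with
four 150-bp exons per gene, and a 0.98 per-caller detection probability.
The split of the total indel rate into a background per-site component and
per-run homopolymer components is the package's own decomposition; the
per-run rates are configured directly because that is the scale on which
run-length dependence acts.

Mutations are planted as fixed homozygous events (matching the post-MA
inbreeding step; heterozygosity is out of scope), with at most one hit per
site per line — the generator warns when configured rates strain that
approximation. Read evidence gives every candidate site, in every line,
$N \sim \text{Poisson}(\text{depth})$ and
$K \sim \text{Binomial}(N, 1-e)$ for carriers or
$\text{Binomial}(N, e)$ otherwise. Noise sites model *systematic*
artifacts: the same spurious allele draws error-level support in every line
and in the ancestral control, which is precisely the signature the
cross-line verification removes. The ancestral control carries no support
at true-variant sites beyond this model — random isolated ancestor errors
are not emitted as calls, mirroring the fact that real callers do not call
a variant from one or two stray reads. A single global seed drives
hierarchical per-line and per-stage streams, so any subset of a simulation
is reproducible in isolation.

What the generator does *not* emulate — alignment artifacts with spatial
structure, coverage dips, GC-dependent depth, segregating heterozygosity,
multi-allelic sites — bounds what passing tests show about real data: they
establish estimator correctness and calibration under the stated model,
not robustness to every upstream failure mode of sequencing.

## Numerical and design notes

* Coordinates are 1-based closed throughout, the Bioconductor convention;
  interval work happens in `IRanges`/`GenomicRanges` and VCF-style anchored
  alleles are used for indels.
* Overlapping gene annotations resolve exon-over-intron; a site in any exon
  is exonic.
* X and mitochondrial chromosomes are recognised by configurable name
  lists (defaults `"X"` and `"MtDNA"`).
* The binomial mass is computed via `lchoose` in log space, with the
  $P \in \{0, 1\}$ boundaries handled exactly; agreement with the direct
  product is at the $10^{-12}$ level for $N \le 30$.
* The Holm–Bonferroni step-down uses the strict inequality
  $p_{(i)} < \alpha/(m-i+1)$ and stops at the first failure; ties keep
  stable input order.
* Genes whose concatenated exons are not a multiple of 3 are excluded from
  coding-effect calls with a warning rather than guessed at.
* Degenerate inputs (no transversions, zero-base partitions, empty bins,
  undefined $P$) return flagged `NA`s or quarantined rows, never silent
  drops.

## Problem sizes used in the shipped checks

The package's own verification runs on a 1 Mb four-chromosome genome with
20 lines at $G = 40$ and per-site rates 100x the study's values, which
yields a few thousand substitutions and indels — enough for 3-standard-error
recovery checks on every substitution class, the planted Ts/Tv, the 2:1
deletion bias and the 11-bp homopolymer rate peak, while keeping a full
simulate–filter–classify–estimate cycle under a minute on one CPU. Filter
calibration uses at least $10^4$ systematic noise sites at $e = 0.01$ and
30x depth; the mutability recovery uses $10^5$ training sites. These sizes
are choices about statistical resolution: scaling rates rather than genome
length keeps per-line counts at the study's order of magnitude.

## Known limitations

* The repeat catalog is perfect-run only (plus the split rule); imperfect
  repeats are represented solely by their qualifying sub-runs, and a
  variant inside an imperfection's spacer bases counts as repeat-adjacent
  at best, not in-repeat.
* Read alignment, the variant callers themselves, copy-number detection
  and rDNA copy-number estimation are out of scope; caller behaviour is
  modelled only through call records and a caller-count field.
* The mutability model is genome-wide; no per-chromosome models are fit.
* `S` is undefined on windows with N; such sites are excluded from the
  feature matrix rather than imputed.

## A short tour

```{r tour, eval = FALSE}
sim <- simulate_experiment(
  experiment = experiment_config(n_lines = 19, generations = 40, seed = 1))
run <- run_acceptance_pipeline(sim)
lines <- sim$experiment$lines
B <- callable_bases(sim$genome)

snps <- dplyr::filter(run$records, variant_type == "snp")
rate_summary(line_rates(snps, lines, B))
tstv_ratio(snps)
plot_spectrum(snps)

hp <- homopolymer_indel_rates(run$records, sim$catalog, lines)
plot_homopolymer_rates(hp)

tr <- build_training_set(sim$genome, snps, n_random = 1e5, seed = 2,
                         catalog = sim$catalog)
m <- fit_penalized_logistic(tr)
tidy(m)
```
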