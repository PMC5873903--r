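---
title: "Combinatorial pooling, decoding, and downstream statistics in tnpool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial pooling, decoding, and downstream statistics in tnpool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnpool)
```

# The problem

An arrayed transposon insertion library stores one bacterial mutant per well
of a stack of 96-well plates. Sequencing each well individually is
prohibitive, so the library is mapped by *combinatorial pooling*: each well
is assigned a 24-bit binary codeword and its culture is pipetted into
exactly the sequencing pools whose bit is 1. After one sequencing run of the
24 pools, the set of pools in which an insertion site appears spells out its
codeword, and hence its well. `tnpool` implements this design and decoding,
plus the downstream statistics used to interpret such a library: gene-level
saturation and rarefaction, pathway-level essentiality prediction among
genes with no insertions, per-gene-family mixed-model association between
gene presence/absence and host colonization load, and a mutant-vs-control
load comparison. A synthetic-data generator produces every input with known
ground truth, which is how the package tests itself.

# The pooling code

Codewords are constant-weight binary words of length 24 with Hamming weight
10, 12, or 14. The even spacing of the weights is what buys error
detection: a single pool failure (or a single spurious pool) changes the
weight by one, producing an odd weight that is never assigned, so
single-pool errors are always *detected* (not corrected — matching is exact
and unmatched barcodes are discarded, mirroring the conservative behaviour
appropriate for a physical library).

**How codewords are chosen.** The weight classes hold
$\binom{24}{10}+\binom{24}{12}+\binom{24}{14} = 6{,}626{,}668$ codewords
(`capacity()`), far more than any practical library, so the constructor
must pick a subset. We draw codewords by seeded uniform sampling of
colexicographic ranks within each weight class (a combinadic unranking maps
rank to codeword), interleaving the classes round-robin. This was a
deliberate choice over sequential colexicographic enumeration: sequential
enumeration concentrates the first few thousand codewords on the
low-numbered pools, so the bitwise union of two such codewords — which is
exactly the pooled signature of sister clones occupying two wells — very
often coincides with another *assigned* codeword, silently implicating an
innocent well. Uniformly spread codewords make such union collisions rare
(order $10^{-3}$ per sister pair at full library scale). The construction
is deterministic given the seed.

Two optional greedy filters tighten the code further: `subset_free = TRUE`
rejects codewords bitwise comparable to an already-assigned one (so a
double dropout from a weight-12 word can never silently land on an assigned
weight-10 word), and `min_distance` enforces a minimum pairwise Hamming
distance. Both are off by default because exact matching with weight
classification already detects the error modes the decoder models; the
filters are available for users who want rescue-decoding headroom.

**Pooling logistics.** `batch_plan()` reproduces the two-stage bench
protocol: plates are pooled five at a time into intermediate sets of 24
tubes, and intermediate tubes sharing a pool position are merged into the
final 24 pools. The plan's execution provably reconstructs each well's
codeword (tested by simulating the plan).

# Decoding

For each insertion site the 24 per-pool read counts are thresholded into a
presence barcode. The published rule is a 50-read cutoff with typical
positive depths above 200; the boundary case (exactly 50 reads) is not
specified, and we adopt `>= threshold` as presence. Each barcode is then
classified by weight:

| weight | status | interpretation |
|---|---|---|
| 10, 12, 14 | candidate → `MAPPED`/`UNMATCHED` | exact design match decides |
| 1–2 | `SEQUENCING_ERROR` | spurious signal |
| 0, 3–9, 11, 13 | `LOW_COVERAGE` | dropout from a valid word |
| > 14 | `SISTER_CLONE_SUSPECT` | merged signal of identical clones in several wells |

Weight-0 barcodes are classed as low coverage rather than sequencing error:
they are absence of signal, not spurious signal. If two different sites
decode to the same well, both are demoted to `UNMATCHED` with a warning —
a physical well holds one clone, so neither claim can be trusted.
No nearest-codeword rescue is attempted by default.

# Synthetic data: what it emulates and what it does not

The generators realize the statistical structure of the study conditions
with known ground truth:

* `gen_annotation()` — non-overlapping gene intervals (uniform lengths
  300–1500 bp, roughly prokaryotic scale) with pathway labels sampled
  without replacement per pathway.
* `gen_library()` — one insertion per mutant, never inside a designated
  essential gene, intergenic with probability 0.134 (the fraction implied
  by the published library: 859 intergenic of 6,418 mapped), sister clones
  duplicated into distinct wells at rate 0.05, wells filled plate-by-plate.
* `gen_pool_reads()` — positive pools draw Negative-Binomial reads with
  mean 200 (the published "most sites had more than 200 reads") and
  dispersion 0.3 (variance $\mu + 0.3\mu^2$; pooled sequencing is
  overdispersed), independently zeroed with dropout probability 0.02;
  absent pools receive Poisson(0.5) index-bleed noise, always far below
  threshold in expectation; sister-clone sites receive the summed counts of
  their wells' pool patterns; spurious sites appear at rate 0.1 per real
  site in 1–2 random pools. `exact_depth = TRUE` gives the noiseless mode
  used for round-trip identities.
* `gen_strain_panel()` — log CFU = baseline 9.2 (natural-log units,
  ≈ $10^4$ CFU, a typical per-fly load) + OG effects + experiment effect
  $\sim N(0, 0.5^2)$ + strain effect $\sim N(0, 0.5^2)$ + residual
  $N(0, 0.5^2)$; counts are `round(exp(log CFU))`; presence is
  Bernoulli(0.5) per strain × OG unless a profile is supplied. The default
  scale is 41 strains, 3 experiments, triplicate.
* `gen_load_table()` — the same structure with treatments as fixed shifts;
  the default layout is 3 experiments × triplicate, matching the published
  mutant experiments.

The generator does **not** simulate raw reads, alignment, chimeras, plate
handling errors, fly-to-fly biology beyond the stated variance components,
or CFU detection limits (left-censoring is available via `detection_limit`
but off by default, since no limit is published). Passing tests on
synthetic data therefore certify the *computational* pipeline — decoding
identities, estimator calibration, enrichment arithmetic — not the upstream
wet-lab or alignment steps.

# Essentiality and enrichment statistics

Genes with zero recovered insertions in a near-saturated library are
candidate essential genes. Per pathway we form the 2×2 table

$$\begin{pmatrix} a & n_{path}-a \\ A-a & (G-n_{path})-(A-a) \end{pmatrix}$$

with $a$ zero-insertion genes in the pathway, $n_{path}$ the pathway size,
$A$ the zero-insertion total and $G$ the gene universe (pathway-vs-rest,
disjoint cells). Significance uses the Pearson statistic without continuity
correction and a Monte-Carlo p-value from $B = 2000$ fixed-margin
resamples (`stats::r2dtable`), $p = (k+1)/(B+1)$, so the attainable floor
is $1/2001 \approx 0.0005$ at four decimals. Benjamini–Hochberg FDR is
applied across tested pathways. The direction call is *essential* when the
pathway's zero-insertion fraction exceeds the background fraction $A/G$,
*nonessential* otherwise. The same machinery, with labels
enriched/depleted and the published ≥ 4-counts-in-both filter, tests
pathway enrichment among top association hits. For the essentiality table
the size filter applies to the pathway size only (a pathway can
legitimately have zero or one zero-insertion genes).

Note that the choice of background matters for borderline directions: a
genome-wide background and a background restricted to pathway-annotated
genes can disagree when a pathway's zero-insertion fraction falls between
the two. `pathway_enrichment()` therefore takes $A$ and $G$ explicitly.

# The association model

For each orthologous group (OG) the model is

$$\log \mathrm{CFU} = \beta_0 + \beta \cdot \mathrm{presence}
  + u_{experiment} + u_{strain} + \varepsilon$$

with independent zero-mean random intercepts for experiment and strain
(strain doubles as "bacterial treatment": replicates of a strain are not
independent). Fits use `lme4` with maximum likelihood; the presence term is
tested by a likelihood-ratio test of the nested ML fits ($\chi^2_1$), which
is well-defined without degrees-of-freedom approximations; a Wald z test is
available via `test = "wald"`. OGs present in fewer than two strains per
class are reported `monomorphic` and left untested. Variance components are
constrained non-negative by the optimizer; boundary (singular) fits are
reported via the `boundary` flag, not errored, because a strain-level
predictor alongside a strain random effect legitimately pushes the strain
variance to zero when the predictor explains it. Bonferroni correction uses
the number of OGs actually tested. The top set is selected on raw
p < 0.001 by default (`use_corrected = TRUE` switches to corrected),
mirroring the published selection rule for enrichment input. Zero CFU
counts are replaced by 1 before the natural-log transform and the number of
replacements is carried in the result.

`compare_loads()` fits the analogous model with treatment as a fixed factor
and experiment as the single random intercept (the published description
mentions start and end dates; one experiment identifier subsumes both), and
reports Wald contrasts against the control. With a single experiment the
random effect is inestimable and the function falls back to a fixed-effects
linear model with a warning. The Wald z is mildly liberal at triplicate
scale (observed null rate ≈ 0.05–0.09 at nominal 0.05 in the test suite's
simulations); users needing exact small-sample inference should increase
replication or use the LRT machinery of `fit_og_association()`.

# Rarefaction

`rarefaction()` reports the mean cumulative number of distinct genes hit as
mutants accumulate, averaged over random orderings; intergenic mutants
occupy draws without adding genes. The analytic counterpart
(`rarefaction_expected()`) is the hypergeometric expectation
$E[\mathrm{distinct}\ at\ k] = \sum_g \left(1 -
\binom{N-m_g}{k}/\binom{N}{k}\right)$, computed with log-binomials for
numerical stability; the permutation estimate converges to it and the test
suite asserts agreement (and cross-checks the closed form against
`vegan::rarefy`).

# Numerical choices and degenerate inputs

* Threshold boundary: exactly `threshold` reads counts as present.
* Monte-Carlo ties: resampled statistics within square-root machine
  epsilon of the observed statistic count as "at least as extreme".
* Tables with an empty margin are excluded from enrichment with a warning.
* `pool_count_histogram()` bins weights 0..24 and always sums to the number
  of sites.
* Empty inputs (no genes, no mutants, empty count matrix) return empty,
  well-formed objects rather than errors; infeasible requests (more
  mutants than target space, more codewords than capacity) raise sizing or
  capacity errors naming the binding constraint.
* One master seed drives every pipeline stage seed, so `run_pipeline()`
  reruns are byte-identical.

# Problem sizes used by the test suite

The suite exercises the decoder at full-library scale (a 53-plate design,
5,050 mutants, 100% recovery required on noiseless data) and the statistics
at desk scale chosen for tight Monte-Carlo error at reasonable runtime:
100 replicate panels of 41 strains for effect recovery (mean bias of
$\hat\beta$ under 0.1 at a true effect of 2.0 natural-log units), 1,000
null OG fits for type-I calibration (rate within a 99% binomial CI of
0.05), 200 permutations against the closed-form rarefaction expectation,
and $B = 2000$ resamples wherever published floor p-values are reproduced.

# Known limitations

* A gene is "hit" by any insertion within its span; insertions in the
  final 3′ fraction of a gene may not abolish function, so zero-insertion
  calls inherit that optimism.
* Essentiality is operational (no recovered disruption under the growth
  condition), and polar effects on neighbouring genes are not modelled.
* Exact-match decoding discards near-miss barcodes by design; the
  `min_distance` filter exists to support rescue decoding, but rescue
  itself is not enabled by default.
* The association scan treats OGs independently; linkage between gene
  families across strains is not modelled, and the Bonferroni correction
  is conservative under that dependence.
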