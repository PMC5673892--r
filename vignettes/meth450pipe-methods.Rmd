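---
title: "Methods and design of meth450pipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of meth450pipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meth450pipe)
```

This vignette is the package's account of the statistical procedures it
implements, the choices that were genuinely open when it was designed,
and what its synthetic-data tests do and do not demonstrate about real
450K cohorts.

## Coordinates and containers

All genomic intervals are 0-based half-open (`[start, end)`, BED
convention); a probe at position *p* belongs to an interval iff
`start <= p < end`. Promoters span 1.5 kb upstream and 0.5 kb downstream
of the TSS, so `[tss-1500, tss+500)` on the + strand and
`[tss-500, tss+1500)` on the − strand; CpG-island promoters are the
interval intersection of promoter and island. Beta values are
methylation fractions in [0,1]; total intensity (methylated +
unmethylated signal) is the strictly positive quantity copy-number
calling consumes. Normalized betas are assumed as input — array
preprocessing (e.g. BMIQ) is upstream of this package's scope.

## Differential methylation by combined rank

Region betas are unweighted means of member-probe betas (missing probes
ignored; a region is dropped when it has fewer than `min_probes = 3`
mapped probes, or fewer than 3 observed in more than 20% of samples).
Three per-region metrics are ranked best-first — |Δβ| (difference of
group means), extremeness of the mean quotient (max of q and 1/q), and
the p-value — and combined as their **maximum** rank: a conservative
conjunction, since a region is called only if *every* metric ranks it
highly. A rank-based criterion is invariant to monotone transforms of
any single metric and robust to the heavy non-normal tails of beta
differences.

The cutoff rule had to be decided here (rank criteria per se do not
supply one): `"auto"` sets it to the number of regions with BH-adjusted
p < 0.05 **and** |Δβ| ≥ 0.1, i.e. the size of the set that passes a
conventional significance-plus-effect filter, and is exposed as a plain
integer for manual control. The p-value engine is Welch's t by default;
`method = "limma"` uses moderated variance (empirical-Bayes shrinkage),
which is preferable for small cohorts. When a group mean is exactly 0
the quotient gains a 0.01 pseudo-count on both numerator and
denominator; beta means are bounded away from 0 in practice so the
distortion is negligible. Paired primary/metastasis contrasts use the
standard paired t-test with BH adjustment; zero-variance difference
vectors (to floating-point tolerance 1e-10) get an `NA` sentinel p-value
and a `degenerate` flag rather than a fabricated statistic.

Cross-cohort validation is deliberately strict: a discovery hit is
validated only when significant in the validation cohort *with the same
direction*; the validation rate is validated / discovery-significant.

## Copy number from total intensities

Each tumor's probe-level track is `log2(tumor / mean(normals))`,
median-centered so that global array-brightness differences cancel —
the implicit assumption is that most of the genome is copy-neutral; in
a genome-doubled tumor the centered baseline would sit at the modal
(not absolute) copy number, a standard limitation of ratio-based
calling without purity/ploidy correction.

Binning is greedy left-to-right with a minimum of 5 probes per bin and
the trailing undersized bin merged into its predecessor — deterministic
and order-independent given sorted probes; only the minimum bin size is
a fixed convention, so the greedy-with-merge completion is a documented
design choice. Segmentation minimizes
`sum of squared deviations + penalty * (#segments)` exactly, by the
O(n²) dynamic program over last-changepoint positions; the test suite
proves equality with brute-force enumeration over all changepoint
placements on short series. The default penalty is BIC-like,
`2 * sigma^2 * log(n)` per chromosome, with sigma estimated robustly as
`mad(diff(x)) / sqrt(2)` so that implanted steps, not noise, pay for
changepoints.

Gene states use the conventional thresholds ±0.2 (single-copy) and
±1.0 (high-level), strict outward comparisons, on a length-weighted
mean of overlapping segment log2 values. Recurrence is scored per
direction as `G_amp(gene) = sum over samples of max(0, log2)` (and the
mirror for deletions): a sample contributes its amplitude only when it
deviates in the scored direction, so G combines frequency with
amplitude and is linear under amplitude scaling. The null permutes each
sample's gene-level values independently across the genome — preserving
every sample's amplitude distribution while destroying locus alignment
— and pools permuted gene scores into one null ECDF;
`p = (1 + #{null >= G}) / (1 + N)` (the +1 avoids literal zeros), then
BH across genes. The continuous G (rather than one restricted to genes
with a discrete call) is what makes null p-values uniform, which the
suite checks by Kolmogorov–Smirnov at 5,000 permutations. The full
peak-deconvolution machinery of marker-level recurrence tools
(peel-off, arm/focal separation) is intentionally out of scope; an
arm-length filter for whole-arm events can be approximated by dropping
segments covering most of a chromosome before `gene_calls()`.

## Mutational signatures

Spectra use the canonical 96-channel pyrimidine frame: 6 substitution
classes × 16 flanking contexts, alphabetical; purine-reference records
are reverse-complemented into frame, and records whose context middle
base contradicts the reference base are rejected (with a warning), so
channel totals always equal accepted mutation counts. Contexts arrive
as 3-mer labels on the catalog — no reference genome is consulted.

Refitting is iterative forward selection: at each step the candidate
signature whose inclusion most reduces SSE is added, with weights
re-optimized by NNLS on normalized frequencies and the weight total
clipped to 1 by rescaling; selection stops below 0.1% relative
improvement; weights under `weight_cutoff = 0.06` (the refitting
literature's default) are zeroed and the survivors refit once. The
suite asserts the greedy SSE lands within 1% of exhaustive best-subset
NNLS over all subsets of ≤ 4 signatures from a 6-signature panel.
Trinucleotide-context normalization (exome vs genome channel
frequencies) is *not* applied by default — the synthetic genome has no
sequence, so channel labels are already in the spectrum's own frame; a
96-vector of context weights can be folded into the reference matrix by
the caller when real exome data require it. Samples under 50 mutations
warn rather than fail: quiet exomes are real.

## Deconvolution and purity

Discriminating probes are chosen per cell type by margin — the k
probes where the type exceeds the *maximum* of the others most, and the
k where it is furthest below the *minimum* — which targets probes
informative for exactly one type. Composition is NNLS of the bulk betas
on the reference profiles over those sites, renormalized to sum to 1.
This constrained-projection route is numerically simpler than quadratic
programming with an equality constraint and equivalent up to how
residual mass is distributed; the renormalization step is also why the
"adding non-informative probes changes nothing" invariant holds only to
about 1e-3 rather than exactly. Collinear reference profiles are
detected and reported by name rather than silently producing an
unidentifiable fit. LUMP-style purity is `min(1, mean beta over
leukocyte-unmethylated probes / 0.85)`; 0.85 is the saturation constant
treated here as a documented, configurable scaling.

## Phylogenies

Distances are plain Euclidean over all probes, pairwise-complete under
missingness (with per-pair probe counts recorded) — the choice when the
missingness mechanism is unknown. Trees come from neighbor joining or,
by default, balanced minimum evolution (`ape::fastme.bal` with NNI
refinement — the tool of record for this tree criterion); negative
branch lengths are clamped to 0. The package implements the Pauplin
balanced tree-length objective `L = sum d_ij * 2^(1-p_ij)` (p_ij =
topological path length) independently, so tests can verify that BME
refinement never increases the objective relative to the NJ start and
that on additive matrices the balanced length equals the total branch
length.

## Nine-state integration

The methylation axis calls a tumor hyper-/hypomethylated at a gene when
its promoter beta lies beyond the normal-tissue mean by more than 0.20.
A "20%" methylation cutoff admits two readings — an absolute beta
difference of 0.20, or ±20% *of* the normal mean — and the absolute
reading is the default here because beta differences are the field's
effect-size currency and the rule stays symmetric for hypo- and
hypermethylation near low normal means; `meth_mode = "relative"`
switches readings. The copy-number axis uses the sign of the discrete
state, either magnitude. The 3×3 cross-product yields exactly the nine
categories, verified against a straight-line oracle on 10⁴ random
triples. In recurrence ranking, loss events are states containing a
deletion and/or hypermethylation and gain events contain amplification
and/or hypomethylation, so mixed states (del+hypo, amp+hyper) count in
*both* directions — a documented convention, since such genes carry
evidence for each. Ties break lexicographically for reproducibility.

## The synthetic-data generator

The generator defines the package's study conditions. Gene layout: 20 kb
bodies 100 kb apart, alternating strands, one 800 bp CpG island centered
on every other TSS; three probes are guaranteed in each promoter and
body (hence `n_probes >= 6 * n_genes`), the rest scattered. Betas are a
shared per-probe baseline (uniform 0.2–0.6) plus truncated-Gaussian
noise (default sd 0.05); DMRs shift member probes by Δβ in a random
tumor subset before noise. Intensities are per-probe lognormal baselines
around 5000 with multiplicative lognormal noise (default sd 0.1 on the
log scale); copy-number segments scale them by `2^log2_ratio`. Mutation
catalogs are i.i.d. multinomial draws from a signature mixture;
reference signatures are strongly peaked (4 high-mass channels over a
2% floor) because diffuse, flat signatures are not identifiable from a
96-channel spectrum at ~10³ mutations — the generator emulates the
regime in which refitting is meaningful, much as the
spontaneous-deamination signature concentrates on N[C>T]G channels.
Reference panels plant 50 marker probes per cell type (0.9 vs 0.1
against a shared background).

What this does **not** emulate: FFPE degradation and probe-specific
noise heterogeneity, type I/II probe chemistry, batch structure, purity
gradients within a cohort, correlated (co-methylated) probes within a
region, and real genomic context frequencies. Passing recovery tests
therefore demonstrates correctness of the algorithms under their stated
models, not field performance on archival tissue.

All generators and the pipeline draw from named substreams of one root
seed (`substream_seed`), so any stage re-run in isolation reproduces the
full-run output and identical seeds give byte-identical run
directories.

## Problem sizes and tolerances used by the test suite

The suite runs at desk scale, chosen so every recovery property is
measured with real power: 1,000 regions × 30 samples with 50 implanted
promoter DMRs (Δβ = 0.3 in 80% of tumors, noise 0.05) for sensitivity
≥ 0.9 at FDR ≤ 0.1; a 1,000-probe chromosome with a 50-bin deletion at
log2 −0.5 (noise 0.1) for breakpoint recovery within ±1 bin; 200 genes
× 10 samples with 2,000–5,000 permutations for recurrence calibration;
20 replicate catalogs of 1,000 mutations for weight recovery within
±0.05 and reconstruction cosine ≥ 0.99; 4-cell-type panels of 500
probes for composition recovery within ±0.03. Exact claims (DP
optimality, nine-state agreement, additive-tree inversion) are asserted
against independent brute-force oracles rather than tolerances.

## Known limitations

No purity/ploidy correction of log2 ratios; no site-level (single-CpG)
differential calling; no de novo signature extraction; no bootstrap
support on trees; recurrence scoring is gene-level, without focal/arm
deconvolution. These are boundaries of scope, not of the data model —
each stage's containers (`beta_matrix`, `segment_set`, `gene_cna`,
`nine_state`) accept externally computed inputs wherever a richer tool
is available.
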