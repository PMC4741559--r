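---
title: "Methods: array-CGH strain divergence profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: array-CGH strain divergence profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Array-based comparative genomic hybridization (array-CGH) measures, for
every gene, the log2 ratio of a test strain's DNA to a reference strain's
DNA. Across a cohort of related strains — here modeled on a collection of
22 diploid distillery yeasts spanning four *Saccharomyces* species groups —
those ratios carry three superimposed signals: genuine copy-number
differences between strains (concentrated in the subtelomeres, where gene
families such as the Y'-element YRF1 helicases expand and contract),
probe-level hybridization bias caused by sequence divergence between each
strain and the single laboratory reference, and stochastic measurement
noise. This package separates them and turns the result into divergent-gene
calls, functional enrichments and strain relationship trees.

# Model and procedure

## Cohort-average re-normalization

Because every strain is hybridized against the same reference, a probe
whose sequence diverges from the reference depresses (or inflates) the
signal of *all* strains by the same additive amount on the log2 scale.
`renormalize()` subtracts each gene's cross-strain arithmetic mean
(the strain's own value included, missing values excluded), which cancels
any per-gene additive bias exactly and makes profiles comparable across
the cohort. The operation is idempotent and leaves every gene with mean
zero. We average log ratios, not intensities: the implied reference is the
geometric mean of the cohort on the raw scale, which is the natural choice
when only ratios are observed.

## Divergence profiles

Per-gene divergence is the population standard deviation (divide by *n*)
of the re-normalized values across strains. We use the population
convention deliberately: the cohort is the entire population of interest,
not a sample from one, and the same convention is used by the selection
threshold so the two stages are consistent. A gene must be observed in at
least two strains to receive an SD.

The smoothed trend is a centered moving average over genes in genome order
(`chromosome, start, gene_id`), computed per chromosome. Windows shrink
symmetrically at chromosome ends and never pad or wrap — padding would
fabricate signal exactly where the biology lives, at the subtelomeres. The
default window of 21 genes is a compromise between resolving subtelomeric
blocks (tens of genes) and suppressing single-gene noise; it is exposed as
a flag because no principled value is implied by the data model.

## Segmentation

Aneuploid blocks in one strain's profile are found as the exact minimizer
of

    sum of squared residuals to segment means + penalty x (number of segments)

over all change-point placements, by an O(n^2) dynamic program. The default
penalty `2 * sigma^2 * log(n)` is a BIC-flavored choice with `sigma`
estimated robustly from first differences (MAD / (sqrt(2) * 0.6745)), so a
single aneuploid block does not inflate the noise estimate. Exact cost ties
resolve toward fewer segments; a constant input therefore always yields one
segment. This stated, testable formulation replaces the interactive
piecewise-regression viewers used in practice for visualization; it is
checked against exhaustive enumeration of all segmentations for n <= 12.

## Divergent-gene selection

The global dispersion scale is the population SD pooled over every
gene x strain value of the re-normalized matrix (grand-mean centered,
missing excluded). A gene is selected when at least one strain's absolute
value strictly exceeds `k` times that scale, `k = 4` by default. Three
decisions here were genuinely open and are fixed as follows:

- **Two-sided exceedance.** Losses are as interesting as gains (deleted
  subtelomeric blocks are a hallmark of species groups), so the absolute
  value is tested even though a one-sided reading is possible.
- **Population SD, computed after re-normalization.** Selection operates
  on the same re-normalized values it reports; computing the scale before
  re-normalization would mix reference bias into the threshold.
- **Strict inequality.** Only measure-zero boundary cases are affected;
  strictness makes the degenerate all-zero matrix select nothing.

The threshold scales with the data, so the selected set is invariant to
multiplying the matrix by a positive constant, and shrinks monotonically
as `k` grows.

## Overrepresentation

Each functional category is tested with the exact hypergeometric upper
tail, accumulated in log space for stability at genome-scale counts, and
verified against direct enumeration. Benjamini–Hochberg step-up FDR is
applied jointly across all tested categories, with significance declared
at `q < 0.05`. The universe is the intersection of the matrix's genes with
the term collection's gene space (the "all annotated genes on the array"
convention); categories with no member in the universe are skipped,
categories with zero overlap are still tested. Terms are flat sets — no
ontology-graph propagation of annotations is performed, a stated departure
from GO-aware tools.

## Strain clustering and the karyotype branch

CGH relatedness: Euclidean distances between re-normalized full profiles
(all genes, not only the selected subset — the selected-set variant is a
caller-side choice), pairwise-complete over missing values, then
complete-linkage agglomeration. Karyotype relatedness: band sizes pooled
and greedily binned (sorted, a bin closes when its span would exceed the
tolerance times the bin mean; default 5% relative), presence/absence per
strain, Jaccard similarity, UPGMA on `1 - J` with merge heights at half
the merge distance (the ultrametric convention).

Both trees share one agglomerator with deterministic tie-breaking by the
lexicographic order of each cluster's smallest leaf label, and a
deterministic smaller-label-first leaf traversal. Determinism matters more
than any particular tie policy: it fixes the heatmap column order and makes
trees reproducible under row permutations of the input. Co-migrating
chromosomes that fall into one bin count once per strain — the band is the
observable, not the chromosome.

# The synthetic cohort: a stated world

`simulate_cohort()` draws

    value[g, s] = bias[g] + delta(g, group(s)) + N(0, noise_sd)

with `bias[g] ~ N(0, reference_bias_sd)` shared by all strains. The
defaults *are* the modeled study design, chosen once:

| parameter | default | why |
|---|---|---|
| group_sizes | 7, 13, 1, 1 | the cohort's four species groups |
| chromosomes | 16, real yeast lengths (230–1532 kb) | spatial realism for subtelomere windows and the PFGE ladder |
| genes per chromosome | 300 | ~genome scale (4800 genes) at desk-test cost |
| subtelomere window | 30 kb each end | typical extent of yeast subtelomeric repeat territory |
| delta_log2 | ±1.0 | a heterozygous-to-homozygous copy change in a diploid |
| noise_sd | 0.15 | per-probe scatter that leaves planted blocks visible but not trivial |
| reference_bias_sd | 0.3 | bias comparable to or larger than noise, as the reference-strain problem demands |
| CNV events | 12 chromosomes; YRF1-like blocks +1 in groups 1 and 4, −1 in group 2; two private events per group | mirrors the qualitative gain/loss structure described for the modeled cohort |
| terms | 30 x 40 genes; one planted inside event regions | one true positive, the rest uniform background |
| band jitter | 0.5% multiplicative | replicate-level PFGE sizing error |
| marker bands | 1300, 1400, 170, 2000 kb | group markers placed in gaps of the chromosome ladder; 1300 kb is the group-1 signature band |

The generator is deterministic given the seed (band patterns use
`seed + 1` so they are identical whether drawn standalone or inside the
cohort). Overlapping same-group events sum their deltas and warn.

What the simulator does **not** emulate: probe-level intensity effects
(dye bias, saturation, spatial artifacts — assumed removed upstream by
scanner software), correlated noise along the genome, mosaicism or partial
ploidy, cross-hybridization between paralogs, and gel-image band calling.
A green recovery test therefore establishes that the pipeline's logic is
correct under its stated noise model — not that the thresholds are optimal
for any particular array platform.

# Numerical choices

- Coordinates are 1-based closed throughout; gene-to-region membership is
  by midpoint, consistent with the subtelomere flag. The annotation writer
  can emit strict 0-based half-open BED on request.
- Symmetry of distance inputs is enforced to 1e-8 and then exactly
  symmetrized; cluster-pair ties are detected at 1e-15.
- Segmentation cost ties are detected at 1e-12 and resolved toward fewer
  segments; the automatic penalty is floored at 1e-12 so constant input is
  handled.
- `hypergeom_upper_tail` returns exactly 1 whenever `k` is at or below the
  smallest achievable overlap, avoiding accumulated round-off at the
  boundary.
- Degenerate inputs are rejected loudly: empty band lists, all-missing
  matrices, even smoother windows, non-positive penalties and thresholds,
  strain pairs sharing fewer than two genes.

# Scope of the acceptance evidence

The acceptance tests are simulation- and property-based by necessity: no
public raw microarray dataset exists for the motivating cohort, so
dataset-specific headline numbers (such as a particular count of selected
genes) cannot be recomputed and are not asserted anywhere. What the tests do
establish, at fixed seeds: oracle equivalence of the hypergeometric tail,
both linkage algorithms and the segmentation DP; the algebraic contracts
of re-normalization, selection and BH; ≥ 0.9 sensitivity and ≤ 0.1 false
discovery of the 4-SD rule against planted truth; exact recovery of the
planted 4-group partition by the tree cut; the planted category ranking
first and significant; FDR calibration under 200 null cohorts; and
concordance of the karyotype and CGH trees. The end-to-end test and the
null-calibration loop use the default cohort size; the pipeline
round-trip test uses a 4-chromosome scaled-down cohort purely to keep the
suite fast — the stages exercised are identical.

# Known limitations

- The 4-SD rule is a global threshold; a strain with unusually noisy
  hybridization inflates the pooled SD for everyone. A robust (e.g.
  MAD-based) variant would be a natural flag but is out of scope.
- Greedy size-sorted binning is order-dependent at bin boundaries; with
  jitter near the tolerance, a lane's band can split from its homologs.
  The tolerance is exposed for exactly that reason.
- Flat term sets mean enrichment significance depends on how the term
  collection was assembled; no parent-term propagation is attempted.
- UPGMA and complete linkage are both sensitive to outlier strains by
  construction; no bootstrap support is computed.
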