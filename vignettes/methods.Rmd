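---
title: "Methods: TE insertions and homoeolog expression bias in wheat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE insertions and homoeolog expression bias in wheat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatTEbias)
```

# The problem

Bread wheat is a young allohexaploid: three diploid progenitors
contributed the A, B and D subgenomes, and most genes survive as
homoeologous groups — triads (one copy per subgenome), dyads (one copy
lost) or tetrads (one copy duplicated). Transposable elements occupy the
bulk of the genome and frequently insert into gene bodies. This package
implements, as a reusable pipeline, an analysis that asks three
questions: (i) are TE insertions within gene bodies distributed randomly
across the members of a homoeologous group, (ii) is insertion
polymorphism within a group associated with unbalanced expression of the
homoeologs, and (iii) are particular TE superfamilies/subfamilies and
insertion contexts (exon, UTR) associated with particular expression-bias
categories and gene functions?

# Coordinate and annotation conventions

All coordinates are 1-based inclusive (GFF3 convention). A TE "insertion
within" a feature means an intersection of at least one base; a TE
straddling a gene edge counts, and a TE overlapping two genes is counted
once per gene. Exon/UTR interval lists are normalized (sorted, merged per
gene) before intersection so overlap widths are well defined. Only TE
records with annotation status `repeat_region` are analyzed; nested
repeats and fragments are filtered out but retained in memory with a
logged count. TE names follow the ClariTeRep scheme
(`<CODE>_<family>[.<subfamily>]`); the three-letter prefix is the Wicker
class/order/superfamily code, and unknown codes degrade to an explicit
`unknown` classification rather than erroring, because the annotation
itself carries an unclassified (`XXX`) bucket.

Genes are assigned to the five chromosomal regions R1/R2a/C/R2b/R3 by the
region containing the gene **midpoint** (`floor((start+stop)/2)`). The
source analyses do not state how boundary-straddling genes were assigned;
the midpoint is our choice — deterministic, symmetric, and unambiguous
with integer flooring. R2a∪C∪R2b form the proximal macro region (TE
dense, low recombination), R1∪R3 the distal one. Low-confidence (LC) gene
models are excluded by default (`include_lc = TRUE` reverses this) since
the analysis is defined over high-confidence genes.

# The conditional-binomial morphism null

For a group of cardinality $k$ whose members each carry a TE insertion
independently with probability $p$:

$$P(\text{mono} \mid \ge 1\ \text{TE}) = \frac{p^k}{1-(1-p)^k},\qquad
  P(\text{poly} \mid \ge 1\ \text{TE}) = \frac{1-p^k-(1-p)^k}{1-(1-p)^k}.$$

Expected monomorphic/polymorphic counts are these probabilities times the
number of TE-containing expressed groups, tested against the observed
split by Pearson goodness of fit (df = 1, no continuity correction).

**Estimating p — an important caveat.** The published analysis estimates
$p$ as the fraction of genes with insertions *among genes of TE-containing
groups* (`p_method = "conditional"`, the package default, which exactly
reproduces the published predictions, e.g. 43.13% polymorphic dyads from
the printed dyad counts). That estimator is inconsistent under the very
null it tests: conditioning on "≥ 1 insertion in the group" inflates the
per-gene rate (for $k=2$, $p=0.5$ it converges to $2/(1+q) \cdot 1/2 =
0.667$), so the predicted conditional split disagrees with the observed
one *even when presence is truly independent Bernoulli*, and the
goodness-of-fit test rejects with probability approaching 1 as the number
of groups grows. We verified this by simulation
(`calibrate_morphism_gof(..., p_method = "conditional")` rejects ~100% on
null data). The package therefore also offers
`p_method = "unconditional"` — numerator unchanged, denominator all genes
of all expressed groups — which is consistent and approximately
calibrated (slightly conservative, since a parameter is estimated;
simulated type-I error ≈ 3–5% at nominal 5%). Consequence for
interpretation: a significant conditional GOF cannot by itself establish
non-randomness of insertion placement; the direction and the
unconditional fit should be consulted. Published chi-square values are
reproduced with the conditional method; calibration claims are made with
the unconditional one.

# Expression-bias categories

Per sample, the TPM values of a group's members are normalized to
proportions; samples whose summed TPM is at or below the 0.5-TPM floor
are excluded, and the group's signature is the mean of per-sample
proportions (mean-of-normalized, which is scale invariant). Triads are
assigned to the nearest of seven ideal centroids in Euclidean distance:

| category | centroid |
|---|---|
| balanced | (1/3, 1/3, 1/3) |
| X dominant | 1 at X, 0 elsewhere |
| X suppressed | 0 at X, 1/2 elsewhere |

Exact ties are broken by a fixed priority — balanced, then dominant, then
suppressed, slots in A, B, D order — implemented as the first minimal row
of the centroid matrix. The centroid coordinates ship as an editable
argument: they follow the ternary-diagram convention of the wheat
homoeolog-expression literature, and the package does not claim to
reproduce externally pre-computed per-triad labels (annotation-version
and pipeline differences make that unattainable; the category *method* is
what is implemented and tested). Dyads use balanced + one-suppressed
centroids (a dominant slot of a pair is the mirror of a suppressed one);
tetrads add one-dominant and two-suppressed centroids (0 at two slots,
1/2 at the rest). Whether the original dyad/tetrad assignments used
thresholds rather than nearest centroids is unstated in our sources;
nearest-centroid is our uniform generalization.

A triad enters the association screens when it is syntenic and expressed
in at least 6 of 15 tissues (both configurable); the screen universe is
the TE-containing subset of those eligible triads, matching the published
2×2 margins.

# Screens and multiplicity

For each TE group (superfamily or subfamily) and each comparison
(balanced vs not, pooled suppressed vs not, pooled dominant vs not) the
2×2 table of presence × category membership is tested by Pearson
chi-square **with Yates correction** — the default of the contingency
routine the published values were computed with, and required to
reproduce them (11.34, 73.45, 87.18, ...). Tables with any cell below 5
are excluded *before* testing; Benjamini–Hochberg adjustment is applied
within each (TE level × comparison) family, matching the published table
groupings. Presence means ≥ 1 insertion in ≥ 1 of the triad's genes — the
screens do not condition on which homoeolog carries the insertion.
Direction is the sign of observed minus expected in the
present-and-in-category cell.

GO enrichment is one-sided (over-representation) Fisher's exact — a
hypergeometric upper tail — against the eligible-triad background, with
FDR per GO domain because BP/MF/CC term counts are reported separately.
A triad's term set is the union of its member genes' annotations (the
most inclusive deterministic choice; optional ancestor propagation when a
parent table is supplied), and queries mapping to fewer than two distinct
terms are refused, mirroring the behaviour of standard SEA services on
short lists.

# The synthetic world

`simulation_config()` defaults restate the real dataset's structure:
6,320 dyads / 18,390 triads / 752 tetrads (70,818 genes), 7 chromosomes
per subgenome, per-gene TE presence 0.403 proximal / 0.310 distal,
cardinality-specific proximal fractions (0.643 for triads, 0.378/0.424
for dyads/tetrads), superfamily weights proportional to the published
genome-wide triad counts of the 14 superfamilies, triad category weights
(0.83 balanced; suppressed 0.0516/0.0531/0.0352 and dominant
0.0090/0.0105/0.0107 per subgenome), and 123 samples over 15 tissues.
Values no source states were fixed once at realistic levels and are not
revisited: Dirichlet concentration 40 around category centroids (within-
category spread comparable to ternary-diagram clouds), per-sample
concentration 300, log-normal sample totals (meanlog 2.5, sdlog 1), dyad
category weights 0.8/0.2, tetrad weights 0.25/0.10/0.45/0.20, synteny
fraction 0.88 and low-breadth fraction 0.08 (chosen so that the eligible
fraction of triads ≈ 0.78, as in the real analysis set), and a Zipf-like
family-abundance decay within superfamilies.

Design note: TE presence is sampled per gene as a Bernoulli draw and only
then materialized as coordinates inside the gene (the per-superfamily
probabilities are chosen so the overall no-TE probability is exactly
$1-p$). The generator therefore instantiates the independence assumption
of the morphism null *exactly* — any deviation a test detects is planted,
never accidental. Planted TE effects multiply the odds of presence for
genes of triads in the target category family (superfamily level only;
subfamily-level planting is not implemented). Planted GO effects add a
fresh term carried at a base rate by background genes and at an
`enrichment`-fold rate by a recorded random query subset.

What the generator does **not** emulate: TE nesting and age structure,
linkage between neighbouring genes, sequence content, realistic
tissue-specific expression programs, and correlations between TE
presence and expression other than the planted ones. A green recovery
test therefore establishes that the pipeline detects effects of the
planted kind at the stated scale — not that the biological analysis is
free of confounding (e.g. the regional density confound is present in the
generator by construction and is handled, as in the published analysis,
by macro-region stratification).

# Numerical choices

* Chi-square tests: Yates correction iff 2×2 (per-cell deviation reduced
  by 0.5, clamped at zero); df = cells − 1 for goodness of fit.
* BH: hand-written step-up with monotonicity enforcement, validated
  against `p.adjust`.
* Proportion rows must sum to 1 within 1e-6; distance ties within 1e-12
  resolve by centroid priority.
* Degenerate fits (p = 1, expected polymorphic 0) return `NA` statistics
  rather than erroring.
* All randomness flows from a single seed; generated datasets are
  byte-identical across runs with the same configuration.

# Known limitations

* The conditional estimator's miscalibration (above) is inherited from
  the published method by design; the package surfaces it rather than
  silently replacing it.
* Subfamily-level planted effects and per-subgenome directional screens
  are not implemented.
* GO term counts of external annotation services are not reproducible
  (annotation-version dependence) and are out of scope; only the SEA
  statistics themselves are tested.
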