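---
title: "Degradation-product peptidomics: models and methods"
author: "degradomics package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degradation-product peptidomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degradomics)
```

## The problem

Proteasomes hydrolyse substrate proteins into short peptides. The 26S
holoenzyme recognises ubiquitinated substrates, unfolds them with its
ATPase ring and translocates them into the 20S core particle, while free
20S core particles act directly on disordered polypeptides. Because the
two complexes share the same catalytic sites, their distinctive behaviour
is read out from their *products*: which peptide bonds are used, how long
the products are, how diverse the repertoire is, and whether products
carrying ubiquitin remnants (isopeptide-linked GG/RGG/LRGG stumps on a
lysine) appear. This package provides the complete analysis layer for such
experiments: it consumes identified-peptide tables from an upstream search
engine (non-tryptic searches; MaxQuant-style columns supported), maps the
peptides back onto the substrate, and computes the comparative statistics
described below. It deliberately does *not* perform spectral searching,
FDR control or disorder prediction: those are consumed as inputs.

## Coordinates and the cleavage-preference statistic

Residues are 1-based; cleavage site $j$ is the bond between residues $j$
and $j+1$, so residue $j$ is the P1 residue of that bond and positions
P4..P1, P1'..P4' frame it. A product spanning residues $s..e$ witnesses a
cleavage at site $s-1$ (unless $s = 1$) and at site $e$ (unless $e = L$).

Per condition, the usage of site $j$ is the integrated PSM count
("MS/MS count") of all unambiguously mapped peptides bounded by $j$. Each
internal product is credited to **both** bounding sites, because one
product is evidence of two cleavage events. The analysis does not say
whether one- or two-sided crediting is the better estimator in all
regimes, so an N-terminus-only mode (`credit = "nterm"`) is provided for
sensitivity analysis; with two-sided crediting the total credited count
equals twice the internal-product counts plus the single-terminus product
counts, which is checked as an invariant in the tests.

The relative cleavage preference of condition A over condition B at site
$j$ is

$$\mathrm{pref}(j) = \log_2 \frac{a_j \vee 0.1}{b_j \vee 0.1},$$

where $a_j, b_j$ are integrated counts and $x \vee 0.1$ substitutes the
pseudo-value 0.1 when the count is zero. Sites with zero counts in *both*
conditions are reported as `NA` rather than $\log_2(0.1/0.1) = 0$: an
unobserved site carries no evidence of "no preference". A site is flagged
`prefer_a`/`prefer_b` when $|\mathrm{pref}(j)| > \log_2 2$, i.e. a
greater-than-twofold preference. The pseudo-value is applied to **raw**
integrated counts; if you normalise counts before the ratio the meaning
of 0.1 changes, which is why normalisation is not silently applied here.
The statistic is antisymmetric under swapping the conditions, and scaling
one condition by a constant $c$ shifts all doubly observed sites by
exactly $\log_2 c$ — so comparisons between conditions of unequal depth
are biased by the depth ratio unless depths are comparable or counts are
normalised; both properties are under test.

## Filters

Three filters mirror common peptidomics practice and are all surfaced as
parameters:

* **Replicate presence** (`filterReplicates`, default `minReplicates = 2`):
  a peptide species counts within a condition only when identified in at
  least 2 replicates (of typically 3). For low-coverage in vivo data a
  permissive `minReplicates = 1` variant is appropriate.
* **Sample floor** (`buildHeatmap`, default `minSamplePsms = 50`): samples
  with fewer than 50 mapped PSMs in total are discarded.
* **Single-sample peptides**: peptides observed in only one retained
  sample are discarded from the occupancy matrix.

Multi-mapping (ambiguous) peptides are excluded from site integration by
default to avoid double counting; an optional mode assigns each occurrence
the fractional count $1/k$. Unmapped peptides are routed aside, not
errors — on real data they belong to other proteins.

## Occupancy heatmap, MDS and Ward clustering

The heatmap matrix normalises PSM counts to counts-per-million within each
sample and then rescales each peptide to its maximum CPM, so every
retained peptide has maximum exactly 1 and the per-peptide maxima are kept
as the side bar-plot values. Rows are ordered by the product's N-terminal
residue, then length, then sequence (a deterministic tie-break). Sample
ordination uses classical (Torgerson) MDS on Euclidean distances of
$\log_2(\mathrm{CPM}+1)$ over the top 100 peptides ranked by per-peptide
maximum CPM, and samples are clustered with Ward linkage (`ward.D2`, the
squared-increase Ward criterion) on the MDS-space distances. A
leading-log-fold-change distance (as in edgeR's `plotMDS`) is a
reasonable alternative; classical MDS on log-CPM was chosen because it is
fully specified without reference to a particular count model. MDS axes
are sign-fixed (first sample non-negative on each axis) so runs are
reproducible.

## Composition around cleavage sites

Windows of residues $j-3..j+4$ (P4..P4'; the span is configurable) are
collected around each used site, weighted by the site's integrated count
so that composition reflects usage (an unweighted mode is available).
Positions that fall off a terminus are excluded from that position's
denominator. Information content follows the Schneider–Stephens
convention, $IC = \log_2 20 - H$ with bit heights $f \times IC$; no
small-sample correction is applied by default because the weights are PSM
counts rather than independent sequences (the correction is available as
a flag). The differential logo reports signed frequency differences and a
per-position Pearson chi-square on the weighted counts, pooling residue
categories with expected count below 1. Because window tokens are derived
from site counts, the per-position tests are positively correlated; the
composition-null study (below) measures the realised family-wise flag
rate under a true null.

## Length, diversity and disorder summaries

Product-length summaries follow the boxplot convention: type-7
(linear-interpolation) quartiles and whiskers at the most extreme points
within 1.5 IQR of the quartiles; type 7 is fixed for cross-implementation
determinism. Each distinct peptide counts once by default
(`per_peptide`), because a product-size distribution is a property of the
repertoire; `per_psm` weighting is available since abundance weighting is
equally defensible. Pairwise distribution comparisons use the
Mann–Whitney U test (exact null when both $n \le 8$ without ties,
otherwise the tie- and continuity-corrected normal approximation);
mean-level comparisons use Welch's unequal-variance t test. Diversity is
reported both as richness and as Shannon entropy (bits) over the
PSM-count distribution, since "diversity" is used informally in this
field. Per-protein disorder scores are the mean of per-residue IUPRED-style
predictions supplied as input tracks.

## Ubiquitin remnants and branched peptides

Remnants are C-terminal suffixes of ubiquitin (...LRLRGG), stored N-to-C
(`RGG`) and displayed in the conventional K-outward notation (`K—GGR`) by
string reversal; lengths 2–4 cover the commonly observed GG/GGR/GGRL
variants and the range is configurable up to the full ubiquitin length.
Remnant masses are residue-mass sums (monoisotopic, no extra water —
isopeptide chemistry), usable directly as variable-modification masses in
a search-engine configuration. A reported branched peptide is accepted
when its remnant is a ubiquitin suffix, its backbone maps uniquely to the
substrate, and the branch lysine coincides with a declared anchor; each
failure mode yields a machine-readable reason. Junction classification
labels a mapped interval `chimeric` when it overlaps two or more annotated
construct segments (e.g. an epitope tag read through into a ubiquitin
unit), which is evidence that the whole fusion was proteolysed.

## The digestion simulator

No raw mass-spectrometry data are required by the package; the simulator
generates peptide tables with the same statistical structure so every
analysis stage can be validated against ground truth.

Each digestion event draws a left and a right product boundary
independently — substrate termini or internal sites, internal sites
weighted by the model's `siteWeights`, termini at the mean positive site
weight — and is accepted when the product length falls inside
`[lengthMin, lengthMax]`. Defaults encode the study conditions the
package targets: a 7–35 residue window for a 20S-like enzyme versus 7–25
for a 26S-like one (free 20S particles release longer products), a
7-residue detection floor (non-tryptic searches do not reliably identify
shorter peptides; censored events are tracked, not silently dropped, so
count-conservation stays testable), three replicates, and a 2-of-3
replicate filter downstream. Replicate $r$ uses seed `seed + r`, so
replicates are independent but reproducible, and the two conditions of a
comparison must use different base seeds.

The simulator emulates: site-preferential non-tryptic cleavage, sampling
depth, replicate-to-replicate noise, the detection floor, and optional
remnant-carrying branched products at anchor lysines. It does **not**
emulate product re-processing (each event is independent, no
processivity), spectral-level effects (ionisation efficiency, missed
identifications correlated with sequence), or search-engine FDR. Passing
recovery tests therefore shows that the analysis layer is a faithful
estimator under the stated generative model, not that the model captures
every property of real digests. One visible consequence of the design is
saturation: on a short substrate at high depth nearly every feasible
product is observed, so per-peptide summaries (richness, length medians)
become nearly deterministic across seeds.

## Validation studies and problem sizes

Four seeded studies, shared verbatim between the test suite and
`scripts/acceptance.R`, define the package's self-validation:

* **Preference recovery** — 50 internal sites on a random 51-mer, true
  per-site weight ratios log-uniform in $[1/8, 8]$, depth $5 \times 10^4$
  events per replicate, 3 replicates, 2-of-3 filter; Spearman correlation
  between true $\log_2$ weight ratios and recovered preferences, over 10
  seeds.
* **Null preference** — identical models with independent seeds; median
  absolute recovered preference.
* **Length signature** — 7–35 versus 7–25 windows at depth $10^4$;
  Mann–Whitney p-value and median product lengths.
* **Composition null** — identical site weights in both conditions (39
  sites, depth 2000 per condition), 200 runs; fraction of runs in which
  the differential logo flags no position at $\alpha = 0.01$.

These sizes were chosen so that each study isolates one estimator at a
depth where its signal is expected to be decisive, while the whole suite
remains quick to run routinely.

## Numerical and degenerate-input choices

* Quartiles: type 7 everywhere.
* Duplicate table rows are summed (PSM counts are additive evidence).
* `wilcox.test`/`t.test` back the rank-sum and t statistics; the exact
  Mann–Whitney branch is enabled exactly when both $n \le 8$ with no
  ties, and two all-identical samples short-circuit to $p = 1$.
* Chi-square categories with expected count < 1 are pooled; empty or
  single-category tables give $p = 1$.
* MDS with two samples pads the second axis with zeros; reflections are
  resolved by the first-sample sign convention.
* Empty peptide tables are warnings, not errors; an all-filtered heatmap
  is an error carrying the observed sample totals.
* Written tables round floats to 6 significant digits and serialise `NA`
  as `"NA"`; re-reading reproduces the written values exactly.

## Known limitations

The preference statistic inherits the biases of PSM counting (no
intensity information); two-sided crediting slightly smooths preferences
between adjacent heavily used sites; the simulator's independence
assumptions understate the correlation structure of real digests; and
the branched-peptide layer validates reported branches rather than
re-localising them from spectra. The packaged cyclin substrate is a
synthetic stand-in that reproduces the documented construct properties
(88 residues, 15 lysines, an anchor lysine at position 64 and the
branched-peptide fixture ARLPLPKE) rather than a published database
sequence, and is labelled accordingly.
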