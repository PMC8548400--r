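# degradomics

Degradation-product peptidomics of 20S and 26S proteasomes (and other
proteases) in R.

## What this package is for

When a proteasome digests a substrate, the peptide products carry the
enzyme's signature: which peptide bonds it used, how long the products
are, how diverse the repertoire is, and — for ubiquitin conjugates —
whether products still carry an isopeptide-linked ubiquitin remnant on a
lysine. Comparative degradomics experiments read these signatures from
non-tryptic LC-MS/MS peptide identifications of in-vitro digests or of
the intracellular peptidome. `degradomics` is the analysis layer for such
data: it maps identified peptides back onto substrate sequences and turns
PSM counts into comparative cleavage statistics. Spectral searching, FDR
control and disorder prediction are upstream; their outputs (peptide
tables, per-residue disorder tracks) are this package's inputs.

The central statistic is the relative cleavage preference at each P1
position. Cleavage site *j* is the bond between residues *j* and *j*+1
(residue *j* = P1). Every unambiguously mapped product credits its summed
PSM count to both of its bounding sites, giving per-site usage *a*ⱼ and
*b*ⱼ in two conditions (say 20S and 26S proteasomes), and

&nbsp;&nbsp;&nbsp;&nbsp;pref(j) = log₂( (aⱼ ∨ 0.1) / (bⱼ ∨ 0.1) ),

where a zero count is replaced by the pseudo-value 0.1 and sites with
zero counts in both conditions are `NA`. Sites beyond a twofold ratio are
flagged `prefer_a` / `prefer_b`. Around the preference statistic the
package provides: replicate-presence filtering (2-of-3 rule), CPM/max
rescaled sample-by-peptide occupancy matrices with MDS ordination and
Ward clustering, P4..P4' composition and information-content logos with a
differential test, product-length and Shannon-diversity summaries
(Mann–Whitney / Welch comparisons), per-protein disorder scores,
ubiquitin-remnant enumeration (GG / RGG / LRGG with monoisotopic masses)
and branched-peptide validation, chimeric (junction-spanning) peptide
classification for fusion constructs, and a seeded digestion simulator
with ground truth for end-to-end validation.

## Worked example

The packaged fixtures are a 76-residue human ubiquitin record and a
synthetic 88-residue cyclin-B1-N-terminus-like substrate (a lysine-only-
at-64 variant used for branched-peptide work; see the fixture FASTA
headers), plus a small two-condition peptide table.

```r
library(degradomics)

fa  <- system.file("extdata", "cyclinb1_nt_synthetic.fasta",
                   package = "degradomics")
cyc <- loadSubstrate(fa, name = "CCNB1_NT_K64_synthetic",
                     anchorLysines = 64)
tab <- loadPeptides(system.file("extdata", "example_peptides.tsv",
                                package = "degradomics"))
tab <- filterReplicates(tab, minReplicates = 2)
mp  <- mapPeptides(tab, cyc)
u20 <- integrateSiteCounts(tab, mp, cyc, "20S")
u26 <- integrateSiteCounts(tab, mp, cyc, "26S")
pref <- computePreference(u20, u26, pseudoValue = 0.1, foldThreshold = 2)
subset(pref, call != "na")
#>    site value_a value_b log2_ratio     call
#> 7     7       0      16  -7.321928 prefer_b
#> 52   52      77      25   1.622930 prefer_a
#> 60   60      77      25   1.622930 prefer_a
#> 73   73      13       0   7.022368 prefer_a
#> 81   81      13       0   7.022368 prefer_a
```

Reading the output: the peptide SEQLQARL (residues 53–60) was seen in
both conditions but three times more often with the 20S enzyme, so both
of its bounding sites (52 and 60) are called `prefer_a` at log₂ ratio
1.62; sites 73/81 were used only in the 20S condition (the 0.1
pseudo-value gives log₂(13/0.1) = 7.02), and site 7 only in the 26S
condition. Remnant annotation works the same way:

```r
ub <- loadSubstrate(system.file("extdata", "ubiquitin_human.fasta",
                                package = "degradomics"))
enumerateRemnants(ub, minLen = 2, maxLen = 4)
#>   sequence length mono_mass notation_outward
#> 1       GG      2  114.0429               GG
#> 2      RGG      3  270.1440              GGR
#> 3     LRGG      4  383.2281             GGRL

annotateBranchedPeptide("ARLPLPKE", branchPos = 7, remnant = "RGG",
                        cyc, ub)$valid
#> [1] TRUE   # maps to 58..65; branch lysine = anchor K64
```

An end-to-end run (simulate or ingest → map → filter → preference,
heatmap/MDS, lengths, composition, remnants, disorder) is available as
`runPipeline(config, outDir)` with a single YAML-able configuration; see
`?runPipeline`. The methods vignette
(`vignettes/degradomics-methods.Rmd`) documents the models, parameter
choices and the simulator's scope.

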