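Package: degradomics
Title: Degradation-Product Peptidomics of 20S and 26S Proteasomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of non-tryptic degradation-product peptidomics from
    proteasome digestion experiments. Maps peptide products onto substrate
    sequences, integrates peptide-spectrum-match (PSM) counts into per-bond
    (P1) cleavage-site usage, and computes the log2 relative cleavage
    preference between two enzyme conditions (such as 20S versus 26S
    proteasomes) with a pseudo-count rule for unobserved sites. Builds
    filtered, counts-per-million normalized sample-by-peptide occupancy
    matrices with multidimensional-scaling ordination and Ward clustering,
    positional amino-acid composition and information-content logos around
    used cleavage sites, product-length and diversity summaries, per-protein
    intrinsic-disorder scores, and annotation of ubiquitin-remnant branched
    (isopeptide) peptides and fusion-construct junction-spanning products.
    Includes a seeded in-silico digestion simulator with ground truth for
    parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
biocViews: Proteomics, MassSpectrometry, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
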