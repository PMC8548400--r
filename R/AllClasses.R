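#' SubstrateRecord: a substrate amino-acid sequence with annotations
#'
#' Holds one substrate protein (or fusion construct) as an amino-acid
#' sequence together with optional construct segment annotations (epitope
#' tags, ubiquitin units, the substrate region itself) and the lysine
#' residues expected to carry isopeptide (ubiquitin-remnant) branches.
#'
#' @slot id single character identifier.
#' @slot sequence [Biostrings::AAString] over the 20 canonical residues,
#'   1-based residue indexing.
#' @slot segments data.frame with columns \code{name}, \code{start},
#'   \code{end}; non-overlapping, sorted, within the sequence.
#' @slot anchorLysines integer vector of residue indices, each pointing at a
#'   lysine.
#'
#' @aliases SubstrateRecord-class
#' @exportClass SubstrateRecord
setClass("SubstrateRecord",
  representation(
    id = "character",
    sequence = "AAString",
    segments = "data.frame",
    anchorLysines = "integer"
  )
)

setValidity("SubstrateRecord", function(object) {
  msg <- character()
  seqc <- as.character(object@sequence)
  if (!nzchar(seqc)) msg <- c(msg, "sequence must be non-empty")
  bad <- setdiff(strsplit(seqc, "")[[1]], AA20)
  if (length(bad))
    msg <- c(msg, paste0("non-canonical residues: ",
                         paste(unique(bad), collapse = ",")))
  if (length(object@id) != 1L || is.na(object@id))
    msg <- c(msg, "id must be a single string")
  L <- nchar(seqc)
  seg <- object@segments
  if (nrow(seg)) {
    if (!all(c("name", "start", "end") %in% names(seg)))
      msg <- c(msg, "segments need columns name, start, end")
    else {
      if (any(seg$start < 1L | seg$end > L | seg$start > seg$end))
        msg <- c(msg, "segment coordinates outside 1..length or start > end")
      if (is.unsorted(seg$start, strictly = TRUE) && nrow(seg) > 1L)
        msg <- c(msg, "segments must be sorted by start")
      if (nrow(seg) > 1L && any(seg$start[-1L] <= seg$end[-nrow(seg)]))
        msg <- c(msg, "segments must be non-overlapping")
    }
  }
  anc <- object@anchorLysines
  if (length(anc)) {
    if (any(anc < 1L | anc > L))
      msg <- c(msg, "anchor lysine index outside sequence")
    else if (any(substring(seqc, anc, anc) != "K"))
      msg <- c(msg, "anchor index does not point at a lysine (K)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SubstrateRecord
#'
#' @param id identifier string.
#' @param sequence amino-acid string (lowercase accepted, upcased).
#' @param segments optional data.frame with columns \code{name},
#'   \code{start}, \code{end} annotating fusion-construct segments.
#' @param anchorLysines integer indices of lysines expected to carry
#'   isopeptide branches.
#' @return a [SubstrateRecord-class] object.
#' @examples
#' SubstrateRecord("toy", "MKTAYIAKQR")
#' @export
SubstrateRecord <- function(id, sequence, segments = NULL,
                            anchorLysines = integer()) {
  sequence <- toupper(as.character(sequence))
  .assertAASequence(sequence, "substrate sequence")
  if (is.null(segments))
    segments <- data.frame(name = character(), start = integer(),
                           end = integer())
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  segments <- segments[order(segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  new("SubstrateRecord", id = as.character(id),
      sequence = AAString(sequence), segments = segments,
      anchorLysines = as.integer(anchorLysines))
}

#' @describeIn SubstrateRecord identifier accessor.
#' @param x a SubstrateRecord.
#' @export
substrateId <- function(x) x@id

#' @describeIn SubstrateRecord sequence accessor (plain character).
#' @export
substrateSeq <- function(x) as.character(x@sequence)

#' @describeIn SubstrateRecord sequence length in residues.
#' @export
substrateLength <- function(x) nchar(as.character(x@sequence))

#' @describeIn SubstrateRecord construct segment annotation table.
#' @export
segmentTable <- function(x) x@segments

#' @describeIn SubstrateRecord anchor lysine residue indices.
#' @export
anchorLysines <- function(x) x@anchorLysines

setMethod("show", "SubstrateRecord", function(object) {
  cat("SubstrateRecord:", object@id, "(", substrateLength(object), "aa )\n")
  if (nrow(object@segments))
    cat("  segments:", paste0(object@segments$name, "[",
        object@segments$start, "-", object@segments$end, "]",
        collapse = ", "), "\n")
  if (length(object@anchorLysines))
    cat("  anchor lysines:",
        paste0("K", object@anchorLysines, collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------

#' PeptideTable: identified peptides with PSM counts
#'
#' A table of peptide observations as produced by an upstream search engine:
#' one row per (sample, peptide sequence, branch) after ingest, with the
#' per-peptide "MS/MS count" (number of peptide-spectrum matches, PSMs).
#' Duplicate keys are summed on construction, because PSM counts are
#' additive evidence.
#'
#' @slot observations data.frame with columns \code{sample_id},
#'   \code{condition}, \code{replicate}, \code{sequence}, \code{psm_count},
#'   \code{branch_pos}, \code{branch_remnant} (the last two NA when the
#'   peptide is linear).
#' @slot provenance list recording the source file and column dialect.
#'
#' @aliases PeptideTable-class
#' @exportClass PeptideTable
setClass("PeptideTable",
  representation(observations = "data.frame", provenance = "list")
)

.PT_COLS <- c("sample_id", "condition", "replicate", "sequence",
              "psm_count", "branch_pos", "branch_remnant")

setValidity("PeptideTable", function(object) {
  obs <- object@observations
  msg <- character()
  if (!all(.PT_COLS %in% names(obs)))
    msg <- c(msg, paste("observations need columns:",
                        paste(.PT_COLS, collapse = ", ")))
  else {
    if (any(obs$psm_count < 0)) msg <- c(msg, "psm_count must be >= 0")
    key <- paste(obs$sample_id, obs$sequence, obs$branch_pos,
                 obs$branch_remnant, sep = "\r")
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (sample_id, sequence, branch) keys")
    hasb <- !is.na(obs$branch_pos)
    if (any(hasb)) {
      bp <- obs$branch_pos[hasb]
      sq <- obs$sequence[hasb]
      ok <- bp >= 1L & bp <= nchar(sq) & substring(sq, bp, bp) == "K"
      if (!all(ok))
        msg <- c(msg, "branch position must point at a K in the peptide")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PeptideTable
#'
#' Duplicate (sample, sequence, branch) rows are aggregated by summing PSM
#' counts; the number of merged rows is reported at message level.
#'
#' @param observations data.frame; required columns \code{sample_id},
#'   \code{condition}, \code{replicate}, \code{sequence}, \code{psm_count};
#'   optional \code{branch_pos}, \code{branch_remnant}.
#' @param provenance list describing the source (file, dialect).
#' @return a [PeptideTable-class].
#' @export
PeptideTable <- function(observations, provenance = list(source = NA,
                                                         dialect = "r")) {
  obs <- as.data.frame(observations)
  if (!"branch_pos" %in% names(obs))
    obs$branch_pos <- rep(NA_integer_, nrow(obs))
  if (!"branch_remnant" %in% names(obs))
    obs$branch_remnant <- rep(NA_character_, nrow(obs))
  need <- setdiff(.PT_COLS, names(obs))
  if (length(need))
    stop("missing peptide table columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  obs <- obs[.PT_COLS]
  obs$sample_id <- as.character(obs$sample_id)
  obs$condition <- as.character(obs$condition)
  obs$replicate <- as.integer(obs$replicate)
  obs$sequence <- toupper(as.character(obs$sequence))
  obs$psm_count <- as.numeric(obs$psm_count)
  obs$branch_pos <- as.integer(obs$branch_pos)
  obs$branch_remnant <- as.character(obs$branch_remnant)
  obs$branch_remnant[!is.na(obs$branch_remnant) &
                     !nzchar(obs$branch_remnant)] <- NA_character_
  obs$branch_remnant[is.na(obs$branch_pos)] <- NA_character_
  if (any(is.na(obs$psm_count)) || any(obs$psm_count < 0))
    stop("psm_count must be non-negative", call. = FALSE)
  key <- paste(obs$sample_id, obs$sequence, obs$branch_pos,
               obs$branch_remnant, sep = "\r")
  if (anyDuplicated(key)) {
    ndup <- nrow(obs) - length(unique(key))
    first <- !duplicated(key)
    agg <- rowsum(obs$psm_count, key, reorder = FALSE)
    merged <- obs[first, , drop = FALSE]
    merged$psm_count <- agg[match(key[first], rownames(agg)), 1L]
    obs <- merged
    message("PeptideTable: summed ", ndup, " duplicate observation row(s)")
  }
  rownames(obs) <- NULL
  new("PeptideTable", observations = obs, provenance = provenance)
}

#' @describeIn PeptideTable observation data.frame accessor.
#' @param x a PeptideTable.
#' @export
observations <- function(x) x@observations

#' @describeIn PeptideTable provenance accessor.
#' @export
provenance <- function(x) x@provenance

setMethod("show", "PeptideTable", function(object) {
  obs <- object@observations
  cat("PeptideTable:", nrow(obs), "observations,",
      length(unique(obs$sequence)), "distinct peptides,",
      length(unique(obs$sample_id)), "samples\n")
  cat("  conditions:", paste(unique(obs$condition), collapse = ", "), "\n")
  cat("  total PSMs:", sum(obs$psm_count), "; branched rows:",
      sum(!is.na(obs$branch_pos)), "\n")
})

# ---------------------------------------------------------------------------

#' DisorderTrack: per-residue intrinsic-disorder scores
#'
#' Per-residue disorder predictions for one protein (IUPRED-style, values in
#' [0, 1]).
#'
#' @slot proteinId single character identifier.
#' @slot scores numeric vector, one value per residue, in [0, 1].
#' @aliases DisorderTrack-class
#' @exportClass DisorderTrack
setClass("DisorderTrack",
  representation(proteinId = "character", scores = "numeric")
)

setValidity("DisorderTrack", function(object) {
  msg <- character()
  if (length(object@scores) == 0L) msg <- c(msg, "empty score track")
  if (any(is.na(object@scores)) ||
      any(object@scores < 0 | object@scores > 1))
    msg <- c(msg, "scores must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a DisorderTrack
#' @param proteinId identifier.
#' @param scores numeric per-residue scores in [0, 1].
#' @return a [DisorderTrack-class].
#' @export
DisorderTrack <- function(proteinId, scores) {
  new("DisorderTrack", proteinId = as.character(proteinId),
      scores = as.numeric(scores))
}

setMethod("show", "DisorderTrack", function(object) {
  cat("DisorderTrack:", object@proteinId, "(", length(object@scores),
      "residues, mean", round(mean(object@scores), 3), ")\n")
})

# ---------------------------------------------------------------------------

#' SiteUsageTable: integrated PSM counts per cleavage site
#'
#' Per-bond (P1) usage for one condition: the integrated MS/MS count of all
#' peptides whose N- or C-terminal boundary falls at each site. Sites with a
#' zero total are omitted from storage but treated as zero downstream.
#'
#' @slot substrateId substrate identifier.
#' @slot substrateLength substrate length in residues.
#' @slot condition condition label.
#' @slot usage data.frame with columns \code{site}, \code{count}.
#' @aliases SiteUsageTable-class
#' @exportClass SiteUsageTable
setClass("SiteUsageTable",
  representation(
    substrateId = "character",
    substrateLength = "integer",
    condition = "character",
    usage = "data.frame"
  )
)

setValidity("SiteUsageTable", function(object) {
  msg <- character()
  u <- object@usage
  if (!all(c("site", "count") %in% names(u)))
    msg <- c(msg, "usage needs columns site, count")
  else {
    if (any(u$site < 1L | u$site > object@substrateLength - 1L))
      msg <- c(msg, "sites must lie in [1, length-1]")
    if (any(u$count < 0)) msg <- c(msg, "counts must be >= 0")
    if (anyDuplicated(u$site)) msg <- c(msg, "duplicate sites")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SiteUsageTable usage data.frame (site, count), sorted by site.
#' @param x a SiteUsageTable.
#' @export
siteCounts <- function(x) x@usage

#' @describeIn SiteUsageTable condition label.
#' @export
conditionLabel <- function(x) x@condition

setMethod("show", "SiteUsageTable", function(object) {
  cat("SiteUsageTable:", object@substrateId, "/", object@condition, "-",
      nrow(object@usage), "used sites of", object@substrateLength - 1L,
      "; total integrated count", sum(object@usage$count), "\n")
})

# ---------------------------------------------------------------------------

#' HeatmapMatrix: filtered, normalized sample x peptide occupancy
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' peptide-by-sample occupancy matrix used for heatmap display: PSM counts
#' converted to counts-per-million (CPM) within each sample, then each
#' peptide rescaled to its maximum CPM so every retained peptide has maximum
#' exactly 1. Rows are peptides ordered by N-terminal residue (then length,
#' then sequence); columns are samples. Assays: \code{scaled} (values in
#' [0, 1]) and \code{cpm}. \code{rowData} carries peptide coordinates and
#' the per-peptide maximum CPM (the side bar-plot values);
#' \code{metadata(x)$filters} records the applied sample/peptide filters.
#'
#' @aliases HeatmapMatrix-class
#' @exportClass HeatmapMatrix
setClass("HeatmapMatrix", contains = "SummarizedExperiment")

setValidity("HeatmapMatrix", function(object) {
  msg <- character()
  if (!all(c("scaled", "cpm") %in% assayNames(object)))
    return("assays 'scaled' and 'cpm' required")
  sc <- assay(object, "scaled")
  if (nrow(sc)) {
    mx <- apply(sc, 1L, max)
    if (any(abs(mx - 1) > 1e-9))
      msg <- c(msg, "every retained peptide must have maximum scaled value 1")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn HeatmapMatrix per-peptide maximum CPM (bar-plot values).
#' @param x a HeatmapMatrix.
#' @export
peptideMaxima <- function(x) setNames(rowData(x)$max_cpm, rownames(x))

#' @describeIn HeatmapMatrix record of applied filters.
#' @export
filtersApplied <- function(x) metadata(x)$filters

# ---------------------------------------------------------------------------

#' PositionalFrequencyMatrix: weighted residue frequencies around P1
#'
#' Amino-acid frequencies at the positions flanking used cleavage sites
#' (P4..P1 on the non-prime side, P1'..P4' on the prime side for the default
#' span of 4). Frequencies at each populated position sum to 1; the
#' effective count weight per position records how much usage supports it.
#'
#' @slot frequencies numeric matrix, 20 residues x positions.
#' @slot effectiveWeight named numeric, total count weight per position.
#' @aliases PositionalFrequencyMatrix-class
#' @exportClass PositionalFrequencyMatrix
setClass("PositionalFrequencyMatrix",
  representation(frequencies = "matrix", effectiveWeight = "numeric")
)

setValidity("PositionalFrequencyMatrix", function(object) {
  f <- object@frequencies
  msg <- character()
  if (any(f < 0)) msg <- c(msg, "frequencies must be non-negative")
  cs <- colSums(f)
  pop <- object@effectiveWeight > 0
  if (any(abs(cs[pop] - 1) > 1e-9))
    msg <- c(msg, "frequencies at populated positions must sum to 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn PositionalFrequencyMatrix frequency matrix accessor.
#' @param x a PositionalFrequencyMatrix.
#' @export
frequencies <- function(x) x@frequencies

#' @describeIn PositionalFrequencyMatrix per-position effective weight.
#' @export
effectiveWeight <- function(x) x@effectiveWeight

setMethod("show", "PositionalFrequencyMatrix", function(object) {
  cat("PositionalFrequencyMatrix:",
      paste(colnames(object@frequencies), collapse = " "), "\n")
  cat("  effective weights:",
      paste(signif(object@effectiveWeight, 4), collapse = " "), "\n")
})

#' LogoMatrix: information-content sequence-logo heights
#'
#' Bit heights per (position, residue) in the Schneider-Stephens convention:
#' height = frequency x information content, where IC(pos) = log2(20) -
#' H(pos).
#'
#' @slot heights numeric matrix, residues x positions (bits).
#' @slot ic named numeric, per-position information content (bits).
#' @aliases LogoMatrix-class
#' @exportClass LogoMatrix
setClass("LogoMatrix",
  representation(heights = "matrix", ic = "numeric")
)

setValidity("LogoMatrix", function(object) {
  if (any(object@ic < -1e-9 | object@ic > log2(20) + 1e-9))
    return("information content must lie in [0, log2(20)]")
  TRUE
})

#' @describeIn LogoMatrix bit-height matrix accessor.
#' @param x a LogoMatrix.
#' @export
logoHeights <- function(x) x@heights

#' @describeIn LogoMatrix per-position information content (bits).
#' @export
informationBits <- function(x) x@ic

# ---------------------------------------------------------------------------

#' DigestionModel: parameters of the in-silico digestion simulator
#'
#' Generative model for non-tryptic, site-preferential digestion of a
#' substrate. Each digestion event draws a left and a right product boundary
#' (substrate termini or internal cleavage sites, sites weighted by
#' \code{siteWeights}) and is accepted when the product length falls within
#' \code{[lengthMin, lengthMax]}. Products shorter than
#' \code{detectionFloor} are censored from the observed table (the MS search
#' strategy does not identify very short peptides) but tracked. Replicate r
#' uses seed \code{seed + r}.
#'
#' @slot substrateId substrate the weights refer to.
#' @slot siteWeights non-negative numeric over sites 1..L-1.
#' @slot lengthMin,lengthMax product size window (residues).
#' @slot detectionFloor minimum observable product length (residues).
#' @slot depth number of accepted digestion events per replicate.
#' @slot nReplicates number of replicates.
#' @slot branchProb probability that a product covering an anchor lysine
#'   carries a ubiquitin remnant.
#' @slot remnantDistribution named probabilities over remnant sequences.
#' @slot seed base random seed.
#' @aliases DigestionModel-class
#' @exportClass DigestionModel
setClass("DigestionModel",
  representation(
    substrateId = "character",
    siteWeights = "numeric",
    lengthMin = "integer",
    lengthMax = "integer",
    detectionFloor = "integer",
    depth = "numeric",
    nReplicates = "integer",
    branchProb = "numeric",
    remnantDistribution = "numeric",
    seed = "integer"
  )
)

setValidity("DigestionModel", function(object) {
  msg <- character()
  if (any(object@siteWeights < 0)) msg <- c(msg, "site weights must be >= 0")
  if (!any(object@siteWeights > 0))
    msg <- c(msg, "at least one positive site weight required")
  if (object@lengthMin > object@lengthMax)
    msg <- c(msg, "lengthMin must be <= lengthMax")
  if (object@lengthMin < 1L) msg <- c(msg, "lengthMin must be >= 1")
  if (object@depth < 0) msg <- c(msg, "depth must be >= 0")
  if (object@branchProb < 0 || object@branchProb > 1)
    msg <- c(msg, "branchProb must be a probability")
  rd <- object@remnantDistribution
  if (length(rd) && abs(sum(rd) - 1) > 1e-9)
    msg <- c(msg, "remnant distribution must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a DigestionModel
#'
#' Defaults emulate a partial, non-tryptic proteasomal digest: product size
#' window 7-35 residues (a 20S-like regime; use 7-25 for a 26S-like one),
#' detection floor 7 residues, three replicates.
#'
#' @param substrate a [SubstrateRecord-class].
#' @param siteWeights non-negative weights over sites 1..L-1 (default
#'   uniform).
#' @param lengthMin,lengthMax product size window in residues.
#' @param detectionFloor minimum observable product length.
#' @param depth accepted digestion events per replicate.
#' @param nReplicates number of replicates.
#' @param branchProb per-event branch probability at anchor lysines.
#' @param remnantDistribution named probabilities over remnant sequences
#'   (canonical N-to-C orientation).
#' @param seed base seed; replicate r uses \code{seed + r}.
#' @return a [DigestionModel-class].
#' @export
digestionModel <- function(substrate, siteWeights = NULL,
                           lengthMin = 7L, lengthMax = 35L,
                           detectionFloor = 7L, depth = 5e4,
                           nReplicates = 3L, branchProb = 0,
                           remnantDistribution = c(GG = 0.5, RGG = 0.3,
                                                   LRGG = 0.2),
                           seed = 1L) {
  L <- substrateLength(substrate)
  if (is.null(siteWeights)) siteWeights <- rep(1, L - 1L)
  if (length(siteWeights) != L - 1L)
    stop("siteWeights must have length L-1 = ", L - 1L, call. = FALSE)
  new("DigestionModel", substrateId = substrateId(substrate),
      siteWeights = as.numeric(siteWeights),
      lengthMin = as.integer(lengthMin), lengthMax = as.integer(lengthMax),
      detectionFloor = as.integer(detectionFloor), depth = as.numeric(depth),
      nReplicates = as.integer(nReplicates),
      branchProb = as.numeric(branchProb),
      remnantDistribution = remnantDistribution, seed = as.integer(seed))
}

#' @describeIn DigestionModel site-weight accessor.
#' @param x a DigestionModel.
#' @export
siteWeights <- function(x) x@siteWeights

setMethod("show", "DigestionModel", function(object) {
  cat("DigestionModel on", object@substrateId, ":",
      length(object@siteWeights), "sites, length window",
      object@lengthMin, "-", object@lengthMax, ", floor",
      object@detectionFloor, "\n")
  cat("  depth", object@depth, "x", object@nReplicates,
      "replicates, branchProb", object@branchProb, ", seed", object@seed,
      "\n")
})
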