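#' Enumerate ubiquitin C-terminal remnants
#'
#' After proteolysis around an isopeptide bond, a suffix of ubiquitin's
#' C-terminus (...LRLRGG) can remain linked to the substrate lysine. This
#' enumerates one remnant per length: the C-terminal suffix of that length,
#' stored canonically N-to-C (e.g. \code{RGG}); the conventional outward
#' notation written from the lysine (e.g. \code{K--GGR}) is the reversed
#' string, reported as \code{notation_outward}. The default length range
#' 2-4 spans the commonly detected variants GG, RGG (GGR), LRGG (GGRL).
#'
#' @param ubiquitin a [SubstrateRecord-class] (or plain string) holding the
#'   ubiquitin sequence.
#' @param minLen,maxLen remnant length bounds in residues.
#' @return data.frame with columns \code{sequence}, \code{length},
#'   \code{mono_mass} (Da, sum of residue monoisotopic masses),
#'   \code{notation_outward}.
#' @examples
#' ub <- loadSubstrate(system.file("extdata", "ubiquitin_human.fasta",
#'                                 package = "degradomics"))
#' enumerateRemnants(ub, 2, 4)$sequence  # "GG" "RGG" "LRGG"
#' @export
enumerateRemnants <- function(ubiquitin, minLen = 2L, maxLen = 4L) {
  seqc <- if (is(ubiquitin, "SubstrateRecord")) substrateSeq(ubiquitin)
          else toupper(as.character(ubiquitin))
  L <- nchar(seqc)
  minLen <- as.integer(minLen); maxLen <- as.integer(maxLen)
  if (minLen < 1L || minLen > maxLen || maxLen > L)
    stop("need 1 <= minLen <= maxLen <= ubiquitin length (", L, ")",
         call. = FALSE)
  lens <- minLen:maxLen
  seqs <- substring(seqc, L - lens + 1L, L)
  data.frame(sequence = seqs, length = lens,
             mono_mass = vapply(seqs, remnantMass, 0, USE.NAMES = FALSE),
             notation_outward = .reverseString(seqs))
}

#' Monoisotopic mass of a remnant (added mass on the branch lysine)
#'
#' Sum of residue monoisotopic masses: an isopeptide-linked remnant adds
#' its residue masses to the lysine with no extra water. An empty remnant
#' has mass 0.
#'
#' @param remnant amino-acid string, N-to-C.
#' @param massTable named numeric residue mass table (defaults to the
#'   packaged monoisotopic table).
#' @return mass in Da.
#' @examples
#' remnantMass("GG")   # 114.04293
#' remnantMass("RGG")  # 270.14404
#' @export
remnantMass <- function(remnant, massTable = AA_MONO_MASS) {
  if (is.na(remnant) || !nzchar(remnant)) return(0)
  res <- strsplit(toupper(remnant), "")[[1]]
  bad <- setdiff(res, names(massTable))
  if (length(bad))
    stop("residue(s) not in mass table: ", paste(unique(bad),
         collapse = ", "), call. = FALSE)
  sum(massTable[res])
}

#' Convert between canonical and outward remnant notation
#'
#' The canonical orientation is N-to-C (\code{"RGG"}); the outward
#' notation writes the residues outward from the lysine (\code{"GGR"}). The
#' conversion is its own inverse (string reversal).
#'
#' @param x remnant string(s).
#' @return reversed string(s).
#' @export
outwardNotation <- function(x) .reverseString(toupper(x))

#' Validate and localize a reported branched (isopeptide) peptide
#'
#' A branched peptide is accepted as a genuine ubiquitin-remnant product
#' when (i) its remnant is a C-terminal suffix of ubiquitin, (ii) its base
#' peptide maps uniquely onto the substrate, and (iii) the branch position
#' lands on a declared anchor lysine. Invalid annotations carry a
#' machine-readable reason (\code{not-a-ubiquitin-suffix},
#' \code{unmapped}, \code{ambiguous}, \code{not-an-anchor}). A branch
#' position that does not point at a lysine is a validation error, not an
#' annotation.
#'
#' @param basePeptide peptide backbone sequence.
#' @param branchPos 1-based position of the branch lysine within the
#'   peptide.
#' @param remnant remnant sequence in canonical N-to-C orientation (use
#'   [outwardNotation()] to convert K-outward input).
#' @param substrate the [SubstrateRecord-class] with declared anchor
#'   lysines.
#' @param ubiquitin ubiquitin [SubstrateRecord-class].
#' @param ilEquivalence collapse I/L when mapping the base peptide.
#' @return list with \code{valid}, \code{reason} (NA when valid),
#'   \code{anchor_residue} (substrate index of the branch lysine),
#'   \code{start}, \code{end}, \code{remnant}, \code{remnant_mass},
#'   \code{substrate_id}.
#' @export
annotateBranchedPeptide <- function(basePeptide, branchPos, remnant,
                                    substrate, ubiquitin,
                                    ilEquivalence = FALSE) {
  basePeptide <- toupper(as.character(basePeptide))
  branchPos <- as.integer(branchPos)
  remnant <- toupper(as.character(remnant))
  if (branchPos < 1L || branchPos > nchar(basePeptide) ||
      substring(basePeptide, branchPos, branchPos) != "K")
    stop("branch position must point at a K in the peptide",
         call. = FALSE)
  res <- list(valid = FALSE, reason = NA_character_,
              anchor_residue = NA_integer_, start = NA_integer_,
              end = NA_integer_, remnant = remnant,
              remnant_mass = remnantMass(remnant),
              substrate_id = substrateId(substrate))
  ubSeq <- substrateSeq(ubiquitin)
  if (!nzchar(remnant) || !endsWith(ubSeq, remnant)) {
    res$reason <- "not-a-ubiquitin-suffix"
    return(res)
  }
  occ <- mapPeptide(basePeptide, substrate, ilEquivalence = ilEquivalence)
  if (nrow(occ) == 0L) { res$reason <- "unmapped"; return(res) }
  if (nrow(occ) > 1L) { res$reason <- "ambiguous"; return(res) }
  res$start <- occ$start; res$end <- occ$end
  res$anchor_residue <- occ$start + branchPos - 1L
  if (!res$anchor_residue %in% anchorLysines(substrate)) {
    res$reason <- "not-an-anchor"
    return(res)
  }
  res$valid <- TRUE
  res
}

#' Annotate all branched observations of a peptide table
#'
#' Applies [annotateBranchedPeptide()] to every observation carrying a
#' branch record.
#'
#' @param table a [PeptideTable-class].
#' @param substrate,ubiquitin as in [annotateBranchedPeptide()].
#' @param ilEquivalence collapse I/L when mapping.
#' @return data.frame, one row per branched observation, with the
#'   annotation fields plus \code{sample_id}, \code{sequence},
#'   \code{branch_pos}, \code{psm_count}.
#' @export
annotateBranchedTable <- function(table, substrate, ubiquitin,
                                  ilEquivalence = FALSE) {
  obs <- observations(table)
  obs <- obs[!is.na(obs$branch_pos), , drop = FALSE]
  if (nrow(obs) == 0L)
    return(data.frame(sample_id = character(), sequence = character(),
                      branch_pos = integer(), psm_count = numeric(),
                      valid = logical(), reason = character(),
                      anchor_residue = integer(), remnant = character(),
                      remnant_mass = numeric()))
  ann <- lapply(seq_len(nrow(obs)), function(i)
    annotateBranchedPeptide(obs$sequence[i], obs$branch_pos[i],
                            obs$branch_remnant[i], substrate, ubiquitin,
                            ilEquivalence = ilEquivalence))
  data.frame(sample_id = obs$sample_id, sequence = obs$sequence,
             branch_pos = obs$branch_pos, psm_count = obs$psm_count,
             valid = vapply(ann, `[[`, TRUE, "valid"),
             reason = vapply(ann, `[[`, "", "reason"),
             anchor_residue = vapply(ann, `[[`, 1L, "anchor_residue"),
             remnant = vapply(ann, `[[`, "", "remnant"),
             remnant_mass = vapply(ann, `[[`, 0, "remnant_mass"))
}

#' Classify a mapped interval against a fusion-construct map
#'
#' A peptide interval lying entirely inside one annotated segment is
#' \code{within_segment}; one overlapping two or more segments is
#' \code{chimeric} (junction-spanning, e.g. an epitope tag read through
#' into a ubiquitin unit); one touching no segment is \code{unannotated}.
#'
#' @param start,end 1-based inclusive interval on the construct.
#' @param substrate a [SubstrateRecord-class] whose \code{segmentTable}
#'   holds the construct map.
#' @return list with \code{class} (\code{within_segment}, \code{chimeric},
#'   or \code{unannotated}) and \code{segments} (overlapped segment names
#'   in construct order).
#' @export
classifyJunction <- function(start, end, substrate) {
  start <- as.integer(start); end <- as.integer(end)
  L <- substrateLength(substrate)
  if (start < 1L || start > end || end > L)
    stop("interval outside construct coordinates", call. = FALSE)
  seg <- segmentTable(substrate)
  hit <- seg$start <= end & seg$end >= start
  n <- sum(hit)
  if (n == 0L) return(list(class = "unannotated", segments = character()))
  if (n == 1L) return(list(class = "within_segment",
                           segments = seg$name[hit]))
  list(class = "chimeric", segments = seg$name[hit])
}
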