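#' Map a peptide onto a substrate sequence
#'
#' Finds all (possibly overlapping) occurrences of a peptide within a
#' substrate, optionally treating isoleucine and leucine as equivalent
#' (isobaric residues that many search engines cannot distinguish).
#'
#' @param sequence peptide amino-acid string.
#' @param substrate a [SubstrateRecord-class] or plain amino-acid string.
#' @param ilEquivalence collapse I and L before matching (default FALSE:
#'   upstream search engines already report a concrete sequence).
#' @return data.frame with columns \code{start}, \code{end}, one row per
#'   occurrence sorted by start; zero rows when the peptide does not occur.
#' @examples
#' mapPeptide("TAYI", SubstrateRecord("toy", "MKTAYIAKQR"))  # 3..6
#' mapPeptide("AA", SubstrateRecord("a4", "AAAA"))           # 3 overlaps
#' @export
mapPeptide <- function(sequence, substrate, ilEquivalence = FALSE) {
  subChar <- if (is(substrate, "SubstrateRecord")) substrateSeq(substrate)
             else toupper(as.character(substrate))
  sequence <- toupper(as.character(sequence))
  .assertAASequence(sequence, "peptide")
  if (ilEquivalence) {
    sequence <- chartr("I", "L", sequence)
    subChar <- chartr("I", "L", subChar)
  }
  if (nchar(sequence) > nchar(subChar))
    return(data.frame(start = integer(), end = integer()))
  m <- matchPattern(sequence, AAString(subChar))
  data.frame(start = Biostrings::start(m), end = Biostrings::end(m))
}

#' Derive the bounding cleavage sites of a mapped peptide
#'
#' A product spanning residues \code{start..end} is evidence for a cleavage
#' N-terminal to it (site \code{start - 1}, absent when the product begins
#' at the substrate N-terminus) and one C-terminal to it (site \code{end},
#' absent when it runs to the substrate C-terminus).
#'
#' @param start,end 1-based inclusive residue coordinates (vectorized).
#' @param substrateLength substrate length in residues.
#' @return data.frame with columns \code{n_term_site}, \code{c_term_site}
#'   (NA where the terminus coincides with a substrate end).
#' @examples
#' deriveSites(3, 6, 10)   # sites 2 and 6
#' deriveSites(1, 10, 10)  # full-length species: no internal cleavage
#' @export
deriveSites <- function(start, end, substrateLength) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L | start > end | end > substrateLength))
    stop("coordinates must satisfy 1 <= start <= end <= substrate length",
         call. = FALSE)
  data.frame(
    n_term_site = ifelse(start == 1L, NA_integer_, start - 1L),
    c_term_site = ifelse(end == substrateLength, NA_integer_, end)
  )
}

#' Map every peptide of a table onto a substrate
#'
#' Builds a per-distinct-sequence mapping index: occurrence count, the
#' (unique) coordinates, ambiguity flag, and the derived bounding cleavage
#' sites. Peptides occurring more than once are flagged \code{ambiguous}
#' (coordinates reported for the first occurrence) and are excluded from
#' site-count integration by default; peptides not found at all are flagged
#' unmapped, not an error (they may derive from other proteins).
#'
#' @param table a [PeptideTable-class] or character vector of sequences.
#' @param substrate a [SubstrateRecord-class].
#' @param ilEquivalence collapse I/L before matching.
#' @return data.frame with one row per distinct sequence: \code{sequence},
#'   \code{n_occ}, \code{mapped}, \code{ambiguous}, \code{start},
#'   \code{end}, \code{n_term_site}, \code{c_term_site}. Carries the
#'   substrate id as attribute \code{substrate_id}.
#' @export
mapPeptides <- function(table, substrate, ilEquivalence = FALSE) {
  seqs <- if (is(table, "PeptideTable"))
    sort(unique(observations(table)$sequence)) else sort(unique(table))
  subChar <- substrateSeq(substrate)
  L <- nchar(subChar)
  target <- if (ilEquivalence) chartr("I", "L", subChar) else subChar
  query <- if (ilEquivalence) chartr("I", "L", seqs) else seqs
  # exhaustive overlapping-occurrence scan via a per-length substring index
  n_occ <- integer(length(seqs))
  start <- rep(NA_integer_, length(seqs))
  for (len in unique(nchar(query))) {
    if (len < 1L || len > L) next
    starts <- seq_len(L - len + 1L)
    subs <- substring(target, starts, starts + len - 1L)
    sel <- which(nchar(query) == len)
    for (i in sel) {
      hit <- starts[subs == query[i]]
      n_occ[i] <- length(hit)
      if (length(hit)) start[i] <- hit[1L]
    }
  }
  end <- start + nchar(seqs) - 1L
  out <- data.frame(sequence = seqs, n_occ = n_occ, mapped = n_occ > 0L,
                    ambiguous = n_occ > 1L, start = start, end = end,
                    n_term_site = NA_integer_, c_term_site = NA_integer_)
  ok <- out$n_occ == 1L
  if (any(ok)) {
    ds <- deriveSites(out$start[ok], out$end[ok], L)
    out$n_term_site[ok] <- ds$n_term_site
    out$c_term_site[ok] <- ds$c_term_site
  }
  if (any(out$ambiguous))
    message("mapPeptides: ", sum(out$ambiguous),
            " multi-mapping peptide(s) flagged ambiguous")
  if (any(!out$mapped))
    message("mapPeptides: ", sum(!out$mapped),
            " peptide(s) did not map to ", substrateId(substrate))
  attr(out, "substrate_id") <- substrateId(substrate)
  attr(out, "substrate_length") <- L
  attr(out, "il_equivalence") <- ilEquivalence
  out
}

#' Replicate-presence filter
#'
#' Retains a peptide species within a condition only when it was identified
#' (PSM count >= 1) in at least \code{minReplicates} replicates of that
#' condition -- the "2 of 3 replicates" rule for in vitro digests; set
#' \code{minReplicates = 1} for the permissive in vivo variant. Retained
#' observations keep their original counts. Peptide species are keyed by
#' (sequence, branch), so a branched peptide is filtered independently of
#' its linear counterpart.
#'
#' @param table a [PeptideTable-class].
#' @param minReplicates minimum number of replicates (default 2).
#' @return a filtered [PeptideTable-class] (subset of the input).
#' @export
filterReplicates <- function(table, minReplicates = 2L) {
  obs <- observations(table)
  minReplicates <- as.integer(minReplicates)
  if (minReplicates < 1L) stop("minReplicates must be >= 1", call. = FALSE)
  if (nrow(obs) == 0L) return(table)
  nrep <- vapply(split(obs$replicate, obs$condition),
                 function(r) length(unique(r)), 1L)
  if (any(minReplicates > nrep))
    stop("minReplicates (", minReplicates, ") exceeds the number of ",
         "replicates in condition(s): ",
         paste(names(nrep)[minReplicates > nrep], collapse = ", "),
         call. = FALSE)
  species <- paste(obs$sequence, obs$branch_pos, obs$branch_remnant,
                   sep = "\r")
  key <- paste(obs$condition, species, sep = "\r")
  present <- obs$psm_count >= 1
  reps <- tapply(obs$replicate[present], key[present],
                 function(r) length(unique(r)))
  nsupport <- reps[key]
  nsupport[is.na(nsupport)] <- 0L
  keep <- nsupport >= minReplicates
  message("filterReplicates: kept ", sum(keep), " of ", nrow(obs),
          " observation row(s) at >=", minReplicates, " replicates")
  out <- obs[keep, , drop = FALSE]
  rownames(out) <- NULL
  new("PeptideTable", observations = out,
      provenance = c(provenance(table),
                     list(replicate_filter = minReplicates)))
}
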