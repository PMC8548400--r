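#' Load a substrate sequence from a FASTA file
#'
#' Reads one record from a (possibly multi-record) FASTA file into a
#' [SubstrateRecord-class]. Lowercase input is upcased; non-canonical
#' letters raise a format error.
#'
#' @param path FASTA file.
#' @param name optional record name to select from a multi-record file
#'   (matched against the first whitespace-delimited token of the header);
#'   required when the file holds more than one record.
#' @param segments optional segment annotation data.frame (columns
#'   \code{name}, \code{start}, \code{end}).
#' @param anchorLysines integer indices of branch-carrying lysines.
#' @return a [SubstrateRecord-class].
#' @examples
#' fa <- system.file("extdata", "ubiquitin_human.fasta",
#'                   package = "degradomics")
#' ub <- loadSubstrate(fa)
#' substrateLength(ub)  # 76
#' @export
loadSubstrate <- function(path, name = NULL, segments = NULL,
                          anchorLysines = integer()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (is.null(name)) {
    if (length(set) > 1L)
      stop("multi-record FASTA; select a record with `name` (available: ",
           paste(ids, collapse = ", "), ")", call. = FALSE)
    i <- 1L
  } else {
    i <- match(name, ids)
    if (is.na(i))
      stop("record '", name, "' not found (available: ",
           paste(ids, collapse = ", "), ")", call. = FALSE)
  }
  SubstrateRecord(ids[i], as.character(set[[i]]), segments = segments,
                  anchorLysines = anchorLysines)
}

#' Load an identified-peptide table
#'
#' Reads a tab-separated peptide table into a [PeptideTable-class].
#' Two column dialects are supported:
#' \describe{
#'   \item{generic}{columns \code{sample_id}, \code{condition},
#'     \code{replicate}, \code{peptide}, \code{psm_count}, and optionally
#'     \code{branch_pos} / \code{branch_remnant} (remnant written N-to-C).}
#'   \item{maxquant}{a MaxQuant \code{peptides.txt}-style layout with
#'     columns \code{Sequence}, \code{MS/MS Count} and \code{Experiment};
#'     the experiment label is used as the sample id, and a trailing
#'     \code{_<number>} suffix (if present) is split into condition and
#'     replicate.}
#' }
#' Duplicate (sample, sequence, branch) rows are summed; dropped and merged
#' row counts are reported at message level. An empty data section yields an
#' empty table with a warning, not an error.
#'
#' @param path TSV file.
#' @param dialect \code{"generic"} (default) or \code{"maxquant"}.
#' @return a [PeptideTable-class].
#' @export
loadPeptides <- function(path, dialect = c("generic", "maxquant")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.delim(path, check.names = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (dialect == "generic") {
    need <- c("sample_id", "condition", "replicate", "peptide", "psm_count")
    miss <- setdiff(need, names(raw))
    if (length(miss))
      stop("missing required column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (nrow(raw) == 0L) {
      warning("peptide table has an empty data section: ", path)
      obs <- data.frame(sample_id = character(), condition = character(),
                        replicate = integer(), sequence = character(),
                        psm_count = numeric())
    } else {
      obs <- data.frame(sample_id = raw$sample_id,
                        condition = raw$condition,
                        replicate = raw$replicate,
                        sequence = raw$peptide,
                        psm_count = raw$psm_count)
      if ("branch_pos" %in% names(raw)) obs$branch_pos <- raw$branch_pos
      if ("branch_remnant" %in% names(raw))
        obs$branch_remnant <- toupper(as.character(raw$branch_remnant))
    }
  } else {
    need <- c("Sequence", "MS/MS Count", "Experiment")
    miss <- setdiff(need, names(raw))
    if (length(miss))
      stop("missing required MaxQuant column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    if (nrow(raw) == 0L) {
      warning("peptide table has an empty data section: ", path)
      obs <- data.frame(sample_id = character(), condition = character(),
                        replicate = integer(), sequence = character(),
                        psm_count = numeric())
    } else {
      exper <- as.character(raw$Experiment)
      hasrep <- grepl("_[0-9]+$", exper)
      cond <- ifelse(hasrep, sub("_[0-9]+$", "", exper), exper)
      repl <- rep(1L, length(exper))
      repl[hasrep] <- as.integer(sub("^.*_", "", exper[hasrep]))
      obs <- data.frame(sample_id = exper, condition = cond,
                        replicate = repl, sequence = raw$Sequence,
                        psm_count = raw[["MS/MS Count"]])
    }
  }
  if (nrow(obs) && any(obs$psm_count < 0, na.rm = TRUE))
    stop("negative psm_count in ", path, call. = FALSE)
  keep <- if (nrow(obs)) !is.na(obs$sequence) & nzchar(obs$sequence) &
                         !is.na(obs$psm_count) else logical(0)
  if (any(!keep))
    message("loadPeptides: dropped ", sum(!keep), " incomplete row(s)")
  message("loadPeptides: read ", sum(keep), " observation row(s) from ",
          basename(path))
  PeptideTable(obs[keep, , drop = FALSE],
               provenance = list(source = path, dialect = dialect))
}

#' Load per-residue disorder score tracks
#'
#' Reads an IUPRED-style long-format TSV with columns \code{protein_id},
#' \code{residue_index}, \code{score} into a list of
#' [DisorderTrack-class] objects (one per protein, ordered by residue
#' index).
#'
#' @param path TSV file.
#' @return named list of [DisorderTrack-class].
#' @export
loadDisorderTracks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.delim(path, check.names = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  need <- c("protein_id", "residue_index", "score")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(raw, raw$protein_id), function(d) {
    d <- d[order(d$residue_index), , drop = FALSE]
    DisorderTrack(d$protein_id[1L], d$score)
  })
  out[order(names(out))]
}

#' Write an analysis result table as TSV
#'
#' Writes a data.frame with a deterministic column order, floats at 6
#' significant digits, NA serialized as \code{"NA"}, and the active
#' configuration echoed into '#'-prefixed header comment lines so every
#' output records how it was produced. Round-trips through
#' [readResultTable()].
#'
#' @param result a data.frame (or object coercible to one).
#' @param path output file.
#' @param config optional named list echoed as \code{# key: value} comments.
#' @return invisibly, the path.
#' @export
writeResultTable <- function(result, path, config = NULL) {
  df <- as.data.frame(result)
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], signif, digits = 6L)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(config))
    writeLines(paste0("# ", names(config), ": ",
                      vapply(config, function(v)
                        paste(format(v), collapse = ","), "")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a result table written by [writeResultTable()]
#'
#' @param path TSV file with optional '#' comment header.
#' @return data.frame.
#' @export
readResultTable <- function(path) {
  read.delim(path, comment.char = "#", check.names = FALSE,
             stringsAsFactors = FALSE)
}
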