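#' Product-length distribution summary
#'
#' Boxplot-convention summary of peptide product lengths within a
#' condition: first and third quartiles and median by type-7 linear
#' interpolation, whiskers at the most extreme points within 1.5x the
#' interquartile range of the quartiles. By default each distinct peptide
#' species counts once (\code{per_peptide}); \code{per_psm} weights each
#' length by its total PSM count.
#'
#' @param table a [PeptideTable-class].
#' @param condition condition label.
#' @param weighting \code{"per_peptide"} (default) or \code{"per_psm"}.
#' @return one-row data.frame: \code{condition}, \code{n}, \code{mean},
#'   \code{median}, \code{q1}, \code{q3}, \code{whisker_low},
#'   \code{whisker_high}.
#' @export
summarizeLengths <- function(table, condition,
                             weighting = c("per_peptide", "per_psm")) {
  weighting <- match.arg(weighting)
  x <- peptideLengths(table, condition, weighting)
  if (length(x) == 0L)
    stop("no peptides in condition '", condition, "'", call. = FALSE)
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3L] - q[1L]
  data.frame(condition = condition, n = length(x), mean = mean(x),
             median = q[2L], q1 = q[1L], q3 = q[3L],
             whisker_low = min(x[x >= q[1L] - 1.5 * iqr]),
             whisker_high = max(x[x <= q[3L] + 1.5 * iqr]))
}

#' Per-peptide product lengths of one condition
#'
#' @inheritParams summarizeLengths
#' @return numeric vector of lengths (residues); with \code{per_psm} each
#'   length is repeated by its summed PSM count.
#' @export
peptideLengths <- function(table, condition,
                           weighting = c("per_peptide", "per_psm")) {
  weighting <- match.arg(weighting)
  obs <- observations(table)
  obs <- obs[obs$condition == condition & obs$psm_count > 0, , drop = FALSE]
  if (nrow(obs) == 0L) return(numeric(0))
  tot <- rowsum(obs$psm_count, obs$sequence)
  len <- nchar(rownames(tot))
  if (weighting == "per_peptide") len else rep(len, round(tot[, 1L]))
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two samples. The exact null distribution is used
#' when both samples have at most 8 observations and there are no ties;
#' otherwise the normal approximation with tie and continuity correction is
#' applied. Two all-identical samples yield p = 1.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with \code{U}, \code{p_value}, and \code{exact} (logical).
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mannWhitneyU <- function(x, y) {
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  if (length(unique(c(x, y))) == 1L)
    return(list(U = length(x) * length(y) / 2, p_value = 1, exact = FALSE))
  exact <- length(x) <= 8L && length(y) <= 8L &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE,
                                     alternative = "two.sided"))
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Welch two-sample t test (two-sided)
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom.
#'
#' @param x,y numeric samples with at least 2 observations each.
#' @return list with \code{t}, \code{df}, \code{p_value}.
#' @export
welchT <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("need n >= 2 per sample", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("zero variance in both samples: t statistic undefined",
         call. = FALSE)
  wt <- t.test(x, y, var.equal = FALSE)
  list(t = unname(wt$statistic), df = unname(wt$parameter),
       p_value = wt$p.value)
}

#' Mean per-protein disorder score
#'
#' The protein's disorder score is the arithmetic mean of its per-residue
#' disorder predictions (IUPRED convention, values in [0, 1]).
#'
#' @param track a [DisorderTrack-class].
#' @return list with \code{protein_id}, \code{score}, \code{n_residues}.
#' @export
meanDisorder <- function(track) {
  stopifnot(is(track, "DisorderTrack"))
  list(protein_id = track@proteinId, score = mean(track@scores),
       n_residues = length(track@scores))
}

#' Proteins with peptide evidence unique to each condition
#'
#' From per-condition protein assignments (each protein listed for a
#' condition when at least one retained peptide maps to it), computes the
#' set of proteins unique to each condition: evidence there and in no other
#' condition. Typical downstream use compares the mean disorder scores of
#' the unique sets with [welchT()] or [mannWhitneyU()].
#'
#' @param assignments data.frame with columns \code{condition},
#'   \code{protein_id}.
#' @return named list (one element per condition) of unique protein-id
#'   vectors, sorted.
#' @export
uniqueConditionProteins <- function(assignments) {
  stopifnot(all(c("condition", "protein_id") %in% names(assignments)))
  sets <- lapply(split(assignments$protein_id, assignments$condition),
                 unique)
  out <- lapply(names(sets), function(cond) {
    others <- unique(unlist(sets[setdiff(names(sets), cond)]))
    sort(setdiff(sets[[cond]], others))
  })
  names(out) <- names(sets)
  out
}
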