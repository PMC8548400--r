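.positionLabels <- function(span) {
  c(paste0("P", span:1), paste0("P", 1:span, "p"))
}

#' Extract residue windows around used cleavage sites
#'
#' For each used site j, takes the window of residues \code{(j-span+1) ..
#' (j+span)} -- the standard protease-nomenclature frame P\{span\}..P1 on
#' the non-prime side and P1'..P\{span\}' on the prime side (P1 is residue
#' j, immediately N-terminal to the cleaved bond). Positions that fall off
#' either terminus are marked absent (NA) and are excluded from that
#' position's denominator downstream. Each window carries the site's
#' integrated count as weight, so composition reflects usage.
#'
#' @param usage a [SiteUsageTable-class].
#' @param substrate the matching [SubstrateRecord-class].
#' @param span window half-width in residues (default 4: P4..P4').
#' @param unweighted give every used site weight 1 instead of its count.
#' @return data.frame with columns \code{site}, \code{weight}, then one
#'   character column per position label (NA when off-terminus).
#' @export
extractWindows <- function(usage, substrate, span = 4L, unweighted = FALSE) {
  if (usage@substrateId != substrateId(substrate))
    stop("usage table and substrate disagree", call. = FALSE)
  span <- as.integer(span)
  seqc <- substrateSeq(substrate)
  L <- nchar(seqc)
  u <- siteCounts(usage)
  labels <- .positionLabels(span)
  out <- data.frame(site = u$site,
                    weight = if (unweighted) rep(1, nrow(u)) else u$count)
  offsets <- c(-(span - 1L):0L, 1L:span)  # residue = site + offset
  for (i in seq_along(labels)) {
    pos <- u$site + offsets[i]
    res <- ifelse(pos >= 1L & pos <= L, substring(seqc, pos, pos),
                  NA_character_)
    out[[labels[i]]] <- res
  }
  out
}

#' Weighted positional amino-acid frequency matrix
#'
#' @param windows window table from [extractWindows()].
#' @return a [PositionalFrequencyMatrix-class]: per-position frequencies
#'   over the 20 canonical residues (columns sum to 1 at populated
#'   positions) and per-position effective count weight.
#' @export
frequencyMatrix <- function(windows) {
  if (nrow(windows) == 0L)
    stop("no windows: cannot build a frequency matrix", call. = FALSE)
  posCols <- setdiff(names(windows), c("site", "weight"))
  freq <- matrix(0, nrow = length(AA20), ncol = length(posCols),
                 dimnames = list(AA20, posCols))
  ew <- setNames(numeric(length(posCols)), posCols)
  for (p in posCols) {
    ok <- !is.na(windows[[p]])
    if (!any(ok)) next
    w <- rowsum(windows$weight[ok], windows[[p]][ok])
    ew[p] <- sum(w)
    if (ew[p] > 0) freq[rownames(w), p] <- w[, 1L] / ew[p]
  }
  new("PositionalFrequencyMatrix", frequencies = freq, effectiveWeight = ew)
}

#' Information-content logo matrix (Schneider-Stephens)
#'
#' Per-position information content \code{IC = log2(20) - H}, where
#' \code{H = -sum(f * log2 f)} is the Shannon entropy of the residue
#' frequencies; bit heights are \code{frequency x IC}. No small-sample
#' correction is applied by default; the correction subtracts the
#' approximate bias \code{(20 - 1) / (2 ln(2) n)} with n the position's
#' effective weight.
#'
#' @param freqs a [PositionalFrequencyMatrix-class].
#' @param smallSampleCorrection apply the small-sample bias correction.
#' @return a [LogoMatrix-class].
#' @export
informationContent <- function(freqs, smallSampleCorrection = FALSE) {
  f <- frequencies(freqs)
  H <- apply(f, 2L, function(p) {
    p <- p[p > 0]
    if (!length(p)) return(log2(20))  # unpopulated: zero IC
    -sum(p * log2(p))
  })
  ic <- log2(20) - H
  if (smallSampleCorrection) {
    n <- effectiveWeight(freqs)
    corr <- ifelse(n > 0, (length(AA20) - 1) / (2 * log(2) * n), 0)
    ic <- pmax(ic - corr, 0)
  }
  heights <- sweep(f, 2L, ic, "*")
  new("LogoMatrix", heights = heights, ic = ic)
}

#' Differential composition between two conditions
#'
#' Per (position, residue) signed frequency difference between two
#' positional frequency matrices, with a per-position chi-square test on
#' the weighted counts (residue categories with expected count < 1 are
#' pooled before the test). Identical inputs give all-zero differences and
#' p = 1.
#'
#' @param freqsA,freqsB [PositionalFrequencyMatrix-class] objects sharing
#'   the same positions.
#' @return list with \code{difference} (residues x positions matrix of
#'   \code{f_A - f_B}), \code{p_value}, \code{statistic} and \code{df} per
#'   position.
#' @export
differentialLogo <- function(freqsA, freqsB) {
  fa <- frequencies(freqsA); fb <- frequencies(freqsB)
  if (!identical(dimnames(fa), dimnames(fb)))
    stop("frequency matrices must share positions and residue order",
         call. = FALSE)
  wa <- effectiveWeight(freqsA); wb <- effectiveWeight(freqsB)
  positions <- colnames(fa)
  diffm <- fa - fb
  stat <- pval <- dfree <- setNames(rep(NA_real_, length(positions)),
                                    positions)
  for (p in positions) {
    ca <- fa[, p] * wa[p]
    cb <- fb[, p] * wb[p]
    keep <- (ca + cb) > 0
    if (wa[p] == 0 || wb[p] == 0 || !any(keep)) next
    tab <- rbind(a = ca[keep], b = cb[keep])
    res <- .chisqPooled(tab)
    stat[p] <- res$statistic; pval[p] <- res$p_value; dfree[p] <- res$df
  }
  list(difference = diffm, p_value = pval, statistic = stat, df = dfree)
}

# Pearson chi-square on a 2 x K table of (possibly fractional) counts,
# pooling columns whose smaller expected count is < 1 into one category.
.chisqPooled <- function(tab) {
  expected <- function(t) outer(rowSums(t), colSums(t)) / sum(t)
  e <- expected(tab)
  small <- apply(e, 2L, min) < 1
  if (sum(small) > 1L) {
    pooled <- rowSums(tab[, small, drop = FALSE])
    tab <- cbind(tab[, !small, drop = FALSE], pooled = pooled)
  }
  K <- ncol(tab)
  if (K < 2L || sum(tab) == 0)
    return(list(statistic = 0, df = 0L, p_value = 1))
  e <- expected(tab)
  x2 <- sum((tab - e)^2 / e)
  df <- K - 1L
  list(statistic = x2, df = df,
       p_value = pchisq(x2, df, lower.tail = FALSE))
}
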