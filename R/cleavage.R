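#' Integrate PSM counts into per-site (P1) usage
#'
#' Each unambiguously mapped peptide contributes its summed PSM count to
#' both of its bounding cleavage sites (N-terminal and C-terminal, where
#' defined): every internal product is evidence of two cleavage events. An
#' N-terminus-only crediting mode is provided for sensitivity analysis.
#' Ambiguous (multi-mapping) peptides are excluded by default; with
#' \code{includeAmbiguous = TRUE} each occurrence receives the fractional
#' count 1/k.
#'
#' @param table a [PeptideTable-class] (replicate-filtered upstream).
#' @param mapping mapping index from [mapPeptides()] for the same
#'   substrate.
#' @param substrate the [SubstrateRecord-class] the mapping refers to.
#' @param condition condition label to integrate (one condition per call).
#' @param credit \code{"both"} (default) or \code{"nterm"}.
#' @param includeAmbiguous include multi-mapping peptides at fractional
#'   count 1/k per occurrence.
#' @return a [SiteUsageTable-class]; sites with zero totals are omitted
#'   from storage but treated as zero downstream.
#' @export
integrateSiteCounts <- function(table, mapping, substrate, condition,
                                credit = c("both", "nterm"),
                                includeAmbiguous = FALSE) {
  credit <- match.arg(credit)
  if (!identical(attr(mapping, "substrate_id"), substrateId(substrate)))
    stop("mapping was built for substrate '", attr(mapping, "substrate_id"),
         "', not '", substrateId(substrate), "'", call. = FALSE)
  L <- substrateLength(substrate)
  obs <- observations(table)
  obs <- obs[obs$condition == condition, , drop = FALSE]
  counts <- rowsum(obs$psm_count, obs$sequence)
  perSeq <- data.frame(sequence = rownames(counts), count = counts[, 1L])
  m <- merge(perSeq, mapping, by = "sequence")
  site <- numeric(0); w <- numeric(0)
  uniq <- m[!m$ambiguous & m$mapped, , drop = FALSE]
  if (nrow(uniq)) {
    site <- c(site, uniq$n_term_site, if (credit == "both")
      uniq$c_term_site)
    w <- c(w, uniq$count, if (credit == "both") uniq$count)
  }
  if (includeAmbiguous && any(m$ambiguous)) {
    amb <- m[m$ambiguous, , drop = FALSE]
    for (i in seq_len(nrow(amb))) {
      occ <- mapPeptide(amb$sequence[i], substrate,
                        ilEquivalence = isTRUE(attr(mapping,
                                                    "il_equivalence")))
      ds <- deriveSites(occ$start, occ$end, L)
      frac <- amb$count[i] / nrow(occ)
      site <- c(site, ds$n_term_site,
                if (credit == "both") ds$c_term_site)
      w <- c(w, rep(frac, nrow(occ)),
             if (credit == "both") rep(frac, nrow(occ)))
    }
  }
  keep <- !is.na(site)
  usage <- if (any(keep)) {
    agg <- rowsum(w[keep], site[keep])
    data.frame(site = as.integer(rownames(agg)), count = agg[, 1L])
  } else data.frame(site = integer(), count = numeric())
  usage <- usage[usage$count > 0, , drop = FALSE]
  usage <- usage[order(usage$site), , drop = FALSE]
  rownames(usage) <- NULL
  new("SiteUsageTable", substrateId = substrateId(substrate),
      substrateLength = L, condition = as.character(condition),
      usage = usage)
}

#' Relative cleavage preference between two conditions
#'
#' For every cleavage site, computes log2 of the ratio of integrated counts
#' between condition A and condition B. Sites with a zero count in one
#' condition take the pseudo-value (0.1 by default) in the ratio; sites
#' zero in both conditions are reported as NA rather than log2(0.1/0.1) =
#' 0, to avoid fabricating "no preference" at unobserved sites. A site is
#' called \code{prefer_a} when the log2 ratio exceeds
#' \code{log2(foldThreshold)} (greater-than-twofold by default),
#' \code{prefer_b} below the negative threshold, \code{none} between, and
#' \code{na} when unobserved. The statistic is antisymmetric under argument
#' swap.
#'
#' @param usageA,usageB [SiteUsageTable-class] objects for the same
#'   substrate (e.g., 20S and 26S conditions).
#' @param pseudoValue value substituted for a zero count (default 0.1).
#' @param foldThreshold fold-change call threshold (default 2).
#' @return data.frame with one row per site 1..L-1: \code{site},
#'   \code{value_a}, \code{value_b}, \code{log2_ratio}, \code{call}.
#' @export
computePreference <- function(usageA, usageB, pseudoValue = 0.1,
                              foldThreshold = 2) {
  if (pseudoValue <= 0) stop("pseudoValue must be > 0", call. = FALSE)
  if (foldThreshold <= 0) stop("foldThreshold must be > 0", call. = FALSE)
  if (usageA@substrateId != usageB@substrateId ||
      usageA@substrateLength != usageB@substrateLength)
    stop("usage tables refer to different substrates", call. = FALSE)
  L <- usageA@substrateLength
  sites <- seq_len(L - 1L)
  va <- vb <- numeric(L - 1L)
  ua <- siteCounts(usageA); ub <- siteCounts(usageB)
  va[ua$site] <- ua$count
  vb[ub$site] <- ub$count
  defined <- va > 0 | vb > 0
  ra <- ifelse(va == 0, pseudoValue, va)
  rb <- ifelse(vb == 0, pseudoValue, vb)
  log2r <- ifelse(defined, log2(ra / rb), NA_real_)
  thr <- log2(foldThreshold)
  call <- rep("na", L - 1L)
  call[defined] <- "none"
  call[defined & log2r > thr] <- "prefer_a"
  call[defined & log2r < -thr] <- "prefer_b"
  data.frame(site = sites, value_a = va, value_b = vb, log2_ratio = log2r,
             call = call)
}

#' Build the filtered, normalized sample x peptide heatmap matrix
#'
#' Converts PSM counts into a peptide-by-sample occupancy matrix:
#' (i) samples whose total mapped PSM count is below \code{minSamplePsms}
#' (50 by default) are discarded; (ii) peptides observed in only a single
#' retained sample are discarded; (iii) counts are normalized to
#' counts-per-million (CPM) within each sample; (iv) each peptide row is
#' rescaled to its maximum CPM, so every retained peptide has maximum
#' exactly 1 and the per-peptide maxima are retained as the side bar-plot
#' values. Rows are ordered by the peptide's N-terminal residue, then
#' length, then sequence; only unambiguously mapped peptides are used.
#'
#' @param table a [PeptideTable-class].
#' @param mapping mapping index from [mapPeptides()].
#' @param minSamplePsms minimum raw mapped-PSM total per sample.
#' @return a [HeatmapMatrix-class].
#' @export
buildHeatmap <- function(table, mapping, minSamplePsms = 50L) {
  obs <- observations(table)
  m <- mapping[!mapping$ambiguous & mapping$mapped, , drop = FALSE]
  obs <- obs[obs$sequence %in% m$sequence, , drop = FALSE]
  if (nrow(obs) == 0L)
    stop("no unambiguously mapped peptide observations", call. = FALSE)
  samples <- sort(unique(obs$sample_id))
  counts <- matrix(0, nrow = nrow(m), ncol = length(samples),
                   dimnames = list(m$sequence, samples))
  idx <- cbind(match(obs$sequence, m$sequence),
               match(obs$sample_id, samples))
  agg <- rowsum(obs$psm_count, paste(idx[, 1L], idx[, 2L]))
  ij <- do.call(rbind, lapply(strsplit(rownames(agg), " "), as.integer))
  counts[ij] <- agg[, 1L]
  totals <- colSums(counts)
  keepSample <- totals >= minSamplePsms
  if (!any(keepSample))
    stop("all samples fell below the ", minSamplePsms,
         "-PSM floor (totals: ", paste(totals, collapse = ", "), ")",
         call. = FALSE)
  nSampleDropped <- sum(!keepSample)
  counts <- counts[, keepSample, drop = FALSE]
  totals <- totals[keepSample]
  support <- rowSums(counts > 0)
  keepPep <- support >= 2L
  nPepDropped <- sum(!keepPep)
  counts <- counts[keepPep, , drop = FALSE]
  if (nrow(counts) == 0L)
    stop("no peptide observed in more than one retained sample",
         call. = FALSE)
  m <- m[keepPep, , drop = FALSE]
  cpm <- sweep(counts, 2L, totals, "/") * 1e6
  maxima <- apply(cpm, 1L, max)
  scaled <- cpm / maxima
  ord <- order(m$start, m$end - m$start, m$sequence)
  meta <- obs[!duplicated(obs$sample_id),
              c("sample_id", "condition", "replicate")]
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  se <- SummarizedExperiment(
    assays = list(scaled = scaled[ord, , drop = FALSE],
                  cpm = cpm[ord, , drop = FALSE]),
    rowData = DataFrame(sequence = m$sequence[ord], start = m$start[ord],
                        end = m$end[ord],
                        length = m$end[ord] - m$start[ord] + 1L,
                        max_cpm = maxima[ord]),
    colData = DataFrame(sample_id = meta$sample_id,
                        condition = meta$condition,
                        replicate = meta$replicate,
                        total_psms = unname(totals),
                        row.names = meta$sample_id))
  metadata(se)$filters <- list(min_sample_psms = minSamplePsms,
                               samples_dropped = nSampleDropped,
                               single_sample_peptides_dropped = nPepDropped)
  new("HeatmapMatrix", se)
}

#' MDS ordination and Ward clustering of samples
#'
#' Classical (Torgerson) multidimensional scaling on Euclidean distances of
#' log2(CPM + 1) over the top \code{topN} peptides ranked by their maximum
#' CPM, followed by Ward-linkage hierarchical clustering of the samples on
#' the MDS-space distances. Coordinates are deterministic up to reflection;
#' the sign convention flips each axis so the first sample's coordinate is
#' non-negative.
#'
#' @param heatmap a [HeatmapMatrix-class].
#' @param topN number of top peptides to use (clamped to the available
#'   peptide count; default 100).
#' @return list with \code{coordinates} (samples x 2 matrix) and
#'   \code{dendrogram} (an \code{hclust} object, Ward linkage).
#' @export
mdsWardCluster <- function(heatmap, topN = 100L) {
  nsamp <- ncol(heatmap)
  if (nsamp < 2L) stop("need at least 2 retained samples", call. = FALSE)
  topN <- min(as.integer(topN), nrow(heatmap))
  ord <- order(rowData(heatmap)$max_cpm, decreasing = TRUE)
  top <- ord[seq_len(topN)]
  lcpm <- log2(assay(heatmap, "cpm")[top, , drop = FALSE] + 1)
  d <- dist(t(lcpm))
  k <- min(2L, nsamp - 1L)
  co <- suppressWarnings(cmdscale(d, k = k))
  if (ncol(co) < 2L)
    co <- cbind(co, matrix(0, nrow = nrow(co), ncol = 2L - ncol(co)))
  for (j in seq_len(ncol(co))) {
    pivot <- which(abs(co[, j]) > 1e-12)[1L]
    if (!is.na(pivot) && co[pivot, j] < 0) co[, j] <- -co[, j]
  }
  colnames(co) <- c("MDS1", "MDS2")
  rownames(co) <- colnames(heatmap)
  hc <- hclust(dist(co), method = "ward.D2")
  list(coordinates = co, dendrogram = hc)
}

#' Product-diversity summary for one condition
#'
#' Richness (number of distinct retained peptide species) and Shannon
#' entropy in bits over the peptide PSM-count distribution. A lower value
#' indicates a narrower product repertoire; processive, translocation-
#' limited degradation (26S-like) is expected to yield lower diversity than
#' an open catalytic chamber (20S-like).
#'
#' @param table a [PeptideTable-class] (replicate-filtered upstream).
#' @param condition condition label.
#' @return data.frame row: \code{condition}, \code{richness},
#'   \code{shannon_entropy} (bits). Empty conditions yield richness 0 and
#'   entropy 0.
#' @export
peptideDiversity <- function(table, condition) {
  obs <- observations(table)
  obs <- obs[obs$condition == condition & obs$psm_count > 0, , drop = FALSE]
  if (nrow(obs) == 0L)
    return(data.frame(condition = condition, richness = 0L,
                      shannon_entropy = 0))
  species <- paste(obs$sequence, obs$branch_pos, obs$branch_remnant,
                   sep = "\r")
  tot <- rowsum(obs$psm_count, species)[, 1L]
  p <- tot / sum(tot)
  data.frame(condition = condition, richness = length(tot),
             shannon_entropy = -sum(p * log2(p)))
}
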