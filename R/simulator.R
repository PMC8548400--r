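# Boundary weights for one draw side. Left boundaries live on 0..L-1
# (0 = substrate N-terminus), right boundaries on 1..L (L = C-terminus).
# Termini receive the mean positive site weight, so ragged ends appear at
# a typical-site rate without a dedicated tuning knob.
.boundaryWeights <- function(w) {
  wt <- mean(w[w > 0])
  list(left = c(wt, w), right = c(w, wt))
}

#' Simulate one replicate of a non-tryptic digest
#'
#' Draws \code{depth} accepted digestion events. Each event samples a left
#' and a right product boundary independently (substrate termini or
#' internal sites, sites weighted by the model's \code{siteWeights}),
#' rejecting pairs whose product length falls outside
#' \code{[lengthMin, lengthMax]}. Products shorter than the detection
#' floor are censored from the observed table but counted, so observed
#' plus censored events equal \code{depth}. Identical peptides are
#' aggregated into PSM counts. Replicate r uses seed \code{seed + r};
#' the same seed reproduces the same table.
#'
#' @param model a [DigestionModel-class].
#' @param substrate the matching [SubstrateRecord-class].
#' @param replicate replicate number (positive integer).
#' @param condition condition label stamped on the observations.
#' @return list with \code{observations} (data.frame in
#'   [PeptideTable-class] column layout), \code{censored} (number of
#'   events below the detection floor) and \code{events} (= depth).
#' @export
simulateDigest <- function(model, substrate, replicate = 1L,
                           condition = "digest") {
  stopifnot(is(model, "DigestionModel"), is(substrate, "SubstrateRecord"))
  if (model@substrateId != substrateId(substrate))
    stop("model and substrate disagree", call. = FALSE)
  L <- substrateLength(substrate)
  w <- model@siteWeights
  bw <- .boundaryWeights(w)
  lmin <- model@lengthMin; lmax <- min(model@lengthMax, L)
  # feasibility: some positive-weight boundary pair inside the window
  lefts <- which(bw$left > 0) - 1L
  rights <- which(bw$right > 0)
  feasible <- any(vapply(lefts, function(b)
    any(rights - b >= lmin & rights - b <= lmax), TRUE))
  if (!feasible)
    stop("no feasible product under the length constraints", call. = FALSE)
  depth <- as.integer(model@depth)
  sampleName <- paste0(condition, "_r", replicate)
  emptyObs <- data.frame(sample_id = character(), condition = character(),
                         replicate = integer(), sequence = character(),
                         psm_count = numeric(),
                         branch_pos = integer(),
                         branch_remnant = character())
  if (depth == 0L)
    return(list(observations = emptyObs, censored = 0L, events = 0L))
  set.seed(model@seed + as.integer(replicate))
  accL <- integer(0); accR <- integer(0)
  while (length(accL) < depth) {
    m <- max(2L * (depth - length(accL)), 1000L)
    dl <- sample.int(L, m, replace = TRUE, prob = bw$left) - 1L
    dr <- sample.int(L, m, replace = TRUE, prob = bw$right)
    len <- dr - dl
    ok <- len >= lmin & len <= lmax
    accL <- c(accL, dl[ok]); accR <- c(accR, dr[ok])
  }
  accL <- accL[seq_len(depth)]; accR <- accR[seq_len(depth)]
  lens <- accR - accL
  censored <- lens < model@detectionFloor
  nCens <- sum(censored)
  obs <- emptyObs
  if (any(!censored)) {
    seqc <- substrateSeq(substrate)
    peps <- substring(seqc, accL[!censored] + 1L, accR[!censored])
    tab <- rowsum(rep(1, length(peps)), peps)
    obs <- data.frame(sample_id = sampleName, condition = condition,
                      replicate = as.integer(replicate),
                      sequence = rownames(tab), psm_count = tab[, 1L],
                      branch_pos = NA_integer_,
                      branch_remnant = NA_character_)
    rownames(obs) <- NULL
  }
  list(observations = obs, censored = nCens, events = depth)
}

#' Simulate a replicated two-condition digestion experiment
#'
#' Runs [simulateDigest()] for every replicate of two models sharing a
#' substrate (emulating, e.g., a 20S-versus-26S product comparison) and
#' returns the combined [PeptideTable-class] together with the ground
#' truth: the per-site true log2 weight ratio between the two models, the
#' length windows and the branch rates.
#'
#' @param modelA,modelB [DigestionModel-class] objects on the same
#'   substrate. Give the two models different seeds so the conditions have
#'   independent sampling noise.
#' @param substrate the shared [SubstrateRecord-class].
#' @param conditionA,conditionB condition labels (defaults "20S", "26S").
#' @return list with \code{table} (a [PeptideTable-class]),
#'   \code{truth} (data.frame \code{site}, \code{log2_weight_ratio} for
#'   sites with positive weight in at least one model) and
#'   \code{censored} (events below the detection floor per sample).
#' @export
simulateTwoCondition <- function(modelA, modelB, substrate,
                                 conditionA = "20S", conditionB = "26S") {
  if (modelA@substrateId != modelB@substrateId)
    stop("models refer to different substrates", call. = FALSE)
  if (modelA@seed == modelB@seed)
    warning("modelA and modelB share a seed: conditions will reuse the ",
            "same random stream")
  runs <- list()
  censored <- integer(0)
  for (side in list(list(m = modelA, cond = conditionA),
                    list(m = modelB, cond = conditionB))) {
    for (r in seq_len(side$m@nReplicates)) {
      sim <- simulateDigest(side$m, substrate, replicate = r,
                            condition = side$cond)
      runs[[length(runs) + 1L]] <- sim$observations
      censored[paste0(side$cond, "_r", r)] <- sim$censored
    }
  }
  obs <- do.call(rbind, runs)
  wa <- modelA@siteWeights; wb <- modelB@siteWeights
  sites <- which(wa > 0 | wb > 0)
  truth <- data.frame(site = sites,
                      log2_weight_ratio = log2(wa[sites] / wb[sites]))
  table <- PeptideTable(obs, provenance = list(
    source = "simulateTwoCondition", dialect = "simulated",
    seeds = c(modelA@seed, modelB@seed)))
  list(table = table, truth = truth, censored = censored)
}

#' Inject ubiquitin-remnant branches into simulated observations
#'
#' Every observation whose (unambiguously mapped) peptide covers an anchor
#' lysine gains a branch with probability \code{branchProb} per PSM event:
#' the PSM count is split binomially into an unbranched and a branched
#' part, the branched part drawing its remnant from the model's remnant
#' distribution. With \code{branchProb = 0} the table is returned
#' unchanged.
#'
#' @param table a [PeptideTable-class].
#' @param model a [DigestionModel-class] (branch parameters and seed).
#' @param substrate [SubstrateRecord-class] with declared anchor lysines.
#' @return a new [PeptideTable-class] with branched rows added.
#' @export
injectBranches <- function(table, model, substrate) {
  if (length(anchorLysines(substrate)) == 0L)
    stop("substrate declares no anchor lysines", call. = FALSE)
  if (model@branchProb == 0) return(table)
  obs <- observations(table)
  mapping <- mapPeptides(table, substrate)
  anchors <- anchorLysines(substrate)
  m <- mapping[!mapping$ambiguous & mapping$mapped, , drop = FALSE]
  # first anchor covered by each mapped peptide, NA when none
  anchorOf <- vapply(seq_len(nrow(m)), function(i) {
    a <- anchors[anchors >= m$start[i] & anchors <= m$end[i]]
    if (length(a)) a[1L] else NA_integer_
  }, 1L)
  covered <- setNames(anchorOf, m$sequence)
  set.seed(model@seed + 7919L)
  rd <- model@remnantDistribution
  out <- vector("list", nrow(obs))
  for (i in seq_len(nrow(obs))) {
    row <- obs[i, , drop = FALSE]
    anc <- covered[row$sequence]
    if (is.na(row$branch_pos) && !is.na(anc) && row$psm_count > 0) {
      nb <- rbinom(1L, round(row$psm_count), model@branchProb)
      if (nb > 0) {
        start <- m$start[match(row$sequence, m$sequence)]
        pos <- anc - start + 1L
        split <- rmultinom(1L, nb, rd)[, 1L]
        branched <- row[rep(1L, sum(split > 0)), , drop = FALSE]
        branched$psm_count <- split[split > 0]
        branched$branch_pos <- pos
        branched$branch_remnant <- names(split)[split > 0]
        row$psm_count <- row$psm_count - nb
        out[[i]] <- rbind(row[row$psm_count > 0, , drop = FALSE], branched)
        next
      }
    }
    out[[i]] <- row
  }
  PeptideTable(do.call(rbind, out),
               provenance = c(provenance(table),
                              list(branch_prob = model@branchProb)))
}
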