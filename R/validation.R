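# Validation studies: seeded end-to-end experiments run against the
# digestion simulator with known ground truth. These define the package's
# self-validation conditions (simulator defaults, depths, windows) in one
# place, shared by the test suite and the acceptance script.

.randomSubstrate <- function(length, seed, id = "sim") {
  set.seed(seed)
  SubstrateRecord(id, paste(sample(AA20, length, replace = TRUE),
                            collapse = ""))
}

#' Cleavage-preference parameter-recovery study
#'
#' For each seed: builds a 51-residue random substrate (50 internal
#' sites), draws per-site true weight ratios log-uniformly on
#' \code{ratioRange} (condition A weights = ratio, condition B uniform),
#' simulates a replicated two-condition digest, applies the
#' replicate-presence filter, integrates site counts and computes the
#' preference statistic, then reports the Spearman correlation between
#' the true per-site log2 weight ratio and the recovered preference.
#'
#' @param seeds integer vector of study seeds (one experiment per seed).
#' @param nSites number of internal cleavage sites (substrate length - 1).
#' @param depth accepted digestion events per replicate.
#' @param nReplicates replicates per condition.
#' @param minReplicates replicate-presence threshold.
#' @param lengthMin,lengthMax product size window (residues).
#' @param ratioRange range of true per-site weight ratios (log-uniform).
#' @return data.frame with one row per seed: \code{seed},
#'   \code{spearman}, \code{n_sites_compared}.
#' @export
recoverPreferenceStudy <- function(seeds = 1:10, nSites = 50L,
                                   depth = 5e4, nReplicates = 3L,
                                   minReplicates = 2L, lengthMin = 7L,
                                   lengthMax = 30L,
                                   ratioRange = c(1 / 8, 8)) {
  res <- lapply(seeds, function(s) {
    sub <- .randomSubstrate(nSites + 1L, seed = s)
    set.seed(s + 31L)
    ratio <- exp(runif(nSites, log(ratioRange[1L]), log(ratioRange[2L])))
    mA <- digestionModel(sub, siteWeights = ratio, lengthMin = lengthMin,
                         lengthMax = lengthMax, depth = depth,
                         nReplicates = nReplicates, seed = s)
    mB <- digestionModel(sub, siteWeights = rep(1, nSites),
                         lengthMin = lengthMin, lengthMax = lengthMax,
                         depth = depth, nReplicates = nReplicates,
                         seed = s + 500000L)
    sim <- simulateTwoCondition(mA, mB, sub)
    tf <- suppressMessages(filterReplicates(sim$table, minReplicates))
    mp <- suppressMessages(mapPeptides(tf, sub))
    pref <- computePreference(
      integrateSiteCounts(tf, mp, sub, "20S"),
      integrateSiteCounts(tf, mp, sub, "26S"))
    m <- merge(pref, sim$truth, by = "site")
    ok <- is.finite(m$log2_ratio) & is.finite(m$log2_weight_ratio)
    data.frame(seed = s,
               spearman = stats::cor(m$log2_ratio[ok],
                                     m$log2_weight_ratio[ok],
                                     method = "spearman"),
               n_sites_compared = sum(ok))
  })
  do.call(rbind, res)
}

#' Null-model preference study
#'
#' Simulates two conditions from identical digestion models (independent
#' seeds) and reports the median absolute recovered preference, which
#' should sit near zero when no true difference exists.
#'
#' @inheritParams recoverPreferenceStudy
#' @param seed single study seed.
#' @return list with \code{median_abs_preference} and \code{n_sites}.
#' @export
nullPreferenceStudy <- function(seed = 1L, nSites = 50L, depth = 5e4,
                                nReplicates = 3L, minReplicates = 2L,
                                lengthMin = 7L, lengthMax = 30L) {
  sub <- .randomSubstrate(nSites + 1L, seed = seed)
  mA <- digestionModel(sub, lengthMin = lengthMin, lengthMax = lengthMax,
                       depth = depth, nReplicates = nReplicates,
                       seed = seed)
  mB <- digestionModel(sub, lengthMin = lengthMin, lengthMax = lengthMax,
                       depth = depth, nReplicates = nReplicates,
                       seed = seed + 500000L)
  sim <- simulateTwoCondition(mA, mB, sub)
  tf <- suppressMessages(filterReplicates(sim$table, minReplicates))
  mp <- suppressMessages(mapPeptides(tf, sub))
  pref <- computePreference(
    integrateSiteCounts(tf, mp, sub, "20S"),
    integrateSiteCounts(tf, mp, sub, "26S"))
  list(median_abs_preference = stats::median(abs(pref$log2_ratio),
                                             na.rm = TRUE),
       n_sites = sum(!is.na(pref$log2_ratio)))
}

#' Product-length signature study
#'
#' Simulates a 20S-like digest (wide product window, longer products)
#' against a 26S-like digest (narrower window) on a shared substrate and
#' tests the per-peptide length distributions with the Mann-Whitney U
#' test. Reports the p-value and the median product lengths, whose order
#' should reflect the wider window.
#'
#' @param seed study seed.
#' @param depth accepted events per replicate.
#' @param windowA,windowB product size windows (residues) for the
#'   20S-like and 26S-like models.
#' @param nReplicates replicates per condition.
#' @return list with \code{p_value}, \code{median_a}, \code{median_b},
#'   \code{n_a}, \code{n_b}.
#' @export
lengthSignatureStudy <- function(seed = 1L, depth = 1e4,
                                 windowA = c(7L, 35L),
                                 windowB = c(7L, 25L),
                                 nReplicates = 3L) {
  sub <- .randomSubstrate(51L, seed = seed)
  mA <- digestionModel(sub, lengthMin = windowA[1L],
                       lengthMax = windowA[2L], depth = depth,
                       nReplicates = nReplicates, seed = seed)
  mB <- digestionModel(sub, lengthMin = windowB[1L],
                       lengthMax = windowB[2L], depth = depth,
                       nReplicates = nReplicates, seed = seed + 500000L)
  sim <- simulateTwoCondition(mA, mB, sub)
  la <- peptideLengths(sim$table, "20S")
  lb <- peptideLengths(sim$table, "26S")
  mw <- mannWhitneyU(la, lb)
  list(p_value = mw$p_value, median_a = stats::median(la),
       median_b = stats::median(lb), n_a = length(la), n_b = length(lb))
}

#' Composition-null calibration study
#'
#' Repeatedly simulates two conditions from the same digestion model
#' (identical site weights, hence identical true cleavage-site
#' composition) and asks how often the differential composition test
#' flags any window position at the given alpha. With a true null the
#' clean-run fraction should stay high.
#'
#' @param nRuns number of seeded simulation runs.
#' @param seed base seed.
#' @param nSites internal sites of the shared random substrate.
#' @param depth accepted events per condition per run.
#' @param lengthMin,lengthMax product size window (residues).
#' @param alpha per-position significance threshold.
#' @return list with \code{fraction_clean}, \code{n_flagged_runs},
#'   \code{n_runs}.
#' @export
compositionNullStudy <- function(nRuns = 200L, seed = 1L, nSites = 39L,
                                 depth = 2000, lengthMin = 7L,
                                 lengthMax = 25L, alpha = 0.01) {
  sub <- .randomSubstrate(nSites + 1L, seed = seed + 2024L)
  set.seed(seed + 7L)
  w <- exp(runif(nSites, log(1 / 4), log(4)))
  flagged <- vapply(seq_len(nRuns), function(r) {
    mA <- digestionModel(sub, siteWeights = w, lengthMin = lengthMin,
                         lengthMax = lengthMax, depth = depth,
                         nReplicates = 1L, seed = seed + 2L * r)
    mB <- digestionModel(sub, siteWeights = w, lengthMin = lengthMin,
                         lengthMax = lengthMax, depth = depth,
                         nReplicates = 1L, seed = seed + 2L * r + 1L)
    sim <- simulateTwoCondition(mA, mB, sub)
    mp <- suppressMessages(mapPeptides(sim$table, sub))
    dl <- differentialLogo(
      frequencyMatrix(extractWindows(
        integrateSiteCounts(sim$table, mp, sub, "20S"), sub)),
      frequencyMatrix(extractWindows(
        integrateSiteCounts(sim$table, mp, sub, "26S"), sub)))
    any(dl$p_value < alpha, na.rm = TRUE)
  }, TRUE)
  list(fraction_clean = mean(!flagged), n_flagged_runs = sum(flagged),
       n_runs = nRuns)
}
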