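#' Default analysis configuration
#'
#' Central defaults for the analysis constants: replicate-presence
#' threshold (2 of 3), the 0.1 pseudo-value and twofold call threshold of
#' the cleavage-preference statistic, the 50-PSM sample floor and top-100
#' peptide rank of the heatmap/MDS stage, and the 7-residue detection
#' floor of the simulator.
#'
#' @param minReplicates,pseudoValue,foldThreshold,minSamplePsms,topN
#'   analysis constants (see module functions).
#' @param ilEquivalence collapse I/L when mapping.
#' @param detectionFloor simulator detection floor (residues).
#' @param seed base random seed.
#' @return named list of settings.
#' @export
analysisConfig <- function(minReplicates = 2L, pseudoValue = 0.1,
                           foldThreshold = 2, minSamplePsms = 50L,
                           topN = 100L, ilEquivalence = FALSE,
                           detectionFloor = 7L, seed = 1L) {
  if (pseudoValue <= 0) stop("pseudoValue must be > 0", call. = FALSE)
  list(minReplicates = as.integer(minReplicates),
       pseudoValue = pseudoValue, foldThreshold = foldThreshold,
       minSamplePsms = as.integer(minSamplePsms), topN = as.integer(topN),
       ilEquivalence = isTRUE(ilEquivalence),
       detectionFloor = as.integer(detectionFloor),
       seed = as.integer(seed))
}

.stageFail <- function(stage, e) {
  stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
}

#' Run the full degradomics pipeline
#'
#' Orchestrates an end-to-end run from a single configuration: ingest (or
#' simulate) a peptide table, map onto the substrate, apply the replicate
#' filter, then compute site usage and cleavage preference, the heatmap
#' matrix with MDS/Ward clustering, length and diversity summaries,
#' composition logos, branched-peptide annotation, and (when disorder
#' tracks are supplied) per-protein disorder scores. A manifest with the
#' configuration snapshot, input digests and seed is written before any
#' stage runs; every TSV output echoes the configuration in '#' header
#' lines, and re-running with an identical configuration reproduces the
#' outputs.
#'
#' @param config named list (or path to a YAML file with the same layout):
#'   \describe{
#'     \item{substrate}{list(fasta=, name=, anchor_lysines=) -- required.}
#'     \item{peptides}{list(path=, dialect=) to ingest a table, OR}
#'     \item{simulate}{list(depth=, n_replicates=, length_min_a=,
#'       length_max_a=, length_min_b=, length_max_b=, condition_a=,
#'       condition_b=) to generate one with [simulateTwoCondition()].}
#'     \item{ubiquitin}{list(fasta=) -- optional, enables the remnant
#'       stage.}
#'     \item{disorder}{list(tracks=, assignments=) -- optional.}
#'     \item{analysis}{overrides for [analysisConfig()] fields.}
#'   }
#' @param outDir output directory (created; must be empty or new).
#' @return invisibly, the output directory.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L)
    config <- read_yaml(config)
  cfg <- do.call(analysisConfig, as.list(config$analysis))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  ## -- manifest (written first) --------------------------------------
  paths <- c(substrate = config$substrate$fasta,
             peptides = config$peptides$path,
             ubiquitin = config$ubiquitin$fasta,
             disorder_tracks = config$disorder$tracks)
  paths <- paths[!vapply(paths, is.null, TRUE)]
  manifest <- list(
    package = "degradomics",
    version = as.character(packageVersion("degradomics")),
    seed = cfg$seed,
    config = config,
    input_md5 = as.list(vapply(paths, function(p)
      unname(md5sum(p)), "")))
  write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  hdr <- c(list(pipeline = "degradomics"), cfg)

  ## -- ingest / simulate ---------------------------------------------
  substrate <- tryCatch(
    loadSubstrate(config$substrate$fasta, name = config$substrate$name,
                  anchorLysines = as.integer(
                    config$substrate$anchor_lysines %||% integer())),
    error = function(e) .stageFail("substrate", e))
  counts <- list()
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    table <- tryCatch({
      L <- substrateLength(substrate)
      mkWeights <- function() {
        set.seed(cfg$seed)
        exp(runif(L - 1L, log(1 / 4), log(4)))
      }
      wA <- sim$site_weights_a %||% mkWeights()
      wB <- sim$site_weights_b %||% wA
      mA <- digestionModel(substrate, siteWeights = wA,
              lengthMin = sim$length_min_a %||% 7L,
              lengthMax = sim$length_max_a %||% 35L,
              detectionFloor = cfg$detectionFloor,
              depth = sim$depth %||% 1e4,
              nReplicates = sim$n_replicates %||% 3L,
              branchProb = sim$branch_prob %||% 0,
              seed = cfg$seed)
      mB <- digestionModel(substrate, siteWeights = wB,
              lengthMin = sim$length_min_b %||% 7L,
              lengthMax = sim$length_max_b %||% 25L,
              detectionFloor = cfg$detectionFloor,
              depth = sim$depth %||% 1e4,
              nReplicates = sim$n_replicates %||% 3L,
              branchProb = sim$branch_prob %||% 0,
              seed = cfg$seed + 104729L)
      out <- simulateTwoCondition(mA, mB, substrate,
               conditionA = sim$condition_a %||% "20S",
               conditionB = sim$condition_b %||% "26S")
      if ((sim$branch_prob %||% 0) > 0 &&
          length(anchorLysines(substrate)))
        out$table <- injectBranches(out$table, mA, substrate)
      writeResultTable(out$truth,
                       file.path(outDir, "ground_truth.tsv"), hdr)
      out$table
    }, error = function(e) .stageFail("simulate", e))
  } else if (!is.null(config$peptides)) {
    table <- tryCatch(
      loadPeptides(config$peptides$path,
                   dialect = config$peptides$dialect %||% "generic"),
      error = function(e) .stageFail("ingest", e))
  } else stop("[ingest] config needs either `peptides` or `simulate`",
              call. = FALSE)
  counts$ingested <- nrow(observations(table))

  ## -- filter + map ----------------------------------------------------
  table <- tryCatch(filterReplicates(table, cfg$minReplicates),
                    error = function(e) .stageFail("filter", e))
  counts$filtered <- nrow(observations(table))
  writeResultTable(observations(table),
                   file.path(outDir, "peptides_filtered.tsv"), hdr)
  mapping <- tryCatch(mapPeptides(table, substrate,
                                  ilEquivalence = cfg$ilEquivalence),
                      error = function(e) .stageFail("map", e))
  counts$mapped <- sum(mapping$mapped)
  writeResultTable(mapping, file.path(outDir, "mapped_peptides.tsv"), hdr)

  ## -- site usage + preference ----------------------------------------
  conds <- unique(observations(table)$condition)
  usage <- tryCatch(lapply(conds, function(cond) {
    u <- integrateSiteCounts(table, mapping, substrate, cond)
    writeResultTable(siteCounts(u),
                     file.path(outDir, paste0("site_usage_", cond, ".tsv")),
                     hdr)
    u
  }), error = function(e) .stageFail("p1", e))
  names(usage) <- conds
  if (length(conds) >= 2L) {
    pref <- tryCatch(
      computePreference(usage[[1L]], usage[[2L]], cfg$pseudoValue,
                        cfg$foldThreshold),
      error = function(e) .stageFail("p1", e))
    writeResultTable(pref, file.path(outDir, "preference.tsv"),
                     c(hdr, list(condition_a = conds[1L],
                                 condition_b = conds[2L])))
  }

  ## -- heatmap + MDS/Ward ----------------------------------------------
  tryCatch({
    hm <- buildHeatmap(table, mapping, cfg$minSamplePsms)
    sc <- assay(hm, "scaled")
    writeResultTable(data.frame(peptide = rownames(sc), sc,
                                check.names = FALSE),
                     file.path(outDir, "heatmap_matrix.tsv"), hdr)
    writeResultTable(data.frame(peptide = rownames(hm),
                                max_cpm = peptideMaxima(hm)),
                     file.path(outDir, "heatmap_peptide_maxima.tsv"), hdr)
    mw <- mdsWardCluster(hm, cfg$topN)
    writeResultTable(data.frame(sample_id = rownames(mw$coordinates),
                                mw$coordinates),
                     file.path(outDir, "mds_coordinates.tsv"), hdr)
    write.tree(as.phylo(mw$dendrogram),
               file.path(outDir, "dendrogram.nwk"))
  }, error = function(e) .stageFail("heatmap", e))

  ## -- lengths, diversity, composition ---------------------------------
  tryCatch({
    lens <- do.call(rbind, lapply(conds, function(cond)
      summarizeLengths(table, cond)))
    writeResultTable(lens, file.path(outDir, "lengths_summary.tsv"), hdr)
    div <- do.call(rbind, lapply(conds, function(cond)
      peptideDiversity(table, cond)))
    writeResultTable(div, file.path(outDir, "diversity.tsv"), hdr)
    if (length(conds) >= 2L) {
      mwu <- mannWhitneyU(peptideLengths(table, conds[1L]),
                          peptideLengths(table, conds[2L]))
      writeResultTable(data.frame(condition_a = conds[1L],
                                  condition_b = conds[2L],
                                  U = mwu$U, p_value = mwu$p_value),
                       file.path(outDir, "lengths_test.tsv"), hdr)
    }
  }, error = function(e) .stageFail("lengths", e))
  tryCatch({
    pfms <- lapply(conds, function(cond)
      frequencyMatrix(extractWindows(usage[[cond]], substrate)))
    names(pfms) <- conds
    for (cond in conds) {
      lg <- informationContent(pfms[[cond]])
      writeResultTable(data.frame(residue = rownames(logoHeights(lg)),
                                  logoHeights(lg), check.names = FALSE),
                       file.path(outDir,
                                 paste0("logo_heights_", cond, ".tsv")),
                       hdr)
    }
    if (length(conds) >= 2L) {
      dl <- differentialLogo(pfms[[1L]], pfms[[2L]])
      writeResultTable(data.frame(position = names(dl$p_value),
                                  statistic = dl$statistic, df = dl$df,
                                  p_value = dl$p_value),
                       file.path(outDir, "differential_logo.tsv"), hdr)
    }
  }, error = function(e) .stageFail("composition", e))

  ## -- remnants (optional) ----------------------------------------------
  if (!is.null(config$ubiquitin)) {
    tryCatch({
      ub <- loadSubstrate(config$ubiquitin$fasta,
                          name = config$ubiquitin$name)
      writeResultTable(enumerateRemnants(ub),
                       file.path(outDir, "remnants.tsv"), hdr)
      ann <- annotateBranchedTable(table, substrate, ub,
                                   ilEquivalence = cfg$ilEquivalence)
      writeResultTable(ann,
                       file.path(outDir, "remnant_annotations.tsv"), hdr)
    }, error = function(e) .stageFail("remnants", e))
  }

  ## -- disorder (optional; skipped with a warning when absent) ----------
  if (!is.null(config$disorder) && !is.null(config$disorder$tracks)) {
    tryCatch({
      tracks <- loadDisorderTracks(config$disorder$tracks)
      scores <- do.call(rbind, lapply(tracks, function(tr)
        as.data.frame(meanDisorder(tr))))
      writeResultTable(scores, file.path(outDir, "disorder_scores.tsv"),
                       hdr)
    }, error = function(e) .stageFail("disorder", e))
  } else {
    warning("disorder stage skipped: no disorder tracks configured")
  }

  writeResultTable(data.frame(stage = names(counts),
                              rows = unlist(counts)),
                   file.path(outDir, "stage_counts.tsv"), hdr)
  invisible(outDir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
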