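toyUsage <- function(counts, sub, cond = "A") {
  # counts: named vector site -> count
  new("SiteUsageTable", substrateId = substrateId(sub),
      substrateLength = substrateLength(sub), condition = cond,
      usage = data.frame(site = as.integer(names(counts)),
                         count = unname(counts)))
}

test_that("integrateSiteCounts credits both bounding sites", {
  sub <- SubstrateRecord("s10", "MKTAYIAKQR")
  tab <- makeTable("a1", "A", 1L, "TAYI", 10)       # maps 3..6
  mp <- suppressMessages(mapPeptides(tab, sub))
  u <- integrateSiteCounts(tab, mp, sub, "A")
  expect_identical(siteCounts(u),
                   data.frame(site = c(2L, 6L), count = c(10, 10)))

  # (1,4):5 and (5,8):7 -> site 4 bounded by both, site 8 by one
  tab2 <- makeTable(c("a1", "a1"), "A", 1L, c("MKTA", "YIAK"), c(5, 7))
  mp2 <- suppressMessages(mapPeptides(tab2, sub))
  u2 <- integrateSiteCounts(tab2, mp2, sub, "A")
  expect_identical(siteCounts(u2),
                   data.frame(site = c(4L, 8L), count = c(12, 7)))

  # N-terminus-only crediting mode
  u3 <- integrateSiteCounts(tab2, mp2, sub, "A", credit = "nterm")
  expect_identical(siteCounts(u3), data.frame(site = 4L, count = 7))

  # empty condition -> empty table
  u4 <- integrateSiteCounts(tab, mp, sub, "missing")
  expect_identical(nrow(siteCounts(u4)), 0L)

  # mapping for another substrate is rejected
  other <- SubstrateRecord("other", "MKTAYIAKQR")
  expect_error(integrateSiteCounts(tab, mp, other, "A"), "substrate")
})

test_that("site-count integration conserves contributed counts", {
  sub <- randomSubstrate(60, seed = 11)
  m <- digestionModel(sub, lengthMin = 7L, lengthMax = 25L, depth = 2000,
                      nReplicates = 1L, seed = 21L)
  obs <- simulateDigest(m, sub, 1L, "A")$observations
  tab <- suppressMessages(PeptideTable(obs))
  mp <- suppressMessages(mapPeptides(tab, sub))
  u <- integrateSiteCounts(tab, mp, sub, "A")
  uniq <- merge(observations(tab), mp[!mp$ambiguous & mp$mapped, ],
                by = "sequence")
  internal <- uniq$start > 1 & uniq$end < substrateLength(sub)
  touching <- xor(uniq$start == 1, uniq$end == substrateLength(sub))
  expected <- 2 * sum(uniq$psm_count[internal]) +
    sum(uniq$psm_count[touching])
  expect_equal(sum(siteCounts(u)$count), expected)
})

test_that("ambiguous peptides are excluded unless fractionally included", {
  sub <- SubstrateRecord("rep", "AGAGAGA")
  tab <- makeTable("a1", "A", 1L, "GAG", 6)          # occurs at 2..4, 4..6
  mp <- suppressMessages(mapPeptides(tab, sub))
  expect_true(mp$ambiguous)
  u <- integrateSiteCounts(tab, mp, sub, "A")
  expect_identical(nrow(siteCounts(u)), 0L)
  uf <- integrateSiteCounts(tab, mp, sub, "A", includeAmbiguous = TRUE)
  # occurrences (2,4) and (4,6): sites 1,4 and 3,6 each get 6/2 = 3
  expect_identical(siteCounts(uf),
                   data.frame(site = c(1L, 3L, 4L, 6L), count = rep(3, 4)))
})

test_that("computePreference implements the pseudo-value ratio and calls", {
  sub <- randomSubstrate(30, seed = 2)
  a <- toyUsage(c(`5` = 10, `7` = 10, `9` = 3), sub, "a")
  b <- toyUsage(c(`5` = 10, `7` = 0, `9` = 8), sub, "b")
  pr <- computePreference(a, b, pseudoValue = 0.1, foldThreshold = 2)
  row <- function(s) pr[pr$site == s, ]
  expect_equal(row(5)$log2_ratio, 0)
  expect_identical(row(5)$call, "none")
  expect_equal(row(7)$log2_ratio, log2(10 / 0.1), tolerance = 1e-12)
  expect_equal(row(7)$log2_ratio, 6.6439, tolerance = 1e-4)
  expect_identical(row(7)$call, "prefer_a")
  expect_equal(row(9)$log2_ratio, -1.4150, tolerance = 1e-4)
  expect_identical(row(9)$call, "prefer_b")
  # unobserved sites are NA, not log2(0.1/0.1) = 0
  expect_true(is.na(row(1)$log2_ratio))
  expect_identical(row(1)$call, "na")
  expect_identical(row(1)$value_a, 0)
  expect_error(computePreference(a, b, pseudoValue = 0), "pseudoValue")
})

test_that("preference is antisymmetric and shifts by log2(c) under scaling", {
  sub <- randomSubstrate(40, seed = 5)
  set.seed(8)
  sitesA <- sample(1:39, 15); sitesB <- sample(1:39, 15)
  a <- toyUsage(setNames(rpois(15, 20) + 1, sitesA), sub, "a")
  b <- toyUsage(setNames(rpois(15, 20) + 1, sitesB), sub, "b")
  ab <- computePreference(a, b); ba <- computePreference(b, a)
  expect_equal(ab$log2_ratio, -ba$log2_ratio)
  expect_identical(ab$call == "prefer_a", ba$call == "prefer_b")
  # scale one condition by c: every site observed in BOTH conditions
  # (no pseudo-substitution) shifts by exactly log2(c)
  c3 <- toyUsage(setNames(siteCounts(a)$count * 3,
                          siteCounts(a)$site), sub, "a")
  shifted <- computePreference(c3, b)
  both <- ab$value_a > 0 & ab$value_b > 0
  expect_equal(shifted$log2_ratio[both], ab$log2_ratio[both] + log2(3))
})

heatmapFixture <- function() {
  sub <- SubstrateRecord("hm", "MKTAYIAKQRLMNPQSTVWY")
  # s3 holds only 49 total PSMs -> dropped by the 50-PSM floor;
  # ONLYONE is then seen in a single retained sample -> dropped
  tab <- makeTable(
    sample_id = c("s1", "s1", "s2", "s2", "s3", "s1"),
    condition = c("A", "A", "B", "B", "B", "A"),
    replicate = c(1L, 1L, 1L, 1L, 2L, 1L),
    sequence = c("TAYI", "AKQRL", "TAYI", "AKQRL", "TAYI", "MNPQ"),
    psm_count = c(100, 60, 50, 150, 49, 40))
  list(sub = sub, tab = tab,
       mp = suppressMessages(mapPeptides(tab, sub)))
}

test_that("buildHeatmap applies the sample and peptide filters", {
  fx <- heatmapFixture()
  hm <- buildHeatmap(fx$tab, fx$mp, minSamplePsms = 50)
  expect_s4_class(hm, "HeatmapMatrix")
  expect_setequal(colnames(hm), c("s1", "s2"))      # s3 dropped (49 < 50)
  expect_setequal(rownames(hm), c("TAYI", "AKQRL")) # MNPQ single-sample
  expect_identical(filtersApplied(hm)$samples_dropped, 1L)
  expect_identical(filtersApplied(hm)$single_sample_peptides_dropped, 1L)
  # rows ordered by N-terminal residue
  expect_identical(rownames(hm), c("TAYI", "AKQRL"))
  sc <- SummarizedExperiment::assay(hm, "scaled")
  expect_equal(unname(apply(sc, 1, max)), c(1, 1))
  # CPM then per-peptide max rescale: TAYI CPMs (500000, 250000)
  expect_equal(unname(sc["TAYI", c("s1", "s2")]), c(1, 0.5))
  expect_equal(unname(peptideMaxima(hm)["TAYI"]), 5e5)
  expect_error(buildHeatmap(fx$tab, fx$mp, minSamplePsms = 1000),
               "floor")
})

test_that("heatmap rescaling is idempotent", {
  fx <- heatmapFixture()
  hm <- buildHeatmap(fx$tab, fx$mp, minSamplePsms = 50)
  sc <- SummarizedExperiment::assay(hm, "scaled")
  again <- sc / apply(sc, 1, max)
  expect_equal(again, sc)
})

test_that("MDS/Ward clustering is deterministic and groups duplicates", {
  sub <- randomSubstrate(40, seed = 13)
  m <- digestionModel(sub, lengthMin = 7L, lengthMax = 20L, depth = 3000,
                      nReplicates = 1L, seed = 33L)
  o1 <- simulateDigest(m, sub, 1L, "A")$observations
  o2 <- o1; o2$sample_id <- "A_r2"; o2$replicate <- 2L
  m3 <- digestionModel(sub, siteWeights = rev(siteWeights(m)),
                       lengthMin = 7L, lengthMax = 20L, depth = 3000,
                       nReplicates = 1L, seed = 44L)
  o3 <- simulateDigest(m3, sub, 1L, "B")$observations
  tab <- suppressMessages(PeptideTable(rbind(o1, o2, o3)))
  mp <- suppressMessages(mapPeptides(tab, sub))
  hm <- buildHeatmap(tab, mp, minSamplePsms = 50)
  mw <- mdsWardCluster(hm, topN = 100)
  expect_identical(dim(mw$coordinates), c(3L, 2L))
  # exact duplicates sit at distance zero and merge first, at height 0
  d <- dist(mw$coordinates)
  dup <- as.matrix(d)["A_r1", "A_r2"]
  expect_equal(unname(dup), 0, tolerance = 1e-6)
  expect_equal(mw$dendrogram$height[1], 0, tolerance = 1e-6)
  first <- sort(mw$dendrogram$labels[-mw$dendrogram$merge[1, ]])
  expect_identical(first, c("A_r1", "A_r2"))
  # sign convention makes the result reproducible
  mw2 <- mdsWardCluster(hm, topN = 100)
  expect_identical(mw$coordinates, mw2$coordinates)
  expect_true(mw$coordinates[1, 1] >= 0)
  # topN larger than the peptide count is clamped, not an error
  expect_silent(mdsWardCluster(hm, topN = 10000))
  one <- buildHeatmap(tab, mp, minSamplePsms = 50)[, 1]
  expect_error(mdsWardCluster(one), "at least 2")
})

test_that("peptideDiversity computes richness and Shannon entropy", {
  tab <- makeTable("a1", "A", 1L, c("AAAA", "CCCC", "DDDD", "EEEE"),
                   c(5, 5, 5, 5))
  d <- peptideDiversity(tab, "A")
  expect_identical(d$richness, 4L)
  expect_equal(d$shannon_entropy, 2)
  one <- makeTable("a1", "A", 1L, "AAAA", 7)
  expect_equal(peptideDiversity(one, "A")$shannon_entropy, 0)
  skew <- makeTable("a1", "A", 1L, c("AAAA", "CCCC", "DDDD", "EEEE"),
                    c(8, 4, 2, 2))
  expect_equal(peptideDiversity(skew, "A")$shannon_entropy, 1.75)
  empty <- peptideDiversity(one, "nothing")
  expect_identical(empty$richness, 0L)
  expect_identical(empty$shannon_entropy, 0)
  # entropy never exceeds log2(richness)
  expect_lte(d$shannon_entropy, log2(d$richness))
})
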