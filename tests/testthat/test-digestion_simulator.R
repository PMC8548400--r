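test_that("simulateDigest is deterministic given a seed", {
  sub <- randomSubstrate(40, seed = 1)
  m <- digestionModel(sub, lengthMin = 7L, lengthMax = 20L, depth = 2000,
                      seed = 9L)
  a <- simulateDigest(m, sub, 1L, "A")
  b <- simulateDigest(m, sub, 1L, "A")
  expect_identical(a, b)
  c <- simulateDigest(m, sub, 2L, "A")
  expect_false(identical(a$observations, c$observations))
})

test_that("zero-weight sites never appear as product boundaries", {
  sub <- randomSubstrate(30, seed = 4)
  w <- rep(1, 29); w[c(10, 15, 20)] <- 0
  m <- digestionModel(sub, siteWeights = w, lengthMin = 5L,
                      lengthMax = 20L, detectionFloor = 5L, depth = 3000,
                      seed = 2L)
  sim <- simulateDigest(m, sub, 1L, "A")
  mp <- suppressMessages(mapPeptides(sim$observations$sequence, sub))
  bounds <- c(mp$n_term_site, mp$c_term_site)
  expect_false(any(bounds %in% c(10, 15, 20)))
})

test_that("a single permitted site forces exactly two products", {
  sub <- randomSubstrate(10, seed = 6)
  w <- rep(0, 9); w[5] <- 1
  m <- digestionModel(sub, siteWeights = w, lengthMin = 5L,
                      lengthMax = 5L, detectionFloor = 5L, depth = 500,
                      seed = 3L)
  sim <- simulateDigest(m, sub, 1L, "A")
  s <- substrateSeq(sub)
  expect_setequal(sim$observations$sequence,
                  c(substr(s, 1, 5), substr(s, 6, 10)))
})

test_that("infeasible length constraints are a model error", {
  sub <- randomSubstrate(10, seed = 6)
  w <- rep(0, 9); w[5] <- 1
  m <- digestionModel(sub, siteWeights = w, lengthMin = 2L,
                      lengthMax = 3L, depth = 10, seed = 1L)
  expect_error(simulateDigest(m, sub, 1L), "no feasible product")
})

test_that("every simulated peptide is a substring of the substrate and
           observed plus censored events equal depth", {
  sub <- randomSubstrate(45, seed = 8)
  m <- digestionModel(sub, lengthMin = 4L, lengthMax = 20L,
                      detectionFloor = 7L, depth = 4000, seed = 12L)
  sim <- simulateDigest(m, sub, 1L, "A")
  expect_equal(sum(sim$observations$psm_count) + sim$censored, 4000)
  expect_gt(sim$censored, 0)   # window 4..20 with floor 7 censors some
  s <- substrateSeq(sub)
  expect_true(all(vapply(sim$observations$sequence,
                         function(p) grepl(p, s, fixed = TRUE), TRUE)))
  # no observed product below the detection floor
  expect_true(all(nchar(sim$observations$sequence) >= 7))
})

test_that("depth 0 yields an empty table but defined ground truth", {
  sub <- randomSubstrate(30, seed = 2)
  mA <- digestionModel(sub, depth = 0, lengthMax = 25L, seed = 1L)
  mB <- digestionModel(sub, depth = 0, lengthMax = 25L, seed = 2L)
  sim <- simulateTwoCondition(mA, mB, sub)
  expect_identical(nrow(observations(sim$table)), 0L)
  expect_identical(nrow(sim$truth), 29L)
  expect_true(all(sim$truth$log2_weight_ratio == 0))
})

test_that("two-condition simulation validates substrates and seeds", {
  a <- randomSubstrate(30, seed = 2, id = "subA")
  b <- randomSubstrate(30, seed = 3, id = "subB")
  mA <- digestionModel(a, depth = 10, lengthMax = 20L, seed = 1L)
  mB <- digestionModel(b, depth = 10, lengthMax = 20L, seed = 2L)
  expect_error(simulateTwoCondition(mA, mB, a), "different substrates")
  mB2 <- digestionModel(a, depth = 10, lengthMax = 20L, seed = 1L)
  expect_warning(simulateTwoCondition(mA, mB2, a), "share a seed")
})

test_that("ground truth records the per-site log2 weight ratio", {
  sub <- randomSubstrate(20, seed = 5)
  wA <- rep(1, 19); wA[7] <- 4
  mA <- digestionModel(sub, siteWeights = wA, depth = 100,
                       lengthMax = 15L, seed = 1L)
  mB <- digestionModel(sub, depth = 100, lengthMax = 15L, seed = 2L)
  sim <- simulateTwoCondition(mA, mB, sub)
  expect_equal(sim$truth$log2_weight_ratio[sim$truth$site == 7], 2)
  expect_equal(sum(sim$truth$log2_weight_ratio), 2)
})

test_that("injectBranches splits counts at anchor-covering peptides", {
  cy <- cyclinK64()
  tab <- makeTable(c("a1", "a1"), "20S", 1L,
                   c("ARLPLPKE", "MALRVTR"), c(40, 10))
  m0 <- digestionModel(cy, branchProb = 0, lengthMax = 40L, seed = 1L)
  expect_identical(observations(injectBranches(tab, m0, cy)),
                   observations(tab))

  m1 <- digestionModel(cy, branchProb = 1,
                       remnantDistribution = c(GG = 1), lengthMax = 40L,
                       seed = 1L)
  b1 <- injectBranches(tab, m1, cy)
  obs <- observations(b1)
  covering <- obs$sequence == "ARLPLPKE"
  expect_true(all(!is.na(obs$branch_pos[covering])))
  expect_true(all(obs$branch_remnant[covering] == "GG"))
  expect_identical(obs$branch_pos[covering], 7L)
  expect_true(all(is.na(obs$branch_pos[!covering])))
  expect_equal(sum(obs$psm_count), 50)   # counts are split, not created

  noAnchor <- SubstrateRecord("x", substrateSeq(cy))
  expect_error(injectBranches(tab, m1, noAnchor), "anchor")
})

test_that("the observed branch fraction tracks branchProb", {
  cy <- cyclinK64()
  tab <- makeTable("a1", "20S", 1L, "ARLPLPKE", 20000)
  m <- digestionModel(cy, branchProb = 0.3, lengthMax = 40L, seed = 42L)
  obs <- observations(injectBranches(tab, m, cy))
  frac <- sum(obs$psm_count[!is.na(obs$branch_pos)]) / sum(obs$psm_count)
  expect_lt(abs(frac - 0.3), 0.05)
})
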