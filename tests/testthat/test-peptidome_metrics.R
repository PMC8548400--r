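test_that("summarizeLengths reproduces the boxplot conventions", {
  tab <- makeTable("a1", "A", 1L,
                   c("AAAAAAA", "CCCCCCCC", "DDDDDDDDD", "EEEEEEEEEE",
                     "FFFFFFFFFFF"), rep(1, 5))    # lengths 7..11
  s <- summarizeLengths(tab, "A")
  expect_identical(s$n, 5L)
  expect_equal(s$median, 9)
  expect_equal(s$q1, 8)
  expect_equal(s$q3, 10)
  expect_equal(s$whisker_low, 7)
  expect_equal(s$whisker_high, 11)

  one <- makeTable("a1", "A", 1L, "GGGGGGGGGGGG", 3)
  s1 <- summarizeLengths(one, "A")
  expect_true(all(unlist(s1[c("mean", "median", "q1", "q3",
                              "whisker_low", "whisker_high")]) == 12))

  # PSM weighting expands lengths {7,7,20} with counts (1,1,2)
  w <- makeTable("a1", "A", 1L,
                 c("AAAAAAA", "CCCCCCC", "DDDDDDDDDDDDDDDDDDDD"),
                 c(1, 1, 2))
  expect_equal(summarizeLengths(w, "A", weighting = "per_psm")$median,
               13.5)
  expect_equal(summarizeLengths(w, "A")$median, 7)
  expect_error(summarizeLengths(w, "missing"), "no peptides")
})

test_that("whiskers exclude points beyond 1.5 IQR", {
  lens <- c(8, 9, 10, 11, 12, 30)
  tab <- makeTable("a1", "A", 1L,
                   mapply(function(n, ch) strrep(ch, n), lens,
                          c("A", "C", "D", "E", "F", "G")), rep(1, 6))
  s <- summarizeLengths(tab, "A")
  q <- quantile(lens, c(.25, .75), type = 7)
  expect_equal(s$whisker_high, max(lens[lens <= q[2] + 1.5 * diff(q)]))
  expect_lt(s$whisker_high, 30)
  expect_equal(s$whisker_low, 8)
})

test_that("mannWhitneyU matches the exact enumeration oracle", {
  r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)
  expect_true(r$exact)

  set.seed(31)
  for (nx in 1:6) for (ny in 1:6) {
    z <- sample(seq(0.01, 1, by = 0.01), nx + ny)   # distinct, no ties
    x <- z[seq_len(nx)]; y <- z[-seq_len(nx)]
    got <- mannWhitneyU(x, y)
    oracle <- mwEnumerate(x, y)
    expect_equal(got$U, oracle$U, info = paste(nx, ny))
    expect_equal(got$p_value, oracle$p_value, tolerance = 1e-12,
                 info = paste(nx, ny))
  }
})

test_that("mannWhitneyU approximation and degenerate behavior", {
  expect_equal(mannWhitneyU(c(2, 2, 2), c(2, 2))$p_value, 1)
  set.seed(5)
  x <- rnorm(200); y <- rnorm(200, mean = 1)
  r <- mannWhitneyU(x, y)
  expect_false(r$exact)
  expect_lt(r$p_value, 1e-6)
  expect_error(mannWhitneyU(numeric(0), 1), "non-empty")
})

test_that("welchT matches the closed-form Welch statistic", {
  x <- c(1, 2, 3, 4); y <- c(3, 4, 5, 6)
  r <- welchT(x, y)
  # independent closed form with Welch-Satterthwaite df
  se <- sqrt(var(x) / 4 + var(y) / 4)
  tt <- (mean(x) - mean(y)) / se
  df <- se^4 / ((var(x) / 4)^2 / 3 + (var(y) / 4)^2 / 3)
  expect_equal(r$t, tt)
  expect_equal(r$df, df)
  expect_equal(r$t, -2.1909, tolerance = 1e-4)
  expect_equal(r$df, 6)
  expect_equal(r$p_value, 2 * pt(tt, df), tolerance = 1e-12)

  same <- welchT(c(1, 5, 9), c(1, 5, 9))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  expect_error(welchT(c(0, 0, 0), c(1, 1, 1)), "zero variance")
  eps <- 1e-9
  jit <- welchT(c(0, 0, 0, eps), c(1, 1, 1, 1 + eps))
  expect_lt(jit$p_value, 1e-6)
})

test_that("meanDisorder averages residues and ignores their order", {
  expect_equal(meanDisorder(DisorderTrack("p", rep(0.5, 8)))$score, 0.5)
  expect_equal(meanDisorder(DisorderTrack("p", c(0, 1)))$score, 0.5)
  expect_equal(meanDisorder(DisorderTrack("p", c(0.2, 0.4, 0.9)))$score,
               0.5)
  set.seed(12)
  s <- runif(50)
  expect_equal(meanDisorder(DisorderTrack("p", s))$score,
               meanDisorder(DisorderTrack("p", sample(s)))$score)
  expect_error(DisorderTrack("p", numeric(0)), "empty")
  expect_error(DisorderTrack("p", c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("uniqueConditionProteins takes per-condition set differences", {
  a <- data.frame(condition = c("A", "A", "B"),
                  protein_id = c("p1", "p2", "p2"))
  u <- uniqueConditionProteins(a)
  expect_identical(u$A, "p1")
  expect_identical(u$B, character(0))
  same <- data.frame(condition = c("A", "B"), protein_id = c("p1", "p1"))
  u2 <- uniqueConditionProteins(same)
  expect_identical(lengths(u2), c(A = 0L, B = 0L))
})

test_that("a high-disorder unique pool shows up in the score comparison", {
  # condition A samples extra proteins from a high-disorder pool; the
  # unique(A) proteins should score above unique(B) proteins
  set.seed(99)
  shared <- paste0("s", 1:40)
  hiA <- paste0("hi", 1:25)
  loB <- paste0("lo", 1:25)
  assign <- data.frame(
    condition = rep(c("A", "B"), times = c(65, 65)),
    protein_id = c(shared, hiA, shared, loB))
  disorder <- c(setNames(runif(40, 0.2, 0.8), shared),
                setNames(runif(25, 0.6, 0.95), hiA),
                setNames(runif(25, 0.05, 0.4), loB))
  u <- uniqueConditionProteins(assign)
  expect_setequal(u$A, hiA)
  r <- welchT(disorder[u$A], disorder[u$B])
  expect_gt(mean(disorder[u$A]), mean(disorder[u$B]))
  expect_lt(r$p_value, 0.001)
})
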