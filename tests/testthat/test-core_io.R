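test_that("loadSubstrate parses, upcases and validates FASTA input", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">toy", "mktayiAKQR"), fa)
  s <- loadSubstrate(fa)
  expect_s4_class(s, "SubstrateRecord")
  expect_identical(substrateSeq(s), "MKTAYIAKQR")
  expect_identical(substrateLength(s), 10L)
  expect_identical(nrow(segmentTable(s)), 0L)

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">bad", "MKTBYI"), bad)
  expect_error(loadSubstrate(bad), "non-canonical")

  expect_error(loadSubstrate(fa, anchorLysines = 3L), "lysine")
  expect_silent(s2 <- loadSubstrate(fa, anchorLysines = 8L))
  expect_identical(anchorLysines(s2), 8L)
  expect_error(loadSubstrate(extdata("cyclinb1_nt_synthetic.fasta")),
               "multi-record")
})

test_that("the packaged cyclin fixture matches the construct description", {
  wt <- cyclinWT()
  expect_identical(substrateLength(wt), 88L)
  expect_identical(
    lengths(regmatches(substrateSeq(wt), gregexpr("K", substrateSeq(wt)))),
    15L)
  k64 <- cyclinK64()
  expect_identical(substrateLength(k64), 88L)
  expect_identical(substring(substrateSeq(k64), 64, 64), "K")
  # the K64-only variant is the wild type with every other K changed to R
  expect_identical(chartr("K", "R", substrateSeq(wt)),
                   chartr("K", "R", substrateSeq(k64)))
})

test_that("loadPeptides sums duplicate keys and conserves total counts", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tcondition\treplicate\tpeptide\tpsm_count",
               "s1\tA\t1\tPEPTIDE\t3",
               "s1\tA\t1\tPEPTIDE\t4",
               "s2\tA\t2\tOTHERSEQ\t5"), tsv)
  tab <- suppressMessages(loadPeptides(tsv))
  obs <- observations(tab)
  expect_identical(nrow(obs), 2L)
  expect_identical(obs$psm_count[obs$sequence == "PEPTIDE"], 7)
  expect_identical(sum(obs$psm_count), 3 + 4 + 5)
})

test_that("the MaxQuant dialect resolves Sequence/MS-MS Count/Experiment", {
  tab <- suppressMessages(
    loadPeptides(extdata("example_maxquant_peptides.tsv"),
                 dialect = "maxquant"))
  obs <- observations(tab)
  expect_true("ARLPLPKE" %in% obs$sequence)
  expect_identical(obs$condition[obs$sample_id == "20S_1"][1], "20S")
  expect_identical(obs$replicate[obs$sample_id == "26S_2"][1], 2L)
})

test_that("degenerate and malformed peptide tables are handled", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_id\tcondition\treplicate\tpeptide\tpsm_count", empty)
  expect_warning(tab <- suppressMessages(loadPeptides(empty)),
                 "empty data section")
  expect_identical(nrow(observations(tab)), 0L)

  miss <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tpeptide", "s1\tPEP"), miss)
  expect_error(suppressMessages(loadPeptides(miss)), "missing required")

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tcondition\treplicate\tpeptide\tpsm_count",
               "s1\tA\t1\tPEPTIDE\t-2"), neg)
  expect_error(suppressMessages(loadPeptides(neg)), "negative")
})

test_that("result tables round-trip through write/read at 6 digits", {
  df <- data.frame(site = c(1L, 2L, 3L),
                   log2_ratio = c(6.6438561897, -1.4150374992, NA),
                   call = c("prefer_a", "prefer_b", "na"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeResultTable(df, f, config = list(pseudo_value = 0.1, fold = 2))
  lines <- readLines(f)
  expect_true(all(startsWith(lines[1:2], "# ")))
  back <- readResultTable(f)
  expect_identical(back$site, df$site)
  expect_equal(back$log2_ratio, signif(df$log2_ratio, 6))
  expect_identical(back$call, df$call)
  expect_true(is.na(back$log2_ratio[3]))

  # empty result: header-only data section
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeResultTable(df[0, ], f2)
  expect_identical(nrow(readResultTable(f2)), 0L)
  expect_identical(names(readResultTable(f2)), names(df))
})

test_that("PeptideTable validates branch records", {
  expect_error(
    PeptideTable(data.frame(sample_id = "s", condition = "A",
                            replicate = 1, sequence = "PEPTIDE",
                            psm_count = 1, branch_pos = 3,
                            branch_remnant = "GG")),
    "point at a K")
  tab <- makeTable("s", "A", 1L, "PEKTIDE", 2, branch_pos = 3L,
                   branch_remnant = "GG")
  expect_identical(observations(tab)$branch_remnant, "GG")
})

test_that("disorder tracks load from long-format TSV", {
  tr <- loadDisorderTracks(extdata("example_disorder.tsv"))
  expect_named(tr, c("P1", "P2"))
  expect_equal(meanDisorder(tr$P1)$score, 0.5)
  expect_identical(meanDisorder(tr$P2)$n_residues, 2L)
})
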