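# Shared fixtures built in code. The packaged FASTA/TSV files live under
# inst/extdata and are loaded through system.file().

extdata <- function(f) system.file("extdata", f, package = "degradomics")

cyclinWT <- function()
  loadSubstrate(extdata("cyclinb1_nt_synthetic.fasta"),
                name = "CCNB1_NT_synthetic")

cyclinK64 <- function()
  loadSubstrate(extdata("cyclinb1_nt_synthetic.fasta"),
                name = "CCNB1_NT_K64_synthetic", anchorLysines = 64L)

ubiquitin <- function() loadSubstrate(extdata("ubiquitin_human.fasta"))

randomSubstrate <- function(L, seed, id = "rnd") {
  set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  SubstrateRecord(id, paste(sample(aa, L, replace = TRUE), collapse = ""))
}

# quick peptide table from vectors; replicate defaults to 1 per sample
makeTable <- function(sample_id, condition, replicate, sequence, psm_count,
                      branch_pos = NA_integer_,
                      branch_remnant = NA_character_) {
  suppressMessages(PeptideTable(data.frame(
    sample_id = sample_id, condition = condition, replicate = replicate,
    sequence = sequence, psm_count = psm_count, branch_pos = branch_pos,
    branch_remnant = branch_remnant)))
}

# independent O(L*n) occurrence scan used as mapping oracle
naiveScan <- function(peptide, subject) {
  n <- nchar(peptide); L <- nchar(subject)
  if (n > L) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(L - n + 1L))
    if (substr(subject, i, i + n - 1L) == peptide) hits <- c(hits, i)
  hits
}

# exhaustive-enumeration Mann-Whitney oracle (no ties)
mwEnumerate <- function(x, y) {
  nx <- length(x); ny <- length(y)
  z <- c(x, y)
  r <- rank(z)
  Uobs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  # under the null every subset of the ranks 1..n is equally likely
  sets <- utils::combn(nx + ny, nx)
  Uall <- apply(sets, 2L, function(ix) sum(ix) - nx * (nx + 1) / 2)
  pl <- mean(Uall <= Uobs); pg <- mean(Uall >= Uobs)
  list(U = Uobs, p_value = min(1, 2 * min(pl, pg)))
}
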