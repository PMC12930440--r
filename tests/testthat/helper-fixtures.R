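# Small fixtures built in code at test time.

writeTempTSV <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# a well-formed 3-row differential TSV with default column names
tinyDiffTSV <- function() {
  writeTempTSV(c("analyte\tlog2fc\tpvalue\tpadj",
                 "GRN\t1.2\t0.001\t0.01",
                 "NECTIN2\t-0.4\t0.2\t0.5",
                 "PDIA1\t2.1\t0.005\t0.02"))
}

# deterministic universe/sets realizing |U|=1235, |A|=72, |B|=364, a=28
paperOverlapSets <- function() {
  uni <- sprintf("A%04d", seq_len(1235))
  list(universe = uni,
       A = uni[1:72],
       B = uni[c(1:28, 73:408)])
}

# exact hypergeometric upper tail by closed-form summation over the overlap
# support (independent of stats::phyper)
hyperTailOracle <- function(N, nA, nB, a) {
  supp <- max(0, nA + nB - N):min(nA, nB)
  probs <- choose(nB, supp) * choose(N - nB, nA - supp) / choose(N, nA)
  sum(probs[supp >= a])
}
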