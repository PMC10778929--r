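# Shared fixtures, built in code at test time.

GENETIC_CODE_DNA <- Biostrings::GENETIC_CODE
SENSE <- names(GENETIC_CODE_DNA)[GENETIC_CODE_DNA != "*"]
STOPS <- names(GENETIC_CODE_DNA)[GENETIC_CODE_DNA == "*"]
FAMILIES <- split(names(GENETIC_CODE_DNA), GENETIC_CODE_DNA)
SENSE_FAMILIES <- FAMILIES[names(FAMILIES) != "*"]

# uniform codon usage table: every synonymous family equally used
uniformTable <- function(species = "uniform") {
  CodonUsageTable(species, setNames(rep(1000 / 64, 64),
                                    names(GENETIC_CODE_DNA)))
}

# table with prescribed per-codon frequencies, all others uniform
customTable <- function(overrides, species = "custom") {
  f <- setNames(rep(10, 64), names(GENETIC_CODE_DNA))
  f[names(overrides)] <- overrides
  CodonUsageTable(species, f)
}

cdsFromCodons <- function(codons, ...) {
  CodingSequence(paste(codons, collapse = ""), ...)
}

# CDS using one fixed codon per degenerate amino acid (each `rep` times)
# plus Met and Trp: Wright's maximal-bias reference composition
maxBiasCDS <- function(rep = 10L) {
  firstCodon <- vapply(SENSE_FAMILIES, `[`, "", 1L)
  cdsFromCodons(unlist(lapply(unname(firstCodon), function(cc)
    base::rep(cc, rep))))
}

# CDS with every sense codon appearing exactly `n` times
allCodonsCDS <- function(n = 100L) {
  cdsFromCodons(base::rep(SENSE, each = n))
}

writeTempFasta <- function(lines) {
  p <- tempfile(fileext = ".fasta")
  writeLines(lines, p)
  p
}
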