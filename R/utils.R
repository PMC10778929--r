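#' @useDynLib cubscape, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats qt qnorm rgamma runif sd median setNames
#' @importFrom utils read.delim write.table
NULL

## Standard genetic code, DNA alphabet ("TTT" ... "GGG"), from Biostrings.
.GC_TABLE <- Biostrings::GENETIC_CODE
.STOP_CODONS <- names(.GC_TABLE)[.GC_TABLE == "*"]
.SENSE_CODONS <- names(.GC_TABLE)[.GC_TABLE != "*"]
.ALL_CODONS <- names(.GC_TABLE)
## codon families keyed by amino acid one-letter code (incl. "*")
.AA_FAMILIES <- split(names(.GC_TABLE), .GC_TABLE)
.DEGENERACY <- lengths(.AA_FAMILIES)

## number of G/C among the three codon positions, per codon
.CODON_GC_COUNT <- vapply(strsplit(.ALL_CODONS, ""), function(b)
  sum(b %in% c("G", "C")), integer(1L))
names(.CODON_GC_COUNT) <- .ALL_CODONS

.isDNA <- function(x) grepl("^[ACGTN]*$", x)

#' Split a CDS string into codons
#' @param seq a nucleotide string whose length is a multiple of 3
#' @return character vector of codons
#' @keywords internal
.splitCodons <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(character(0L))
  stopifnot(n %% 3L == 0L)
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

.translateCodons <- function(codons) {
  aa <- .GC_TABLE[codons]
  aa[is.na(aa)] <- "X"   # codons containing N
  unname(aa)
}

## evaluate `expr` under a fixed RNG state without disturbing the caller's
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

## deterministic sub-seed derivation (kept below 2^31)
.deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(index) * 9973) %% 2147483647)
}

.normalizeSeq <- function(x) {
  x <- toupper(as.character(x))
  chartr("U", "T", x)
}
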