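#' CodingSequence: one species' CDS for one gene or isoform
#'
#' Frame-validated coding sequence over the DNA alphabet \{A,C,G,T,N\}. The
#' sequence length must be a multiple of 3 and must not contain an internal
#' stop codon in frame 0 (a terminal stop codon is permitted and is stripped
#' automatically before any metric is computed).
#'
#' @slot id record identifier (e.g. an accession)
#' @slot species species label
#' @slot gene gene / isoform label (e.g. "B56a", "B56d/g")
#' @slot seq uppercase DNA string, length divisible by 3
#' @export
setClass("CodingSequence",
  representation(id = "character", species = "character",
                 gene = "character", seq = "character"))

setValidity("CodingSequence", function(object) {
  msg <- character(0L)
  s <- object@seq
  if (length(s) != 1L) msg <- c(msg, "'seq' must be a single string")
  else {
    if (!.isDNA(s)) msg <- c(msg, "'seq' contains characters outside {A,C,G,T,N}")
    if (nchar(s) %% 3L != 0L)
      msg <- c(msg, sprintf("length of 'seq' (%d) is not divisible by 3", nchar(s)))
    else if (nchar(s) >= 3L) {
      cods <- .splitCodons(s)
      internal <- cods[-length(cods)]
      bad <- which(internal %in% .STOP_CODONS)
      if (length(bad))
        msg <- c(msg, sprintf("internal stop codon at codon position %s",
                              paste(bad - 1L, collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CodingSequence
#'
#' Input is uppercased and RNA 'U' is transcribed back to DNA 'T' on entry
#' (the package's canonical internal alphabet is DNA).
#'
#' @param seq nucleotide string (DNA or RNA alphabet, any case)
#' @param id,species,gene metadata labels
#' @return a [CodingSequence-class] object
#' @examples
#' cds <- CodingSequence("atggaataa", id = "x", species = "Homo_sapiens",
#'                       gene = "B56a")
#' codons(cds)
#' @export
CodingSequence <- function(seq, id = "", species = "", gene = "") {
  new("CodingSequence", id = as.character(id), species = as.character(species),
      gene = as.character(gene), seq = .normalizeSeq(seq))
}

#' CodonUsageTable: per-codon reference frequencies for one species
#'
#' Holds codon frequencies per thousand codons (as distributed by the Codon
#' Usage Database) together with relative adaptiveness weights
#' \eqn{w_c = f_c / \max_{c' \in syn(c)} f_{c'}}, recomputed from the
#' frequencies on construction. Codons with zero reference frequency receive
#' a pseudo-frequency of 0.5 (per-thousand units) before normalization so
#' that all weights are strictly positive and CAI is always defined.
#'
#' @slot species species label
#' @slot freq named numeric, frequency per thousand for all 64 codons
#' @slot weights named numeric, relative adaptiveness in (0, 1]
#' @export
setClass("CodonUsageTable",
  representation(species = "character", freq = "numeric", weights = "numeric"))

.codonWeights <- function(freq, pseudo = 0.5) {
  w <- setNames(numeric(length(.ALL_CODONS)), .ALL_CODONS)
  for (fam in .AA_FAMILIES) {
    f <- freq[fam]
    f[f == 0] <- pseudo
    w[fam] <- f / max(f)
  }
  w
}

setValidity("CodonUsageTable", function(object) {
  msg <- character(0L)
  missing <- setdiff(.ALL_CODONS, names(object@freq))
  if (length(missing))
    msg <- c(msg, paste("missing codons:", paste(missing, collapse = ", ")))
  else {
    if (any(object@freq < 0)) msg <- c(msg, "negative codon frequency")
    w <- object@weights
    if (!identical(names(w), names(object@freq)))
      msg <- c(msg, "weights and freq must be parallel")
    for (fam in .AA_FAMILIES)
      if (length(msg) == 0L && abs(max(w[fam]) - 1) > 0)
        msg <- c(msg, sprintf("max weight in family {%s} is not 1",
                              paste(fam, collapse = ",")))
    if (length(msg) == 0L &&
        !isTRUE(all.equal(unname(w[.ALL_CODONS]),
                          unname(.codonWeights(object@freq[.ALL_CODONS])))))
      msg <- c(msg, "weights are not the recomputation from freq")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CodonUsageTable
#'
#' @param species species label
#' @param freq named numeric vector of frequencies per thousand; names must
#'   cover all 64 codons (DNA or RNA alphabet)
#' @return a [CodonUsageTable-class] object with weights derived from `freq`
#' @export
CodonUsageTable <- function(species, freq) {
  names(freq) <- .normalizeSeq(names(freq))
  missing <- setdiff(.ALL_CODONS, names(freq))
  if (length(missing))
    stop("codon usage table is missing codons: ", paste(missing, collapse = ", "))
  if (any(freq < 0)) stop("negative codon frequency in usage table")
  freq <- freq[.ALL_CODONS]
  new("CodonUsageTable", species = as.character(species), freq = freq,
      weights = .codonWeights(freq))
}

#' DomainPartition: named codon-coordinate regions of a CDS
#'
#' Regions use 0-based, half-open codon coordinates, must not overlap, and
#' carry unique names. An implicit "whole" region covering all sense codons
#' always exists and need not be listed.
#'
#' @slot regions data.frame with columns `name`, `start`, `end` (codons)
#' @export
setClass("DomainPartition", representation(regions = "data.frame"))

setValidity("DomainPartition", function(object) {
  r <- object@regions
  msg <- character(0L)
  if (!all(c("name", "start", "end") %in% names(r)))
    return("regions must have columns name, start, end")
  if (anyDuplicated(r$name)) msg <- c(msg, "region names must be unique")
  if (any(r$start >= r$end)) msg <- c(msg, "each region must satisfy start < end")
  if (any(r$start < 0)) msg <- c(msg, "region starts must be >= 0")
  if (nrow(r) > 1L) {
    o <- order(r$start)
    if (any(r$start[o][-1L] < r$end[o][-nrow(r)]))
      msg <- c(msg, "regions must not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DomainPartition
#'
#' @param ... named regions given as length-2 integer vectors
#'   `c(start, end)` in 0-based half-open codon coordinates, or a single
#'   data.frame with columns `name`, `start`, `end`.
#' @return a [DomainPartition-class] object
#' @examples
#' DomainPartition(nterm = c(0, 50), core = c(50, 450), cterm = c(450, 500))
#' @export
DomainPartition <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.data.frame(args[[1L]])) {
    r <- args[[1L]][, c("name", "start", "end")]
  } else {
    if (is.null(names(args)) || any(names(args) == ""))
      stop("regions must be named")
    r <- data.frame(name = names(args),
                    start = vapply(args, function(x) as.integer(x[1L]), 0L),
                    end = vapply(args, function(x) as.integer(x[2L]), 0L))
  }
  rownames(r) <- NULL
  r$start <- as.integer(r$start); r$end <- as.integer(r$end)
  new("DomainPartition", regions = r)
}

#' LFEProfile: sliding-window local folding energy deltas for one CDS
#'
#' Per window (anchored at its 0-based start offset from the CDS start):
#' the native local folding energy, the mean over synonymous-codon
#' permutations of the whole sequence, and their difference
#' deltaLFE = native - permuted mean. Negative deltaLFE means stronger than
#' predicted secondary structure. `rampCodons` is the length, in codons, of
#' the 5' prefix with weaker than predicted structure (deltaLFE > 0).
#'
#' @slot gene,species labels
#' @slot windowStarts integer, nt offsets of window starts (0-based)
#' @slot nativeLFE,permutedMeanLFE,deltaLFE numeric per window (NA where a
#'   window contains an ambiguous base)
#' @slot xIntercepts numeric nt positions where the deltaLFE trace crosses 0
#' @slot rampCodons integer ramp length in codons
#' @slot window,step,nPermutations analysis parameters
#' @export
setClass("LFEProfile",
  representation(gene = "character", species = "character",
                 windowStarts = "integer", nativeLFE = "numeric",
                 permutedMeanLFE = "numeric", deltaLFE = "numeric",
                 xIntercepts = "numeric", rampCodons = "integer",
                 window = "integer", step = "integer",
                 nPermutations = "integer"))

setValidity("LFEProfile", function(object) {
  n <- length(object@windowStarts)
  msg <- character(0L)
  if (length(object@nativeLFE) != n || length(object@permutedMeanLFE) != n ||
      length(object@deltaLFE) != n)
    msg <- c(msg, "per-window slots must have equal length")
  else {
    d <- object@nativeLFE - object@permutedMeanLFE
    ok <- is.na(d) == is.na(object@deltaLFE)
    if (!all(ok) || !isTRUE(all.equal(d[!is.na(d)],
                                      object@deltaLFE[!is.na(d)])))
      msg <- c(msg, "deltaLFE must equal nativeLFE - permutedMeanLFE")
  }
  if (length(msg)) msg else TRUE
})

#' AggregateProfile: cross-species mean deltaLFE per window start
#'
#' @slot gene gene label
#' @slot windowStarts integer nt offsets (positions with no species dropped)
#' @slot meanDeltaLFE numeric, unweighted mean across species per position
#' @slot nSpecies integer, number of species contributing per position
#' @export
setClass("AggregateProfile",
  representation(gene = "character", windowStarts = "integer",
                 meanDeltaLFE = "numeric", nSpecies = "integer"))

setValidity("AggregateProfile", function(object) {
  if (length(object@windowStarts) != length(object@meanDeltaLFE) ||
      length(object@windowStarts) != length(object@nSpecies))
    return("parallel slots must have equal length")
  if (any(object@nSpecies < 1L))
    return("positions with no contributing species must be absent")
  TRUE
})
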