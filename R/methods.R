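#' @name accessors
#' @title Accessors for cubscape S4 objects
#' @param x an object
#' @param ... ignored
#' @description Small accessor generics: `codons()` returns the codon list
#' of a [CodingSequence-class] (terminal stop included if present);
#' `senseCodons()` strips the terminal stop; `cdsID()`, `cdsSpecies()`,
#' `cdsGene()`, `cdsSeq()` return metadata; `codonFreq()` and
#' `codonWeights()` expose a [CodonUsageTable-class]'s per-thousand
#' frequencies and relative-adaptiveness weights; `regions()` the region
#' table of a [DomainPartition-class]; `windowStarts()`, `nativeLFE()`,
#' `permutedMeanLFE()`, `deltaLFE()`, `rampCodons()` the per-window slots
#' of an [LFEProfile-class].
NULL

#' @rdname accessors
#' @export
setGeneric("codons", function(x) standardGeneric("codons"))
#' @rdname accessors
#' @export
setMethod("codons", "CodingSequence", function(x) .splitCodons(x@seq))

#' @rdname accessors
#' @export
setGeneric("senseCodons", function(x) standardGeneric("senseCodons"))
#' @rdname accessors
#' @export
setMethod("senseCodons", "CodingSequence", function(x) {
  cods <- .splitCodons(x@seq)
  n <- length(cods)
  if (n > 0L && cods[n] %in% .STOP_CODONS) cods <- cods[-n]
  cods
})

#' @rdname accessors
#' @export
cdsID <- function(x) x@id
#' @rdname accessors
#' @export
cdsSpecies <- function(x) x@species
#' @rdname accessors
#' @export
cdsGene <- function(x) x@gene
#' @rdname accessors
#' @export
cdsSeq <- function(x) x@seq

#' @rdname accessors
#' @export
codonFreq <- function(x) x@freq
#' @rdname accessors
#' @export
codonWeights <- function(x) x@weights
#' @rdname accessors
#' @export
tableSpecies <- function(x) x@species

#' @rdname accessors
#' @export
regions <- function(x) x@regions

#' @rdname accessors
#' @export
windowStarts <- function(x) x@windowStarts
#' @rdname accessors
#' @export
nativeLFE <- function(x) x@nativeLFE
#' @rdname accessors
#' @export
permutedMeanLFE <- function(x) x@permutedMeanLFE
#' @rdname accessors
#' @export
deltaLFE <- function(x) x@deltaLFE
#' @rdname accessors
#' @export
rampCodons <- function(x) x@rampCodons

setMethod("show", "CodingSequence", function(object) {
  cods <- .splitCodons(object@seq)
  cat(sprintf("CodingSequence '%s' (%s, %s): %d nt / %d codons\n",
              object@id, object@gene, object@species,
              nchar(object@seq), length(cods)))
  s <- object@seq
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(" ", s, "\n")
})

setMethod("show", "CodonUsageTable", function(object) {
  cat(sprintf("CodonUsageTable for %s (64 codons, per-thousand)\n",
              object@species))
  top <- sort(object@freq, decreasing = TRUE)[1:5]
  cat("  most frequent:",
      paste(sprintf("%s=%.1f", names(top), top), collapse = " "), "\n")
})

setMethod("show", "DomainPartition", function(object) {
  cat(sprintf("DomainPartition with %d regions (codon coordinates, 0-based half-open)\n",
              nrow(object@regions)))
  print(object@regions, row.names = FALSE)
})

setMethod("show", "LFEProfile", function(object) {
  cat(sprintf("LFEProfile %s / %s: %d windows (window=%d nt, step=%d nt, %d permutations)\n",
              object@gene, object@species, length(object@windowStarts),
              object@window, object@step, object@nPermutations))
  cat(sprintf("  ramp: %d codons; x-intercepts at nt: %s\n", object@rampCodons,
              if (length(object@xIntercepts))
                paste(round(object@xIntercepts, 2), collapse = ", ")
              else "none"))
})

setMethod("show", "AggregateProfile", function(object) {
  cat(sprintf("AggregateProfile %s: %d window positions, %d-%d species per position\n",
              object@gene, length(object@windowStarts),
              min(object@nSpecies), max(object@nSpecies)))
})

#' Tabulate an LFE profile or aggregate as a data.frame
#'
#' @param x an [LFEProfile-class] or [AggregateProfile-class]
#' @param row.names,optional,... passed for S3 compatibility, ignored
#' @return data.frame, one row per window position
#' @export
as.data.frame.LFEProfile <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(gene = x@gene, species = x@species,
             window_start_nt = x@windowStarts, native_lfe = x@nativeLFE,
             permuted_mean_lfe = x@permutedMeanLFE, delta_lfe = x@deltaLFE)
}

#' @rdname as.data.frame.LFEProfile
#' @export
as.data.frame.AggregateProfile <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(gene = x@gene, window_start_nt = x@windowStarts,
             mean_delta_lfe = x@meanDeltaLFE, n_species = x@nSpecies)
}
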