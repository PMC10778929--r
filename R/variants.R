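## Classification of coding single-nucleotide substitutions and the
## synonymous / missense abundance summaries.

#' Classify a coding substitution
#'
#' Compares the affected codon's translation before and after the
#' substitution under the standard genetic code. Only single-nucleotide
#' substitutions are in scope; indels and multi-nucleotide variants are
#' rejected.
#'
#' @param cds a [CodingSequence-class]
#' @param cdsPosition 0-based nucleotide offset into the CDS (vectorized)
#' @param ref,alt reference and alternate bases (single characters)
#' @return character vector with values `"synonymous"`, `"missense"`,
#'   `"nonsense"` or `"stop_loss"`
#' @examples
#' cds <- CodingSequence("ATGGAATAA")
#' classifySubstitution(cds, 5, "A", "G")  # GAA -> GAG, both Glu
#' @export
classifySubstitution <- function(cds, cdsPosition, ref, alt) {
  ref <- .normalizeSeq(ref); alt <- .normalizeSeq(alt)
  if (any(nchar(ref) != 1L) || any(nchar(alt) != 1L))
    stop("only single-nucleotide substitutions are supported ",
         "(indels / multi-nucleotide variants are out of scope)")
  if (any(!ref %in% c("A", "C", "G", "T")) ||
      !all(alt %in% c("A", "C", "G", "T")))
    stop("ref and alt must be single DNA bases")
  if (any(ref == alt)) stop("variant with ref == alt")
  seq <- cdsSeq(cds)
  n <- nchar(seq)
  pos <- as.integer(cdsPosition)
  if (any(pos < 0L | pos >= n)) stop("cds_position out of range")
  have <- substring(seq, pos + 1L, pos + 1L)
  bad <- which(have != ref)
  if (length(bad))
    stop("ref allele mismatch at cds_position ",
         paste(pos[bad], collapse = ", "), " (CDS has ",
         paste(have[bad], collapse = ", "), ")")
  codonIdx <- pos %/% 3L
  offset <- pos %% 3L
  before <- substring(seq, codonIdx * 3L + 1L, codonIdx * 3L + 3L)
  after <- before
  substring(after, offset + 1L, offset + 1L) <- alt
  aaB <- .GC_TABLE[before]; aaA <- .GC_TABLE[after]
  out <- ifelse(aaB == aaA, "synonymous",
         ifelse(aaA == "*", "nonsense",
         ifelse(aaB == "*", "stop_loss", "missense")))
  unname(out)
}

#' Summarize a variant list into mutation-abundance percentages
#'
#' Counts synonymous, missense, nonsense and stop-loss substitutions and
#' reports the abundance of synonymous mutations with respect to all
#' mutations and with respect to missense mutations.
#'
#' @param cds a [CodingSequence-class]
#' @param variants data.frame with columns `cds_position`, `ref`, `alt`
#'   (as from [readVariantTable()])
#' @return one-row data.frame with columns n_total, n_synonymous,
#'   n_missense, n_nonsense, n_stop_loss, syn_vs_all_pct,
#'   syn_vs_missense_pct (`NA` with a warning when there are no missense
#'   mutations)
#' @export
summarizeMutations <- function(cds, variants) {
  if (nrow(variants) == 0L) stop("empty variant list")
  cls <- classifySubstitution(cds, variants$cds_position, variants$ref,
                              variants$alt)
  nTotal <- length(cls)
  nSyn <- sum(cls == "synonymous")
  nMis <- sum(cls == "missense")
  nNon <- sum(cls == "nonsense")
  synMis <- if (nMis == 0L) {
    warning("no missense mutations; syn_vs_missense_pct undefined")
    NA_real_
  } else 100 * nSyn / nMis
  data.frame(n_total = nTotal, n_synonymous = nSyn, n_missense = nMis,
             n_nonsense = nNon, n_stop_loss = sum(cls == "stop_loss"),
             syn_vs_all_pct = 100 * nSyn / nTotal,
             syn_vs_missense_pct = synMis)
}
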