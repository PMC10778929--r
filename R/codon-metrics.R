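## Codon-usage-bias metrics: effective number of codons (Nc), Codon
## Adaptation Index (CAI) with its expected-CAI null, GC3% / GC%, and the
## whole-gene percent-difference normalizations.

.regionCodons <- function(x) {
  cods <- if (is(x, "CodingSequence")) senseCodons(x) else {
    x <- .normalizeSeq(x)
    if (length(x) == 1L && nchar(x[1L]) > 3L) .splitCodons(x) else x
  }
  ## drop stop codons and codons containing ambiguity codes
  cods[!(cods %in% .STOP_CODONS) & !grepl("N", cods)]
}

#' Effective number of codons (Nc)
#'
#' Wright's estimator of the effective number of codons, from 20 (maximal
#' bias: one codon per amino acid) to 61 (uniform synonymous usage). For
#' each amino acid \eqn{a} with degeneracy \eqn{k \ge 2} observed
#' \eqn{n_a \ge 2} times, the codon homozygosity is estimated as
#' \deqn{\hat F_a = (n_a \sum_i p_i^2 - 1) / (n_a - 1)}
#' over the observed synonymous proportions \eqn{p_i}. With
#' \eqn{\bar F_k} the mean of valid \eqn{\hat F_a} within each degeneracy
#' class and \eqn{N_k} the number of degeneracy-\eqn{k} amino acids
#' observed in the region,
#' \deqn{N_c = N_1 + N_2/\bar F_2 + N_3/\bar F_3 + N_4/\bar F_4 + N_6/\bar F_6.}
#' If no valid \eqn{\hat F} exists for the 3-fold class (Ile),
#' \eqn{\bar F_3 = (\bar F_2 + \bar F_4)/2} is substituted. Estimates
#' \eqn{\hat F_a \le 0} (possible at small \eqn{n_a}) are treated as
#' missing. The result is truncated at 61; truncation is flagged in the
#' `"truncated"` attribute.
#'
#' The `"ncw"` variant uses pseudocounted proportions
#' \eqn{p_i = (n_i + 1)/(n_a + k)} with \eqn{\hat F_a = \sum_i p_i^2}
#' (the weighted Nc implemented by the CAIcal server).
#'
#' Stop codons, the terminal stop, and codons containing N are excluded
#' before counting.
#'
#' @param x a [CodingSequence-class], a nucleotide string, or a character
#'   vector of codons
#' @param variant `"wright"` (default) or `"ncw"`
#' @return Nc as a single numeric in \[1, 61\] (attribute `"truncated"`
#'   TRUE when the raw estimate exceeded 61), or `NA` with a warning when
#'   no degenerate family has at least two occurrences
#' @examples
#' effectiveCodonNumber(strrep("TTTTTC", 2))   # Phe TTT=2,TTC=2
#' @export
effectiveCodonNumber <- function(x, variant = c("wright", "ncw")) {
  variant <- match.arg(variant)
  cods <- .regionCodons(x)
  if (length(cods) == 0L) stop("region has no countable codons")
  aa <- .translateCodons(cods)
  counts <- split(cods, aa)

  Fhat <- list(`2` = numeric(0), `3` = numeric(0), `4` = numeric(0),
               `6` = numeric(0))
  Nk <- c(`1` = 0L, `2` = 0L, `3` = 0L, `4` = 0L, `6` = 0L)
  for (a in names(counts)) {
    k <- .DEGENERACY[[a]]
    kk <- as.character(k)
    Nk[kk] <- Nk[kk] + 1L
    if (k < 2L) next
    n_a <- length(counts[[a]])
    if (n_a < 2L) next
    ni <- table(factor(counts[[a]], levels = .AA_FAMILIES[[a]]))
    f <- if (variant == "wright") {
      p <- as.numeric(ni) / n_a
      (n_a * sum(p^2) - 1) / (n_a - 1)
    } else {
      p <- (as.numeric(ni) + 1) / (n_a + k)
      sum(p^2)
    }
    if (f <= 0) next  # clamp: treated as missing for this family
    Fhat[[kk]] <- c(Fhat[[kk]], f)
  }

  Fbar <- vapply(Fhat, function(v) if (length(v)) mean(v) else NA_real_,
                 numeric(1))
  if (all(is.na(Fbar))) {
    warning("Nc undefined: no degenerate amino-acid family with >= 2 ",
            "occurrences and a valid homozygosity estimate")
    return(NA_real_)
  }
  if (Nk["3"] > 0L && is.na(Fbar["3"]) &&
      !is.na(Fbar["2"]) && !is.na(Fbar["4"]))
    Fbar["3"] <- (Fbar["2"] + Fbar["4"]) / 2
  nc <- as.numeric(Nk["1"])
  for (kk in c("2", "3", "4", "6")) {
    if (Nk[kk] == 0L) next
    if (is.na(Fbar[kk])) {
      warning("no valid homozygosity estimate for degeneracy-", kk,
              " amino acids; they are omitted from Nc")
      next
    }
    nc <- nc + Nk[kk] / Fbar[kk]
  }
  nc <- unname(nc)
  truncated <- nc > 61
  if (truncated) nc <- 61
  structure(nc, truncated = truncated)
}

#' Flag codon usage bias from an Nc value
#'
#' Sequences with Nc at or below the cutoff (35 by convention) are
#' considered to possess codon usage bias.
#'
#' @param nc numeric Nc value(s); `NA` propagates
#' @param cutoff CUB cutoff (default 35)
#' @return logical
#' @export
classifyCUB <- function(nc, cutoff = 35) {
  nc <- as.numeric(nc)
  nc <= cutoff
}

#' Codon Adaptation Index (CAI)
#'
#' Geometric mean of the relative adaptiveness weights \eqn{w_c} over the
#' region's codons, excluding ATG, TGG and stop codons (non-degenerate and
#' termination codons carry no synonymous choice).
#'
#' @param x region as for [effectiveCodonNumber()]
#' @param table a [CodonUsageTable-class]
#' @return CAI in (0, 1]
#' @export
codonAdaptationIndex <- function(x, table) {
  cods <- .regionCodons(x)
  cods <- cods[!(cods %in% c("ATG", "TGG"))]
  if (length(cods) == 0L)
    stop("no codons contribute to CAI in this region")
  w <- codonWeights(table)[cods]
  exp(mean(log(w)))
}

## expected GC count per residue under the theta-tilted synonymous draw
.tiltedExpectedGC <- function(aaCounts, theta) {
  tot <- 0
  for (a in names(aaCounts)) {
    g <- .CODON_GC_COUNT[.AA_FAMILIES[[a]]]
    q <- theta^g
    tot <- tot + aaCounts[[a]] * sum(q * g) / sum(q)
  }
  tot
}

## sample nRep synonymous codon sequences for aa vector, q ∝ theta^gc(c);
## returns matrix [position, replicate] of codon strings
.sampleSynonymous <- function(aa, theta, nRep) {
  L <- length(aa)
  out <- matrix("", nrow = L, ncol = nRep)
  for (a in unique(aa)) {
    fam <- .AA_FAMILIES[[a]]
    idx <- which(aa == a)
    if (length(fam) == 1L) { out[idx, ] <- fam; next }
    q <- theta^.CODON_GC_COUNT[fam]
    q <- q / sum(q)
    draws <- sample.int(length(fam), length(idx) * nRep, replace = TRUE,
                        prob = q)
    out[idx, ] <- fam[draws]
  }
  out
}

#' Expected CAI (eCAI) from GC-matched random synonymous sequences
#'
#' Generates `nReplicates` random synonymous sequences preserving the
#' region's amino-acid sequence, with each residue's codon drawn from a
#' GC-tilted synonymous distribution \eqn{q_c \propto \theta^{gc(c)}}
#' (\eqn{gc(c)} = number of G/C in the codon). \eqn{\theta} is calibrated
#' by bisection so the expected replicate GC content equals the query
#' region's GC content (tolerance 1e-6); if the query GC lies outside the
#' achievable synonymous range, \eqn{\theta} is clamped to the bracket end
#' with a warning. The CAI of each replicate is computed and the one-sided
#' upper normal tolerance bound \eqn{m + k s} covering `population` of the
#' replicate distribution with confidence `confidence` is returned
#' (\eqn{k} from the noncentral-t factor), clamped at CAI's upper bound 1.
#'
#' @inheritParams codonAdaptationIndex
#' @param nReplicates number of random synonymous replicates (default 500)
#' @param population covered fraction of the replicate CAI distribution
#' @param confidence confidence level of the tolerance bound
#' @param seed integer seed; the result is deterministic given the seed
#' @return eCAI in (0, 1] with attributes `"mean"` and `"sd"` of the
#'   replicate CAI distribution
#' @export
expectedCAI <- function(x, table, nReplicates = 500L, population = 0.90,
                        confidence = 0.90, seed = 20231227L) {
  if (nReplicates < 2L) stop("nReplicates must be >= 2")
  cods <- .regionCodons(x)
  if (length(cods[!(cods %in% c("ATG", "TGG"))]) == 0L)
    stop("no codons contribute to CAI in this region")
  aa <- .translateCodons(cods)
  gcTarget <- sum(.CODON_GC_COUNT[cods])
  aaCounts <- table(aa)

  ## bisection for theta on log scale; expected GC is increasing in theta
  lo <- -30; hi <- 30
  gLo <- .tiltedExpectedGC(aaCounts, exp(lo))
  gHi <- .tiltedExpectedGC(aaCounts, exp(hi))
  if (gcTarget <= gLo + 1e-9 || gcTarget >= gHi - 1e-9) {
    if (gHi - gLo > 1e-9)
      warning("query GC outside achievable synonymous range; ",
              "tilt clamped to bracket end")
    theta <- if (gcTarget <= gLo + 1e-9) exp(lo) else exp(hi)
    if (gHi - gLo <= 1e-9) theta <- 1  # no synonymous GC freedom at all
  } else {
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      g <- .tiltedExpectedGC(aaCounts, exp(mid))
      if (abs(g - gcTarget) < 1e-6) break
      if (g < gcTarget) lo <- mid else hi <- mid
    }
    theta <- exp((lo + hi) / 2)
  }

  logw <- log(codonWeights(table))
  contributes <- !(names(logw) %in% c("ATG", "TGG", .STOP_CODONS))
  cai <- .withSeed(seed, {
    reps <- .sampleSynonymous(aa, theta, nReplicates)
    vapply(seq_len(nReplicates), function(j) {
      c_j <- reps[, j]
      keep <- contributes[match(c_j, names(logw))]
      exp(mean(logw[c_j[keep]]))
    }, numeric(1))
  })

  m <- mean(cai); s <- sd(cai)
  ## noncentral-t quantile; its "full precision" warning is spurious at
  ## the ~1e-6 accuracy relevant here
  k <- suppressWarnings(
    qt(confidence, df = nReplicates - 1L,
       ncp = qnorm(population) * sqrt(nReplicates))) / sqrt(nReplicates)
  bound <- m + k * s
  clamped <- bound > 1
  structure(min(1, bound), mean = m, sd = s, clamped = clamped)
}

#' GC content at the third codon position (GC3%)
#'
#' Percentage of codons whose third position is G or C. Stop codons and
#' codons containing N are excluded; ATG and TGG are included.
#'
#' @param x region as for [effectiveCodonNumber()]
#' @return percentage in \[0, 100\]
#' @export
gc3Percent <- function(x) {
  cods <- .regionCodons(x)
  if (length(cods) == 0L) stop("region has no countable codons")
  third <- substring(cods, 3L, 3L)
  100 * mean(third %in% c("G", "C"))
}

#' GC content (GC%)
#'
#' Percentage of G+C among the region's unambiguous nucleotides (stop
#' codon and N bases excluded).
#'
#' @param x region as for [effectiveCodonNumber()]
#' @return percentage in \[0, 100\]
#' @export
gcPercent <- function(x) {
  nt <- strsplit(paste(.regionCodons(x), collapse = ""), "")[[1L]]
  nt <- nt[nt != "N"]
  if (length(nt) == 0L) stop("region has no countable nucleotides")
  100 * mean(nt %in% c("G", "C"))
}

#' Percent difference of a domain value against a reference value
#'
#' `100 * (domain - reference) / reference`. Used both for the
#' domain-vs-whole-gene normalization of Nc/GC3/GC and for the CAI vs eCAI
#' comparison (positive values indicate frequently used codons, negative
#' values rare codons).
#'
#' @param domainValue,referenceValue numeric
#' @return percent difference; `NA` with a warning when the reference is 0
#' @export
percentDifference <- function(domainValue, referenceValue) {
  out <- 100 * (domainValue - referenceValue) / referenceValue
  zero <- which(!is.na(referenceValue) & referenceValue == 0)
  if (length(zero)) {
    warning("percent difference undefined for zero reference")
    out[zero] <- NA_real_
  }
  out
}

#' Per-region codon-usage-bias report
#'
#' Computes Nc, CAI, eCAI, GC3% and GC% for the whole gene, for each region
#' of the partition, and (optionally) for the first `firstN` codons, then
#' normalizes each domain value against the whole-gene value as a percent
#' difference. Metric failures in a region are reported as `NA` fields
#' (with a warning) rather than aborting the report.
#'
#' @param cds a [CodingSequence-class]
#' @param partition a [DomainPartition-class]
#' @param table a [CodonUsageTable-class]
#' @param ncVariant `"wright"` or `"ncw"`
#' @param ecai compute the eCAI null (default TRUE; the dominant cost)
#' @param ecaiReplicates,population,confidence eCAI parameters
#' @param firstN length of the 5' prefix analysed separately (default 10;
#'   0 disables)
#' @param cubCutoff Nc cutoff for the CUB flag (default 35)
#' @param seed integer seed for the eCAI replicates
#' @return data.frame, one row per region, with columns gene, species,
#'   region, n_codons, nc, nc_variant, cai, ecai, cai_vs_ecai_pct, gc3_pct,
#'   gc_pct, nc_norm_pct, gc3_norm_pct, gc_norm_pct, cub_flag
#' @export
regionReport <- function(cds, partition, table,
                         ncVariant = c("wright", "ncw"), ecai = TRUE,
                         ecaiReplicates = 500L, population = 0.90,
                         confidence = 0.90, firstN = 10L, cubCutoff = 35,
                         seed = 20231227L) {
  ncVariant <- match.arg(ncVariant)
  nSense <- length(senseCodons(cds))
  regs <- list(whole = c(0L, nSense))
  r <- regions(partition)
  for (i in seq_len(nrow(r))) regs[[r$name[i]]] <- c(r$start[i], r$end[i])
  if (firstN > 0L && firstN <= nSense)
    regs[[paste0("first_", firstN)]] <- c(0L, as.integer(firstN))

  one <- function(name, coords, k) {
    sub <- extractRegion(cds, coords)
    saf <- function(f) tryCatch(f, error = function(e) {
      warning("region '", name, "': ", conditionMessage(e)); NA_real_ })
    ncv <- saf(as.numeric(effectiveCodonNumber(sub, variant = ncVariant)))
    caiv <- saf(codonAdaptationIndex(sub, table))
    ecaiv <- if (ecai)
      saf(as.numeric(expectedCAI(sub, table, nReplicates = ecaiReplicates,
                                 population = population,
                                 confidence = confidence,
                                 seed = .deriveSeed(seed, k))))
      else NA_real_
    data.frame(gene = cdsGene(cds), species = cdsSpecies(cds), region = name,
               n_codons = length(senseCodons(sub)), nc = ncv,
               nc_variant = ncVariant, cai = caiv, ecai = ecaiv,
               cai_vs_ecai_pct = if (!is.na(caiv) && !is.na(ecaiv))
                 percentDifference(caiv, ecaiv) else NA_real_,
               gc3_pct = saf(gc3Percent(sub)), gc_pct = saf(gcPercent(sub)))
  }

  rows <- do.call(rbind, lapply(seq_along(regs), function(k)
    one(names(regs)[k], regs[[k]], k)))
  whole <- rows[rows$region == "whole", ]
  rows$nc_norm_pct <- percentDifference(rows$nc, whole$nc)
  rows$gc3_norm_pct <- percentDifference(rows$gc3_pct, whole$gc3_pct)
  rows$gc_norm_pct <- percentDifference(rows$gc_pct, whole$gc_pct)
  rows$cub_flag <- classifyCUB(rows$nc, cubCutoff)
  rownames(rows) <- NULL
  rows
}
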