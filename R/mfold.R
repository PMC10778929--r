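## Local folding energy (LFE) profiles: sliding-window minimum free energy
## of the native mRNA minus the mean over whole-sequence synonymous-codon
## permutations (deltaLFE), plus x-intercepts and ramp lengths.

#' Folding backends
#'
#' A folding backend is a list with a `name` and an `energy` function
#' mapping a character vector of RNA windows to a numeric vector of
#' minimum free energies (always <= 0; 0 for an unpairable sequence; `NA`
#' elements pass through as `NA`).
#'
#' `builtinFoldBackend()` is the default: a nested-structure (no
#' pseudoknots) dynamic program over pairs AU, GC, GU with stabilities
#' 2, 3, 1, minimum hairpin loop of 3 unpaired bases, and energy
#' `-(3 #GC + 2 #AU + 1 #GU)` in arbitrary units. It is exact (equal to
#' exhaustive enumeration over all nested structures) and dependency-free.
#'
#' `viennaFoldBackend()` wraps the external `RNAfold` program (ViennaRNA)
#' behind the same contract and returns thermodynamic energies in
#' kcal/mol; it errors if `RNAfold` is not on the PATH.
#'
#' @param minLoop minimum hairpin loop size for the built-in model
#' @return a backend list with elements `name` and `energy`
#' @export
builtinFoldBackend <- function(minLoop = 3L) {
  list(name = "builtin",
       energy = function(windows) .foldMFEBatch(as.character(windows),
                                                as.integer(minLoop)))
}

#' @rdname builtinFoldBackend
#' @export
viennaFoldBackend <- function() {
  if (Sys.which("RNAfold") == "")
    stop("RNAfold not found on PATH; install ViennaRNA or use builtinFoldBackend()")
  list(name = "vienna", energy = function(windows) {
    windows <- as.character(windows)
    out <- rep(NA_real_, length(windows))
    ok <- !is.na(windows)
    if (!any(ok)) return(out)
    res <- system2("RNAfold", c("--noPS"), input = windows[ok], stdout = TRUE)
    elines <- grep("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", res, value = TRUE)
    if (length(elines) != sum(ok)) stop("unexpected RNAfold output")
    out[ok] <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1",
                              elines))
    out
  })
}

#' Minimum folding energy of RNA windows
#'
#' @param windows character vector of RNA/DNA windows (T is read as U)
#' @param backend a folding backend (see [builtinFoldBackend()])
#' @return numeric vector of energies (<= 0)
#' @examples
#' foldEnergy("GGGAAAACCC")   # three GC pairs closing a 4-base loop: -9
#' @export
foldEnergy <- function(windows, backend = builtinFoldBackend()) {
  backend$energy(chartr("T", "U", toupper(as.character(windows))))
}

#' Optimal structure of one window under the built-in model
#'
#' @param window a single RNA/DNA string
#' @param minLoop minimum hairpin loop size
#' @return list with `energy` and dot-bracket `structure`
#' @export
foldStructure <- function(window, minLoop = 3L) {
  .foldStructureOne(chartr("T", "U", toupper(as.character(window))),
                    as.integer(minLoop))
}

#' Full sliding windows over a nucleotide sequence
#'
#' Emits every complete window `[s, s + window)` with
#' `s = 0, step, 2 step, ...`; no partial tail window is produced. If the
#' sequence is shorter than one window an empty result is returned with a
#' warning.
#'
#' @param seq nucleotide string
#' @param window window width in nt (default 40)
#' @param step step between window starts in nt (default 10)
#' @return data.frame with columns `start` (0-based nt offset) and `seq`
#' @export
nucleotideWindows <- function(seq, window = 40L, step = 10L) {
  stopifnot(window > 0L, step > 0L)
  seq <- .normalizeSeq(seq)
  n <- nchar(seq)
  if (n < window) {
    warning("sequence shorter than one window (", n, " < ", window, ")")
    return(data.frame(start = integer(0L), seq = character(0L)))
  }
  starts <- seq.int(0L, n - window, by = step)
  data.frame(start = as.integer(starts),
             seq = substring(seq, starts + 1L, starts + window))
}

#' Synonymous-codon permutation of a CDS
#'
#' Shuffles codons uniformly at random among positions encoding the same
#' amino acid. The protein sequence and the codon multiset (hence the
#' nucleotide content) are exactly preserved. Codons containing N and stop
#' codons are left in place.
#'
#' @param cds a [CodingSequence-class]
#' @param seed integer seed; `NULL` uses the current RNG state
#' @return a [CodingSequence-class] with permuted codons
#' @export
synonymousPermutation <- function(cds, seed = NULL) {
  cods <- codons(cds)
  .withSeed(seed, {
    aa <- .translateCodons(cods)
    aa[grepl("N", cods)] <- "X"          # ambiguity: not exchangeable
    for (a in unique(aa)) {
      if (a == "X") next
      idx <- which(aa == a)
      if (length(idx) > 1L) cods[idx] <- cods[sample(idx)]
    }
    CodingSequence(paste(cods, collapse = ""), id = cdsID(cds),
                   species = cdsSpecies(cds), gene = cdsGene(cds))
  })
}

## internal: x-intercepts by linear interpolation between window anchors
.xIntercepts <- function(starts, values) {
  keep <- !is.na(values)
  if (!any(keep)) stop("all-missing deltaLFE profile")
  s <- starts[keep]; v <- values[keep]
  out <- numeric(0L)
  out <- c(out, s[v == 0])               # exact zeros at the window start
  if (length(v) >= 2L) {
    for (i in seq_len(length(v) - 1L)) {
      if (v[i] == 0 || v[i + 1L] == 0) next
      if (sign(v[i]) != sign(v[i + 1L]))
        out <- c(out, s[i] + (s[i + 1L] - s[i]) * v[i] / (v[i] - v[i + 1L]))
    }
  }
  sort(out)
}

## internal: ramp length in codons — length of the 5' prefix with
## weaker-than-predicted structure (deltaLFE > 0)
.rampCodons <- function(starts, values, window) {
  keep <- !is.na(values)
  s <- starts[keep]; v <- values[keep]
  if (length(v) == 0L) return(NA_integer_)
  if (v[1L] <= 0) return(0L)
  for (i in seq_len(length(v) - 1L)) {
    if (v[i] > 0 && v[i + 1L] <= 0) {
      x <- if (v[i + 1L] == 0) s[i + 1L] else
        s[i] + (s[i + 1L] - s[i]) * v[i] / (v[i] - v[i + 1L])
      return(as.integer(floor(x / 3)))
    }
  }
  as.integer(floor((s[length(s)] + window) / 3))
}

#' deltaLFE profile of a coding sequence
#'
#' For each full sliding window of the CDS (terminal stop stripped), the
#' native local folding energy and the mean energy of the same window
#' extracted from `nPermutations` whole-sequence synonymous-codon
#' permutations are computed; deltaLFE = native - permuted mean. Negative
#' deltaLFE indicates stronger than predicted secondary structure. Windows
#' containing an ambiguous base are reported as `NA`.
#'
#' @param cds a [CodingSequence-class]
#' @param nPermutations number of synonymous permutations (default 20)
#' @param window,step sliding-window width and step in nt (defaults 40, 10)
#' @param backend folding backend (see [builtinFoldBackend()])
#' @param seed integer seed driving the permutations
#' @return an [LFEProfile-class]
#' @export
deltaLFEProfile <- function(cds, nPermutations = 20L, window = 40L,
                            step = 10L, backend = builtinFoldBackend(),
                            seed = 20231227L) {
  sense <- paste(senseCodons(cds), collapse = "")
  wins <- nucleotideWindows(sense, window = window, step = step)
  if (nrow(wins) == 0L)
    stop("CDS shorter than one window; no profile")
  strip <- CodingSequence(sense, id = cdsID(cds), species = cdsSpecies(cds),
                          gene = cdsGene(cds))
  perms <- .withSeed(seed, lapply(seq_len(nPermutations), function(r)
    synonymousPermutation(strip)))

  starts <- wins$start
  natWin <- wins$seq
  natWin[grepl("N", natWin)] <- NA_character_
  permWin <- unlist(lapply(perms, function(p)
    substring(cdsSeq(p), starts + 1L, starts + window)), use.names = FALSE)
  permWin[grepl("N", permWin)] <- NA_character_

  energies <- foldEnergy(c(natWin, permWin), backend = backend)
  native <- energies[seq_along(starts)]
  permMat <- matrix(energies[-seq_along(starts)], nrow = length(starts))
  permMean <- rowMeans(permMat)
  delta <- native - permMean

  new("LFEProfile", gene = cdsGene(cds), species = cdsSpecies(cds),
      windowStarts = as.integer(starts), nativeLFE = native,
      permutedMeanLFE = permMean, deltaLFE = delta,
      xIntercepts = .xIntercepts(starts, delta),
      rampCodons = .rampCodons(starts, delta, window),
      window = as.integer(window), step = as.integer(step),
      nPermutations = as.integer(nPermutations))
}

#' x-intercepts of a deltaLFE trace
#'
#' Positions (in nt from the CDS start) where the window-start-anchored
#' deltaLFE trace crosses zero, by linear interpolation between
#' consecutive window anchors; exact zeros are reported at their window
#' start. For an [LFEProfile-class] the intercepts computed at
#' construction are returned; a numeric vector of deltaLFE values may also
#' be supplied together with its window `starts`.
#'
#' @param x an [LFEProfile-class] or a numeric vector of deltaLFE values
#' @param starts window start positions (required for numeric `x`)
#' @param ... ignored
#' @return numeric vector of nt positions
#' @export
setGeneric("xIntercepts", function(x, ...) standardGeneric("xIntercepts"))

#' @rdname xIntercepts
#' @export
setMethod("xIntercepts", "LFEProfile", function(x, ...) x@xIntercepts)

#' @rdname xIntercepts
#' @export
setMethod("xIntercepts", "numeric", function(x, starts, ...)
  .xIntercepts(starts, x))

#' Aggregate deltaLFE profiles across species
#'
#' Unweighted mean deltaLFE per window start across all species possessing
#' that window (aligned from the CDS start); the number of contributing
#' species is recorded per position and positions with none are dropped.
#'
#' @param profiles list of [LFEProfile-class] objects for one gene
#' @return an [AggregateProfile-class]
#' @export
aggregateProfiles <- function(profiles) {
  if (length(profiles) == 0L) stop("no profiles to aggregate")
  genes <- unique(vapply(profiles, function(p) p@gene, ""))
  if (length(genes) != 1L)
    stop("profiles mix genes: ", paste(genes, collapse = ", "))
  starts <- sort(unique(unlist(lapply(profiles, windowStarts))))
  sums <- numeric(length(starts)); n <- integer(length(starts))
  for (p in profiles) {
    i <- match(windowStarts(p), starts)
    d <- deltaLFE(p)
    ok <- !is.na(d)
    sums[i[ok]] <- sums[i[ok]] + d[ok]
    n[i[ok]] <- n[i[ok]] + 1L
  }
  keep <- n > 0L
  new("AggregateProfile", gene = genes,
      windowStarts = as.integer(starts[keep]),
      meanDeltaLFE = sums[keep] / n[keep], nSpecies = n[keep])
}

#' Plot a deltaLFE profile
#'
#' @param x an [LFEProfile-class] or [AggregateProfile-class]
#' @param y ignored
#' @param ... passed to [graphics::plot.default()]
#' @return invisibly, `x`
#' @importFrom graphics abline lines
#' @export
plot.LFEProfile <- function(x, y, ...) {
  plot(x@windowStarts, x@deltaLFE, type = "l",
       xlab = "distance from CDS start (nt)", ylab = "deltaLFE",
       main = sprintf("%s / %s", x@gene, x@species), ...)
  abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' @rdname plot.LFEProfile
#' @export
plot.AggregateProfile <- function(x, y, ...) {
  plot(x@windowStarts, x@meanDeltaLFE, type = "l",
       xlab = "distance from CDS start (nt)", ylab = "mean deltaLFE",
       main = x@gene, ...)
  abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}
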