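# Independent oracles, deliberately naive: exhaustive enumeration and
# brute force, never sharing code with the implementation under test.

# exhaustive max pairing score over ALL nested structures (no memoisation):
# at each step either leave position i unpaired or pair it with any legal k
oracleFoldEnergy <- function(seq, minLoop = 3L) {
  score <- function(a, b) {
    p <- paste0(a, b)
    if (p %in% c("GC", "CG")) return(3L)
    if (p %in% c("AU", "UA")) return(2L)
    if (p %in% c("GU", "UG")) return(1L)
    0L
  }
  b <- strsplit(chartr("T", "U", toupper(seq)), "")[[1L]]
  best <- function(i, j) {
    if (j - i < minLoop + 1L) return(0L)
    m <- best(i + 1L, j)
    for (k in (i + minLoop + 1L):j) {
      s <- score(b[i], b[k])
      if (s == 0L) next
      m <- max(m, s + best(i + 1L, k - 1L) +
                 (if (k < j) best(k + 1L, j) else 0L))
    }
    m
  }
  if (length(b) < minLoop + 2L) return(0)
  as.numeric(-best(1L, length(b)))
}

# longest gap run by character-wise scan
oracleMaxGapRun <- function(row) {
  best <- 0L; cur <- 0L
  for (ch in strsplit(row, "")[[1L]]) {
    if (ch == "-") { cur <- cur + 1L; best <- max(best, cur) }
    else cur <- 0L
  }
  best
}

# translation through seqinr (independent genetic-code implementation)
oracleTranslate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1L]])
}

# variant classification via the seqinr-based translation oracle
oracleClassify <- function(codonBefore, offset, alt) {
  codonAfter <- codonBefore
  substring(codonAfter, offset + 1L, offset + 1L) <- alt
  aaB <- oracleTranslate(codonBefore)
  aaA <- oracleTranslate(codonAfter)
  if (aaB == aaA) "synonymous"
  else if (aaA == "*") "nonsense"
  else if (aaB == "*") "stop_loss"
  else "missense"
}

# direct hand computation of Wright's estimator for one k=2 family
oracleNcTwoFold <- function(countA, countB) {
  n <- countA + countB
  p <- c(countA, countB) / n
  f <- (n * sum(p^2) - 1) / (n - 1)
  1 / f
}
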