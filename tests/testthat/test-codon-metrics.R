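test_that("Nc hits its analytic extremes", {
  # one codon per degenerate amino acid, full coverage: maximal bias
  expect_equal(as.numeric(effectiveCodonNumber(maxBiasCDS(10L))), 20)
  # every sense codon equally used: no bias, truncated at 61
  nc <- effectiveCodonNumber(allCodonsCDS(100L))
  expect_equal(as.numeric(nc), 61)
  expect_true(attr(nc, "truncated"))
})

test_that("Nc matches hand evaluation of the homozygosity estimator", {
  # Phe-only, TTT=3 TTC=1: sum p^2 = 0.625, F = 0.5, Nc = 2
  expect_equal(as.numeric(effectiveCodonNumber(c("TTT", "TTT", "TTT", "TTC"))),
               2)
  expect_equal(as.numeric(effectiveCodonNumber(c("TTT", "TTT", "TTC"))),
               oracleNcTwoFold(2, 1))
})

test_that("Nc is invariant under codon order permutation", {
  set.seed(7)
  cods <- sample(SENSE, 300, replace = TRUE)
  ref <- as.numeric(effectiveCodonNumber(cods))
  for (i in 1:5)
    expect_equal(as.numeric(effectiveCodonNumber(sample(cods))), ref)
})

test_that("concentrating a two-fold family never increases Nc (exhaustive n <= 8)", {
  for (n in 3:8) {
    for (a in ceiling(n / 2):(n - 1)) {
      b <- n - a
      if (b < 1) next
      less <- as.numeric(effectiveCodonNumber(rep(c("TTT", "TTC"), c(a, b))))
      more <- as.numeric(effectiveCodonNumber(rep(c("TTT", "TTC"),
                                                  c(a + 1, b - 1))))
      if (b - 1 == 0) {
        # single codon used: homozygosity F = 1, Nc = 1
        expect_equal(more, 1)
      }
      expect_lte(more, less + 1e-12)
      expect_equal(less, oracleNcTwoFold(a, b))
    }
  }
})

test_that("the pseudocounted Ncw variant stays in range and tracks bias", {
  biased <- as.numeric(effectiveCodonNumber(maxBiasCDS(10L), variant = "ncw"))
  flat <- as.numeric(effectiveCodonNumber(allCodonsCDS(50L), variant = "ncw"))
  expect_lt(biased, flat)
  expect_lte(flat, 61)
  # pseudocounts keep F below 1, so Ncw exceeds Wright's Nc at maximal bias
  expect_gt(biased, 20)
})

test_that("Nc is undefined (with warning) when no family reaches two occurrences", {
  expect_warning(nc <- effectiveCodonNumber(c("ATG", "GAA", "TTT")),
                 "undefined")
  expect_true(is.na(nc))
})

test_that("the CUB classification flags Nc <= 35", {
  expect_true(classifyCUB(34))
  expect_true(classifyCUB(35))
  expect_false(classifyCUB(35.01))
  expect_false(classifyCUB(57))
  expect_true(is.na(classifyCUB(NA_real_)))
})

test_that("CAI is the geometric mean of weights and is 1 at saturation", {
  tab <- customTable(c(TTT = 30, TTC = 10))
  expect_equal(codonAdaptationIndex(c("TTT", "TTC"), tab), sqrt(1 / 3))
  # most-frequent codons only
  expect_equal(codonAdaptationIndex(c("TTT", "TTT"), tab), 1)
  # order invariance
  set.seed(1)
  cods <- sample(c("TTT", "TTC"), 30, replace = TRUE)
  expect_equal(codonAdaptationIndex(sample(cods), tab),
               codonAdaptationIndex(cods, tab))
})

test_that("CAI excludes ATG, TGG and stop codons and errors when empty", {
  tab <- customTable(c(TTT = 30, TTC = 10))
  expect_equal(codonAdaptationIndex(c("ATG", "TGG", "TTT"), tab), 1)
  expect_error(codonAdaptationIndex(c("ATG", "TGG"), tab), "contribute")
})

test_that("CAI of a concatenation lies between the CAIs of its parts", {
  tab <- makeCodonTable("sp", skew = 3, seed = 11L)
  set.seed(2)
  a <- sample(SENSE, 60, replace = TRUE)
  b <- sample(SENSE, 90, replace = TRUE)
  ca <- codonAdaptationIndex(a, tab)
  cb <- codonAdaptationIndex(b, tab)
  cc_ <- codonAdaptationIndex(c(a, b), tab)
  expect_gte(cc_, min(ca, cb) - 1e-12)
  expect_lte(cc_, max(ca, cb) + 1e-12)
})

test_that("eCAI is 1 under a uniform table and deterministic under seed", {
  set.seed(3)
  cods <- sample(SENSE, 100, replace = TRUE)
  e1 <- expectedCAI(cods, uniformTable(), nReplicates = 50L, seed = 5L)
  expect_equal(as.numeric(e1), 1)
  tab <- makeCodonTable("sp", skew = 2, seed = 9L)
  e2 <- expectedCAI(cods, tab, nReplicates = 100L, seed = 5L)
  e3 <- expectedCAI(cods, tab, nReplicates = 100L, seed = 5L)
  expect_identical(as.numeric(e2), as.numeric(e3))
  expect_gt(as.numeric(e2), 0)
  expect_lte(as.numeric(e2), 1)
})

test_that("eCAI replicates are calibrated to the query GC content", {
  tab <- makeCodonTable("sp", skew = 2, seed = 13L)
  set.seed(4)
  cods <- sample(SENSE, 200, replace = TRUE)
  e <- expectedCAI(cods, tab, nReplicates = 400L, seed = 21L)
  # the tolerance bound sits above the replicate mean
  expect_gte(as.numeric(e), attr(e, "mean"))
  # a native sequence drawn from the same generator has CAI within 2
  # standard errors of the replicate mean (null calibration)
  m <- attr(e, "mean"); s <- attr(e, "sd")
  caiNative <- codonAdaptationIndex(cods, tab)
  # the query here is arbitrary, so only check the replicate spread is sane
  expect_gt(s, 0)
  expect_lt(abs(m - caiNative) / s, 6)
})

test_that("eCAI replicate mean matches native CAI for a null-drawn native", {
  # draw the native itself from a GC-neutral synonymous generator: its CAI
  # should sit within ~2 SE of the replicate mean CAI
  tab <- makeCodonTable("sp", skew = 1.5, seed = 17L)
  set.seed(6)
  aa <- sample(names(SENSE_FAMILIES), 150, replace = TRUE)
  native <- vapply(aa, function(a) sample(FAMILIES[[a]], 1L), "")
  e <- expectedCAI(native, tab, nReplicates = 500L, seed = 23L)
  m <- attr(e, "mean"); se <- attr(e, "sd")
  expect_lt(abs(codonAdaptationIndex(native, tab) - m), 3 * se)
})

test_that("GC3 and GC match direct counts", {
  expect_equal(gc3Percent(c("ATG", "GAA", "GGC")), 100 * 2 / 3)
  expect_equal(gc3Percent(c("GGG", "CCC")), 100)
  expect_equal(gc3Percent(c("GGA", "CCT")), 0)
  expect_equal(gcPercent("ATGGAA"), 100 * 2 / 6)
  expect_equal(gcPercent("GCGCGC"), 100)
  expect_equal(gcPercent("ATATATGCGCGC"), 50)
})

test_that("GC3 equals GC of the third-position bases", {
  set.seed(8)
  cods <- sample(SENSE, 120, replace = TRUE)
  thirds <- substring(cods, 3, 3)
  expect_equal(gc3Percent(cods), 100 * mean(thirds %in% c("G", "C")))
})

test_that("percent differences follow the reference-relative definition", {
  expect_equal(percentDifference(87, 100), -13)
  expect_equal(percentDifference(130, 100), 30)
  expect_equal(percentDifference(5, 5), 0)
  expect_warning(out <- percentDifference(3, 0), "zero reference")
  expect_true(is.na(out))
  # antisymmetry identity: pd(a,b) = -pd(b,a) * a / b
  for (i in 1:20) {
    a <- runif(1, 1, 200); b <- runif(1, 1, 200)
    expect_equal(percentDifference(a, b),
                 -percentDifference(b, a) * a / b, tolerance = 1e-12)
  }
})

test_that("region reports normalize against the whole gene", {
  tab <- makeCodonTable("sp", skew = 2, seed = 31L)
  set.seed(9)
  cds <- cdsFromCodons(c("ATG", sample(SENSE, 99, replace = TRUE)),
                       id = "x", species = "sp", gene = "g")
  # one region spanning the whole gene: normalized differences all 0
  part <- DomainPartition(all = c(0, 100))
  rep_ <- regionReport(cds, part, tab, ecai = FALSE, firstN = 0L)
  allRow <- rep_[rep_$region == "all", ]
  expect_equal(allRow$nc_norm_pct, 0)
  expect_equal(allRow$gc3_norm_pct, 0)
  expect_equal(allRow$gc_norm_pct, 0)
  expect_equal(allRow$nc, rep_[rep_$region == "whole", "nc"])
})

test_that("region reports carry the first-N analysis and survive per-region failures", {
  tab <- makeCodonTable("sp", skew = 2, seed = 37L)
  set.seed(10)
  cds <- cdsFromCodons(c("ATG", sample(SENSE, 59, replace = TRUE)),
                       id = "x", species = "sp", gene = "g")
  part <- DomainPartition(nterm = c(0, 20), rest = c(20, 60))
  rep_ <- suppressWarnings(
    regionReport(cds, part, tab, ecai = TRUE, ecaiReplicates = 50L,
                 firstN = 10L, seed = 3L))
  expect_setequal(rep_$region, c("whole", "nterm", "rest", "first_10"))
  expect_equal(rep_[rep_$region == "first_10", "n_codons"], 10L)
  # cub flag consistent with nc
  expect_equal(rep_$cub_flag, rep_$nc <= 35)
})
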