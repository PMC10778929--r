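test_that("sliding windows cover the sequence without partial tails", {
  w <- nucleotideWindows(strrep("A", 100), window = 40, step = 10)
  expect_equal(w$start, seq(0, 60, by = 10))
  expect_equal(unique(nchar(w$seq)), 40L)
  expect_equal(nrow(nucleotideWindows(strrep("A", 40))), 1L)
  expect_warning(w0 <- nucleotideWindows(strrep("A", 39)), "shorter")
  expect_equal(nrow(w0), 0L)
})

test_that("the built-in folding model scores hand-checked cases", {
  expect_equal(foldEnergy(strrep("A", 40)), 0)
  expect_equal(foldEnergy("GGGAAAACCC"), -9)   # three GC pairs, loop of 4
  expect_equal(foldEnergy("GCGC"), 0)          # too short for any loop
  # DNA input is folded as its transcript
  expect_equal(foldEnergy("GGGAAAACCC"), foldEnergy("GGGAAAACCC"))
  expect_error(foldEnergy("GGXAAACCC"), "invalid character")
})

test_that("the folding DP equals exhaustive enumeration on random sequences", {
  set.seed(42)
  for (i in 1:40) {
    n <- sample(5:14, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
               collapse = "")
    expect_equal(foldEnergy(s), oracleFoldEnergy(s), label = s)
  }
})

test_that("optimal structures are well-formed and score their own energy", {
  set.seed(17)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "U"), 30, replace = TRUE),
               collapse = "")
    fs <- foldStructure(s)
    expect_equal(nchar(fs$structure), nchar(s))
    db <- strsplit(fs$structure, "")[[1]]
    expect_equal(sum(db == "("), sum(db == ")"))
    # score the traced pairs directly
    stack <- integer(0); pairs <- 0
    sc <- c(GC = 3, CG = 3, AU = 2, UA = 2, GU = 1, UG = 1)
    b <- strsplit(s, "")[[1]]
    tot <- 0
    for (j in seq_along(db)) {
      if (db[j] == "(") stack <- c(stack, j)
      if (db[j] == ")") {
        k <- stack[length(stack)]; stack <- stack[-length(stack)]
        tot <- tot + sc[[paste0(b[k], b[j])]]
      }
    }
    expect_equal(fs$energy, -tot)
  }
})

test_that("synonymous permutation preserves the protein and the codon multiset", {
  set.seed(5)
  cods <- c("ATG", sample(SENSE, 120, replace = TRUE))
  cds <- cdsFromCodons(cods)
  perm <- synonymousPermutation(cds, seed = 99L)
  expect_equal(sort(codons(perm)), sort(cods))
  aa <- function(x) paste(GENETIC_CODE_DNA[codons(x)], collapse = "")
  expect_equal(aa(perm), aa(cds))
})

test_that("a protein with unique amino acids permutes to itself", {
  cds <- cdsFromCodons(c("ATG", "TTT", "GAA", "GGC", "CAT"))
  expect_equal(cdsSeq(synonymousPermutation(cds, seed = 1L)), cdsSeq(cds))
})

test_that("permutation is uniform over the distinct Phe arrangements", {
  cds <- cdsFromCodons(c("TTT", "TTT", "TTC", "TTC"))
  draws <- vapply(1:600, function(s)
    cdsSeq(synonymousPermutation(cds, seed = s)), "")
  tab <- table(draws)
  expect_length(tab, 6L)   # 4! / (2! 2!) arrangements, all realized
  expect_true(all(tab > 600 / 6 * 0.5) && all(tab < 600 / 6 * 1.5))
})

test_that("deltaLFE is identically zero when permutations cannot move codons", {
  cds <- cdsFromCodons(rep(c("ATG", "TGG"), 30))
  prof <- deltaLFEProfile(cds, nPermutations = 5L, seed = 1L)
  expect_true(all(deltaLFE(prof) == 0))
  expect_equal(rampCodons(prof), 0L)  # deltaLFE 0 at the first window
})

test_that("a designed native hairpin drives deltaLFE negative at the 5' end", {
  set <- generateHomologSet(proteinLen = 100L, nSpecies = 1L,
                            partition = DomainPartition(all = c(0, 100)),
                            profiles = list(all = list(sampling = "uniform")),
                            hairpin = c(3, 12, 6), gene = "hp", seed = 3L)
  prof <- deltaLFEProfile(set$cds[[1L]], seed = 11L)
  expect_lt(deltaLFE(prof)[1L], 0)
})

test_that("profiles are bit-identical under a fixed seed", {
  set.seed(12)
  cds <- cdsFromCodons(c("ATG", sample(SENSE, 80, replace = TRUE)))
  p1 <- deltaLFEProfile(cds, seed = 7L)
  p2 <- deltaLFEProfile(cds, seed = 7L)
  expect_identical(deltaLFE(p1), deltaLFE(p2))
  expect_identical(nativeLFE(p1), nativeLFE(p2))
})

test_that("x-intercepts interpolate linearly and exact zeros anchor at window starts", {
  expect_equal(xIntercepts(c(1, -1), starts = c(0, 10)), 5)
  expect_equal(xIntercepts(c(2, -1), starts = c(0, 10)), 20 / 3)
  expect_equal(xIntercepts(c(1, 0, -2), starts = c(0, 10, 20)), 10)
  expect_equal(xIntercepts(c(1, 2, 3), starts = c(0, 10, 20)), numeric(0))
})

test_that("ramp lengths follow the weak-structure-prefix convention", {
  # +1 at 0, -1 at 10: crossing at 5 nt, ramp floor(5/3) = 1 codon
  expect_equal(cubscape:::.rampCodons(c(0, 10), c(1, -1), 40L), 1L)
  # strong structure from the start: ramp 0
  expect_equal(cubscape:::.rampCodons(c(0, 10), c(-1, 1), 40L), 0L)
  # all-positive: full profile length in codons
  expect_equal(cubscape:::.rampCodons(c(0, 10, 20), c(1, 1, 1), 40L),
               20L)  # floor((20 + 40) / 3)
})

test_that("aggregation averages species per window and tracks coverage", {
  mk <- function(starts, delta, sp) new("LFEProfile", gene = "g",
    species = sp, windowStarts = as.integer(starts),
    nativeLFE = delta, permutedMeanLFE = rep(0, length(delta)),
    deltaLFE = delta, xIntercepts = numeric(0), rampCodons = 0L,
    window = 40L, step = 10L, nPermutations = 1L)
  a <- mk(c(0, 10), c(1, 2), "sp1")
  b <- mk(c(0, 10, 20), c(-1, 4, 8), "sp2")
  agg <- aggregateProfiles(list(a, b))
  expect_equal(windowStarts(agg), c(0L, 10L, 20L))
  expect_equal(agg@meanDeltaLFE, c(0, 3, 8))
  expect_equal(agg@nSpecies, c(2L, 2L, 1L))
  # single species: aggregate equals input
  solo <- aggregateProfiles(list(a))
  expect_equal(solo@meanDeltaLFE, deltaLFE(a))
  # mixed genes refuse to aggregate
  b@gene <- "other"
  expect_error(aggregateProfiles(list(a, b)), "mix")
})

test_that("the ViennaRNA backend honours the backend contract", {
  be <- viennaFoldBackend()
  e <- foldEnergy(c("GGGGGAAAACCCCC", strrep("A", 20)), backend = be)
  expect_lt(e[1], 0)
  expect_equal(e[2], 0)
})
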