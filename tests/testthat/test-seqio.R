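test_that("FASTA records parse into frame-validated coding sequences", {
  p <- writeTempFasta(c(">B56a|Homo_sapiens|x", "ATGGAATAA",
                        ">lonely_header", "atggaauaa"))
  recs <- readCodingFasta(p)
  expect_length(recs, 2L)
  expect_equal(codons(recs[["x"]]), c("ATG", "GAA", "TAA"))
  expect_equal(cdsGene(recs[["x"]]), "B56a")
  expect_equal(cdsSpecies(recs[["x"]]), "Homo_sapiens")
  # lowercase and RNA U normalize to the same DNA sequence
  expect_equal(cdsSeq(recs[["lonely_header"]]), "ATGGAATAA")
  expect_equal(cdsID(recs[["lonely_header"]]), "lonely_header")
})

test_that("records violating the frame or containing internal stops are rejected by id", {
  p <- writeTempFasta(c(">g|s|bad_frame", "ATGGAATAAG",
                        ">g|s|internal_stop", "ATGTAAGAATAA",
                        ">g|s|good", "ATGGAATAA"))
  expect_warning(recs <- readCodingFasta(p), "bad_frame")
  expect_named(recs, "good")
})

test_that("FASTA write/read round-trips all fields", {
  cds <- list(CodingSequence("ATGGAAGGCTAA", id = "acc1",
                             species = "Mus_musculus", gene = "B56d/g"),
              CodingSequence("ATGTTTTTC", id = "acc2",
                             species = "Rattus_norvegicus", gene = "B56e"))
  p <- tempfile(fileext = ".fasta")
  writeCodingFasta(cds, p)
  back <- readCodingFasta(p)
  for (x in cds) {
    y <- back[[cdsID(x)]]
    expect_equal(cdsSeq(y), cdsSeq(x))
    expect_equal(cdsSpecies(y), cdsSpecies(x))
    expect_equal(cdsGene(y), cdsGene(x))
  }
})

test_that("Kazusa codon table entries map to per-thousand frequencies and weights", {
  p <- tempfile(fileext = ".txt")
  fields <- sprintf("%s %.1f (%d)", chartr("T", "U", names(GENETIC_CODE_DNA)),
                    rep(15.6, 64), rep(1000L, 64))
  fields[1] <- "UUU 30.0 (3000)"   # TTT
  fields[2] <- "UUC 10.0 (1000)"   # TTC
  writeLines(paste(fields, collapse = "  "), p)
  tab <- readCodonTable(p, species = "test_species")
  expect_equal(unname(codonFreq(tab)["TTT"]), 30)
  expect_equal(unname(codonWeights(tab)["TTT"]), 1)
  expect_equal(unname(codonWeights(tab)["TTC"]), 1 / 3)
  expect_equal(tableSpecies(tab), "test_species")
})

test_that("codon tables with missing codons or negative frequencies error", {
  p <- tempfile(fileext = ".txt")
  writeLines("UUU 17.6 (714298)", p)
  expect_error(readCodonTable(p), "missing codons")
  expect_error(CodonUsageTable("x", setNames(c(-1, rep(1, 63)),
                                             names(GENETIC_CODE_DNA))),
               "negative")
})

test_that("uniform synonymous frequencies give weight 1 everywhere", {
  expect_true(all(codonWeights(uniformTable()) == 1))
})

test_that("zero-frequency codons receive a positive pseudo-weight", {
  tab <- customTable(c(TTT = 30, TTC = 0))
  w <- codonWeights(tab)
  expect_gt(w[["TTC"]], 0)
  expect_equal(unname(w[["TTC"]]), 0.5 / 30)
})

test_that("codon table write/read round-trips frequencies exactly", {
  tab <- makeCodonTable("sp1", skew = 2, seed = 42L)
  p <- tempfile(fileext = ".txt")
  writeCodonTable(tab, p)
  back <- readCodonTable(p, species = "sp1")
  expect_equal(codonFreq(back), codonFreq(tab))
  expect_equal(codonWeights(back), codonWeights(tab))
})

test_that("gap filtering drops rows at the 60-gap threshold and not below", {
  mk <- function(gapLen, total = 150L) {
    paste0(strrep("A", 10L), strrep("-", gapLen),
           strrep("K", total - 10L - gapLen))
  }
  aln <- c(sp_at = mk(60L), sp_below = mk(59L),
           sp_split = paste0(strrep("A", 30L), strrep("-", 30L),
                             strrep("K", 30L), strrep("-", 30L),
                             strrep("A", 30L)))
  expect_message(kept <- filterByGap(aln, maxGapRun = 60L), "sp_at")
  expect_named(kept, c("sp_below", "sp_split"))
  # rows with two separate sub-threshold runs agree with the scan oracle
  expect_lt(oracleMaxGapRun(aln[["sp_split"]]), 60L)
  # idempotence
  expect_silent(kept2 <- filterByGap(kept, maxGapRun = 60L))
  expect_identical(kept2, kept)
  expect_error(filterByGap(character(0)), "empty")
})

test_that("region extraction uses 0-based half-open codon coordinates", {
  cods <- c("ATG", rep(c("GAA", "TTT"), 50))  # 101 codons, no stop
  cds <- cdsFromCodons(cods)
  sub <- extractRegion(cds, c(0, 10))
  expect_equal(nchar(cdsSeq(sub)), 30L)
  expect_equal(codons(sub), cods[1:10])
  expect_error(extractRegion(cds, c(95, 102)), "out of bounds")
})

test_that("the terminal stop codon is excluded from every region including whole", {
  cds <- CodingSequence("ATGGAATTTTAA")
  whole <- extractRegion(cds, "whole")
  expect_equal(codons(whole), c("ATG", "GAA", "TTT"))
  expect_equal(codons(extractRegion(cds, c(0, 3))), c("ATG", "GAA", "TTT"))
})

test_that("a partition's regions plus uncovered codons reassemble the whole", {
  cds <- maxBiasCDS(3L)
  part <- DomainPartition(a = c(0, 10), b = c(25, 40))
  n <- length(senseCodons(cds))
  covered <- c(0:9, 25:39)
  uncovered <- setdiff(0:(n - 1), covered)
  pieces <- c(codons(extractRegion(cds, "a", part)),
              codons(extractRegion(cds, "b", part)),
              senseCodons(cds)[uncovered + 1])
  expect_equal(sort(pieces), sort(senseCodons(cds)))
})

test_that("domain partitions reject overlaps, bad bounds and duplicate names", {
  expect_error(DomainPartition(a = c(0, 10), b = c(5, 20)), "overlap")
  expect_error(DomainPartition(a = c(10, 10)), "start < end")
  expect_error(DomainPartition(a = c(0, 10), a = c(10, 20)), "unique")
  p <- tempfile(fileext = ".yaml")
  part <- DomainPartition(nterm = c(0, 50), core = c(50, 450))
  writeDomainPartition(part, p)
  expect_equal(regions(readDomainPartition(p)), regions(part))
})

test_that("variant tables validate the reference allele against the CDS", {
  cds <- CodingSequence("ATGGAATAA")
  p <- tempfile(fileext = ".tsv")
  writeVariantTable(data.frame(cds_position = c(3L, 5L), ref = c("G", "A"),
                               alt = c("A", "G")), p)
  v <- readVariantTable(p, cds = cds)
  expect_equal(nrow(v), 2L)
  writeVariantTable(data.frame(cds_position = 3L, ref = "C", alt = "A"), p)
  expect_error(readVariantTable(p, cds = cds), "mismatch")
})
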