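## Synthetic multi-species homolog sets with region-wise codon-bias
## contrasts (rare-codon ramps, GC3-elevated domains, designed 5'
## hairpins), species codon usage tables, and variant lists — so every
## pipeline stage is testable without any download.

.SENSE_AA <- setdiff(names(.AA_FAMILIES), "*")

#' Generate a random species codon usage table
#'
#' Frequencies within each synonymous family are Dirichlet-style draws
#' with concentration `1/(1 + skew)`: larger `skew` concentrates usage on
#' one dominant codon per family; `skew = 0` returns the exactly uniform
#' table (the infinite-concentration limit). Family totals are
#' proportional to family size and scaled to per-thousand.
#'
#' @param species species label
#' @param skew non-negative bias strength (0 = uniform usage)
#' @param seed integer seed; same seed, same table
#' @return a [CodonUsageTable-class]
#' @export
makeCodonTable <- function(species, skew = 2, seed = 1L) {
  stopifnot(skew >= 0)
  freq <- setNames(numeric(64L), .ALL_CODONS)
  .withSeed(seed, {
    for (fam in .AA_FAMILIES) {
      k <- length(fam)
      p <- if (skew == 0) rep(1 / k, k) else {
        g <- rgamma(k, shape = 1 / (1 + skew))
        while (sum(g) == 0) g <- rgamma(k, shape = 1 / (1 + skew))
        g / sum(g)
      }
      freq[fam] <- p * 1000 * k / 64
    }
  })
  CodonUsageTable(species, freq)
}

## per-residue sampling distribution over a synonymous family under a
## region bias profile
.profileProb <- function(fam, table, sampling, theta = 1) {
  k <- length(fam)
  w <- codonWeights(table)[fam]
  switch(sampling,
    frequent = {
      p <- rep(0.1 / max(1L, k - 1L), k)
      p[which.max(w)] <- if (k == 1L) 1 else 0.9
      p / sum(p)
    },
    rare = { p <- 1 / w; p / sum(p) },
    uniform = rep(1 / k, k),
    gc3_tilted = {
      gc3 <- substring(fam, 3L, 3L) %in% c("G", "C")
      p <- theta^gc3
      p / sum(p)
    },
    stop("unknown sampling profile: ", sampling))
}

## calibrate the gc3 tilt theta so the expected GC3 over `aa` hits target
.calibrateGC3Theta <- function(aa, targetGC3) {
  expGC3 <- function(theta) {
    mean(vapply(aa, function(a) {
      fam <- .AA_FAMILIES[[a]]
      gc3 <- substring(fam, 3L, 3L) %in% c("G", "C")
      q <- theta^gc3
      sum(q[gc3]) / sum(q)
    }, numeric(1)))
  }
  lo <- -25; hi <- 25
  if (targetGC3 <= expGC3(exp(lo))) return(exp(lo))
  if (targetGC3 >= expGC3(exp(hi))) return(exp(hi))
  for (it in 1:100) {
    mid <- (lo + hi) / 2
    if (expGC3(exp(mid)) < targetGC3) lo <- mid else hi <- mid
    if (hi - lo < 1e-9) break
  }
  exp((lo + hi) / 2)
}

## designed codon-aligned stem-loop: (GGC)^k (AAA)^m (GCC)^k.
## The GGC arm reverse-complements the GCC arm, giving stemLen GC pairs;
## synonymous permutation mixes these Gly/Ala codons with differently
## coded Gly/Ala elsewhere in the gene, breaking stem pairs.
.hairpinCodons <- function(stemLen, loopLen) {
  if (stemLen %% 3L != 0L || loopLen %% 3L != 0L || stemLen < 3L ||
      loopLen < 3L)
    stop("hairpin stem_len and loop_len must be multiples of 3 and >= 3")
  c(rep("GGC", stemLen %/% 3L), rep("AAA", loopLen %/% 3L),
    rep("GCC", stemLen %/% 3L))
}

#' Generate a synthetic multi-species homolog set
#'
#' One protein sequence is drawn; each species' CDS encodes exactly that
#' protein, with every residue's codon sampled according to the bias
#' profile of the region containing it, against that species' own codon
#' usage table. An optional hairpin specification fixes a designed
#' stem-loop (shared across species) whose synonymous alternatives break
#' stem pairs, emulating stronger-than-predicted native 5' structure.
#' Every CDS starts with ATG and ends with a TAA terminal stop.
#'
#' @param proteinLen protein length in codons (ATG and the designed
#'   hairpin, if any, are part of this length)
#' @param nSpecies number of species
#' @param partition a [DomainPartition-class] whose regions tile
#'   `[0, proteinLen)`
#' @param profiles named list, one entry per partition region:
#'   `list(sampling = "frequent" | "rare" | "uniform" | "gc3_tilted",
#'   target_gc3 = <fraction>, theta = <tilt>)`; for `gc3_tilted` either
#'   `theta` or `target_gc3` (calibrated by bisection) must be given
#' @param tables optional named list of [CodonUsageTable-class], one per
#'   species; generated with [makeCodonTable()] when omitted
#' @param hairpin optional `c(start_nt, stem_len, loop_len)` in nt, all
#'   multiples of 3, with `start_nt >= 3` (the initiator ATG is kept)
#' @param gene gene label stamped on every CDS
#' @param seed integer seed; the whole set is deterministic given the seed
#' @return list with elements `cds` (named list of
#'   [CodingSequence-class] per species), `tables` (named list of
#'   [CodonUsageTable-class]), `protein` (the shared amino-acid string)
#' @export
generateHomologSet <- function(proteinLen = 500L, nSpecies = 28L,
                               partition = DomainPartition(
                                 nterm = c(0, 50),
                                 core = c(50, proteinLen - 50),
                                 cterm = c(proteinLen - 50, proteinLen)),
                               profiles = NULL, tables = NULL,
                               hairpin = NULL, gene = "geneA", seed = 1L) {
  r <- regions(partition)
  o <- order(r$start)
  if (r$start[o][1L] != 0L || r$end[o][nrow(r)] != proteinLen ||
      (nrow(r) > 1L && any(r$start[o][-1L] != r$end[o][-nrow(r)])))
    stop("partition regions must tile [0, proteinLen)")
  if (is.null(profiles))
    profiles <- setNames(rep(list(list(sampling = "uniform")), nrow(r)),
                         r$name)
  if (!all(r$name %in% names(profiles)))
    stop("profiles must cover every partition region")

  hairpinCods <- NULL; hairpinAt <- integer(0L)
  if (!is.null(hairpin)) {
    startNt <- as.integer(hairpin[1L])
    if (startNt %% 3L != 0L || startNt < 3L)
      stop("hairpin start_nt must be a positive multiple of 3 ",
           "(the initiator ATG is kept)")
    hairpinCods <- .hairpinCodons(as.integer(hairpin[2L]),
                                  as.integer(hairpin[3L]))
    hairpinAt <- startNt %/% 3L + seq_along(hairpinCods)  # 1-based codons
    if (max(hairpinAt) > proteinLen)
      stop("hairpin extends beyond the protein")
  }

  .withSeed(seed, {
    ## shared protein: ATG start; no stops (sense families only)
    aa <- c("M", sample(.SENSE_AA, proteinLen - 1L, replace = TRUE))
    if (!is.null(hairpinCods)) aa[hairpinAt] <- .GC_TABLE[hairpinCods]

    if (is.null(tables)) {
      tables <- lapply(seq_len(nSpecies), function(i)
        makeCodonTable(sprintf("species%02d", i), skew = 2,
                       seed = .deriveSeed(seed, i)))
      names(tables) <- vapply(tables, tableSpecies, "")
    }

    regionOf <- integer(proteinLen)  # region row index per 1-based codon
    for (i in seq_len(nrow(r)))
      regionOf[(r$start[i] + 1L):r$end[i]] <- i

    cdsList <- lapply(names(tables), function(sp) {
      tab <- tables[[sp]]
      cods <- character(proteinLen)
      for (i in seq_len(nrow(r))) {
        prof <- profiles[[r$name[i]]]
        theta <- 1
        if (identical(prof$sampling, "gc3_tilted")) {
          theta <- if (!is.null(prof$theta)) prof$theta else
            .calibrateGC3Theta(aa[regionOf == i & seq_len(proteinLen) > 1L],
                               prof$target_gc3)
        }
        for (pos in which(regionOf == i)) {
          fam <- .AA_FAMILIES[[aa[pos]]]
          if (length(fam) == 1L) { cods[pos] <- fam; next }
          p <- .profileProb(fam, tab, prof$sampling, theta)
          cods[pos] <- fam[sample.int(length(fam), 1L, prob = p)]
        }
      }
      cods[1L] <- "ATG"
      if (!is.null(hairpinCods)) cods[hairpinAt] <- hairpinCods
      CodingSequence(paste(c(cods, "TAA"), collapse = ""),
                     id = paste0(gene, "_", sp), species = sp, gene = gene)
    })
    names(cdsList) <- names(tables)
    list(cds = cdsList, tables = tables, protein = paste(aa, collapse = ""))
  })
}

#' Generate a variant list with prescribed class quotas
#'
#' Rejection-samples single-nucleotide substitutions on the CDS until the
#' requested numbers of synonymous, missense and nonsense variants are
#' reached.
#'
#' @param cds a [CodingSequence-class]
#' @param nSyn,nMis,nNon requested counts per class
#' @param seed integer seed
#' @param maxTries sampling attempts before giving up
#' @return data.frame with columns cds_position, ref, alt, class
#' @export
generateVariants <- function(cds, nSyn, nMis, nNon, seed = 1L,
                             maxTries = 100000L) {
  seq <- cdsSeq(cds)
  n <- nchar(seq)
  want <- c(synonymous = nSyn, missense = nMis, nonsense = nNon)
  .withSeed(seed, {
    got <- list()
    counts <- c(synonymous = 0L, missense = 0L, nonsense = 0L)
    seen <- character(0L)
    for (tries in seq_len(maxTries)) {
      if (all(counts >= want)) break
      pos <- sample.int(n, 1L) - 1L
      ref <- substring(seq, pos + 1L, pos + 1L)
      if (ref == "N") next
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      key <- paste(pos, alt)
      if (key %in% seen) next
      cls <- classifySubstitution(cds, pos, ref, alt)
      if (!cls %in% names(want) || counts[cls] >= want[cls]) next
      seen <- c(seen, key)
      counts[cls] <- counts[cls] + 1L
      got[[length(got) + 1L]] <- data.frame(cds_position = pos, ref = ref,
                                            alt = alt, class = cls)
    }
    if (!all(counts >= want))
      stop("variant quota unachievable on this CDS (got ",
           paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
           ")")
    out <- do.call(rbind, got)
    out[order(out$cds_position, out$alt), ]
  })
}

#' Write a five-gene, multi-species synthetic study set to disk
#'
#' Emulates a B56-like gene-family analysis: five genes sharing a species
#' cohort, with per-gene contrasts — `alphaLike` carries a designed 5'
#' hairpin (codons 1-10) and a GC3-elevated N-terminal domain;
#' `rampLike` has rare codons in its first ten codons and frequent codons
#' elsewhere; `frequentLike` uses frequent codons throughout; `plainLike`
#' samples uniformly; `lowGC3Like` has a GC3-depleted N-terminal domain.
#' Writes per-gene FASTA, per-species Kazusa-format codon tables, the
#' domain-partition YAML, a variant TSV for one gene, and a ready-to-run
#' pipeline config YAML.
#'
#' @param outDir output directory (created if needed)
#' @param nSpecies cohort size (default 28, the study-cohort size)
#' @param proteinLen protein length in codons (default 500)
#' @param seed integer seed
#' @return the path of the written run config, invisibly
#' @export
writeB56LikePreset <- function(outDir, nSpecies = 28L, proteinLen = 500L,
                               seed = 20231227L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  nt <- min(50L, proteinLen %/% 4L)
  partition <- DomainPartition(nterm = c(0, nt),
                               core = c(nt, proteinLen - nt),
                               cterm = c(proteinLen - nt, proteinLen))
  ## finer generator partitions realise the contrasts; the analysis
  ## partition above is what the pipeline consumes
  genParts <- list(
    alphaLike = list(
      partition = DomainPartition(hairpin = c(0, 11), nterm = c(11, nt),
                                  rest = c(nt, proteinLen)),
      profiles = list(hairpin = list(sampling = "uniform"),
                      nterm = list(sampling = "gc3_tilted", target_gc3 = 0.8),
                      rest = list(sampling = "uniform")),
      hairpin = c(3, 12, 6)),
    rampLike = list(
      partition = DomainPartition(ramp = c(0, 10),
                                  rest = c(10, proteinLen)),
      profiles = list(ramp = list(sampling = "rare"),
                      rest = list(sampling = "frequent")),
      hairpin = NULL),
    frequentLike = list(
      partition = DomainPartition(all = c(0, proteinLen)),
      profiles = list(all = list(sampling = "frequent")),
      hairpin = NULL),
    plainLike = list(
      partition = DomainPartition(all = c(0, proteinLen)),
      profiles = list(all = list(sampling = "uniform")),
      hairpin = NULL),
    lowGC3Like = list(
      partition = DomainPartition(nterm = c(0, nt),
                                  rest = c(nt, proteinLen)),
      profiles = list(nterm = list(sampling = "gc3_tilted", target_gc3 = 0.3),
                      rest = list(sampling = "uniform")),
      hairpin = NULL))

  tables <- lapply(seq_len(nSpecies), function(i)
    makeCodonTable(sprintf("species%02d", i), skew = 2,
                   seed = .deriveSeed(seed, i)))
  names(tables) <- vapply(tables, tableSpecies, "")
  tabDir <- file.path(outDir, "codon_tables")
  dir.create(tabDir, showWarnings = FALSE)
  for (sp in names(tables))
    writeCodonTable(tables[[sp]], file.path(tabDir, paste0(sp, ".txt")))

  fastaPaths <- list()
  firstSet <- NULL
  for (g in names(genParts)) {
    gp <- genParts[[g]]
    set <- generateHomologSet(proteinLen = proteinLen, nSpecies = nSpecies,
                              partition = gp$partition,
                              profiles = gp$profiles, tables = tables,
                              hairpin = gp$hairpin, gene = g,
                              seed = .deriveSeed(seed, match(g, names(genParts)) * 101L))
    if (is.null(firstSet)) firstSet <- set
    p <- file.path(outDir, paste0(g, ".fasta"))
    writeCodingFasta(set$cds, p)
    fastaPaths[[g]] <- p
  }

  partPath <- file.path(outDir, "partition.yaml")
  writeDomainPartition(partition, partPath)

  vcds <- firstSet$cds[[1L]]
  v <- generateVariants(vcds, nSyn = 6L, nMis = 12L, nNon = 2L,
                        seed = .deriveSeed(seed, 7L))
  varPath <- file.path(outDir, "variants.tsv")
  writeVariantTable(v[, c("cds_position", "ref", "alt")], varPath)

  cfg <- list(
    genes = lapply(names(fastaPaths), function(g)
      list(name = g, fasta = basename(fastaPaths[[g]]))),
    codon_table_dir = "codon_tables",
    partition = basename(partPath),
    variants = list(gene = names(genParts)[1L],
                    cds = cdsID(vcds), file = basename(varPath)),
    params = list(nc_variant = "wright", ecai_replicates = 500L,
                  ecai_population = 0.9, ecai_confidence = 0.9,
                  window = 40L, step = 10L, n_permutations = 20L,
                  first_n = 10L, cub_cutoff = 35, gap_cutoff = 60L,
                  seed = as.integer(seed)),
    output_dir = "results")
  cfgPath <- file.path(outDir, "run.yaml")
  yaml::write_yaml(cfg, cfgPath)
  invisible(cfgPath)
}
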