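#' Read coding sequences from a FASTA file
#'
#' Headers of the form `gene|species|id` are parsed into the corresponding
#' [CodingSequence-class] fields; any other header is kept whole as the id.
#' Sequences are uppercased and RNA `U` is converted to DNA `T`. Records
#' whose length is not a multiple of 3, that contain characters outside
#' \{A,C,G,T,N\}, or that contain an internal stop codon are rejected with
#' a warning naming the offending ids; valid records are returned.
#'
#' @param path path to a FASTA file
#' @return named list of [CodingSequence-class] objects (named by id)
#' @export
readCodingFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  headers <- names(set)
  seqs <- .normalizeSeq(as.character(set))
  out <- list()
  rejected <- character(0L)
  for (i in seq_along(seqs)) {
    parts <- strsplit(headers[i], "|", fixed = TRUE)[[1L]]
    if (length(parts) == 3L) {
      gene <- parts[1L]; species <- parts[2L]; id <- parts[3L]
    } else {
      gene <- ""; species <- ""; id <- headers[i]
    }
    cds <- tryCatch(CodingSequence(seqs[i], id = id, species = species,
                                   gene = gene),
                    error = function(e) e)
    if (is(cds, "error")) {
      rejected <- c(rejected, sprintf("%s (%s)", id, conditionMessage(cds)))
    } else {
      out <- c(out, stats::setNames(list(cds), id))
    }
  }
  if (length(rejected))
    warning("rejected ", length(rejected), " record(s): ",
            paste(rejected, collapse = "; "))
  out
}

#' Write coding sequences to FASTA
#'
#' Headers are written as `gene|species|id` so that
#' [readCodingFasta()] round-trips all fields.
#'
#' @param cdsList list of [CodingSequence-class] objects
#' @param path output path
#' @return `path`, invisibly
#' @export
writeCodingFasta <- function(cdsList, path) {
  if (is(cdsList, "CodingSequence")) cdsList <- list(cdsList)
  seqs <- Biostrings::DNAStringSet(vapply(cdsList, cdsSeq, ""))
  names(seqs) <- vapply(cdsList, function(x)
    paste(cdsGene(x), cdsSpecies(x), cdsID(x), sep = "|"), "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a codon usage table in Codon Usage Database (Kazusa) text format
#'
#' Parses fields of the form `CODON  freq  ( count )` with the codon in the
#' RNA alphabet, e.g. `UUU 17.6 (714298)`. The per-thousand frequency field
#' is retained; relative adaptiveness weights are derived on construction.
#'
#' @param path path to the table file
#' @param species species label; defaults to the file name without extension
#' @return a [CodonUsageTable-class]
#' @export
readCodonTable <- function(path, species = NULL) {
  if (!file.exists(path)) stop("codon table file not found: ", path)
  if (is.null(species))
    species <- sub("\\.[^.]*$", "", basename(path))
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  num <- "-?[0-9.]+(?:[eE][+-]?[0-9]+)?"
  pat <- sprintf("([ACGU]{3})\\s+(%s)\\s*\\(\\s*-?[0-9]+\\s*\\)", num)
  fields <- regmatches(txt, gregexpr(pat, txt))[[1L]]
  if (length(fields) == 0L)
    stop("no Kazusa-format codon entries found in ", path)
  codon <- sub("^([ACGU]{3}).*", "\\1", fields)
  freq <- as.numeric(sub(sprintf("^[ACGU]{3}\\s+(%s).*", num), "\\1", fields))
  if (anyDuplicated(codon)) stop("duplicated codon entries in ", path)
  names(freq) <- codon
  if (any(freq < 0)) stop("negative frequency in ", path)
  CodonUsageTable(species, freq)  # errors if any of the 64 codons is missing
}

#' Write a codon usage table in Kazusa text format
#'
#' @param table a [CodonUsageTable-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeCodonTable <- function(table, path) {
  f <- codonFreq(table)
  rna <- chartr("T", "U", names(f))
  ## 4 fields per line, as distributed by the Codon Usage Database
  entries <- sprintf("%s %s (%d)", rna, formatC(f, format = "g", digits = 17),
                     as.integer(round(f * 10)))
  lines <- vapply(split(entries, (seq_along(entries) - 1L) %/% 4L),
                  paste, "", collapse = "  ")
  writeLines(lines, path)
  invisible(path)
}

#' Remove alignment rows with long gap runs
#'
#' Rows (species) whose gapped amino-acid string contains a contiguous run
#' of `maxGapRun` or more gap characters are excluded; removals are
#' reported via `message()`.
#'
#' @param aligned named character vector or `Biostrings::AAStringSet` of
#'   equal-length gapped amino-acid strings (gap character `-`)
#' @param maxGapRun minimum gap-run length triggering exclusion (default 60)
#' @return the alignment with offending rows removed, same type as input
#' @export
filterByGap <- function(aligned, maxGapRun = 60L) {
  isSet <- is(aligned, "AAStringSet")
  rows <- if (isSet) as.character(aligned) else aligned
  if (length(rows) == 0L) stop("empty alignment")
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows must have equal length")
  maxRun <- vapply(strsplit(rows, ""), function(ch) {
    r <- rle(ch == "-")
    if (any(r$values)) max(r$lengths[r$values]) else 0L
  }, integer(1L))
  drop <- maxRun >= maxGapRun
  if (any(drop))
    message("excluded ", sum(drop), " row(s) with a gap run >= ", maxGapRun,
            ": ", paste(names(rows)[drop], collapse = ", "))
  aligned[!drop]
}

#' Extract a codon region from a coding sequence
#'
#' Coordinates are 0-based, half-open, in codon units, and index the sense
#' codons of the CDS: the terminal stop codon (if present) is stripped
#' before extraction, so it is excluded from every region including the
#' whole-gene region.
#'
#' @param cds a [CodingSequence-class]
#' @param region length-2 integer vector `c(start, end)`, or a region name
#'   together with `partition`
#' @param partition optional [DomainPartition-class] used when `region` is
#'   a name; the name `"whole"` selects all sense codons
#' @return a [CodingSequence-class] covering the requested codons
#' @export
extractRegion <- function(cds, region, partition = NULL) {
  cods <- senseCodons(cds)
  if (is.character(region)) {
    if (identical(region, "whole")) {
      region <- c(0L, length(cods))
    } else {
      if (is.null(partition)) stop("named region requires a partition")
      r <- regions(partition)
      i <- match(region, r$name)
      if (is.na(i)) stop("no region named '", region, "' in partition")
      region <- c(r$start[i], r$end[i])
    }
  }
  start <- as.integer(region[1L]); end <- as.integer(region[2L])
  if (start < 0L || end > length(cods) || start >= end)
    stop(sprintf("region [%d,%d) out of bounds for %d sense codons",
                 start, end, length(cods)))
  CodingSequence(paste(cods[(start + 1L):end], collapse = ""),
                 id = cdsID(cds), species = cdsSpecies(cds),
                 gene = cdsGene(cds))
}

#' Read a domain partition from a YAML config
#'
#' Expected layout:
#' ```yaml
#' regions:
#'   - {name: nterm, start: 0, end: 50}
#'   - {name: core,  start: 50, end: 450}
#' ```
#' Coordinates are 0-based half-open codon units.
#'
#' @param path YAML file path
#' @return a [DomainPartition-class]
#' @export
readDomainPartition <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$regions)) stop("partition file has no 'regions' key: ", path)
  r <- do.call(rbind, lapply(cfg$regions, function(x)
    data.frame(name = x$name, start = as.integer(x$start),
               end = as.integer(x$end))))
  DomainPartition(r)
}

#' Write a domain partition to YAML
#' @param partition a [DomainPartition-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeDomainPartition <- function(partition, path) {
  r <- regions(partition)
  yaml::write_yaml(list(regions = lapply(seq_len(nrow(r)), function(i)
    list(name = r$name[i], start = r$start[i], end = r$end[i]))), path)
  invisible(path)
}

#' Read a variant list (TSV with header: cds_position, ref, alt)
#'
#' Positions are 0-based nucleotide offsets into the CDS. When `cds` is
#' supplied each record's `ref` is checked against the sequence.
#'
#' @param path TSV path
#' @param cds optional [CodingSequence-class] for reference validation
#' @return data.frame with columns cds_position, ref, alt
#' @export
readVariantTable <- function(path, cds = NULL) {
  v <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cds_position", "ref", "alt")
  if (!all(need %in% names(v)))
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  v$ref <- .normalizeSeq(v$ref); v$alt <- .normalizeSeq(v$alt)
  if (any(v$ref == v$alt)) stop("variant with ref == alt")
  if (!is.null(cds)) {
    have <- substring(cdsSeq(cds), v$cds_position + 1L, v$cds_position + 1L)
    bad <- which(have != v$ref)
    if (length(bad))
      stop("ref allele mismatch at cds_position ",
           paste(v$cds_position[bad], collapse = ", "))
  }
  v[, need]
}

#' Write a variant list as TSV
#' @param variants data.frame with columns cds_position, ref, alt
#' @param path output path
#' @return `path`, invisibly
#' @export
writeVariantTable <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
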