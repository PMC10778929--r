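## Orchestration: run the codon-usage-bias metrics and the deltaLFE
## profiling over a multi-gene, multi-species study set described by a
## YAML config, writing tidy TSV tables and a JSON run manifest.

.defaultParams <- function() {
  list(nc_variant = "wright", ecai_replicates = 500L,
       ecai_population = 0.9, ecai_confidence = 0.9, window = 40L,
       step = 10L, n_permutations = 20L, first_n = 10L, cub_cutoff = 35,
       gap_cutoff = 60L, seed = 20231227L)
}

#' Read and validate a pipeline run config
#'
#' The YAML config lists per-gene FASTA paths, a directory of per-species
#' Kazusa codon tables (file name = species label), the domain-partition
#' YAML, optional variants, analysis parameters, and an output directory.
#' Relative paths are resolved against the config file's directory.
#' Missing parameters are filled with the packaged defaults.
#'
#' @param path path to the YAML config
#' @return validated config list with resolved paths and parameters
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base, p)
  if (is.null(cfg$genes) || length(cfg$genes) == 0L)
    stop("config lists no genes")
  for (i in seq_along(cfg$genes)) {
    cfg$genes[[i]]$fasta <- resolve(cfg$genes[[i]]$fasta)
    if (!file.exists(cfg$genes[[i]]$fasta))
      stop("FASTA not found: ", cfg$genes[[i]]$fasta)
  }
  cfg$codon_table_dir <- resolve(cfg$codon_table_dir)
  if (!dir.exists(cfg$codon_table_dir))
    stop("codon table directory not found: ", cfg$codon_table_dir)
  cfg$partition <- resolve(cfg$partition)
  if (!file.exists(cfg$partition))
    stop("partition file not found: ", cfg$partition)
  if (!is.null(cfg$variants) && !is.null(cfg$variants$file))
    cfg$variants$file <- resolve(cfg$variants$file)
  defaults <- .defaultParams()
  for (nm in names(defaults))
    if (is.null(cfg$params[[nm]])) cfg$params[[nm]] <- defaults[[nm]]
  stopifnot(cfg$params$window > 0L, cfg$params$step > 0L,
            cfg$params$n_permutations >= 1L,
            cfg$params$ecai_population > 0, cfg$params$ecai_population < 1,
            cfg$params$ecai_confidence > 0, cfg$params$ecai_confidence < 1)
  if (is.null(cfg$output_dir)) cfg$output_dir <- "results"
  cfg$output_dir <- resolve(cfg$output_dir)
  cfg
}

.loadStudySet <- function(cfg) {
  tabFiles <- list.files(cfg$codon_table_dir, full.names = TRUE)
  tables <- lapply(tabFiles, readCodonTable)
  names(tables) <- vapply(tables, tableSpecies, "")
  genes <- list()
  for (g in cfg$genes) {
    recs <- readCodingFasta(g$fasta)
    bySpecies <- list()
    for (cds in recs) {
      sp <- cdsSpecies(cds)
      if (!sp %in% names(tables)) {
        message("skipping ", cdsID(cds), ": no codon table for species ", sp)
        next
      }
      bySpecies[[sp]] <- cds
    }
    if (length(bySpecies) == 0L)
      stop("gene ", g$name, " has zero usable species")
    genes[[g$name]] <- bySpecies
  }
  list(genes = genes, tables = tables,
       partition = readDomainPartition(cfg$partition))
}

.writeManifest <- function(cfg, outDir, stage) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(stage = stage, params = cfg$params,
                   genes = vapply(cfg$genes, function(g) g$name, ""),
                   package_version = as.character(utils::packageVersion("cubscape")))
  jsonlite::write_json(manifest,
                       file.path(outDir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the codon-usage-bias metrics pipeline
#'
#' For every gene and species, computes the per-region CUB report
#' ([regionReport()]: Nc, CAI, eCAI, GC3%, GC%, whole-gene-normalized
#' percent differences, CUB flag, first-N-codon analysis) and writes
#' `metrics.tsv` plus the cross-species per-gene/region summary
#' `metrics_means.tsv` (unweighted mean, and median alongside).
#' Per-record failures are logged and skipped; the run fails only if a
#' gene has no usable species.
#'
#' @param config path to a run config YAML, or a list as returned by
#'   [readRunConfig()]
#' @param ecai compute the eCAI null (default TRUE; dominant cost)
#' @return invisibly, a list with the per-species `metrics` and
#'   cross-species `means` data.frames
#' @export
runCub <- function(config, ecai = TRUE) {
  cfg <- if (is.character(config)) readRunConfig(config) else config
  set <- .loadStudySet(cfg)
  p <- cfg$params
  rows <- list()
  k <- 0L
  for (g in names(set$genes)) {
    message("CUB metrics for ", g, ": ", length(set$genes[[g]]), " species")
    for (sp in sort(names(set$genes[[g]]))) {
      k <- k + 1L
      rep_ <- tryCatch(
        regionReport(set$genes[[g]][[sp]], set$partition,
                     set$tables[[sp]], ncVariant = p$nc_variant,
                     ecai = ecai, ecaiReplicates = p$ecai_replicates,
                     population = p$ecai_population,
                     confidence = p$ecai_confidence, firstN = p$first_n,
                     cubCutoff = p$cub_cutoff,
                     seed = .deriveSeed(p$seed, k)),
        error = function(e) {
          message("skipping ", g, "/", sp, ": ", conditionMessage(e)); NULL })
      if (!is.null(rep_)) rows[[length(rows) + 1L]] <- rep_
    }
  }
  metrics <- do.call(rbind, rows)
  num <- c("nc", "cai", "ecai", "cai_vs_ecai_pct", "gc3_pct", "gc_pct",
           "nc_norm_pct", "gc3_norm_pct", "gc_norm_pct")
  means <- do.call(rbind, lapply(
    split(metrics, list(metrics$gene, metrics$region), drop = TRUE),
    function(d) {
      cbind(data.frame(gene = d$gene[1L], region = d$region[1L],
                       n_species = nrow(d)),
            as.data.frame(lapply(d[num], mean, na.rm = TRUE)),
            setNames(as.data.frame(lapply(d[num], median, na.rm = TRUE)),
                     paste0(num, "_median")))
    }))
  means <- means[order(means$gene, means$region), ]
  rownames(means) <- NULL
  outDir <- cfg$output_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  write.table(metrics, file.path(outDir, "metrics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(means, file.path(outDir, "metrics_means.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  .writeManifest(cfg, outDir, "cub")
  invisible(list(metrics = metrics, means = means))
}

#' Run the deltaLFE profiling pipeline
#'
#' Computes a per-species [deltaLFEProfile()] for every gene, writes the
#' window-level `lfe_profiles.tsv`, the per-sequence
#' `lfe_intercepts.tsv` (x-intercepts and ramp lengths), and the
#' cross-species `lfe_aggregate.tsv`. Deterministic under the config
#' seed.
#'
#' @inheritParams runCub
#' @param backend folding backend (see [builtinFoldBackend()])
#' @return invisibly, a list with `profiles` (nested list by gene then
#'   species) and `aggregates` (list of [AggregateProfile-class])
#' @export
runLfe <- function(config, backend = builtinFoldBackend()) {
  cfg <- if (is.character(config)) readRunConfig(config) else config
  set <- .loadStudySet(cfg)
  p <- cfg$params
  profRows <- list(); intRows <- list(); aggRows <- list()
  profiles <- list(); aggregates <- list()
  k <- 0L
  for (g in names(set$genes)) {
    message("deltaLFE profiles for ", g, ": ", length(set$genes[[g]]),
            " species")
    profiles[[g]] <- list()
    for (sp in sort(names(set$genes[[g]]))) {
      k <- k + 1L
      prof <- tryCatch(
        deltaLFEProfile(set$genes[[g]][[sp]],
                        nPermutations = p$n_permutations,
                        window = p$window, step = p$step,
                        backend = backend, seed = .deriveSeed(p$seed, k)),
        error = function(e) {
          message("skipping ", g, "/", sp, ": ", conditionMessage(e)); NULL })
      if (is.null(prof)) next
      profiles[[g]][[sp]] <- prof
      profRows[[length(profRows) + 1L]] <- as.data.frame(prof)
      intRows[[length(intRows) + 1L]] <- data.frame(
        gene = g, species = sp, ramp_codons = rampCodons(prof),
        x_intercepts_nt = paste(round(xIntercepts(prof), 4),
                                collapse = ","))
    }
    if (length(profiles[[g]]) == 0L)
      stop("gene ", g, " has zero usable species")
    agg <- aggregateProfiles(profiles[[g]])
    aggregates[[g]] <- agg
    aggRows[[length(aggRows) + 1L]] <- as.data.frame(agg)
  }
  outDir <- cfg$output_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  write.table(do.call(rbind, profRows),
              file.path(outDir, "lfe_profiles.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(do.call(rbind, intRows),
              file.path(outDir, "lfe_intercepts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(do.call(rbind, aggRows),
              file.path(outDir, "lfe_aggregate.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  .writeManifest(cfg, outDir, "lfe")
  invisible(list(profiles = profiles, aggregates = aggregates))
}

#' Run the variant-abundance summary
#'
#' Classifies the variant list of the config (or explicit arguments)
#' against its CDS and writes `mutation_summary.tsv`.
#'
#' @inheritParams runCub
#' @return invisibly, the one-row summary data.frame
#' @export
runVariants <- function(config) {
  cfg <- if (is.character(config)) readRunConfig(config) else config
  if (is.null(cfg$variants)) stop("config has no variants entry")
  set <- .loadStudySet(cfg)
  g <- cfg$variants$gene
  recs <- set$genes[[g]]
  cds <- NULL
  for (x in recs) if (cdsID(x) == cfg$variants$cds) cds <- x
  if (is.null(cds)) stop("variants CDS '", cfg$variants$cds,
                         "' not found in gene ", g)
  v <- readVariantTable(cfg$variants$file, cds = cds)
  s <- summarizeMutations(cds, v)
  outDir <- cfg$output_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  write.table(cbind(data.frame(gene = g, cds = cdsID(cds)), s),
              file.path(outDir, "mutation_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(s)
}
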