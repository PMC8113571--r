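## End-to-end orchestration: mine -> design -> filter -> genotype ->
## screen -> stats, with a stage-by-stage filter ledger and artifact
## export. The stage order follows the discovery cascade: primer
## designability first, then the A/T-only motif filter, then the
## proximity filter; the survivors are genotyped and screened.

#' Pipeline configuration
#'
#' Bundles every stage's configuration plus the seed. Unknown keys are
#' rejected.
#'
#' @param mining A [mining_config()].
#' @param primers A [primer_constraints()].
#' @param stutter A [stutter_model()].
#' @param filters A [call_filters()].
#' @param min_nonref_accessions Polymorphism screen threshold.
#' @param anchor_bp Anchor window width for the genotyper.
#' @param seed Integer seed.
#' @param ... Unknown keys (rejected).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mining = mining_config(),
                            primers = primer_constraints(),
                            stutter = stutter_model(),
                            filters = call_filters(),
                            min_nonref_accessions = 2L,
                            anchor_bp = 10L, seed = 1L, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown pipeline config keys: ",
         paste(names(extra), collapse = ", "))
  }
  stopifnot(inherits(mining, "mining_config"),
            inherits(primers, "primer_constraints"),
            inherits(stutter, "stutter_model"),
            inherits(filters, "call_filters"))
  structure(list(mining = mining, primers = primers, stutter = stutter,
                 filters = filters,
                 min_nonref_accessions = as.integer(min_nonref_accessions),
                 anchor_bp = as.integer(anchor_bp), seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(config, f)
  unname(tools::md5sum(f))
}

provenance_line <- function(config) {
  sprintf("# ssrscape %s config=%s",
          as.character(utils::packageVersion("ssrscape")),
          config_hash(config))
}

#' Run the full SSR discovery pipeline
#'
#' Mines SSR loci from the genome, extracts flanks and designs primers,
#' removes A/T-only and proximal loci, genotypes the panel from the
#' alignments, screens for polymorphism, and computes marker statistics
#' on the surviving loci. Every stage's input/kept/removed counts are
#' recorded in a filter ledger whose conservation is checked on every
#' run.
#'
#' @param genome Named character vector of chromosome sequences, or a
#'   FASTA path.
#' @param alignments Named list of alignment data frames or SAM/BAM
#'   paths (one per accession).
#' @param genes Optional gene table (from [read_gff_genes()]) or GFF3
#'   path for genic annotation.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for artifact export (BED, primer
#'   catalog TSV, VCF, ledger TSV, catalog TSV, band scores TSV).
#' @return List with `loci`, `designed`, `pursued`, `genotypes`,
#'   `screen`, `ledger`, `catalog`, `stats`, `genic_fraction` (NA
#'   without annotation), `binary`.
#' @export
run_pipeline <- function(genome, alignments, genes = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome))) {
    if (!file.exists(genome)) stop("reference FASTA not found: ", genome)
    genome <- read_fasta(genome)
  }
  if (is.character(genes) && length(genes) == 1L) {
    genes <- read_gff_genes(genes)
  }
  loci <- mine_genome(genome, config$mining)
  if (nrow(loci) == 0L) stop("mining found no SSR loci")
  flanks <- extract_flanks(loci, genome, config$mining$flank_len)
  designed <- design_primers(flanks, config$primers)
  st_design <- designed[designed$designable, , drop = FALSE]
  at <- filter_at_only(st_design)
  prox <- filter_proximal(at$kept, config$mining$min_gap)
  pursued <- prox$kept
  gm <- genotype_panel(alignments, pursued, config$stutter, config$filters,
                       config$anchor_bp)
  # loci with at least one PASS call anywhere in the panel
  pass_by_locus <- tapply(gm$calls$status == "PASS",
                          factor(gm$calls$locus, levels = pursued$name), any)
  called <- pursued$name[pass_by_locus]
  scr <- screen_polymorphic(gm, config$min_nonref_accessions)
  mono_in_called <- intersect(scr$removed_mono_or_missing, called)
  ledger <- build_ledger(data.frame(
    stage = c("mined", "primer_design", "at_only", "proximity",
              "genotyped", "mono_or_missing", "low_nonref"),
    input = c(nrow(loci), nrow(loci), nrow(st_design), nrow(at$kept),
              nrow(pursued), length(called),
              length(called) - length(mono_in_called)),
    kept = c(nrow(loci), nrow(st_design), nrow(at$kept), nrow(pursued),
             length(called), length(called) - length(mono_in_called),
             length(scr$kept)),
    stringsAsFactors = FALSE))
  genic <- NA
  genic_flags <- NULL
  if (!is.null(genes)) {
    kept_rows <- pursued[pursued$name %in% scr$kept, , drop = FALSE]
    ann <- annotate_genic(kept_rows, genes)
    genic <- ann$fraction
    genic_flags <- ann$genic[match(designed$name, kept_rows$name)]
  }
  catalog <- if (length(scr$kept)) {
    build_catalog(scr$kept, designed, gm, genic_flags)
  } else NULL
  binary <- NULL
  stats <- NULL
  if (length(scr$kept)) {
    keep_calls <- gm$calls[gm$calls$locus %in% scr$kept, , drop = FALSE]
    sub <- structure(list(calls = keep_calls,
                          loci = gm$loci[gm$loci$name %in% scr$kept, ,
                                         drop = FALSE],
                          accessions = gm$accessions),
                     class = "genotype_matrix")
    binary <- suppressWarnings(genotypes_to_binary(sub))
    stats <- marker_stats_table(binary)
  }
  res <- list(loci = loci, designed = designed, pursued = pursued,
              genotypes = gm, screen = scr, ledger = ledger,
              catalog = catalog, stats = stats, genic_fraction = genic,
              binary = binary)
  if (!is.null(out_dir)) export_artifacts(res, config, out_dir)
  res
}

export_artifacts <- function(res, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- provenance_line(config)
  tsv <- function(df, file) {
    path <- file.path(out_dir, file)
    writeLines(prov, path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    path
  }
  bed <- res$pursued
  bed$ref_units <- bed$units
  write_ssr_bed(bed, file.path(out_dir, "pursued_loci.bed"))
  tsv(res$designed[, c("name", "chrom", "start", "end", "motif", "unit_len",
                       "units", "designable", "forward", "reverse",
                       "product_len", "m13_forward")],
      "primers.tsv")
  tsv(as.data.frame(res$ledger), "ledger.tsv")
  if (!is.null(res$catalog)) tsv(res$catalog, "catalog.tsv")
  if (!is.null(res$stats)) tsv(res$stats$report, "marker_stats.tsv")
  if (!is.null(res$binary)) {
    write_band_scores(res$binary, file.path(out_dir, "band_scores.tsv"))
  }
  write_str_vcf(res$genotypes, res$pursued, file.path(out_dir, "calls.vcf"))
  writeLines(prov, file.path(out_dir, "run_info.txt"))
  invisible(out_dir)
}
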