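## Panel-level polymorphism screening, the stage-by-stage filter ledger,
## and genic/intergenic annotation of loci.

#' Screen a genotype matrix for polymorphic loci
#'
#' A locus is `removed_mono_or_missing` when every non-missing call is
#' homozygous reference or every call is missing; otherwise it is
#' `removed_low_nonref` when fewer than `min_nonref_accessions`
#' accessions carry at least one non-reference allele (a heterozygous
#' ref/alt call counts as carrying one); otherwise it is kept. The three
#' classes partition the input and are invariant to row and column
#' order.
#'
#' @param gm A `genotype_matrix` from [genotype_panel()].
#' @param min_nonref_accessions Minimum number of accessions with a
#'   non-reference allele for a locus to be polymorphic.
#' @param max_missing_fraction Optional stricter screen: loci whose
#'   missing-call fraction exceeds this are classed
#'   `removed_mono_or_missing`. The default 1 removes only loci missing
#'   in every accession.
#' @return List with `kept`, `removed_mono_or_missing`,
#'   `removed_low_nonref` (character vectors of locus names) and
#'   `classification` (data frame locus/class/n_nonref_accessions).
#' @export
screen_polymorphic <- function(gm, min_nonref_accessions = 2L,
                               max_missing_fraction = 1) {
  calls <- gm$calls
  loci <- gm$loci
  stopifnot(nrow(loci) >= 1L, length(gm$accessions) >= 1L)
  ref <- loci$units[match(calls$locus, loci$name)]
  pass <- calls$status == "PASS"
  nonref <- pass & (calls$a1 != ref | calls$a2 != ref)
  by_locus <- factor(calls$locus, levels = loci$name)
  n_nonref <- tapply(nonref, by_locus, sum)
  any_pass_nonref <- n_nonref > 0L
  too_missing <- tapply(!pass, by_locus, mean) > max_missing_fraction
  cls <- ifelse(!any_pass_nonref | too_missing, "removed_mono_or_missing",
                ifelse(n_nonref < min_nonref_accessions,
                       "removed_low_nonref", "kept"))
  classification <- data.frame(locus = loci$name, class = as.character(cls),
                               n_nonref_accessions = as.integer(n_nonref),
                               stringsAsFactors = FALSE)
  list(kept = classification$locus[classification$class == "kept"],
       removed_mono_or_missing =
         classification$locus[classification$class == "removed_mono_or_missing"],
       removed_low_nonref =
         classification$locus[classification$class == "removed_low_nonref"],
       classification = classification)
}

#' Build a stage-by-stage filter ledger
#'
#' Each stage records its input, kept and removed counts; conservation
#' (kept + removed = input) and chaining (one stage's input equals the
#' previous stage's kept count) are enforced.
#'
#' @param stages Data frame with columns `stage`, `input`, `kept` in
#'   pipeline order.
#' @return Data frame of class `filter_ledger` with an added `removed`
#'   column.
#' @export
build_ledger <- function(stages) {
  stopifnot(all(c("stage", "input", "kept") %in% names(stages)))
  if (any(stages$kept > stages$input) || any(stages$kept < 0)) {
    stop("stage kept count outside [0, input]")
  }
  if (nrow(stages) > 1L) {
    prev_kept <- stages$kept[-nrow(stages)]
    nxt_input <- stages$input[-1L]
    if (any(prev_kept != nxt_input)) {
      bad <- which(prev_kept != nxt_input)[1L]
      stop("ledger chain mismatch: stage '", stages$stage[bad + 1L],
           "' input ", nxt_input[bad], " != previous kept ", prev_kept[bad])
    }
  }
  stages$removed <- stages$input - stages$kept
  structure(stages, class = c("filter_ledger", "data.frame"))
}

#' Write a ledger as TSV
#'
#' @param ledger A [build_ledger()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  utils::write.table(as.data.frame(ledger), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annotate loci as genic or intergenic
#'
#' A locus is genic when its half-open interval overlaps any gene
#' interval by at least 1 bp (gene coordinates are converted from
#' 1-based inclusive to 0-based half-open).
#'
#' @param loci Locus data frame (`chrom`, 0-based `start`, exclusive
#'   `end`).
#' @param genes Gene data frame from [read_gff_genes()] (1-based
#'   inclusive `start`, `end`).
#' @return List with `genic` (logical vector parallel to `loci`) and
#'   `fraction` (genic share of loci).
#' @export
annotate_genic <- function(loci, genes) {
  if (nrow(loci) == 0L) return(list(genic = logical(), fraction = NaN))
  if (nrow(genes) == 0L) {
    return(list(genic = rep(FALSE, nrow(loci)), fraction = 0))
  }
  lg <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(start = loci$start + 1L,
                                                end = loci$end))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(start = genes$start,
                                                end = genes$end))
  hits <- GenomicRanges::countOverlaps(lg, gg, minoverlap = 1L)
  genic <- hits > 0L
  list(genic = genic, fraction = mean(genic))
}

#' Assemble the polymorphic-locus catalog
#'
#' One row per locus that survived every screen: name, position, motif,
#' reference repeat count, primer pair, flanks, number of distinct
#' alleles observed in the panel, and the genic flag.
#'
#' @param kept Character vector of kept locus names.
#' @param designed A [design_primers()] result covering the kept loci.
#' @param gm The `genotype_matrix`.
#' @param genic Optional logical vector parallel to `designed` rows.
#' @return Data frame catalog.
#' @export
build_catalog <- function(kept, designed, gm, genic = NULL) {
  rows <- designed[designed$name %in% kept, , drop = FALSE]
  calls <- gm$calls[gm$calls$status == "PASS", , drop = FALSE]
  n_alleles <- vapply(rows$name, function(nm) {
    cc <- calls[calls$locus == nm, ]
    length(unique(c(cc$a1, cc$a2)))
  }, 1L)
  out <- data.frame(name = rows$name, chrom = rows$chrom,
                    position = rows$start + 1L, motif = rows$motif,
                    ref_units = rows$units,
                    forward = rows$forward, reverse = rows$reverse,
                    product_len = rows$product_len,
                    left_flank = rows$left_flank,
                    right_flank = rows$right_flank,
                    n_alleles = n_alleles, stringsAsFactors = FALSE)
  if (!is.null(genic)) {
    out$genic <- genic[match(rows$name, designed$name)]
  }
  if (any(out$n_alleles < 2L)) {
    stop("catalog locus with fewer than 2 observed alleles: ",
         out$name[out$n_alleles < 2L][1L])
  }
  rownames(out) <- NULL
  out
}
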