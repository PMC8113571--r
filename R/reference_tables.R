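## Published summary tables from a genome-wide SSR survey of the
## spinach (Sp75) reference genome and its 48-accession validation
## panel, shipped as plain TSV. They are the printed inputs for the
## package's summary/accounting operations: chromosome-wise locus
## counts and lengths, the stepwise filter cascade by motif class, and
## the per-marker validation statistics (Na, He, PIC).

#' Bundled spinach SSR survey tables
#'
#' @param which One of `"chrom_counts"` (chromosome lengths, SSR and
#'   polymorphic-SSR counts), `"filter_cascade"` (per-motif-class counts
#'   through the discovery cascade: total, primer designed, proximal
#'   removed, A/T-only removed, pursued, called, mono-or-missing
#'   removed, low-non-reference removed, polymorphic), or
#'   `"validation_markers"` (36 assayed markers with primers, product
#'   size, Na, He, PIC; two markers that failed to amplify carry NA).
#' @return Data frame.
#' @export
spinach_ssr_tables <- function(which = c("chrom_counts", "filter_cascade",
                                         "validation_markers")) {
  which <- match.arg(which)
  file <- switch(which,
                 chrom_counts = "spinach_chrom_ssr_counts.tsv",
                 filter_cascade = "spinach_filter_cascade.tsv",
                 validation_markers = "spinach_validation_markers.tsv")
  path <- system.file("extdata", file, package = "ssrscape")
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
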