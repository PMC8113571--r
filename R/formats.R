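## Readers and writers for the standard formats the pipeline touches.
## Dialects are fixed so outputs are bit-stable:
##   FASTA  : wrapped at 60 columns on write, uppercased on read
##   SSR BED: 6 tab-separated columns (chrom, start, end, unit_len,
##            ref_units, name), 0-based half-open coordinates
##   SAM    : plain-text canonical interchange; BAM via Rsamtools when
##            available
##   VCF    : minimal 4.2 with full-tract REF/ALT allele strings
##   GFF3   : 1-based inclusive, gene features only on read

#' Read a FASTA file
#'
#' Reads every record of a FASTA file, concatenating wrapped sequence
#' lines and uppercasing the sequence. Records are returned in file
#' order.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector: names are sequence identifiers (the
#'   header up to the first whitespace), values are uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 50L)
  first <- first[nzchar(trimws(first))]
  if (length(first) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(first[1L], ">")) {
    bad <- which(nzchar(trimws(readLines(path))))[1L]
    stop("malformed FASTA header at line ", bad, ": expected '>'")
  }
  set <- Biostrings::readDNAStringSet(path)
  if (any(Biostrings::width(set) == 0L)) {
    stop("FASTA record with empty sequence: ",
         names(set)[Biostrings::width(set) == 0L][1L])
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(names(seqs)))) stop("FASTA record with empty identifier")
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

## ---- SSR BED dialect -------------------------------------------------

validate_ssr_bed <- function(df, where = "SSR BED") {
  need <- c("chrom", "start", "end", "unit_len", "ref_units", "name")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(where, ": missing columns ", paste(miss, collapse = ", "))
  if (any(df$start < 0) || any(df$start >= df$end)) {
    stop(where, ": requires 0 <= start < end")
  }
  if (any(df$unit_len < 2L | df$unit_len > 6L)) {
    stop(where, ": unit_len must be in [2, 6]")
  }
  span <- df$end - df$start
  if (any(span != df$unit_len * df$ref_units)) {
    bad <- which(span != df$unit_len * df$ref_units)[1L]
    stop(where, ": end - start (", span[bad], ") is not unit_len x ref_units",
         " for locus ", df$name[bad])
  }
  invisible(df)
}

#' Write SSR loci as a 6-column BED file
#'
#' Columns are chrom, start, end, unit_len, ref_units, name with 0-based
#' half-open coordinates. [read_ssr_bed()] is the exact inverse.
#'
#' @param records Data frame with columns `chrom`, `start`, `end`,
#'   `unit_len`, `ref_units`, `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ssr_bed <- function(records, path) {
  validate_ssr_bed(records, "write_ssr_bed")
  out <- records[, c("chrom", "start", "end", "unit_len", "ref_units", "name")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 6-column SSR BED file
#'
#' @param path Path to a BED file written by [write_ssr_bed()].
#' @return Data frame with columns `chrom`, `start`, `end`, `unit_len`,
#'   `ref_units`, `name`.
#' @export
read_ssr_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end",
                                        "unit_len", "ref_units", "name"),
                          colClasses = c("character", "integer", "integer",
                                         "integer", "integer", "character"))
  validate_ssr_bed(df, paste0("read_ssr_bed(", path, ")"))
  df
}

## ---- CIGAR arithmetic ------------------------------------------------

# Parse a vector of CIGAR strings into a list of list(len=int, op=chr).
parse_cigar <- function(cigars) {
  toks <- regmatches(cigars, gregexpr("\\d+[MIDNSHP=X]", cigars))
  lapply(toks, function(tk) {
    if (length(tk) == 0L) stop("unparseable CIGAR")
    list(len = as.integer(substr(tk, 1L, nchar(tk) - 1L)),
         op = substr(tk, nchar(tk), nchar(tk)))
  })
}

cigar_query_len <- function(ops) {
  sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
}

cigar_ref_span <- function(ops) {
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

## ---- SAM / BAM -------------------------------------------------------

#' Read alignment records from SAM (or BAM)
#'
#' Plain-text SAM is the canonical interchange format; BAM is read
#' through Rsamtools when that package is installed. Unmapped records are
#' skipped. Each record's CIGAR is checked against its sequence length.
#'
#' @param path Path to a SAM (`.sam`) or BAM (`.bam`) file.
#' @param region Optional list/data.frame with `chrom`, `start`, `end`
#'   (0-based half-open) restricting output to overlapping records.
#' @return Data frame with columns `qname`, `flag`, `rname`, `pos`
#'   (1-based leftmost), `cigar`, `seq`, and `ref_end` (1-based inclusive
#'   rightmost reference position).
#' @export
read_alignments <- function(path, region = NULL) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    aln <- read_bam_records(path)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
    if (length(lines) == 0L) {
      aln <- data.frame(qname = character(), flag = integer(),
                        rname = character(), pos = integer(),
                        cigar = character(), seq = character(),
                        stringsAsFactors = FALSE)
    } else {
      fields <- strsplit(lines, "\t", fixed = TRUE)
      nf <- lengths(fields)
      if (any(nf < 11L)) {
        stop("SAM record with fewer than 11 fields: ",
             fields[[which(nf < 11L)[1L]]][1L])
      }
      aln <- data.frame(
        qname = vapply(fields, `[[`, "", 1L),
        flag = as.integer(vapply(fields, `[[`, "", 2L)),
        rname = vapply(fields, `[[`, "", 3L),
        pos = as.integer(vapply(fields, `[[`, "", 4L)),
        cigar = vapply(fields, `[[`, "", 6L),
        seq = vapply(fields, `[[`, "", 10L),
        stringsAsFactors = FALSE)
    }
  }
  mapped <- bitwAnd(aln$flag, 4L) == 0L
  aln <- aln[mapped, , drop = FALSE]
  if (nrow(aln) == 0L) {
    aln$ref_end <- integer()
    return(aln)
  }
  ops <- parse_cigar(aln$cigar)
  qlen <- vapply(ops, cigar_query_len, 1L)
  bad <- which(qlen != nchar(aln$seq))
  if (length(bad)) {
    stop("CIGAR/sequence length mismatch for read ", aln$qname[bad[1L]],
         ": CIGAR consumes ", qlen[bad[1L]], " bases, sequence has ",
         nchar(aln$seq[bad[1L]]))
  }
  aln$ref_end <- aln$pos + vapply(ops, cigar_ref_span, 1L) - 1L
  if (!is.null(region)) {
    keep <- aln$rname == region$chrom &
      aln$pos <= region$end &                 # region end is exclusive, pos 1-based
      aln$ref_end >= region$start + 1L
    aln <- aln[keep, , drop = FALSE]
  }
  rownames(aln) <- NULL
  aln
}

read_bam_records <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading BAM requires the Rsamtools package; supply SAM instead")
  }
  b <- Rsamtools::scanBam(path)[[1L]]
  data.frame(qname = b$qname, flag = b$flag,
             rname = as.character(b$rname), pos = b$pos,
             cigar = b$cigar, seq = as.character(b$seq),
             stringsAsFactors = FALSE)
}

#' Write alignment records as SAM
#'
#' @param aln Data frame with columns `qname`, `flag`, `rname`, `pos`,
#'   `cigar`, `seq`.
#' @param chrom_lengths Named integer vector for the `@SQ` header lines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, chrom_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  if (nrow(aln)) {
    o <- order(match(aln$rname, names(chrom_lengths)), aln$pos)
    aln <- aln[o, , drop = FALSE]
    body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                    aln$qname, aln$flag, aln$rname, aln$pos, aln$cigar,
                    aln$seq, strrep("I", nchar(aln$seq)))
  } else {
    body <- character()
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---- VCF -------------------------------------------------------------

#' Write SSR genotype calls as a minimal VCF 4.2
#'
#' One line per locus. REF is the reference repeat-tract sequence; ALT
#' alleles are the observed alternate tract sequences ordered by repeat
#' count. Per-sample fields are GT, Q (call quality) and FR (filter
#' reason, "." for PASS); missing calls are encoded "./.".
#'
#' @param genotype_matrix A [genotype_panel()] result.
#' @param loci SSR locus table (with `motif`) aligned to the matrix by
#'   locus name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_str_vcf <- function(genotype_matrix, loci, path) {
  calls <- genotype_matrix$calls
  accs <- genotype_matrix$accessions
  loci <- loci[match(genotype_matrix$loci$name, loci$name), , drop = FALSE]
  if (is.null(loci$ref_units)) loci$ref_units <- loci$units
  if (anyNA(loci$ref_units)) stop("loci table missing reference repeat counts")
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=RU,Number=1,Type=String,Description=\"Repeat unit\">",
           "##INFO=<ID=REFUNITS,Number=1,Type=Integer,Description=\"Reference repeat count\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=Q,Number=1,Type=Float,Description=\"Call quality\">",
           "##FORMAT=<ID=FR,Number=1,Type=String,Description=\"Filter reason\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", accs), collapse = "\t"))
  rows <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    loc <- loci[i, ]
    lc <- calls[calls$locus == loc$name, , drop = FALSE]
    lc <- lc[match(accs, lc$accession), , drop = FALSE]
    pass <- !is.na(lc$a1) & lc$status == "PASS"
    obs_units <- sort(unique(c(lc$a1[pass], lc$a2[pass])))
    if (any(obs_units <= 0)) stop("allele with non-positive repeat count at ",
                                  loc$name)
    alt_units <- setdiff(obs_units, loc$ref_units)
    alleles <- c(loc$ref_units, alt_units)       # index 0 = REF
    gt <- vapply(seq_along(accs), function(j) {
      if (!pass[j]) return("./.")
      paste(match(lc$a1[j], alleles) - 1L, match(lc$a2[j], alleles) - 1L,
            sep = "/")
    }, "")
    q <- ifelse(pass, sprintf("%.4f", lc$quality), ".")
    fr <- ifelse(pass, ".", ifelse(is.na(lc$reason), ".", lc$reason))
    samp <- paste(gt, q, fr, sep = ":")
    rows[i] <- paste(c(loc$chrom, loc$start + 1L, loc$name,
                       strrep(loc$motif, loc$ref_units),
                       if (length(alt_units))
                         paste(strrep(loc$motif, alt_units), collapse = ",")
                       else ".",
                       ".", "PASS",
                       sprintf("RU=%s;REFUNITS=%d", loc$motif, loc$ref_units),
                       "GT:Q:FR", samp), collapse = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

## ---- GFF3 ------------------------------------------------------------

#' Read gene features from a GFF3 file
#'
#' Keeps only features of type `gene`; coordinates stay 1-based
#' inclusive as in the source annotation.
#'
#' @param path Path to a GFF3 file.
#' @return Data frame with columns `chrom`, `start`, `end`, `id`.
#' @export
read_gff_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), id = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 9L)) stop("GFF3 line with fewer than 9 fields")
  type <- vapply(fields, `[[`, "", 3L)
  keep <- type == "gene"
  fields <- fields[keep]
  if (length(fields) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), id = character(),
                      stringsAsFactors = FALSE))
  }
  start <- as.integer(vapply(fields, `[[`, "", 4L))
  end <- as.integer(vapply(fields, `[[`, "", 5L))
  if (any(start > end)) stop("GFF3 gene with start > end")
  attr9 <- vapply(fields, `[[`, "", 9L)
  id <- sub("^.*ID=([^;]+).*$", "\\1", attr9)
  data.frame(chrom = vapply(fields, `[[`, "", 1L),
             start = start, end = end, id = id, stringsAsFactors = FALSE)
}

#' Write gene features as GFF3
#'
#' @param genes Data frame with columns `chrom`, `start`, `end`, `id`
#'   (1-based inclusive coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(genes, path) {
  if (nrow(genes) && any(genes$start > genes$end)) {
    stop("gene with start > end")
  }
  lines <- "##gff-version 3"
  if (nrow(genes)) {
    lines <- c(lines,
               sprintf("%s\tssrscape\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       genes$chrom, genes$start, genes$end, genes$id))
  }
  writeLines(lines, path)
  invisible(path)
}
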