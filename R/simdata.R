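## Synthetic-data generator: a reference genome with planted perfect SSR
## loci, a diploid accession panel with known repeat-count variation,
## gene annotations, and stutter-noised pre-aligned reads. Everything is
## a deterministic function of the config seed and serves as ground
## truth for pipeline tests.
##
## Reads are emitted pre-aligned (correct POS/CIGAR) rather than as
## FASTQ: alignment is outside this package's scope, and planted CIGARs
## exercise the genotyper's tract arithmetic directly.

#' Panel simulation configuration
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' a multi-chromosome reference, a 21-accession diploid panel
#' resequenced to 30x depth, and a geometric stutter process with
#' per-read stutter probability 0.05 and decay 0.8.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bp.
#' @param n_loci Planted loci per chromosome.
#' @param motif_len_weights Sampling weights for unit lengths 2-6.
#' @param units_extra Planted repeat counts are the mining minimum for
#'   the unit length plus 0..`units_extra`.
#' @param n_accessions Accessions in the panel.
#' @param polymorphic_fraction Fraction of loci drawn polymorphic.
#' @param max_offset Largest repeat-unit offset of an alternate allele.
#' @param depth Read depth over each locus region.
#' @param read_len Read length in bp.
#' @param read_pad Reads are tiled over the locus plus this many bp of
#'   flank on each side.
#' @param p_s,rho Stutter model parameters used when noising reads.
#' @param sub_rate Per-base substitution error rate outside anchors.
#' @param gene_fraction Fraction of loci covered by a planted gene.
#' @param flank_len,min_gap Mining geometry the planted spacing must
#'   respect.
#' @param anchor_bp Anchor width assumed when validating read length.
#' @param seed Integer seed; fully determines all outputs.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 2L, chrom_len = 60000L, n_loci = 8L,
                       motif_len_weights = c(`2` = 0.41, `3` = 0.31,
                                             `4` = 0.14, `5` = 0.09,
                                             `6` = 0.05),
                       units_extra = 3L, n_accessions = 21L,
                       polymorphic_fraction = 0.4, max_offset = 3L,
                       depth = 30, read_len = 100L, read_pad = 150L,
                       p_s = 0.05, rho = 0.8, sub_rate = 0.001,
                       gene_fraction = 0.3, flank_len = 250L,
                       min_gap = 100L, anchor_bp = 10L, seed = 1L) {
  cfg <- list(n_chrom = as.integer(n_chrom), chrom_len = as.integer(chrom_len),
              n_loci = as.integer(n_loci),
              motif_len_weights = motif_len_weights,
              units_extra = as.integer(units_extra),
              n_accessions = as.integer(n_accessions),
              polymorphic_fraction = polymorphic_fraction,
              max_offset = as.integer(max_offset), depth = depth,
              read_len = as.integer(read_len), read_pad = as.integer(read_pad),
              p_s = p_s, rho = rho, sub_rate = sub_rate,
              gene_fraction = gene_fraction, flank_len = as.integer(flank_len),
              min_gap = as.integer(min_gap), anchor_bp = as.integer(anchor_bp),
              seed = as.integer(seed))
  # worst-case tract: (min_units + extra + max_offset) units of a 6-mer
  max_tract <- (4L + cfg$units_extra + cfg$max_offset) * 6L
  if (cfg$read_len <= max_tract + 2L * cfg$anchor_bp) {
    stop("read_len too short to span the largest planted tract plus anchors")
  }
  slot <- cfg$chrom_len %/% cfg$n_loci
  if (slot < max_tract + 2L * cfg$flank_len + cfg$min_gap + 200L) {
    stop("infeasible packing: n_loci x spacing exceeds chrom_len")
  }
  structure(cfg, class = "sim_config")
}

min_units_default <- c(`2` = 6L, `3` = 5L, `4` = 4L, `5` = 4L, `6` = 4L)

# Random primitive motif of length k containing at least one G/C.
random_motif <- function(k) {
  repeat {
    m <- paste(sample(DNA_BASES, k, replace = TRUE), collapse = "")
    if (grepl("[GC]", m) && is_primitive(m)) return(m)
  }
}

#' Simulate a reference genome with planted SSR loci
#'
#' Chromosomes are i.i.d. uniform ACGT background with perfect SSR
#' tracts planted at recorded positions, one per evenly spaced slot so
#' that planted loci always respect the proximity filter and flank
#' geometry. Guard bases prevent tract extension, and the background is
#' screened after planting: any accidental run meeting the mining
#' thresholds is disrupted, so mining truth is unambiguous. A stated
#' fraction of loci is covered by a planted gene.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_truth` with `genome` (named character),
#'   `loci` (planted SSR table), `genes` (1-based inclusive intervals),
#'   `config`.
#' @export
simulate_reference <- function(config = sim_config()) {
  set.seed(config$seed)
  genome <- character(config$n_chrom)
  names(genome) <- sprintf("chr%02d", seq_len(config$n_chrom))
  all_loci <- list()
  mcfg <- mining_config(flank_len = config$flank_len,
                        min_gap = config$min_gap)
  for (ci in seq_len(config$n_chrom)) {
    chrom <- names(genome)[ci]
    chars <- sample(DNA_BASES, config$chrom_len, replace = TRUE)
    slot <- config$chrom_len %/% config$n_loci
    ks <- as.integer(sample(names(config$motif_len_weights), config$n_loci,
                            replace = TRUE, prob = config$motif_len_weights))
    rows <- vector("list", config$n_loci)
    for (i in seq_len(config$n_loci)) {
      k <- ks[i]
      units <- min_units_default[[as.character(k)]] +
        sample.int(config$units_extra + 1L, 1L) - 1L
      motif <- random_motif(k)
      start <- (i - 1L) * slot + config$flank_len +
        sample.int(100L, 1L) + 50L           # 0-based tract start
      end <- start + units * k
      mchars <- strsplit(strrep(motif, units), "", fixed = TRUE)[[1L]]
      chars[(start + 1L):end] <- mchars
      # guard bases: no extension of the periodic run into the flanks
      last <- substr(motif, k, k)
      first <- substr(motif, 1L, 1L)
      chars[start] <- sample(setdiff(DNA_BASES, last), 1L)
      chars[end + 1L] <- sample(setdiff(DNA_BASES, first), 1L)
      rows[[i]] <- data.frame(chrom = chrom, start = start, end = end,
                              motif = motif, unit_len = k,
                              units = as.integer(units),
                              stringsAsFactors = FALSE)
    }
    loci <- do.call(rbind, rows)
    loci$name <- name_locus(loci$chrom, loci$unit_len, loci$start)
    seqstr <- paste(chars, collapse = "")
    # disrupt accidental runs so mining recovers exactly the planted set
    for (pass in 1:20) {
      mined <- find_ssrs(seqstr, chrom, mcfg)
      extra <- mined[!mined$name %in% loci$name, , drop = FALSE]
      if (nrow(extra) == 0L) break
      for (j in seq_len(nrow(extra))) {
        mid <- extra$start[j] + (extra$end[j] - extra$start[j]) %/% 2L
        # keep clear of planted tracts and their guard bases
        inside <- any(mid >= loci$start - 1L & mid < loci$end + 1L)
        if (inside) mid <- extra$start[j]
        cur <- substr(seqstr, mid + 1L, mid + 1L)
        substr(seqstr, mid + 1L, mid + 1L) <- setdiff(DNA_BASES, cur)[1L]
      }
    }
    genome[chrom] <- seqstr
    all_loci[[ci]] <- loci
  }
  loci <- do.call(rbind, all_loci)
  rownames(loci) <- NULL
  # plant genes over a stated fraction of loci
  n_genic <- round(config$gene_fraction * nrow(loci))
  genic_idx <- if (n_genic > 0L) {
    sort(sample.int(nrow(loci), n_genic))
  } else integer()
  genes <- if (length(genic_idx)) {
    data.frame(chrom = loci$chrom[genic_idx],
               start = pmax(loci$start[genic_idx] - 200L, 0L) + 1L,
               end = loci$end[genic_idx] + 200L,
               id = sprintf("gene%04d", seq_along(genic_idx)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               id = character(), stringsAsFactors = FALSE)
  }
  structure(list(genome = genome, loci = loci, genes = genes,
                 config = config),
            class = "sim_truth")
}

#' Simulate diploid genotypes for an accession panel
#'
#' Each locus is drawn polymorphic with probability
#' `polymorphic_fraction`; at polymorphic loci accession alleles are
#' drawn from the reference count plus unit offsets, redrawing until at
#' least two accessions carry a non-reference allele. Monomorphic loci
#' are homozygous reference everywhere. The recorded `polymorphic` flag
#' is evaluated on the realised genotypes with the same rule the
#' polymorphism screen uses (>= 2 non-reference accessions).
#'
#' @param truth A [simulate_reference()] result.
#' @param config Defaults to `truth$config`.
#' @return List with `genotypes` (locus x accession long table with
#'   `a1`, `a2`) and `loci` (truth loci plus `polymorphic` flag).
#' @export
simulate_panel <- function(truth, config = truth$config) {
  set.seed(config$seed + 1000L)
  accs <- sprintf("acc%02d", seq_len(config$n_accessions))
  loci <- truth$loci
  rows <- vector("list", nrow(loci))
  poly <- logical(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    ref <- loci$units[i]
    make_mono <- stats::runif(1L) >= config$polymorphic_fraction
    if (make_mono) {
      a1 <- a2 <- rep(ref, config$n_accessions)
    } else {
      offs <- setdiff(seq(-config$max_offset, config$max_offset), 0L)
      offs <- offs[ref + offs >= 2L]
      n_alt <- min(length(offs), sample.int(2L, 1L))
      alts <- ref + sample(offs, n_alt)
      pool <- c(ref, alts)
      prob <- c(0.6, rep(0.4 / n_alt, n_alt))
      for (attempt in 1:100) {
        a1 <- sample(pool, config$n_accessions, replace = TRUE, prob = prob)
        a2 <- sample(pool, config$n_accessions, replace = TRUE, prob = prob)
        if (sum(a1 != ref | a2 != ref) >= 2L) break
      }
    }
    swap <- a1 > a2
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
    poly[i] <- sum(a1 != ref | a2 != ref) >= 2L
    rows[[i]] <- data.frame(locus = loci$name[i], accession = accs,
                            a1 = as.integer(a1), a2 = as.integer(a2),
                            stringsAsFactors = FALSE)
  }
  loci$polymorphic <- poly
  list(genotypes = do.call(rbind, rows), loci = loci, accessions = accs)
}

# Alignment path of an accession-local region against the reference
# region, as ops over the whole local region. u0 = reference units,
# ue = accession/effective units for this read.
region_path <- function(left_len, right_len, u0, ue, k) {
  delta <- (ue - u0) * k
  if (delta == 0L) {
    len <- left_len + u0 * k + right_len
    op <- "M"
  } else if (delta > 0L) {
    h <- (u0 %/% 2L) * k
    len <- c(left_len + h, delta, u0 * k - h + right_len)
    op <- c("M", "I", "M")
  } else {
    h <- (ue %/% 2L) * k
    len <- c(left_len + h, -delta, ue * k - h + right_len)
    op <- c("M", "D", "M")
  }
  keep <- len > 0L | op == "D"
  list(len = len[keep], op = op[keep])
}

# Slice a region alignment path to the read [qs, qe] (1-based query
# coords within the local region). Returns list(pos_offset, cigar):
# pos_offset is the 0-based reference offset of the first aligned base
# relative to the region start. Leading/trailing insertions become soft
# clips; leading/trailing deletions are dropped.
slice_path <- function(ops, qs, qe) {
  out_len <- integer(0)
  out_op <- character(0)
  q <- 0L  # query consumed so far
  r <- 0L  # reference consumed so far
  pos_offset <- NA_integer_
  for (i in seq_along(ops$len)) {
    len <- ops$len[i]
    op <- ops$op[i]
    if (op %in% c("M", "I")) {
      ov_lo <- max(qs, q + 1L)
      ov_hi <- min(qe, q + len)
      if (ov_hi >= ov_lo) {
        take <- ov_hi - ov_lo + 1L
        if (op == "M") {
          if (is.na(pos_offset)) pos_offset <- r + (ov_lo - q - 1L)
          out_len <- c(out_len, take)
          out_op <- c(out_op, "M")
        } else {
          out_len <- c(out_len, take)
          out_op <- c(out_op, if (is.na(pos_offset)) "S" else "I")
        }
      }
      q <- q + len
      if (op == "M") r <- r + len
    } else if (op == "D") {
      if (q >= qs && q < qe && !is.na(pos_offset)) {
        out_len <- c(out_len, len)
        out_op <- c(out_op, "D")
      }
      r <- r + len
    }
    if (q >= qe) break
  }
  # trailing I becomes S; trailing D already excluded by q < qe test
  if (length(out_op) && out_op[length(out_op)] == "I") {
    out_op[length(out_op)] <- "S"
  }
  # collapse adjacent identical ops
  keep_i <- which(c(TRUE, out_op[-1L] != out_op[-length(out_op)]))
  if (length(keep_i) < length(out_op)) {
    grp <- cumsum(c(TRUE, out_op[-1L] != out_op[-length(out_op)]))
    out_len <- as.integer(tapply(out_len, grp, sum))
    out_op <- out_op[keep_i]
  }
  list(pos_offset = pos_offset,
       cigar = paste0(out_len, out_op, collapse = ""))
}

#' Simulate stutter-noised pre-aligned reads for the panel
#'
#' Reads are tiled to the configured depth over each locus plus
#' `read_pad` bp of flank. Each read copies one of the accession's two
#' haplotypes; with probability `p_s` its apparent tract length is
#' perturbed by a geometric(`rho`) number of units with fair sign.
#' Substitution errors are added outside the anchor windows. Records
#' carry correct POS and CIGAR against the reference.
#'
#' @param truth A [simulate_reference()] result.
#' @param panel A [simulate_panel()] result.
#' @param config Defaults to `truth$config`.
#' @return Named list (one per accession) of alignment data frames with
#'   columns `qname`, `flag`, `rname`, `pos`, `cigar`, `seq`.
#' @export
simulate_reads <- function(truth, panel, config = truth$config) {
  set.seed(config$seed + 2000L)
  loci <- truth$loci
  genome <- truth$genome
  out <- vector("list", length(panel$accessions))
  names(out) <- panel$accessions
  gt <- panel$genotypes
  for (ai in seq_along(panel$accessions)) {
    acc <- panel$accessions[ai]
    v_qname <- v_rname <- v_cigar <- v_seq <- character()
    v_pos <- integer()
    for (li in seq_len(nrow(loci))) {
      loc <- list(chrom = loci$chrom[li], start = loci$start[li],
                  end = loci$end[li], motif = loci$motif[li],
                  unit_len = loci$unit_len[li], units = loci$units[li],
                  name = loci$name[li])
      g <- gt[gt$locus == loc$name & gt$accession == acc, ]
      alleles <- c(g$a1, g$a2)
      k <- loc$unit_len
      u0 <- loc$units
      rstart <- max(loc$start - config$read_pad, 0L)      # 0-based
      rend <- min(loc$end + config$read_pad, nchar(genome[[loc$chrom]]))
      left <- substr(genome[[loc$chrom]], rstart + 1L, loc$start)
      right <- substr(genome[[loc$chrom]], loc$end + 1L, rend)
      n_reads <- max(1L, round(config$depth * (rend - rstart) /
                                 config$read_len))
      lq <- lr <- lc <- ls <- character(n_reads)
      lp <- integer(n_reads)
      m <- 0L
      for (rj in seq_len(n_reads)) {
        u <- alleles[sample.int(2L, 1L)]
        if (stats::runif(1L) < config$p_s) {
          gshift <- stats::rgeom(1L, 1 - config$rho) + 1L
          u <- max(1L, u + gshift * sample(c(-1L, 1L), 1L))
        }
        local <- paste0(left, strrep(loc$motif, u), right)
        llen <- nchar(local)
        if (llen < config$read_len) next
        qs <- sample.int(llen - config$read_len + 1L, 1L)
        qe <- qs + config$read_len - 1L
        path <- region_path(nchar(left), nchar(right), u0, u, k)
        sl <- slice_path(path, qs, qe)
        if (is.na(sl$pos_offset)) next   # read entirely inserted bases
        readseq <- substr(local, qs, qe)
        if (config$sub_rate > 0) {
          readseq <- add_substitutions(readseq, sl, rstart, loc, config)
        }
        m <- m + 1L
        lq[m] <- sprintf("%s_%s_r%04d", acc, loc$name, rj)
        lr[m] <- loc$chrom
        lp[m] <- rstart + sl$pos_offset + 1L
        lc[m] <- sl$cigar
        ls[m] <- readseq
      }
      v_qname <- c(v_qname, lq[seq_len(m)])
      v_rname <- c(v_rname, lr[seq_len(m)])
      v_pos <- c(v_pos, lp[seq_len(m)])
      v_cigar <- c(v_cigar, lc[seq_len(m)])
      v_seq <- c(v_seq, ls[seq_len(m)])
    }
    out[[ai]] <- data.frame(qname = v_qname, flag = 0L, rname = v_rname,
                            pos = v_pos, cigar = v_cigar, seq = v_seq,
                            stringsAsFactors = FALSE)
  }
  out
}

# Substitute bases (uniform errors) at read positions aligned outside
# the tract-plus-anchor window.
add_substitutions <- function(readseq, sl, rstart, loc, config) {
  ops <- parse_cigar(sl$cigar)[[1L]]
  q <- 0L
  r <- rstart + sl$pos_offset           # 0-based ref coord
  lo <- loc$start - config$anchor_bp
  hi <- loc$end + config$anchor_bp      # [lo, hi) protected
  eligible <- integer(0)
  for (i in seq_along(ops$len)) {
    len <- ops$len[i]
    op <- ops$op[i]
    if (op %in% c("M", "=", "X")) {
      refpos <- r + seq_len(len) - 1L
      qpos <- q + seq_len(len)
      eligible <- c(eligible, qpos[refpos < lo | refpos >= hi])
      q <- q + len
      r <- r + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      r <- r + len
    }
  }
  if (length(eligible) == 0L) return(readseq)
  hit <- eligible[stats::runif(length(eligible)) < config$sub_rate]
  if (length(hit) == 0L) return(readseq)
  chars <- strsplit(readseq, "", fixed = TRUE)[[1L]]
  for (p in hit) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Write simulator outputs to a directory
#'
#' Writes the reference FASTA, truth BED, GFF3, per-accession SAM files
#' and a truth genotype TSV.
#'
#' @param truth A [simulate_reference()] result.
#' @param panel A [simulate_panel()] result.
#' @param reads A [simulate_reads()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths.
#' @export
write_sim_outputs <- function(truth, panel, reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chrom_lengths <- nchar(truth$genome)
  paths <- list(
    fasta = file.path(dir, "reference.fa"),
    bed = file.path(dir, "truth_loci.bed"),
    gff = file.path(dir, "genes.gff3"),
    genotypes = file.path(dir, "truth_genotypes.tsv"))
  write_fasta(truth$genome, paths$fasta)
  bed <- truth$loci
  bed$ref_units <- bed$units
  write_ssr_bed(bed, paths$bed)
  write_gff_genes(truth$genes, paths$gff)
  utils::write.table(panel$genotypes, paths$genotypes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$sam <- vapply(names(reads), function(acc) {
    p <- file.path(dir, paste0(acc, ".sam"))
    write_sam(reads[[acc]], chrom_lengths, p)
    p
  }, "")
  paths
}

#' Evaluate pipeline outputs against simulator truth
#'
#' @param mined Mining result (locus data frame).
#' @param gm A `genotype_matrix` over the truth loci, or NULL.
#' @param screen Result of [screen_polymorphic()], or NULL.
#' @param truth A [simulate_reference()] result.
#' @param panel A [simulate_panel()] result (required with `gm`).
#' @return List with `mining_precision`, `mining_recall`, and (when
#'   genotypes/screen are supplied) `genotype_concordance`,
#'   `missing_rate`, `screen_precision`, `screen_recall`.
#' @export
end_to_end_truth_eval <- function(mined, gm = NULL, screen = NULL, truth,
                                  panel = NULL) {
  key <- function(df) paste(df$chrom, df$start, df$end, df$motif)
  tp <- sum(key(mined) %in% key(truth$loci))
  res <- list(mining_precision = if (nrow(mined)) tp / nrow(mined) else NA,
              mining_recall = tp / nrow(truth$loci))
  if (!is.null(gm)) {
    if (is.null(panel)) stop("panel truth required to score genotypes")
    tg <- panel$genotypes
    idx <- paste(tg$locus, tg$accession)
    calls <- gm$calls
    m <- match(paste(calls$locus, calls$accession), idx)
    if (anyNA(m)) stop("locus/accession id mismatch between calls and truth")
    pass <- calls$status == "PASS"
    conc <- calls$a1[pass] == tg$a1[m][pass] & calls$a2[pass] == tg$a2[m][pass]
    res$genotype_concordance <- mean(conc)
    res$missing_rate <- mean(!pass)
  }
  if (!is.null(screen)) {
    truth_poly <- panel$loci$name[panel$loci$polymorphic]
    kept <- screen$kept
    res$screen_precision <- if (length(kept)) {
      mean(kept %in% truth_poly)
    } else NA
    res$screen_recall <- if (length(truth_poly)) {
      mean(truth_poly %in% kept)
    } else NA
  }
  res
}
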