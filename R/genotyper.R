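## In-silico diploid repeat-count genotyping from read alignments.
##
## Each spanning read yields an observed repeat count (reference tract
## span plus net indel bp inside the tract, divided by the unit length;
## off-frame when not a whole number of units). Genotypes are called by
## maximum a posteriori over all unordered pairs of candidate alleles
## under a symmetric geometric stutter likelihood, then filtered on call
## quality, flank-indel fraction and stutter fraction.

#' Geometric stutter model
#'
#' A read reports its true allele `a` with probability `1 - p_s`;
#' otherwise it gains or loses `g` repeat units where `g` is geometric
#' with decay `rho` and the sign is fair:
#' `P(k | a) = p_s (1 - rho) rho^(|k - a| - 1) / 2` for `k != a`.
#'
#' @param p_s Per-read stutter probability in `[0, 1)`.
#' @param rho Geometric decay in `(0, 1)`.
#' @return List of class `stutter_model`.
#' @export
stutter_model <- function(p_s = 0.05, rho = 0.8) {
  if (p_s < 0 || p_s >= 1) stop("p_s must be in [0, 1)")
  if (rho <= 0 || rho >= 1) stop("rho must be in (0, 1)")
  structure(list(p_s = p_s, rho = rho), class = "stutter_model")
}

#' Call-level filters
#'
#' Defaults mirror a conventional STR-calling configuration: minimum
#' call quality 0.9, maximum flank-indel read fraction 0.15, maximum
#' stutter read fraction 0.15, and at least 5 spanning reads.
#'
#' @param min_call_qual Minimum posterior probability of the called
#'   genotype.
#' @param max_flank_indel Maximum fraction of spanning reads with an
#'   indel in the anchor windows.
#' @param max_stutter Maximum fraction of reads discordant with both
#'   called alleles (off-frame reads count toward this fraction).
#' @param min_spanning_reads Minimum spanning reads for a call.
#' @return List of class `call_filters`.
#' @export
call_filters <- function(min_call_qual = 0.9, max_flank_indel = 0.15,
                         max_stutter = 0.15, min_spanning_reads = 5L) {
  fr <- c(min_call_qual, max_flank_indel, max_stutter)
  if (any(fr < 0 | fr > 1)) stop("filter fractions must be in [0, 1]")
  structure(list(min_call_qual = min_call_qual,
                 max_flank_indel = max_flank_indel,
                 max_stutter = max_stutter,
                 min_spanning_reads = as.integer(min_spanning_reads)),
            class = "call_filters")
}

#' Measure the repeat tract in one aligned read
#'
#' A read is spanning when its alignment covers the tract plus
#' `anchor_bp` on both sides. The observed tract length is the reference
#' tract span plus inserted minus deleted bp whose reference position
#' falls inside the tract; when that length is not a whole number of
#' units the read is off-frame. Any insertion or deletion touching the
#' two anchor windows sets the flank-indel flag.
#'
#' @param aln One alignment record (list/row with `pos` 1-based and
#'   `cigar`).
#' @param locus One SSR locus (list/row with 0-based `start`, exclusive
#'   `end`, `unit_len`).
#' @param anchor_bp Anchor window width in bp.
#' @return List with `spanning`, `units` (NA when off-frame or
#'   non-spanning), `off_frame`, `flank_indel`.
#' @export
measure_read <- function(aln, locus, anchor_bp = 10L) {
  ops <- parse_cigar(aln$cigar)[[1L]]
  measure_read_ops(as.integer(aln$pos), ops, locus, anchor_bp)
}

measure_read_ops <- function(pos1, ops, locus, anchor_bp = 10L) {
  start <- locus$start            # 0-based inclusive
  end <- locus$end                # 0-based exclusive
  ref0 <- pos1 - 1L               # 0-based alignment start
  ref_end0 <- ref0 + cigar_ref_span(ops)   # 0-based exclusive
  if (ref_end0 <= start || ref0 >= end) {
    stop("alignment does not overlap locus")
  }
  spanning <- ref0 <= start - anchor_bp && ref_end0 >= end + anchor_bp
  if (!spanning) {
    return(list(spanning = FALSE, units = NA_integer_, off_frame = FALSE,
                flank_indel = FALSE))
  }
  anchor_lo <- start - anchor_bp   # [anchor_lo, start) left window
  anchor_hi <- end + anchor_bp     # [end, anchor_hi) right window
  delta <- 0L
  flank_indel <- FALSE
  r <- ref0
  for (i in seq_along(ops$len)) {
    len <- ops$len[i]
    op <- ops$op[i]
    if (op %in% c("M", "=", "X")) {
      r <- r + len
    } else if (op == "I") {
      # insertion anchored between r-1 and r
      if (r > start && r < end) delta <- delta + len
      if ((r > anchor_lo && r <= start) || (r > end && r <= anchor_hi)) {
        flank_indel <- TRUE
      }
    } else if (op %in% c("D", "N")) {
      dstart <- r
      dend <- r + len
      ov_tract <- min(dend, end) - max(dstart, start)
      if (ov_tract > 0L) delta <- delta - ov_tract
      if (min(dend, start) - max(dstart, anchor_lo) > 0L ||
          min(dend, anchor_hi) - max(dstart, end) > 0L) {
        flank_indel <- TRUE
      }
    }
    # S/H/P consume no reference
  }
  tract_bp <- (end - start) + delta
  if (tract_bp %% locus$unit_len == 0L && tract_bp >= 0L) {
    list(spanning = TRUE, units = tract_bp %/% locus$unit_len,
         off_frame = FALSE, flank_indel = flank_indel)
  } else {
    list(spanning = TRUE, units = NA_integer_, off_frame = TRUE,
         flank_indel = flank_indel)
  }
}

#' Measure all reads over one locus
#'
#' @param aln Alignment data frame (see [read_alignments()]).
#' @param locus One SSR locus row.
#' @param anchor_bp Anchor window width in bp.
#' @return Data frame with one row per overlapping read: `spanning`,
#'   `units`, `off_frame`, `flank_indel`.
#' @export
measure_reads <- function(aln, locus, anchor_bp = 10L) {
  if (is.null(aln$ref_end)) {
    aln$ref_end <- aln$pos +
      vapply(parse_cigar(aln$cigar), cigar_ref_span, 1L) - 1L
  }
  keep <- aln$rname == locus$chrom & aln$pos <= locus$end &
    aln$ref_end >= locus$start + 1L
  aln <- aln[keep, , drop = FALSE]
  n <- nrow(aln)
  if (n == 0L) {
    return(data.frame(spanning = logical(), units = integer(),
                      off_frame = logical(), flank_indel = logical()))
  }
  opsl <- parse_cigar(aln$cigar)
  spanning <- off_frame <- flank_indel <- logical(n)
  units <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    m <- measure_read_ops(aln$pos[i], opsl[[i]], locus, anchor_bp)
    spanning[i] <- m$spanning
    units[i] <- m$units
    off_frame[i] <- m$off_frame
    flank_indel[i] <- m$flank_indel
  }
  data.frame(spanning = spanning, units = units, off_frame = off_frame,
             flank_indel = flank_indel)
}

# P(k | a) under the stutter model, vectorised over k.
stutter_prob <- function(k, a, model) {
  d <- abs(k - a)
  ifelse(d == 0L, 1 - model$p_s,
         model$p_s * (1 - model$rho) * model$rho^(d - 1) / 2)
}

#' Log-likelihood of a diploid genotype given read observations
#'
#' Per read, `P(k | a1, a2) = (P(k | a1) + P(k | a2)) / 2`; the
#' log-likelihood sums over in-frame reads. Off-frame and flank-indel
#' reads must be excluded by the caller.
#'
#' @param ks Integer vector of observed repeat counts (in-frame reads).
#' @param a1,a2 Allele repeat counts.
#' @param model A [stutter_model()].
#' @return Log-likelihood (may be `-Inf` when `p_s = 0` and a read
#'   matches neither allele).
#' @export
genotype_likelihood <- function(ks, a1, a2, model = stutter_model()) {
  if (length(ks) == 0L) stop("need at least one in-frame observation")
  sum(log(0.5 * stutter_prob(ks, a1, model) +
            0.5 * stutter_prob(ks, a2, model)))
}

#' Call a diploid genotype at one locus for one accession
#'
#' Candidate alleles are the distinct in-frame observed repeat counts
#' plus the reference count; the genotype space is all unordered pairs
#' under a uniform prior. The call's quality is the posterior of the
#' maximum-a-posteriori genotype. Filters (in order): fewer spanning
#' reads than `min_spanning_reads` gives MISSING(no_reads); flank-indel
#' fraction above `max_flank_indel` gives MISSING(flank_indel); no
#' usable in-frame read gives MISSING(off_frame); stutter fraction
#' (reads discordant with both called alleles, off-frame included) above
#' `max_stutter` gives MISSING(stutter); quality below `min_call_qual`
#' gives MISSING(low_qual). Posterior ties break toward the pair
#' containing the reference allele, then lexicographically.
#'
#' @param obs A [measure_reads()] data frame for one accession at one
#'   locus.
#' @param model A [stutter_model()].
#' @param filters A [call_filters()].
#' @param ref_units Reference repeat count at the locus.
#' @return List with `a1`, `a2` (a1 <= a2, NA when missing), `quality`,
#'   `status` ("PASS"/"MISSING"), `reason` (NA when PASS).
#' @export
call_genotype <- function(obs, model = stutter_model(),
                          filters = call_filters(), ref_units) {
  miss <- function(reason) list(a1 = NA_integer_, a2 = NA_integer_,
                                quality = NA_real_, status = "MISSING",
                                reason = reason)
  sp <- obs[obs$spanning, , drop = FALSE]
  if (nrow(sp) < filters$min_spanning_reads) return(miss("no_reads"))
  if (mean(sp$flank_indel) > filters$max_flank_indel) {
    return(miss("flank_indel"))
  }
  usable <- sp[!sp$flank_indel, , drop = FALSE]
  ks <- usable$units[!usable$off_frame]
  n_off <- sum(usable$off_frame)
  if (length(ks) == 0L) return(miss("off_frame"))
  cand <- sort(unique(c(ks, ref_units)))
  # all unordered pairs (a1 <= a2)
  idx <- which(upper.tri(matrix(0, length(cand), length(cand)), diag = TRUE),
               arr.ind = TRUE)
  pairs <- cbind(a1 = cand[idx[, "row"]], a2 = cand[idx[, "col"]])
  ll <- apply(pairs, 1L, function(p) genotype_likelihood(ks, p[1L], p[2L],
                                                         model))
  mx <- max(ll)
  post <- exp(ll - mx)
  post <- post / sum(post)
  top <- which(post >= max(post) - 1e-12)
  if (length(top) > 1L) {
    has_ref <- pairs[top, "a1"] == ref_units | pairs[top, "a2"] == ref_units
    top <- top[order(-has_ref, pairs[top, "a1"], pairs[top, "a2"])]
  }
  best <- top[1L]
  a1 <- pairs[best, "a1"]
  a2 <- pairs[best, "a2"]
  stutter_frac <- (n_off + sum(ks != a1 & ks != a2)) / (n_off + length(ks))
  if (stutter_frac > filters$max_stutter) return(miss("stutter"))
  q <- post[best]
  if (q < filters$min_call_qual) return(miss("low_qual"))
  list(a1 = as.integer(min(a1, a2)), a2 = as.integer(max(a1, a2)),
       quality = q, status = "PASS", reason = NA_character_)
}

#' Genotype a panel of accessions over a set of loci
#'
#' @param alignments Named list of alignment data frames (or SAM/BAM
#'   paths), one per accession.
#' @param loci SSR locus data frame.
#' @param model A [stutter_model()].
#' @param filters A [call_filters()].
#' @param anchor_bp Anchor window width in bp.
#' @return A `genotype_matrix`: list with `calls` (long data frame:
#'   locus, accession, a1, a2, quality, status, reason), `loci` and
#'   `accessions`. Loci with no reads anywhere are present with all
#'   calls MISSING(no_reads).
#' @export
genotype_panel <- function(alignments, loci, model = stutter_model(),
                           filters = call_filters(), anchor_bp = 10L) {
  accs <- names(alignments)
  if (is.null(accs) || any(!nzchar(accs))) {
    stop("alignments must be a named list (accession ids)")
  }
  if (anyDuplicated(accs)) stop("accession id collision")
  if (anyDuplicated(loci$name)) stop("duplicate locus names")
  alignments <- lapply(alignments, function(a) {
    if (is.character(a)) read_alignments(a) else a
  })
  ncell <- length(accs) * nrow(loci)
  v_locus <- v_acc <- v_status <- v_reason <- character(ncell)
  v_a1 <- v_a2 <- integer(ncell)
  v_q <- numeric(ncell)
  n <- 0L
  for (ai in seq_along(accs)) {
    aln <- alignments[[ai]]
    if (is.null(aln$ref_end)) {
      aln$ref_end <- aln$pos +
        vapply(parse_cigar(aln$cigar), cigar_ref_span, 1L) - 1L
    }
    for (li in seq_len(nrow(loci))) {
      locus <- list(chrom = loci$chrom[li], start = loci$start[li],
                    end = loci$end[li], unit_len = loci$unit_len[li],
                    units = loci$units[li], name = loci$name[li])
      obs <- measure_reads(aln, locus, anchor_bp)
      call <- call_genotype(obs, model, filters, locus$units)
      n <- n + 1L
      v_locus[n] <- locus$name
      v_acc[n] <- accs[ai]
      v_a1[n] <- call$a1
      v_a2[n] <- call$a2
      v_q[n] <- if (is.null(call$quality)) NA_real_ else call$quality
      v_status[n] <- call$status
      v_reason[n] <- call$reason
    }
  }
  calls <- data.frame(locus = v_locus, accession = v_acc, a1 = v_a1,
                      a2 = v_a2, quality = v_q, status = v_status,
                      reason = v_reason, stringsAsFactors = FALSE)
  structure(list(calls = calls,
                 loci = loci[, intersect(c("chrom", "start", "end", "motif",
                                           "unit_len", "units", "name"),
                                         names(loci)), drop = FALSE],
                 accessions = accs),
            class = "genotype_matrix")
}
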