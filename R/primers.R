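## Deterministic primer feasibility search over locus flanks.
##
## This is a purpose-built feasibility oracle, not a thermodynamic
## primer designer: it decides, reproducibly, whether a locus admits a
## primer pair under the product-size, melting-temperature, GC and
## length constraints, and returns the best-scoring pair when one
## exists. Melting temperature uses the simple composition formula
## Tm = 64.9 + 41 (nGC - 16.4) / N, which is monotone in GC count at
## fixed length.

#' Primer design constraints
#'
#' Defaults: product size 100-400 bp, annealing temperature 60 C
#' (59-61 C), minimum GC 40%, primer length 20 nt (18-25 nt).
#'
#' @param product_size Length-2 integer vector, allowed product size.
#' @param tm_opt,tm_lo,tm_hi Optimal and allowed melting temperatures.
#' @param min_gc Minimum GC fraction.
#' @param len_opt,len_range Optimal primer length and allowed range.
#' @return A list of class `primer_constraints`.
#' @export
primer_constraints <- function(product_size = c(100L, 400L),
                               tm_opt = 60, tm_lo = 59, tm_hi = 61,
                               min_gc = 0.40,
                               len_opt = 20L, len_range = c(18L, 25L)) {
  if (tm_lo > tm_opt || tm_opt > tm_hi) stop("need tm_lo <= tm_opt <= tm_hi")
  if (product_size[1L] > product_size[2L] || len_range[1L] > len_range[2L]) {
    stop("empty product size or primer length range")
  }
  structure(list(product_size = as.integer(product_size),
                 tm_opt = tm_opt, tm_lo = tm_lo, tm_hi = tm_hi,
                 min_gc = min_gc, len_opt = as.integer(len_opt),
                 len_range = as.integer(len_range)),
            class = "primer_constraints")
}

#' GC fraction of a sequence
#'
#' @param seq Non-empty A/C/G/T string (vectorised).
#' @return Numeric fraction of G and C bases.
#' @export
gc_fraction <- function(seq) {
  if (any(!grepl("^[ACGT]+$", seq))) stop("sequence must be non-empty ACGT")
  vapply(strsplit(seq, "", fixed = TRUE),
         function(ch) mean(ch %in% c("G", "C")), 1)
}

#' Melting temperature (composition formula)
#'
#' Tm = 64.9 + 41 (nGC - 16.4) / N for a sequence of length N with nGC
#' G or C bases. Valid for lengths 10-40 nt.
#'
#' @param seq A/C/G/T string of length 10-40 nt (vectorised).
#' @return Melting temperature in degrees Celsius.
#' @export
melting_temp <- function(seq) {
  n <- nchar(seq)
  if (any(n < 10L | n > 40L)) stop("melting_temp requires length 10-40 nt")
  gc <- gc_fraction(seq) * n
  64.9 + 41 * (gc - 16.4) / n
}

#' Prepend the M13 tail to a primer
#'
#' The fixed tail CACGACGTTGTAAAACGAC is added at the 5' end of forward
#' primers for fluorescent-dye fragment genotyping.
#'
#' @param primer Non-empty primer sequence (vectorised).
#' @return Tailed primer.
#' @export
add_m13_tail <- function(primer) {
  if (any(!nzchar(primer))) stop("empty primer")
  paste0("CACGACGTTGTAAAACGAC", primer)
}

# Maximal homopolymer run length per window, from precomputed runs.
# windows: data.frame(s, e) 1-based inclusive within the flank.
window_has_homopolymer <- function(runs, s, e, min_run = 5L) {
  bad <- logical(length(s))
  if (nrow(runs) == 0L) return(bad)
  for (i in seq_len(nrow(runs))) {
    ov <- pmin(e, runs$end[i]) - pmax(s, runs$start[i]) + 1L
    bad <- bad | ov >= min_run
  }
  bad
}

homopolymer_runs <- function(chars, min_run = 5L) {
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_run
  data.frame(start = (ends - r$lengths + 1L)[keep], end = ends[keep])
}

# All admissible primer windows in one flank: returns data.frame with
# 1-based start/end (within the flank), seq (binding-site orientation),
# tm, gc, len.
candidate_windows <- function(flank, constraints) {
  L <- nchar(flank)
  lmin <- constraints$len_range[1L]
  if (L < lmin) {
    return(data.frame(s = integer(), e = integer(), len = integer(),
                      tm = numeric(), gc = numeric(), seq = character()))
  }
  chars <- strsplit(flank, "", fixed = TRUE)[[1L]]
  valid <- chars %in% DNA_BASES
  gccum <- c(0L, cumsum(chars %in% c("G", "C")))
  okcum <- c(0L, cumsum(valid))
  runs <- homopolymer_runs(chars)
  res <- list()
  for (len in seq(lmin, min(constraints$len_range[2L], L))) {
    s <- seq_len(L - len + 1L)
    e <- s + len - 1L
    ok <- (okcum[e + 1L] - okcum[s]) == len         # ACGT only
    gcn <- gccum[e + 1L] - gccum[s]
    tm <- 64.9 + 41 * (gcn - 16.4) / len
    gc <- gcn / len
    ok <- ok & gc >= constraints$min_gc &
      tm >= constraints$tm_lo & tm <= constraints$tm_hi
    if (!any(ok)) next
    ok[ok] <- !window_has_homopolymer(runs, s[ok], e[ok])
    if (!any(ok)) next
    res[[length(res) + 1L]] <- data.frame(
      s = s[ok], e = e[ok], len = len, tm = tm[ok], gc = gc[ok],
      seq = substring(flank, s[ok], e[ok]), stringsAsFactors = FALSE)
  }
  if (length(res) == 0L) {
    return(data.frame(s = integer(), e = integer(), len = integer(),
                      tm = numeric(), gc = numeric(), seq = character()))
  }
  do.call(rbind, res)
}

# 3'-terminal 4-mers complementary (reverse-complement) between partners?
three_prime_clash <- function(fwd, rev) {
  f3 <- substr(fwd, nchar(fwd) - 3L, nchar(fwd))
  r3 <- substr(rev, nchar(rev) - 3L, nchar(rev))
  r3rc <- vapply(strsplit(chartr("ACGT", "TGCA", r3), "", fixed = TRUE),
                 function(ch) paste(rev(ch), collapse = ""), "")
  f3 == r3rc
}

#' Design a primer pair for one flanked locus
#'
#' Deterministic scan: candidate forward primers are substrings of the
#' left flank ending at least 1 bp before the repeat tract; candidate
#' reverse primers are reverse complements of right-flank substrings
#' starting at least 1 bp after the tract. Candidates must satisfy the
#' Tm window, minimum GC and length range, contain no homopolymer run of
#' 5+, and the pair must not have reverse-complementary 3'-terminal
#' 4-mers. Among admissible pairs whose product (spanning the full
#' tract) lies in the product-size range, the pair minimising
#' (|Tm_f - opt| + |Tm_r - opt|, |len_f - opt| + |len_r - opt|,
#' product length) is returned.
#'
#' @param flanked One row of an [extract_flanks()] result (or a list
#'   with `left_flank`, `tract`, `right_flank`).
#' @param constraints A [primer_constraints()].
#' @return A list with `forward`, `reverse`, `product_len`,
#'   `forward_tm`, `reverse_tm`, `forward_gc`, `reverse_gc`, or `NULL`
#'   when no admissible pair exists (a "primer not designable" locus).
#' @export
design_primer_pair <- function(flanked, constraints = primer_constraints()) {
  lf <- flanked$left_flank
  rf <- flanked$right_flank
  tract_len <- nchar(flanked$tract)
  Lf <- nchar(lf)
  Rf <- nchar(rf)
  # forward primers must end at least 1 bp before the tract
  fc <- candidate_windows(lf, constraints)
  fc <- fc[fc$e <= Lf - 1L, , drop = FALSE]
  # reverse binding sites must start at least 1 bp after the tract
  rc <- candidate_windows(rf, constraints)
  rc <- rc[rc$s >= 2L, , drop = FALSE]
  if (nrow(fc) == 0L || nrow(rc) == 0L) return(NULL)
  pmin_ <- constraints$product_size[1L]
  pmax_ <- constraints$product_size[2L]
  nf <- nrow(fc)
  nr <- nrow(rc)
  f_up <- Lf - fc$s + 1L            # bp from forward 5' end to tract start
  fi <- rep(seq_len(nf), each = nr)
  ri <- rep(seq_len(nr), times = nf)
  prod <- f_up[fi] + tract_len + rc$e[ri]
  keep <- prod >= pmin_ & prod <= pmax_
  if (!any(keep)) return(NULL)
  fi <- fi[keep]; ri <- ri[keep]; prod <- prod[keep]
  key1 <- abs(fc$tm[fi] - constraints$tm_opt) +
    abs(rc$tm[ri] - constraints$tm_opt)
  key2 <- abs(fc$len[fi] - constraints$len_opt) +
    abs(rc$len[ri] - constraints$len_opt)
  # deterministic tie-break: leftmost, shortest candidates first
  o <- order(key1, key2, prod, fc$s[fi], fc$len[fi], rc$s[ri], rc$len[ri])
  for (idx in o) {
    i <- fi[idx]; j <- ri[idx]
    rev_primer <- revcomp(rc$seq[j])
    if (three_prime_clash(fc$seq[i], rev_primer)) next
    return(list(forward = fc$seq[i], reverse = rev_primer,
                product_len = as.integer(prod[idx]),
                forward_tm = fc$tm[i], reverse_tm = rc$tm[j],
                forward_gc = fc$gc[i], reverse_gc = rc$gc[j]))
  }
  NULL
}

#' Design primers for a table of flanked loci
#'
#' @param flanks An [extract_flanks()] result.
#' @param constraints A [primer_constraints()].
#' @return The input with added columns `designable`, `forward`,
#'   `reverse`, `product_len`, `forward_tm`, `reverse_tm`,
#'   `m13_forward` (NA where no pair exists).
#' @export
design_primers <- function(flanks, constraints = primer_constraints()) {
  n <- nrow(flanks)
  out <- flanks
  out$designable <- logical(n)
  out$forward <- out$reverse <- out$m13_forward <- NA_character_
  out$product_len <- NA_integer_
  out$forward_tm <- out$reverse_tm <- NA_real_
  for (i in seq_len(n)) {
    p <- design_primer_pair(flanks[i, ], constraints)
    if (!is.null(p)) {
      out$designable[i] <- TRUE
      out$forward[i] <- p$forward
      out$reverse[i] <- p$reverse
      out$product_len[i] <- p$product_len
      out$forward_tm[i] <- p$forward_tm
      out$reverse_tm[i] <- p$reverse_tm
      out$m13_forward[i] <- add_m13_tail(p$forward)
    }
  }
  out
}
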