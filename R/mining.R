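## Perfect-SSR detection and locus-level filters.
##
## Detection reports every maximal perfect tandem run of a primitive
## 2-6 bp motif meeting a per-unit-length minimum repeat count, each run
## once at its smallest primitive unit. Runs are broken at N. Mono-
## nucleotide repeats are excluded by the primitivity rule (an "AA"
## motif is a tandem of "A").

#' Mining configuration
#'
#' @param min_units Named integer vector mapping unit length (as
#'   character "2".."6") to the minimum repeat count. Defaults to 6, 5,
#'   4, 4, 4 for di- through hexanucleotide motifs.
#' @param flank_len Flank length in bp extracted around each locus.
#' @param min_gap Minimum distance in bp tolerated between adjacent loci
#'   before both are discarded.
#' @return A list of class `mining_config`.
#' @export
mining_config <- function(min_units = c(`2` = 6L, `3` = 5L, `4` = 4L,
                                        `5` = 4L, `6` = 4L),
                          flank_len = 250L, min_gap = 100L) {
  min_units <- as.integer(min_units[as.character(2:6)])
  names(min_units) <- as.character(2:6)
  if (any(is.na(min_units)) || any(min_units < 2L)) {
    stop("min_units must cover unit lengths 2..6 with values >= 2")
  }
  if (flank_len <= 0L) stop("flank_len must be positive")
  if (min_gap < 0L) stop("min_gap must be >= 0")
  structure(list(min_units = min_units, flank_len = as.integer(flank_len),
                 min_gap = as.integer(min_gap)),
            class = "mining_config")
}

#' Is a motif primitive?
#'
#' A motif is primitive when it is not itself a tandem repetition of a
#' shorter word; only primitive motifs define SSR loci, so an (AT)x6 run
#' is never double-reported as (ATAT)x3.
#'
#' @param motif Character vector of motifs (1-6 bp, A/C/G/T only).
#' @return Logical vector.
#' @export
is_primitive <- function(motif) {
  if (any(!grepl("^[ACGT]{1,6}$", motif))) {
    stop("motif must be 1-6 bp over A, C, G, T")
  }
  vapply(motif, function(m) {
    n <- nchar(m)
    for (d in seq_len(n - 1L)) {
      if (n %% d == 0L && strrep(substr(m, 1L, d), n %/% d) == m) return(FALSE)
    }
    TRUE
  }, logical(1L), USE.NAMES = FALSE)
}

#' Name an SSR locus
#'
#' The locus name is `{chrom}_{unit_len}_{start1}` where `start1` is the
#' 1-based start position of the repeat tract.
#'
#' @param chrom Chromosome name.
#' @param unit_len Motif length.
#' @param start 0-based tract start.
#' @return Character vector of names.
#' @export
name_locus <- function(chrom, unit_len, start) {
  paste(chrom, unit_len, start + 1L, sep = "_")
}

empty_loci <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             motif = character(), unit_len = integer(), units = integer(),
             name = character(), stringsAsFactors = FALSE)
}

#' Find perfect SSR loci in one sequence
#'
#' Scans a chromosome for maximal perfect tandem repeats of primitive
#' di- to hexanucleotide motifs meeting the configured minimum repeat
#' counts. Runs containing N are broken at the N. A run representable at
#' several unit lengths is reported once, at its smallest primitive
#' unit. In the rare event that two qualifying runs at different unit
#' lengths share bases, the locus starting earlier (then the smaller
#' unit) wins, so reported loci never overlap.
#'
#' @param seq Uppercase nucleotide string.
#' @param chrom Chromosome name used for coordinates and locus names.
#' @param config A [mining_config()].
#' @return Data frame with columns `chrom`, `start` (0-based), `end`
#'   (exclusive), `motif` (as it appears on the forward strand at the
#'   run start), `unit_len`, `units`, `name`, sorted by `start`.
#' @export
find_ssrs <- function(seq, chrom, config = mining_config()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  L <- nchar(seq)
  if (L < 4L) return(empty_loci())
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ok <- chars %in% DNA_BASES
  out <- list()
  for (k in 2:6) {
    minu <- config$min_units[[as.character(k)]]
    if (L < k * minu) next
    n <- L - k
    eq <- chars[seq_len(n)] == chars[(k + 1L):L]
    eq <- eq & ok[seq_len(n)] & ok[(k + 1L):L]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & (r$lengths + k) %/% k >= minu)
    for (h in hit) {
      i <- starts[h]                       # 1-based run start
      units <- (r$lengths[h] + k) %/% k
      motif <- substr(seq, i, i + k - 1L)
      if (!is_primitive(motif)) next
      out[[length(out) + 1L]] <- list(start = i - 1L, k = k, units = units,
                                      motif = motif)
    }
  }
  if (length(out) == 0L) return(empty_loci())
  df <- data.frame(
    chrom = chrom,
    start = vapply(out, `[[`, 1L, "start"),
    unit_len = vapply(out, `[[`, 1L, "k"),
    units = vapply(out, `[[`, 1L, "units"),
    motif = vapply(out, `[[`, "", "motif"),
    stringsAsFactors = FALSE)
  df$end <- df$start + df$unit_len * df$units
  df <- df[order(df$start, df$unit_len), , drop = FALSE]
  # drop loci overlapping an earlier-kept one (earlier start, smaller unit win)
  if (nrow(df) > 1L) {
    keep <- logical(nrow(df))
    last_end <- -1L
    for (i in seq_len(nrow(df))) {
      if (df$start[i] >= last_end) {
        keep[i] <- TRUE
        last_end <- df$end[i]
      }
    }
    df <- df[keep, , drop = FALSE]
  }
  df$name <- name_locus(df$chrom, df$unit_len, df$start)
  rownames(df) <- NULL
  df[, c("chrom", "start", "end", "motif", "unit_len", "units", "name")]
}

#' Mine SSRs across a genome
#'
#' @param genome Named character vector of chromosome sequences (as from
#'   [read_fasta()]).
#' @param config A [mining_config()].
#' @return Combined locus data frame, ordered by chromosome then start.
#' @export
mine_genome <- function(genome, config = mining_config()) {
  res <- lapply(names(genome), function(ch) find_ssrs(genome[[ch]], ch, config))
  df <- do.call(rbind, c(res, list(empty_loci())))
  rownames(df) <- NULL
  df
}

#' Remove loci whose motif contains only A and T
#'
#' @param loci Locus data frame.
#' @return List with elements `kept` and `removed`; their union is the
#'   input and input order is preserved within each.
#' @export
filter_at_only <- function(loci) {
  at_only <- !grepl("[CG]", loci$motif)
  list(kept = loci[!at_only, , drop = FALSE],
       removed = loci[at_only, , drop = FALSE])
}

#' Remove pairs of loci lying closer than a minimum gap
#'
#' For every pair of same-chromosome adjacent loci separated by fewer
#' than `min_gap` bp, both members are removed. Proximity is evaluated
#' on the original list, so any locus with at least one close neighbour
#' is discarded.
#'
#' @param loci Locus data frame sorted by (chrom, start), non-overlapping.
#' @param min_gap Minimum tolerated gap in bp (next start minus previous
#'   end).
#' @return List with elements `kept` and `removed`.
#' @export
filter_proximal <- function(loci, min_gap = 100L) {
  if (nrow(loci) < 2L) return(list(kept = loci, removed = loci[0, , drop = FALSE]))
  o <- order(loci$chrom, loci$start)
  loci <- loci[o, , drop = FALSE]
  same <- loci$chrom[-1L] == loci$chrom[-nrow(loci)]
  gap <- loci$start[-1L] - loci$end[-nrow(loci)]
  if (any(same & gap < 0L)) stop("overlapping loci supplied to filter_proximal")
  close <- same & gap < min_gap
  drop <- logical(nrow(loci))
  drop[which(close)] <- TRUE
  drop[which(close) + 1L] <- TRUE
  list(kept = loci[!drop, , drop = FALSE],
       removed = loci[drop, , drop = FALSE])
}

#' Extract flanking sequence around loci
#'
#' @param loci Locus data frame.
#' @param genome Named character vector of chromosome sequences.
#' @param flank_len Flank length in bp; flanks are clipped at chromosome
#'   ends and flagged `truncated`.
#' @return Data frame: locus columns plus `left_flank`, `tract`,
#'   `right_flank`, `truncated`.
#' @export
extract_flanks <- function(loci, genome, flank_len = 250L) {
  if (nrow(loci) == 0L) {
    out <- loci
    out$left_flank <- character()
    out$tract <- character()
    out$right_flank <- character()
    out$truncated <- logical()
    return(out)
  }
  clen <- nchar(genome)[loci$chrom]
  if (any(is.na(clen)) || any(loci$end > clen)) {
    stop("locus beyond chromosome end")
  }
  ls <- pmax(loci$start - flank_len, 0L)
  re <- pmin(loci$end + flank_len, clen)
  seqs <- genome[loci$chrom]
  out <- loci
  out$left_flank <- substr(seqs, ls + 1L, loci$start)
  out$tract <- substr(seqs, loci$start + 1L, loci$end)
  out$right_flank <- substr(seqs, loci$end + 1L, re)
  out$truncated <- nchar(out$left_flank) < flank_len |
    nchar(out$right_flank) < flank_len
  rownames(out) <- NULL
  out
}

#' Summarise a mining run
#'
#' Per-chromosome locus counts and densities (loci/Mb, one decimal) and
#' per-unit-length counts with percentage shares (two decimals), plus
#' genome totals and the overall density.
#'
#' @param loci Locus data frame.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @return List of class `mining_summary` with elements `per_chrom`,
#'   `per_unit`, `total`, `total_bp`, `density`.
#' @export
summarize_ssrs <- function(loci, chrom_lengths) {
  if (any(chrom_lengths <= 0)) stop("zero-length chromosome")
  if (nrow(loci) && !all(loci$chrom %in% names(chrom_lengths))) {
    stop("locus on a chromosome absent from chrom_lengths")
  }
  cnt <- table(factor(loci$chrom, levels = names(chrom_lengths)))
  per_chrom <- data.frame(
    chrom = names(chrom_lengths),
    length_bp = as.numeric(chrom_lengths),
    n_ssr = as.integer(cnt),
    stringsAsFactors = FALSE)
  per_chrom$density <- round(ssr_density(per_chrom$n_ssr, per_chrom$length_bp), 1)
  ucnt <- table(factor(loci$unit_len, levels = 2:6))
  per_unit <- data.frame(
    unit_len = 2:6,
    n_ssr = as.integer(ucnt),
    stringsAsFactors = FALSE)
  per_unit$pct <- if (nrow(loci)) round(per_unit$n_ssr / nrow(loci) * 100, 2)
  else rep(0, 5L)
  structure(list(per_chrom = per_chrom, per_unit = per_unit,
                 total = nrow(loci), total_bp = sum(chrom_lengths),
                 density = round(ssr_density(nrow(loci), sum(chrom_lengths)), 1)),
            class = "mining_summary")
}

#' SSR density in loci per megabase
#'
#' @param count Number of loci.
#' @param length_bp Sequence length in bp.
#' @return Numeric density (loci/Mb), unrounded.
#' @export
ssr_density <- function(count, length_bp) {
  if (any(length_bp <= 0)) stop("zero-length sequence")
  count / (length_bp / 1e6)
}
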