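# Independent oracles and small fixture builders shared across tests.

# Primitivity oracle: a word is primitive iff all its rotations are
# distinct (independent of the divisor check used in the package).
oracle_primitive <- function(m) {
  n <- nchar(m)
  rots <- vapply(seq_len(n), function(i) {
    paste0(substr(m, i, n), substr(m, 1, i - 1))
  }, "")
  length(unique(rots)) == n
}

# Brute-force SSR scanner: tests every (position, unit length) pair.
# For each start j and unit length k it counts the consecutive
# period-k matches from j (next-false lookup), keeps left-maximal runs
# (no single-character periodic extension), requires a primitive
# ACGT motif and the minimum repeat count, then applies the same
# no-overlap resolution rule as the package (earlier start, then
# smaller unit length, wins).
oracle_find_ssrs <- function(seq, chrom, config = mining_config()) {
  L <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  valid <- chars %in% c("A", "C", "G", "T")
  res <- list()
  for (k in 2:6) {
    minu <- config$min_units[[as.character(k)]]
    if (L < k * minu) next
    n <- L - k
    eq <- chars[seq_len(n)] == chars[(k + 1):L] &
      valid[seq_len(n)] & valid[(k + 1):L]
    false_pos <- c(which(!eq), n + 1L)
    starts <- which(eq & !c(FALSE, eq[-n]))     # left-maximal TRUE positions
    for (j in starts) {
      nf <- false_pos[findInterval(j - 1L, false_pos) + 1L]
      units <- ((nf - j) + k) %/% k
      if (units < minu) next
      motif <- substr(seq, j, j + k - 1L)
      if (!oracle_primitive(motif)) next
      res[[length(res) + 1L]] <- data.frame(
        chrom = chrom, start = j - 1L, end = j - 1L + units * k,
        motif = motif, unit_len = k, units = units,
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), motif = character(),
                      unit_len = integer(), units = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, res)
  df <- df[order(df$start, df$unit_len), , drop = FALSE]
  keep <- logical(nrow(df))
  last_end <- -1L
  for (i in seq_len(nrow(df))) {
    if (df$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- df$end[i]
    }
  }
  rownames(df) <- NULL
  df[keep, , drop = FALSE]
}

# Exhaustive MAP genotype oracle: enumerates all unordered candidate
# pairs, computes the likelihood read by read from the stutter
# probability written out longhand, and returns the posterior-maximal
# pair with the package's tie-break (reference-containing pair first,
# then lexicographic).
oracle_map_genotype <- function(ks, ref_units, p_s = 0.05, rho = 0.8) {
  pk <- function(k, a) {
    if (k == a) 1 - p_s else p_s * (1 - rho) * rho^(abs(k - a) - 1) / 2
  }
  cand <- sort(unique(c(ks, ref_units)))
  best <- NULL
  best_ll <- -Inf
  for (i in seq_along(cand)) {
    for (j in i:length(cand)) {
      a1 <- cand[i]; a2 <- cand[j]
      ll <- 0
      for (k in ks) ll <- ll + log(0.5 * pk(k, a1) + 0.5 * pk(k, a2))
      better <- ll > best_ll + 1e-12
      tie <- abs(ll - best_ll) <= 1e-12
      if (tie && !is.null(best)) {
        new_ref <- a1 == ref_units || a2 == ref_units
        old_ref <- best[1] == ref_units || best[2] == ref_units
        better <- (new_ref && !old_ref) ||
          (new_ref == old_ref &&
             (a1 < best[1] || (a1 == best[1] && a2 < best[2])))
      }
      if (better) {
        best <- c(a1, a2)
        best_ll <- ll
      }
    }
  }
  best
}

# Report-style rounding (half up, 2 decimals) used to compare computed
# means with printed table values.
round_half_up_test <- function(x) floor(x * 100 + 0.5) / 100

# Observation table builder for call_genotype tests.
make_obs <- function(units, flank_indel = rep(FALSE, length(units)),
                     off_frame = is.na(units),
                     spanning = rep(TRUE, length(units))) {
  data.frame(spanning = spanning, units = as.integer(units),
             off_frame = off_frame, flank_indel = flank_indel)
}

# Random valid SSR BED record table.
random_bed_records <- function(n) {
  unit_len <- sample(2:6, n, replace = TRUE)
  ref_units <- sample(4:12, n, replace = TRUE)
  start <- sample.int(1e6, n)
  data.frame(chrom = sample(sprintf("chr%02d", 1:4), n, replace = TRUE),
             start = start, end = start + unit_len * ref_units,
             unit_len = unit_len, ref_units = ref_units,
             name = sprintf("L%04d", seq_len(n)),
             stringsAsFactors = FALSE)
}

# Small shared simulation (cached per session) for pipeline-level tests.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_chrom = 2, chrom_len = 30000, n_loci = 8,
                        n_accessions = 8, depth = 25, seed = 314)
      truth <- simulate_reference(cfg)
      panel <- simulate_panel(truth)
      reads <- simulate_reads(truth, panel)
      cache <<- list(cfg = cfg, truth = truth, panel = panel, reads = reads)
    }
    cache
  }
})
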