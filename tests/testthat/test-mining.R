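test_that("is_primitive agrees with the rotation oracle on all motifs up to 6 bp", {
  motifs <- unlist(lapply(1:6, function(k) {
    apply(expand.grid(rep(list(c("A", "C", "G", "T")), k)), 1, paste,
          collapse = "")
  }))
  expect_identical(is_primitive(motifs),
                   vapply(motifs, oracle_primitive, logical(1),
                          USE.NAMES = FALSE))
  expect_error(is_primitive("ATN"), "A, C, G, T")
})

test_that("find_ssrs detects a planted (ATG)6 run exactly once", {
  seq <- paste0("CCGTT", strrep("ATG", 6), "GGACC")
  loci <- find_ssrs(seq, "chr1")
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$motif, "ATG")
  expect_identical(loci$units, 6L)
  expect_identical(loci$unit_len, 3L)
  expect_identical(loci$start, 5L)
  expect_identical(loci$end, 23L)
})

test_that("runs containing N are broken and short runs are dropped", {
  expect_identical(nrow(find_ssrs(strrep("ACGTN", 50), "chr1")), 0L)
  # an N in the middle of an otherwise qualifying run splits it below threshold
  seq <- paste0(strrep("AG", 4), "N", strrep("AG", 4))
  expect_identical(nrow(find_ssrs(seq, "chr1")), 0L)
})

test_that("find_ssrs equals the brute-force scanner on random sequences", {
  set.seed(2024)
  for (i in 1:30) {
    # enriched background so qualifying runs actually occur
    seq <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE,
                        prob = c(0.35, 0.15, 0.15, 0.35)), collapse = "")
    ins <- sample(c("AG", "ATC", "TTGT", "ATGCC"), 4, replace = TRUE)
    for (m in ins) {
      at <- sample(2500, 1)
      substr(seq, at, at + nchar(m) * 7 - 1) <- strrep(m, 7)
    }
    got <- find_ssrs(seq, "c")
    want <- oracle_find_ssrs(seq, "c")
    expect_identical(got[, c("start", "end", "motif", "unit_len", "units")],
                     want[, c("start", "end", "motif", "unit_len", "units")])
  }
})

test_that("reported loci are primitive, non-overlapping and named uniquely", {
  truth <- shared_sim()$truth
  mined <- mine_genome(truth$genome)
  expect_true(all(is_primitive(mined$motif)))
  expect_false(anyDuplicated(mined$name) > 0)
  by_chrom <- split(mined, mined$chrom)
  for (b in by_chrom) {
    b <- b[order(b$start), ]
    if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
})

test_that("A/T-only filter partitions loci by motif alphabet", {
  loci <- data.frame(chrom = "c", start = c(0, 100, 200), motif = c("AT", "AG", "AAT"),
                     unit_len = c(2L, 2L, 3L), units = c(6L, 6L, 5L))
  loci$end <- loci$start + loci$unit_len * loci$units
  loci$name <- name_locus(loci$chrom, loci$unit_len, loci$start)
  r <- filter_at_only(loci)
  expect_identical(r$removed$motif, c("AT", "AAT"))
  expect_identical(r$kept$motif, "AG")
  expect_identical(nrow(r$kept) + nrow(r$removed), nrow(loci))

  set.seed(5)
  truth <- shared_sim()$truth
  mined <- mine_genome(truth$genome)
  r2 <- filter_at_only(mined)
  expect_identical(nrow(r2$removed), sum(!grepl("[CG]", mined$motif)))
})

test_that("proximity filter removes both members of every close pair", {
  mk <- function(starts, ends, chrom = "c") {
    data.frame(chrom = chrom, start = starts, end = ends,
               motif = "AG", unit_len = 2L, units = (ends - starts) / 2,
               name = paste0("L", seq_along(starts)))
  }
  # 50 bp gap: both removed
  r <- filter_proximal(mk(c(0, 70), c(20, 90)), 100)
  expect_identical(nrow(r$kept), 0L)
  # 150 bp gap: both kept
  r <- filter_proximal(mk(c(0, 170), c(20, 190)), 100)
  expect_identical(nrow(r$kept), 2L)
  # chain with gaps 50, 500: first two removed, third kept
  r <- filter_proximal(mk(c(0, 70, 590), c(20, 90, 610)), 100)
  expect_identical(r$kept$name, "L3")
  expect_identical(sort(r$removed$name), c("L1", "L2"))
  # exact threshold gap is kept (rule is strictly less than)
  r <- filter_proximal(mk(c(0, 120), c(20, 140)), 100)
  expect_identical(nrow(r$kept), 2L)
  # different chromosomes never interact
  r <- filter_proximal(mk(c(0, 30), c(20, 50), chrom = c("c1", "c2")), 100)
  expect_identical(nrow(r$kept), 2L)
  expect_error(filter_proximal(mk(c(0, 10), c(20, 30)), 100), "overlap")
})

test_that("flank extraction returns exact reference substrings, clipped at ends", {
  genome <- c(chr1 = paste(rep(c("A", "C", "G", "T"), 250), collapse = ""))
  loci <- data.frame(chrom = "chr1", start = c(10L, 500L), end = c(30L, 520L),
                     motif = "AC", unit_len = 2L, units = 10L,
                     name = c("a", "b"))
  fl <- extract_flanks(loci, genome, 250)
  expect_identical(nchar(fl$left_flank), c(10L, 250L))
  expect_identical(fl$truncated, c(TRUE, FALSE))
  whole <- paste0(fl$left_flank, fl$tract, fl$right_flank)
  ls <- pmax(loci$start - 250, 0)
  re <- pmin(loci$end + 250, nchar(genome))
  expect_identical(whole, unname(substr(rep(genome, 2), ls + 1, re)))
  bad <- loci
  bad$end[2] <- 2000L
  expect_error(extract_flanks(bad, genome, 250), "beyond")
})

test_that("locus names use the 1-based start convention", {
  expect_identical(name_locus("chr03", 3L, 9824682L), "chr03_3_9824683")
  expect_identical(name_locus("chr01", 6L, 0L), "chr01_6_1")
})

test_that("mining summary reproduces density and share arithmetic", {
  loci <- data.frame(chrom = rep("Chr01", 5200), start = 1,
                     unit_len = rep(c(2L, 3L), c(2600, 2600)))
  s <- summarize_ssrs(loci, c(Chr01 = 50662332))
  expect_identical(s$per_chrom$density, 102.6)
  expect_identical(s$per_unit$pct[1:2], c(50, 50))
  s0 <- summarize_ssrs(loci[0, ], c(Chr01 = 50662332))
  expect_identical(s0$per_chrom$density, 0)
  expect_error(summarize_ssrs(loci, c(Chr01 = 0)), "zero-length")

  truth <- shared_sim()$truth
  mined <- mine_genome(truth$genome)
  s2 <- summarize_ssrs(mined, nchar(truth$genome))
  expect_identical(sum(s2$per_chrom$n_ssr), nrow(truth$loci))
  expect_identical(as.integer(table(factor(truth$loci$unit_len, levels = 2:6))),
                   s2$per_unit$n_ssr)
})
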