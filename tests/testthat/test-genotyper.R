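# A locus used across read-measurement cases: (ATG)6 at [100, 118).
fix_locus <- list(chrom = "chr1", start = 100L, end = 118L,
                  motif = "ATG", unit_len = 3L, units = 6L,
                  name = "chr1_3_101")

test_that("measure_read counts tract units from CIGAR arithmetic", {
  # perfect match spanning tract + anchors
  m <- measure_read(list(pos = 81L, cigar = "60M"), fix_locus)
  expect_true(m$spanning)
  expect_identical(m$units, 6L)
  # 6 bp insertion inside the tract: 18 + 6 = 24 = 3 x 8
  m <- measure_read(list(pos = 81L, cigar = "28M6I26M"), fix_locus)
  expect_identical(m$units, 8L)
  expect_false(m$flank_indel)
  # 2 bp deletion inside the tract: 16 bp not divisible by 3
  m <- measure_read(list(pos = 81L, cigar = "28M2D26M"), fix_locus)
  expect_true(m$off_frame)
  expect_true(is.na(m$units))
  # read starting 3 bp after (start - anchor) is not spanning
  m <- measure_read(list(pos = 94L, cigar = "60M"), fix_locus)
  expect_false(m$spanning)
  # indel in the anchor window flags flank_indel
  m <- measure_read(list(pos = 81L, cigar = "15M2I45M"), fix_locus)
  expect_true(m$flank_indel)
  expect_identical(m$units, 6L)
  expect_error(measure_read(list(pos = 500L, cigar = "60M"), fix_locus),
               "overlap")
})

test_that("genotype likelihood follows the stutter closed forms", {
  mod <- stutter_model(0.05, 0.8)
  expect_equal(genotype_likelihood(rep(6L, 10), 6, 6, mod), 10 * log(0.95))
  # heterozygote beats homozygote on a balanced read split
  ks <- c(6L, 6L, 8L, 8L)
  expect_gt(genotype_likelihood(ks, 6, 8, mod),
            genotype_likelihood(ks, 6, 6, mod))
  # stutter mass sums to one over all unit shifts (geometric series)
  shifts <- 1:200
  mass <- (1 - mod$p_s) +
    2 * sum(mod$p_s * (1 - mod$rho) * mod$rho^(shifts - 1) / 2)
  expect_equal(mass, 1, tolerance = 1e-12)
  # symmetry in allele order
  expect_identical(genotype_likelihood(ks, 6, 8, mod),
                   genotype_likelihood(ks, 8, 6, mod))
})

test_that("call_genotype returns calibrated calls and reasoned missingness", {
  mod <- stutter_model()
  flt <- call_filters()
  # unanimous reads give a confident homozygote
  call <- call_genotype(make_obs(rep(6L, 20)), mod, flt, ref_units = 6L)
  expect_identical(call$status, "PASS")
  expect_identical(c(call$a1, call$a2), c(6L, 6L))
  expect_gt(call$quality, 0.99)
  # balanced split gives the heterozygote
  call <- call_genotype(make_obs(rep(c(6L, 8L), each = 10)), mod, flt, 6L)
  expect_identical(c(call$a1, call$a2), c(6L, 8L))
  expect_identical(call$status, "PASS")
  # flank-indel fraction 0.25 > 0.15
  call <- call_genotype(make_obs(rep(6L, 20),
                                 flank_indel = rep(c(TRUE, FALSE), c(5, 15))),
                        mod, flt, 6L)
  expect_identical(call$reason, "flank_indel")
  # too few spanning reads
  call <- call_genotype(make_obs(rep(6L, 3)), mod, flt, 6L)
  expect_identical(call$reason, "no_reads")
  # heavy stutter-discordant reads
  call <- call_genotype(make_obs(c(rep(6L, 16), 5L, 7L, 9L, 10L)), mod, flt, 6L)
  expect_identical(call$reason, "stutter")
  # posterior over the genotype space sums to 1
  obs <- make_obs(c(6L, 6L, 7L, 8L, 8L, 9L))
  ks <- obs$units
  cand <- sort(unique(c(ks, 6L)))
  tot <- 0
  for (i in seq_along(cand)) for (j in i:length(cand)) {
    tot <- tot + exp(genotype_likelihood(ks, cand[i], cand[j], mod))
  }
  call <- call_genotype(obs, mod, call_filters(min_call_qual = 0,
                                               max_stutter = 1), 6L)
  best <- exp(genotype_likelihood(ks, call$a1, call$a2, mod))
  expect_equal(call$quality, best / tot, tolerance = 1e-9)
})

test_that("MAP call equals exhaustive enumeration on random read sets", {
  set.seed(31)
  mod <- stutter_model()
  loose <- call_filters(min_call_qual = 0, max_stutter = 1,
                        min_spanning_reads = 1)
  for (rep in 1:200) {
    truth_a <- sample(4:12, 2, replace = TRUE)
    n <- sample(5:25, 1)
    ks <- sample(truth_a, n, replace = TRUE)
    stut <- runif(n) < 0.1
    ks[stut] <- pmax(1L, ks[stut] + sample(c(-2L, -1L, 1L, 2L),
                                           sum(stut), replace = TRUE))
    ref <- sample(4:12, 1)
    call <- call_genotype(make_obs(ks), mod, loose, ref)
    want <- oracle_map_genotype(ks, ref, mod$p_s, mod$rho)
    expect_identical(c(call$a1, call$a2), as.integer(want))
  }
})

test_that("clean simulated panel is recovered exactly; empty input is all missing", {
  cfg <- sim_config(n_chrom = 1, chrom_len = 20000, n_loci = 5,
                    n_accessions = 4, depth = 25, p_s = 0, sub_rate = 0,
                    seed = 55)
  truth <- simulate_reference(cfg)
  panel <- simulate_panel(truth)
  reads <- simulate_reads(truth, panel)
  gm <- genotype_panel(reads, truth$loci)
  expect_true(all(gm$calls$status == "PASS"))
  m <- match(paste(gm$calls$locus, gm$calls$accession),
             paste(panel$genotypes$locus, panel$genotypes$accession))
  expect_identical(gm$calls$a1, panel$genotypes$a1[m])
  expect_identical(gm$calls$a2, panel$genotypes$a2[m])

  empty <- reads[[1]][0, ]
  gm2 <- genotype_panel(list(accA = empty), truth$loci)
  expect_true(all(gm2$calls$status == "MISSING"))
  expect_true(all(gm2$calls$reason == "no_reads"))

  expect_error(genotype_panel(setNames(reads[1:2], c("a", "a")),
                              truth$loci), "collision")
})

test_that("concordance degrades monotonely as stutter increases", {
  base <- sim_config(n_chrom = 1, chrom_len = 20000, n_loci = 5,
                     n_accessions = 5, depth = 30, sub_rate = 0, seed = 202)
  conc <- vapply(c(0, 0.1, 0.3), function(ps) {
    cfg <- base
    cfg$p_s <- ps
    truth <- simulate_reference(cfg)
    panel <- simulate_panel(truth)
    reads <- simulate_reads(truth, panel, cfg)
    gm <- genotype_panel(reads, truth$loci)
    m <- match(paste(gm$calls$locus, gm$calls$accession),
               paste(panel$genotypes$locus, panel$genotypes$accession))
    # whole-panel truth concordance: missing cells count as discordant
    mean(gm$calls$status == "PASS" &
           gm$calls$a1 == panel$genotypes$a1[m] &
           gm$calls$a2 == panel$genotypes$a2[m], na.rm = FALSE)
  }, 1)
  conc[is.na(conc)] <- 0
  expect_true(all(diff(conc) <= 1e-9))
})
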