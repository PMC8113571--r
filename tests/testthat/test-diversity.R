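test_that("binary scoring encodes allele presence per accession", {
  calls <- data.frame(
    locus = "L1",
    accession = c("a1", "a2", "a3"),
    a1 = c(6L, 6L, NA), a2 = c(8L, 6L, NA),
    quality = c(0.99, 0.99, NA),
    status = c("PASS", "PASS", "MISSING"),
    reason = c(NA, NA, "no_reads"), stringsAsFactors = FALSE)
  loci <- data.frame(name = "L1", units = 6L)
  gm <- structure(list(calls = calls, loci = loci,
                       accessions = c("a1", "a2", "a3")),
                  class = "genotype_matrix")
  b <- genotypes_to_binary(gm)
  expect_identical(colnames(b), c("L1:6", "L1:8"))
  expect_identical(unname(b["a1", ]), c(1, 1))     # het 6/8
  expect_identical(unname(b["a2", ]), c(1, 0))     # hom 6/6
  expect_true(all(is.na(b["a3", ])))               # missing, not zero
})

test_that("simulated panel yields one binary column per true allele", {
  s <- shared_sim()
  gm <- genotype_panel(s$reads, s$truth$loci)
  b <- suppressWarnings(genotypes_to_binary(gm))
  col_loci <- attr(b, "loci")
  calls <- gm$calls[gm$calls$status == "PASS", ]
  for (nm in unique(col_loci)) {
    cc <- calls[calls$locus == nm, ]
    expect_identical(sum(col_loci == nm),
                     length(unique(c(cc$a1, cc$a2))))
  }
})

test_that("allele frequencies are band shares and normalise", {
  m <- rbind(c(1, 0), c(1, 0), c(0, 1), c(1, 1))
  p <- allele_frequencies(m)
  expect_equal(unname(p), c(0.6, 0.4))
  expect_equal(sum(p), 1)
  m2 <- matrix(c(rep(1, 30), rep(0, 30), rep(0, 10), rep(1, 10)), ncol = 2)
  expect_equal(unname(allele_frequencies(m2)), c(0.75, 0.25))
  expect_error(allele_frequencies(matrix(0, 3, 2)), "all-zero")
  set.seed(8)
  for (r in 1:25) {
    m3 <- matrix(rbinom(40, 1, 0.4), ncol = 4)
    if (all(colSums(m3) > 0)) expect_equal(sum(allele_frequencies(m3)), 1)
  }
})

test_that("He and PIC follow their closed forms and ordering", {
  expect_equal(expected_heterozygosity(c(0.5, 0.5)), 0.5)
  expect_equal(expected_heterozygosity(1), 0)
  for (k in 2:6) {
    expect_equal(expected_heterozygosity(rep(1 / k, k)), 1 - 1 / k)
  }
  expect_equal(pic(c(0.5, 0.5)), 1 - 0.5 - 2 * 0.25 * 0.25)
  expect_equal(pic(1), 0)
  expect_error(pic(c(0.5, 0.4)), "sum to 1")
  expect_error(expected_heterozygosity(c(0.7, 0.4)), "sum to 1")
  # 0 <= PIC <= He < 1 on random simplex draws; equality iff monomorphic
  set.seed(16)
  for (r in 1:10000) {
    k <- sample(1:6, 1)
    p <- rexp(k)
    p <- p / sum(p)
    he <- expected_heterozygosity(p)
    pc <- pic(p)
    expect_true(pc >= -1e-12 && pc <= he + 1e-12 && he < 1)
    if (k == 1) expect_equal(pc, he)
  }
  # invariance to allele relabeling
  p <- c(0.5, 0.3, 0.2)
  expect_equal(expected_heterozygosity(p), expected_heterozygosity(rev(p)))
  expect_equal(pic(p), pic(rev(p)))
})

test_that("marker stats table gives per-locus Na/He/PIC plus means", {
  m <- cbind("L1:6" = c(1, 1, 0, 1), "L1:8" = c(0, 1, 1, 0),
             "L2:4" = c(1, 1, 1, 1))
  st <- marker_stats_table(m)
  expect_identical(st$per_locus$na, c(2L, 1L))
  expect_equal(st$per_locus$he[2], 0)
  expect_equal(st$per_locus$pic[2], 0)
  p1 <- allele_frequencies(m[, 1:2])
  expect_equal(st$per_locus$he[1], expected_heterozygosity(p1))
  expect_identical(st$report$locus[3], "Mean")
  # single monomorphic locus: means are (1, 0, 0)
  st2 <- marker_stats_table(cbind("L9:5" = c(1, 1, 1)))
  expect_equal(unname(st2$means), c(1, 0, 0))
})

test_that("validation-marker panel means reproduce the printed summary", {
  tab <- spinach_ssr_tables("validation_markers")
  amplified <- tab[!is.na(tab$he), ]
  expect_identical(nrow(tab), 36L)
  expect_identical(nrow(amplified), 34L)
  expect_equal(round_half_up_test(mean(amplified$he)), 0.40)
  expect_equal(round_half_up_test(mean(amplified$pic)), 0.25)
})

test_that("PCA separates constructed clusters and satisfies SVD identities", {
  m <- rbind(matrix(rep(c(1, 0), each = 12), nrow = 4, ncol = 6, byrow = FALSE),
             matrix(rep(c(0, 1), each = 12), nrow = 4, ncol = 6, byrow = FALSE))
  m <- cbind(m[, 1:3], 1 - m[, 4:6])
  rownames(m) <- paste0("s", 1:8)
  colnames(m) <- paste0("L", 1:6, ":1")
  res <- pca_binary(m)
  expect_gt(res$var_explained[1], 0.999)
  expect_true(all(sign(res$coords[1:4, 1]) != sign(res$coords[5:8, 1])))
  expect_equal(sum(res$var_explained), 1)
  expect_true(all(diff(res$var_explained) <= 1e-12))
  # duplicated accessions coincide in PC space
  m2 <- rbind(m, s9 = m[1, ])
  res2 <- pca_binary(m2)
  expect_equal(unname(res2$coords["s9", ]), unname(res2$coords["s1", ]))
  expect_error(pca_binary(matrix(1, 3, 3)), "constant")
})

test_that("Jaccard distances behave like a metric on binary profiles", {
  m <- rbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0), c = c(0, 0, 1, 1))
  d <- distance_matrix(m)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  set.seed(23)
  for (r in 1:20) {
    m2 <- matrix(rbinom(60, 1, 0.5), nrow = 6)
    rownames(m2) <- paste0("x", 1:6)
    d2 <- distance_matrix(m2)
    for (i in 1:6) for (j in 1:6) for (k in 1:6) {
      expect_lte(d2[i, j], d2[i, k] + d2[k, j] + 1e-12)
    }
  }
})

test_that("NJ recovers additive trees exactly and errors below 3 taxa", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  D <- ape::cophenetic.phylo(tr)
  res <- nj_tree(D)
  expect_setequal(res$tree$tip.label, c("A", "B", "C", "D"))
  back <- ape::cophenetic.phylo(res$tree)
  expect_equal(back[rownames(D), colnames(D)], D, tolerance = 1e-9)
  expect_false(res$clamped)
  # 3 taxa: closed-form star branch lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  res3 <- nj_tree(D3)
  b3 <- ape::cophenetic.phylo(res3$tree)
  expect_equal(b3[rownames(D3), colnames(D3)], D3, tolerance = 1e-9)
  expect_error(nj_tree(D3[1:2, 1:2]), "at least 3")
  # leaf set preserved under perturbation, negative lengths clamped
  set.seed(9)
  P <- D + matrix(runif(16, 0, 0.2), 4)
  P <- (P + t(P)) / 2
  diag(P) <- 0
  dimnames(P) <- dimnames(D)
  resP <- nj_tree(P)
  expect_setequal(resP$tree$tip.label, rownames(P))
  expect_true(all(resP$tree$edge.length >= 0))
})

test_that("STRUCTURE export writes one row per accession with -9 missing", {
  m <- rbind(a = c(1, NA, 0), b = c(0, 1, 1))
  colnames(m) <- c("L1:6", "L1:7", "L2:4")
  f <- withr::local_tempfile()
  export_structure(m, f)
  lines <- readLines(f)
  expect_identical(length(lines), 2L)
  expect_identical(strsplit(lines[1], "\t")[[1]], c("a", "1", "-9", "0"))
  fields <- strsplit(lines, "\t")
  expect_true(all(lengths(fields) == ncol(m) + 1L))
})

test_that("band-score TSV writer and reader are inverse", {
  s <- shared_sim()
  gm <- genotype_panel(s$reads, s$truth$loci)
  b <- suppressWarnings(genotypes_to_binary(gm))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_band_scores(b, f)
  back <- read_band_scores(f)
  expect_identical(colnames(back), colnames(b))
  expect_identical(rownames(back), rownames(b))
  expect_equal(unname(back[, ]), unname(b[, ]))
  expect_identical(attr(back, "loci"), attr(b, "loci"))
})
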