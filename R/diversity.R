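## Marker characterisation and panel genetics on binary band scores:
## 1/0 presence/absence coding per (locus, allele), band-share allele
## frequencies, Na/He/PIC, PCA, Jaccard distances, neighbor-joining
## trees and STRUCTURE-format export.
##
## Allele frequencies from dominant 1/0 band data are band-share
## frequencies (carriers of an allele / total carrier counts at the
## locus): dominant scoring cannot distinguish homozygotes from
## heterozygotes, so band shares are the standard dominant-data
## convention.

#' Convert a genotype matrix to binary band scores
#'
#' One column per (locus, distinct allele) pair over PASS calls, named
#' `locus:allele`. An accession scores 1 when either called allele
#' equals the column's allele, 0 otherwise, and NA at loci where its
#' call is missing. Loci with no PASS call are dropped with a warning.
#'
#' @param gm A `genotype_matrix`.
#' @return Numeric matrix (accessions x alleles) of 0/1/NA with a
#'   `loci` attribute mapping columns to locus names.
#' @export
genotypes_to_binary <- function(gm) {
  calls <- gm$calls
  accs <- gm$accessions
  cols <- list()
  col_locus <- character()
  dropped <- character()
  for (nm in gm$loci$name) {
    lc <- calls[calls$locus == nm, , drop = FALSE]
    lc <- lc[match(accs, lc$accession), , drop = FALSE]
    pass <- lc$status == "PASS"
    if (!any(pass)) {
      dropped <- c(dropped, nm)
      next
    }
    alleles <- sort(unique(c(lc$a1[pass], lc$a2[pass])))
    for (al in alleles) {
      v <- ifelse(pass, as.numeric(lc$a1 == al | lc$a2 == al), NA_real_)
      cols[[paste0(nm, ":", al)]] <- v
      col_locus <- c(col_locus, nm)
    }
  }
  if (length(dropped)) {
    warning("loci without PASS calls dropped: ", paste(dropped, collapse = ", "))
  }
  m <- do.call(cbind, cols)
  rownames(m) <- accs
  attr(m, "loci") <- col_locus
  m
}

binary_col_loci <- function(scores) {
  lc <- attr(scores, "loci")
  if (is.null(lc)) lc <- sub(":[^:]*$", "", colnames(scores))
  lc
}

#' Band-share allele frequencies at one locus
#'
#' @param scores Binary matrix restricted to one locus's allele columns
#'   (accessions x alleles, 0/1/NA).
#' @return Numeric vector of frequencies summing to 1.
#' @export
allele_frequencies <- function(scores) {
  scores <- as.matrix(scores)
  counts <- colSums(scores == 1, na.rm = TRUE)
  tot <- sum(counts)
  if (tot == 0) stop("locus with no scored allele (all-zero)")
  counts / tot
}

check_simplex <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("allele frequencies must be non-negative and sum to 1")
  }
}

#' Expected heterozygosity (gene diversity)
#'
#' `He = 1 - sum(p_i^2)`.
#'
#' @param p Allele frequency vector summing to 1.
#' @return He in `[0, 1)`.
#' @export
expected_heterozygosity <- function(p) {
  check_simplex(p)
  1 - sum(p^2)
}

#' Polymorphism information content (Botstein convention)
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @param p Allele frequency vector summing to 1.
#' @return PIC in `[0, 1)`; always `<=` He with equality only for a
#'   monomorphic locus.
#' @export
pic <- function(p) {
  check_simplex(p)
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p_i^2)^2 - sum p_i^4
  1 - s2 - (s2^2 - s4)
}

#' Per-locus marker statistics and panel means
#'
#' Computes Na (number of alleles), He and PIC per locus from binary
#' band scores, plus arithmetic means over loci. Values are retained at
#' full precision; `round_digits` controls only the `report` copy.
#'
#' @param scores Binary band-score matrix (accessions x alleles) with
#'   columns grouped by locus (names `locus:allele` or a `loci`
#'   attribute).
#' @param round_digits Decimals for the rounded report table.
#' @return List of class `marker_stats`: `per_locus` (locus, na, he,
#'   pic), `means` (named numeric), `report` (rounded per-locus table
#'   with a means row).
#' @export
marker_stats_table <- function(scores, round_digits = 2L) {
  col_locus <- binary_col_loci(scores)
  loci <- unique(col_locus)
  per <- lapply(loci, function(nm) {
    p <- allele_frequencies(scores[, col_locus == nm, drop = FALSE])
    data.frame(locus = nm, na = length(p),
               he = expected_heterozygosity(p), pic = pic(p),
               stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, per)
  means <- c(na = mean(per_locus$na), he = mean(per_locus$he),
             pic = mean(per_locus$pic))
  report <- per_locus
  report$he <- round_half_up(report$he, round_digits)
  report$pic <- round_half_up(report$pic, round_digits)
  report <- rbind(report,
                  data.frame(locus = "Mean",
                             na = round_half_up(means["na"], round_digits),
                             he = round_half_up(means["he"], round_digits),
                             pic = round_half_up(means["pic"], round_digits)))
  rownames(report) <- NULL
  structure(list(per_locus = per_locus, means = means, report = report),
            class = "marker_stats")
}

# round-half-up (report convention; base round() is round-half-even)
round_half_up <- function(x, digits = 2L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Principal component analysis of binary band scores
#'
#' Missing marks are mean-imputed per column; columns are centred and
#' the SVD taken. Variance explained is `sigma_k^2 / sum(sigma^2)`. The
#' sign of each component is fixed so its largest-magnitude loading is
#' positive.
#'
#' @param scores Binary matrix (accessions x alleles; at least 2 of
#'   each).
#' @return List with `coords` (accessions x components), `loadings`,
#'   `var_explained`.
#' @export
pca_binary <- function(scores) {
  m <- as.matrix(scores)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need >= 2 accessions and alleles")
  for (j in seq_len(ncol(m))) {
    mu <- mean(m[, j], na.rm = TRUE)
    m[is.na(m[, j]), j] <- mu
  }
  m <- scale(m, center = TRUE, scale = FALSE)
  if (all(abs(m) < 1e-12)) stop("constant score matrix")
  sv <- svd(m)
  k <- sum(sv$d > max(sv$d) * 1e-10)
  d <- sv$d[seq_len(k)]
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sign(v[which.max(abs(v[, j])), j])
    if (s < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  coords <- sweep(u, 2L, d, `*`)
  rownames(coords) <- rownames(scores)
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coords = coords, loadings = v,
       var_explained = d^2 / sum(sv$d^2))
}

#' Jaccard distance matrix between accessions
#'
#' `d(a, b) = 1 - shared / union` over allele columns scored (non-NA)
#' in both accessions; two identical all-zero profiles have distance 0.
#'
#' @param scores Binary matrix (accessions x alleles).
#' @return Symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(scores) {
  m <- as.matrix(scores)
  n <- nrow(m)
  if (n < 2L) stop("need >= 2 accessions")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (!any(ok)) stop("accession pair with zero co-scored columns: ",
                         rownames(m)[i], " / ", rownames(m)[j])
      a <- m[i, ok]
      b <- m[j, ok]
      un <- sum(a == 1 | b == 1)
      sh <- sum(a == 1 & b == 1)
      d[i, j] <- d[j, i] <- if (un == 0) 0 else 1 - sh / un
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via ape); additive matrices are
#' recovered exactly. Negative branch lengths are clamped to zero and
#' flagged.
#'
#' @param D Symmetric distance matrix with at least 3 taxa.
#' @return List with `tree` (an `ape::phylo`), `newick` (serialisation)
#'   and `clamped` (TRUE when negative branch lengths were clamped).
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-9 || any(diag(D) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  tr <- ape::nj(stats::as.dist(D))
  clamped <- any(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  list(tree = tr, newick = ape::write.tree(tr), clamped = clamped)
}

#' Export binary band scores in STRUCTURE input format
#'
#' Dominant/binary convention: one row per accession (accession id
#' followed by one column per allele), missing marks written as -9.
#'
#' @param scores Binary matrix (accessions x alleles).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_structure <- function(scores, path) {
  m <- as.matrix(scores)
  m[is.na(m)] <- -9
  lines <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], trim = TRUE)), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read/write band-score TSV
#'
#' Accessions x alleles table, allele columns named `locus:allele`,
#' first column `accession`; missing scores are empty/NA.
#'
#' @param scores Binary matrix.
#' @param path File path.
#' @return For the writer, `path` invisibly; for the reader, a binary
#'   matrix with a `loci` attribute.
#' @export
write_band_scores <- function(scores, path) {
  df <- data.frame(accession = rownames(scores), as.data.frame(scores),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_band_scores
#' @export
read_band_scores <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  attr(m, "loci") <- sub(":[^:]*$", "", colnames(m))
  m
}
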