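# Capture Hi-C: pair filtering, binning, balancing, subtraction,
# sub-matrix tests, diamond signal and boundary calling.

span1 <- genomic_interval("chr1", 0, 50000, "capture")

test_that("pair filtering applies inclusive MAPQ and span containment", {
  pairs <- data.frame(
    chrom1 = "chr1", pos1 = c(1000, 1000, 1000, 60000, 9000),
    chrom2 = "chr1", pos2 = c(2000, 2000, 2000, 2000, 3000),
    mapq1 = c(30, 29, 60, 40, 40), mapq2 = c(60, 60, 30, 40, 40))
  out <- filter_pairs(pairs, span1, mapq_min = 30)
  expect_equal(nrow(out), 3L)          # (30,60), (60,30), (40,40) in span
  expect_true(all(pmin(out$mapq1, out$mapq2) >= 30))
  # canonicalization orders positions
  expect_true(all(out$pos1 <= out$pos2))
  expect_equal(out$pos1[3], 3000)
})

test_that("pair binning builds a symmetric count matrix", {
  pairs <- data.frame(chrom1 = "chr1", pos1 = c(2 * 5000 + 10, 4 * 5000 + 1),
                      chrom2 = "chr1", pos2 = c(7 * 5000 + 10, 4 * 5000 + 2),
                      mapq1 = 60, mapq2 = 60)
  cm <- bin_pairs(pairs, span1, bin_size = 5000)
  expect_equal(cm$counts[3, 8], 1)
  expect_equal(cm$counts[8, 3], 1)
  expect_equal(cm$counts[5, 5], 1)     # diagonal incremented once
  expect_equal(sum(cm$counts), 3)

  pairs10 <- pairs[rep(1, 10), ]
  cm10 <- bin_pairs(pairs10, span1, bin_size = 5000)
  expect_equal(cm10$counts[3, 8], 10)

  bad <- data.frame(chrom1 = "chr1", pos1 = 60000, chrom2 = "chr1",
                    pos2 = 1000, mapq1 = 60, mapq2 = 60)
  expect_error(bin_pairs(bad, span1, 5000), "outside span")
})

test_that("iterative balancing equalizes marginals", {
  # equal-marginal matrix is a fixed point
  m <- matrix(c(0, 4, 4, 0), 2)
  cm <- balance_ice(m, min_marginal = 1)
  expect_equal(cm$balanced, matrix(c(0, 1, 1, 0), 2))
  expect_equal(cm$weights, c(0.5, 0.5))
  # balanced = W %*% counts %*% W
  expect_equal(diag(cm$weights) %*% m %*% diag(cm$weights), cm$balanced)

  set.seed(41)
  m <- matrix(rpois(400, 30), 20)
  m <- m + t(m)
  cm <- balance_ice(m, min_marginal = 1, tol = 1e-8)
  marg <- rowSums(cm$balanced, na.rm = TRUE)
  expect_lt(sd(marg) / mean(marg), 1e-7)
  expect_equal(unname(marg), rep(1, 20), tolerance = 1e-5)
  # symmetry preserved
  expect_equal(cm$balanced, t(cm$balanced))

  # zero row is masked; all-masked input errors
  m2 <- m; m2[3, ] <- 0; m2[, 3] <- 0
  cm2 <- balance_ice(m2, min_marginal = 1)
  expect_true(cm2$bad_bins[3])
  expect_true(all(is.na(cm2$balanced[3, ])))
  expect_error(balance_ice(matrix(0, 3, 3)), "all bins masked")
})

test_that("balancing is idempotent", {
  set.seed(43)
  m <- matrix(rpois(225, 40), 15)
  m <- m + t(m)
  cm <- balance_ice(m, min_marginal = 1, tol = 1e-8)
  again <- balance_ice(cm$balanced, min_marginal = 0, tol = 1e-8)
  expect_equal(max(abs(again$weights - again$weights[1])), 0,
               tolerance = 1e-6)
  expect_equal(again$balanced, cm$balanced, tolerance = 1e-6)
})

random_balanced_pair <- function(n = 12) {
  m <- matrix(rpois(n * n, 25) + 1, n)
  m <- m + t(m)
  a <- balance_ice(m, min_marginal = 1)
  m2 <- matrix(rpois(n * n, 25) + 1, n)
  m2 <- m2 + t(m2)
  b <- balance_ice(m2, min_marginal = 1)
  list(a = a, b = b)
}

test_that("subtraction is antisymmetric and scale-invariant", {
  set.seed(47)
  p <- random_balanced_pair()
  expect_equal(subtract_matrices(p$a, p$a)$diff,
               matrix(0, 12, 12))
  d1 <- subtract_matrices(p$a, p$b)$diff
  d2 <- subtract_matrices(p$b, p$a)$diff
  expect_equal(d1, -d2)
  # multiplying either balanced matrix by a constant changes nothing
  a_scaled <- p$a
  a_scaled$balanced <- a_scaled$balanced * 7.3
  expect_equal(subtract_matrices(a_scaled, p$b)$diff, d1)
  # union of bad bins is masked
  bbad <- p$b
  bbad$bad_bins[4] <- TRUE
  bbad$balanced[4, ] <- NA; bbad$balanced[, 4] <- NA
  d3 <- subtract_matrices(p$a, bbad)
  expect_true(all(is.na(d3$diff[4, ])))
})

test_that("sub-matrix comparison tests scaled bin values", {
  n <- 10
  bal <- matrix(1 / (n * n), n, n)
  A <- fake_balanced_cm(bal, bin_size = 5000)
  res <- compare_submatrices(A, A, rows = genomic_interval("chr1", 0, 25000),
                             cols = genomic_interval("chr1", 25000, 50000))
  expect_equal(res$p_value, 1)

  # 5 bins all shifted upward: exact two-sided p = 2/2^5
  balB <- bal
  balB[1, 6:10] <- balB[1, 6:10] * 3
  B <- fake_balanced_cm(balB, bin_size = 5000)
  res <- compare_submatrices(
    A, B, rows = genomic_interval("chr1", 0, 5000),
    cols = genomic_interval("chr1", 25000, 50000))
  expect_equal(res$n_pairs, 5L)
  expect_equal(res$p_value, 0.0625)

  # masked bins contribute no pairs
  balM <- balB; balM[, 10] <- NA; balM[10, ] <- NA
  M <- fake_balanced_cm(balM, bin_size = 5000)
  res <- compare_submatrices(
    A, M, rows = genomic_interval("chr1", 0, 5000),
    cols = genomic_interval("chr1", 25000, 50000))
  expect_equal(res$n_pairs, 4L)
})

test_that("diamond signal dips at block boundaries", {
  n <- 40
  # uniform matrix: constant interior signal
  u <- fake_balanced_cm(matrix(3, n, n))
  sig <- diamond_bin_signal(u, w = 5)
  expect_equal(sig[6:(n - 6)], rep(3, n - 11))
  expect_true(is.na(sig[n]))

  # two blocks, within h = 2, between 0: zero diamond exactly at the join
  bal <- matrix(0, n, n)
  bal[1:20, 1:20] <- 2
  bal[21:40, 21:40] <- 2
  cm <- fake_balanced_cm(bal)
  sig <- diamond_bin_signal(cm, w = 5)
  expect_equal(sig[20], 0)
  expect_true(all(sig[c(10, 30)] == 2))
  expect_equal(which.min(sig[6:34]) + 5L, 20L)

  # w = 1 reduces to the superdiagonal
  sig1 <- diamond_bin_signal(cm, w = 1)
  expect_equal(sig1[-n], bal[cbind(1:(n - 1), 2:n)])
})

test_that("boundary calling recovers planted block structure", {
  # uniform matrix: no boundaries
  u <- fake_balanced_cm(matrix(5, 60, 60), bin_size = 10000)
  expect_equal(nrow(call_boundaries(u, w = 8)), 0L)

  # strong two-block matrix: exactly one boundary at the planted bin
  set.seed(53)
  m <- planted_block_matrix(120, boundary = 60, base = 150, contrast = 6)
  cm <- balance_ice(m, min_marginal = 1)
  cm$bin_size <- 10000L
  cm$span <- genomic_interval("chr1", 0, 120 * 10000, "span")
  b <- call_boundaries(cm, w = 20)
  expect_equal(nrow(b), 1L)
  expect_lte(abs(b$bin_index - 61L), 1L)
  expect_equal(b$position, (b$bin_index - 1) * 10000)

  # three equal blocks: two boundaries at the junctions
  m3 <- matrix(0.2, 90, 90)
  for (blk in list(1:30, 31:60, 61:90)) m3[blk, blk] <- 5
  diag3 <- fake_balanced_cm(m3, bin_size = 10000)
  b3 <- call_boundaries(diag3, w = 10)
  expect_equal(nrow(b3), 2L)
  expect_equal(b3$bin_index, c(31L, 61L))

  # too few bins: empty result with warning
  expect_warning(out <- call_boundaries(u, w = 40), "too few bins")
  expect_equal(nrow(out), 0L)
  # sub-10-kb boundary calling warns
  small <- fake_balanced_cm(matrix(5, 60, 60), bin_size = 5000)
  expect_warning(call_boundaries(small, w = 8), "10-kb")
})

test_that("matrices and pairs round-trip through text files", {
  pairs <- data.frame(chrom1 = "chr1", pos1 = c(100, 200),
                      chrom2 = "chr1", pos2 = c(300, 400),
                      mapq1 = c(40, 50), mapq2 = c(60, 30))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(pairs, f)
  expect_equal(read_pairs(f), pairs)

  cm <- balance_ice(matrix(c(0, 4, 4, 0), 2), min_marginal = 1)
  cm$span <- genomic_interval("chr1", 0, 10000)
  cm$bin_size <- 5000L
  mf <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(cm, mf, which = "balanced")
  df <- read.table(mf, header = TRUE, sep = "\t")
  expect_equal(df$bin_start, c(0, 5000))
  expect_equal(df$b0, c(0, 1))
})
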