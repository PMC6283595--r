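# Capture Hi-C: contact-pair filtering, matrix binning, iterative
# balancing, balanced-matrix subtraction, differential sub-matrix tests,
# and diamond bin-signal boundary detection.

#' Filter contact pairs by mapping quality and capture span
#'
#' Keeps pairs with `min(mapq1, mapq2) >= mapq_min` (threshold inclusive)
#' and both mates inside the capture span, and canonicalizes same-chrom
#' pairs so `pos1 <= pos2`. Positions are fragment-middle coordinates.
#'
#' @param pairs data.frame with `chrom1`, `pos1`, `chrom2`, `pos2`,
#'   `mapq1`, `mapq2`.
#' @param span `genomic_interval` of the capture region.
#' @param mapq_min Minimum mapping quality (default 30).
#' @return The filtered, canonicalized pairs data.frame.
#' @export
filter_pairs <- function(pairs, span, mapq_min = 30) {
  stopifnot(inherits(span, "genomic_interval"))
  keep <- pmin(pairs$mapq1, pairs$mapq2) >= mapq_min &
    in_interval(span, pairs$chrom1, pairs$pos1) &
    in_interval(span, pairs$chrom2, pairs$pos2)
  out <- pairs[keep, , drop = FALSE]
  flip <- out$chrom1 == out$chrom2 & out$pos1 > out$pos2
  if (any(flip)) {
    tmp <- out$pos1[flip]; out$pos1[flip] <- out$pos2[flip]; out$pos2[flip] <- tmp
    tmp <- out$mapq1[flip]; out$mapq1[flip] <- out$mapq2[flip]; out$mapq2[flip] <- tmp
  }
  rownames(out) <- NULL
  out
}

#' Bin contact pairs into a symmetric contact matrix
#'
#' Bin index is `floor((pos - span$start) / bin_size)`; each pair
#' increments `counts[i, j]` and `counts[j, i]`, the diagonal once.
#' Pairs must be pre-filtered to the span.
#'
#' @param pairs Filtered pairs data.frame.
#' @param span Capture span `genomic_interval`.
#' @param bin_size Bin width in bp (5 kb for contact maps, 10 kb for
#'   boundary calling, conventionally).
#' @return A `contact_matrix`: list with `span`, `bin_size`, `counts`
#'   (symmetric), `balanced = NULL`, `weights = NULL`, `bad_bins = NULL`.
#' @export
bin_pairs <- function(pairs, span, bin_size = 5000) {
  stopifnot(inherits(span, "genomic_interval"), bin_size >= 1)
  n_bins <- as.integer(ceiling(interval_length(span) / bin_size))
  i <- floor((pairs$pos1 - span$start) / bin_size) + 1L
  j <- floor((pairs$pos2 - span$start) / bin_size) + 1L
  if (nrow(pairs) &&
      (any(i < 1L | i > n_bins) || any(j < 1L | j > n_bins) ||
       any(pairs$chrom1 != span$chrom) || any(pairs$chrom2 != span$chrom)))
    stop("pair position outside span; filter pairs first")
  counts <- matrix(0, n_bins, n_bins)
  if (nrow(pairs)) {
    lo <- pmin(i, j); hi <- pmax(i, j)
    tab <- table(factor(paste(lo, hi), levels = unique(paste(lo, hi))))
    uk <- do.call(rbind, strsplit(names(tab), " "))
    ui <- as.integer(uk[, 1]); uj <- as.integer(uk[, 2])
    counts[cbind(ui, uj)] <- as.numeric(tab)
    off <- ui != uj
    counts[cbind(uj[off], ui[off])] <- as.numeric(tab)[off]
  }
  structure(list(span = span, bin_size = as.integer(bin_size),
                 counts = counts, balanced = NULL, weights = NULL,
                 bad_bins = NULL),
            class = "contact_matrix")
}

#' Iteratively balance a contact matrix
#'
#' Iterative correction: bins with raw marginal below `min_marginal` (or
#' zero) are masked; per-bin biases are updated multiplicatively until
#' the coefficient of variation of the unmasked marginals drops below
#' `tol`. The balanced matrix is `W %*% counts %*% W` with diagonal
#' weights `W`, scaled so every unmasked row sums to 1; masked rows and
#' columns are `NA`.
#'
#' @param cm A `contact_matrix` (or bare symmetric matrix).
#' @param max_iter Iteration cap (default 200).
#' @param tol Convergence tolerance on the marginal CV (default 1e-5).
#' @param min_marginal Mask bins with raw marginal below this (default 10).
#' @return The `contact_matrix` with `balanced`, `weights`, `bad_bins`
#'   filled.
#' @export
balance_ice <- function(cm, max_iter = 200, tol = 1e-5, min_marginal = 10) {
  if (is.matrix(cm))
    cm <- structure(list(span = NULL, bin_size = NA_integer_, counts = cm,
                         balanced = NULL, weights = NULL, bad_bins = NULL),
                    class = "contact_matrix")
  counts <- cm$counts
  if (max(abs(counts - t(counts))) > 1e-8) stop("counts matrix not symmetric")
  n <- nrow(counts)
  marg <- rowSums(counts)
  bad <- marg < min_marginal | marg == 0
  if (all(bad)) stop("all bins masked")
  sub <- counts[!bad, !bad, drop = FALSE]
  b <- rep(1, nrow(sub))
  for (iter in seq_len(max_iter)) {
    M <- sub / outer(b, b)
    s <- rowSums(M)
    cv <- stats::sd(s) / mean(s)
    if (is.na(cv) || cv < tol) break
    b <- b * s / mean(s)
  }
  M <- sub / outer(b, b)
  s_mean <- mean(rowSums(M))
  balanced_sub <- M / s_mean           # unmasked rows sum to 1
  w_sub <- 1 / (b * sqrt(s_mean))      # balanced = W counts W
  balanced <- matrix(NA_real_, n, n)
  balanced[!bad, !bad] <- balanced_sub
  weights <- rep(NA_real_, n)
  weights[!bad] <- w_sub
  cm$balanced <- balanced
  cm$weights <- weights
  cm$bad_bins <- bad
  cm
}

scaled_balanced <- function(cm) {
  if (is.null(cm$balanced)) stop("matrix not balanced; run balance_ice() first")
  tot <- sum(cm$balanced, na.rm = TRUE)
  if (tot <= 0) stop("balanced matrix has no unmasked signal")
  cm$balanced / tot
}

#' Subtract two balanced contact matrices
#'
#' Each balanced matrix is first scaled to unit total over its unmasked
#' cells (balancing only determines a matrix up to a constant, so a scale
#' convention must be fixed), then subtracted elementwise. The union of
#' the two bad-bin masks is `NA` in the output.
#'
#' @param cmA,cmB Balanced `contact_matrix` objects on the same span and
#'   bin size.
#' @return A `contact_difference`: list with `span`, `bin_size`, `diff`
#'   (A minus B), `bad_bins`.
#' @export
subtract_matrices <- function(cmA, cmB) {
  if (!identical(dim(cmA$counts), dim(cmB$counts)) ||
      !identical(cmA$bin_size, cmB$bin_size))
    stop("matrices must share span and bin size")
  a <- scaled_balanced(cmA)
  b <- scaled_balanced(cmB)
  bad <- cmA$bad_bins | cmB$bad_bins
  d <- a - b
  d[bad, ] <- NA_real_
  d[, bad] <- NA_real_
  structure(list(span = cmA$span, bin_size = cmA$bin_size, diff = d,
                 bad_bins = bad),
            class = "contact_difference")
}

interval_to_bins <- function(interval, span, bin_size, n_bins) {
  stopifnot(interval$chrom == span$chrom,
            interval$start >= span$start, interval$end <= span$end)
  lo <- floor((interval$start - span$start) / bin_size) + 1L
  hi <- ceiling((interval$end - span$start) / bin_size)
  seq.int(max(1L, lo), min(n_bins, hi))
}

#' Differential contact test on a sub-matrix
#'
#' Paired two-sided Wilcoxon signed-rank test over the corresponding
#' unmasked bin values of two unit-total-scaled balanced matrices,
#' restricted to the `rows` x `cols` rectangle.
#'
#' @param cmA,cmB Balanced `contact_matrix` objects on the same span and
#'   bin size.
#' @param rows,cols `genomic_interval`s inside the span selecting the
#'   sub-matrix.
#' @return A `paired_test_result` (`delta_fraction` here is the mean
#'   difference of scaled contact values, B minus A).
#' @export
compare_submatrices <- function(cmA, cmB, rows, cols) {
  if (!identical(dim(cmA$counts), dim(cmB$counts)) ||
      !identical(cmA$bin_size, cmB$bin_size))
    stop("matrices must share span and bin size")
  n <- nrow(cmA$counts)
  ri <- interval_to_bins(rows, cmA$span, cmA$bin_size, n)
  ci <- interval_to_bins(cols, cmA$span, cmA$bin_size, n)
  a <- scaled_balanced(cmA)[ri, ci]
  b <- scaled_balanced(cmB)[ri, ci]
  ok <- !is.na(a) & !is.na(b)
  lab <- sprintf("%s:%d-%d x %s:%d-%d", rows$chrom, rows$start, rows$end,
                 cols$chrom, cols$start, cols$end)
  if (!any(ok)) {
    warning("no unmasked bins in sub-matrix ", lab)
    test <- list(statistic = 0, p_value = 1, n_pairs = 0L)
    delta <- NA_real_
  } else {
    test <- suppressWarnings(signed_rank_test(a[ok], b[ok]))
    delta <- mean(b[ok] - a[ok])
  }
  structure(list(region = lab, n_pairs = test$n_pairs,
                 statistic = test$statistic, p_value = test$p_value,
                 delta_fraction = delta),
            class = "paired_test_result")
}

#' Diamond bin-signal of a balanced matrix
#'
#' For each bin i, the mean balanced contact between the w bins ending at
#' i and the w bins starting at i+1 (the "diamond" straddling the
#' inter-bin gap), truncated at matrix edges and skipping masked cells.
#' TAD boundaries appear as local minima of this signal.
#'
#' @param cm A balanced `contact_matrix` (or bare matrix, possibly with
#'   NAs).
#' @param w Window half-width in bins (default 28 at 10-kb bins).
#' @return Numeric per-bin signal (`NA` where the diamond is empty).
#' @export
diamond_bin_signal <- function(cm, w = 28) {
  stopifnot(w >= 1)
  bal <- if (is.matrix(cm)) cm else {
    if (is.null(cm$balanced)) stop("matrix not balanced; run balance_ice() first")
    cm$balanced
  }
  n <- nrow(bal)
  sig <- rep(NA_real_, n)
  for (i in seq_len(n - 1L)) {
    u <- seq.int(max(1L, i - w + 1L), i)
    v <- seq.int(i + 1L, min(n, i + w))
    cells <- bal[u, v, drop = FALSE]
    if (all(is.na(cells))) next
    sig[i] <- mean(cells, na.rm = TRUE)
  }
  sig
}

#' Call TAD boundaries from the diamond bin-signal
#'
#' Candidate boundaries are strict local minima of the diamond signal
#' within a +/- w neighborhood; each candidate is filtered by a one-sided
#' rank-sum test of its diamond (between-domain) values against the
#' flanking within-domain diamonds centered w bins away on either side
#' (which have the same cell-distance composition, so pure distance
#' decay does not bias the test), Bonferroni-corrected over candidates,
#' and retained when the adjusted p < `p_threshold`. Candidates closer
#' than w bins are resolved to the lower signal. The reported position
#' is the bin start of the first bin of the downstream domain.
#'
#' @param cm A balanced `contact_matrix`.
#' @param w Window in bins (default 28; the conventional setting is 10-kb
#'   bins). Calling at 5-kb bins warns, as masked gaps are typically too
#'   numerous at that resolution.
#' @param p_threshold Significance threshold for the rank-sum filter.
#' @return data.frame with `bin_index` (first bin of the downstream
#'   domain, 1-based), `position` (its genomic start, when the matrix has
#'   a span), `bin_signal`, `p_value`, `window_w`. Empty (with a warning)
#'   when the matrix has at most 2w bins.
#' @export
call_boundaries <- function(cm, w = 28, p_threshold = 0.05) {
  bal <- if (is.matrix(cm)) cm else cm$balanced
  if (is.null(bal)) stop("matrix not balanced; run balance_ice() first")
  bin_size <- if (is.matrix(cm)) NA_integer_ else cm$bin_size
  span <- if (is.matrix(cm)) NULL else cm$span
  if (!is.na(bin_size) && bin_size < 10000)
    warning("boundary calling below 10-kb bins: masked gaps may be too numerous")
  n <- nrow(bal)
  empty <- data.frame(bin_index = integer(0), position = numeric(0),
                      bin_signal = numeric(0), p_value = numeric(0),
                      window_w = integer(0))
  if (n <= 2 * w) {
    warning("matrix has too few bins (", n, ") for window ", w)
    return(empty)
  }
  sig <- diamond_bin_signal(cm, w)
  cand <- integer(0)
  for (i in seq_len(n - 1L)) {
    if (is.na(sig[i])) next
    nb <- seq.int(max(1L, i - w), min(n, i + w))
    nb <- setdiff(nb, i)
    vals <- sig[nb]
    if (all(is.na(vals))) next
    if (sig[i] < min(vals, na.rm = TRUE)) cand <- c(cand, i)
  }
  if (!length(cand)) return(empty)
  diamond_cells <- function(i) {
    if (i < 1L || i >= n) return(numeric(0))
    u <- seq.int(max(1L, i - w + 1L), i)
    v <- seq.int(i + 1L, min(n, i + w))
    cells <- as.numeric(bal[u, v])
    cells[!is.na(cells)]
  }
  pvals <- vapply(cand, function(i) {
    diamond <- diamond_cells(i)
    flanking <- c(diamond_cells(i - w), diamond_cells(i + w))
    if (length(diamond) < 2L || length(flanking) < 2L) return(NA_real_)
    suppressWarnings(stats::wilcox.test(diamond, flanking,
                                        alternative = "less")$p.value)
  }, numeric(1))
  pvals <- pmin(1, pvals * length(cand))  # Bonferroni over candidates
  keep <- is.na(pvals) | pvals < p_threshold
  cand <- cand[keep]; pvals <- pvals[keep]
  if (!length(cand)) return(empty)
  # resolve candidates closer than w bins to the one with lower signal
  ord <- order(sig[cand])
  chosen <- integer(0)
  for (i in cand[ord]) {
    if (!length(chosen) || all(abs(chosen - i) >= w)) chosen <- c(chosen, i)
  }
  chosen <- sort(chosen)
  pv <- pvals[match(chosen, cand)]
  data.frame(bin_index = chosen + 1L,
             position = if (!is.null(span))
               span$start + as.numeric(chosen) * bin_size else NA_real_,
             bin_signal = sig[chosen],
             p_value = pv,
             window_w = as.integer(w))
}

# ---- I/O -------------------------------------------------------------------

#' Read contact pairs from a tab-separated file
#'
#' Columns: chrom1 pos1 chrom2 pos2 mapq1 mapq2 (header optional,
#' detected).
#'
#' @param path TSV file.
#' @return Pairs data.frame.
#' @export
read_pairs <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  df <- utils::read.table(path, header = has_header, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!has_header)
    names(df) <- c("chrom1", "pos1", "chrom2", "pos2", "mapq1", "mapq2")
  df
}

#' Write contact pairs as TSV
#' @param pairs Pairs data.frame.
#' @param path Output file.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a contact matrix as dense TSV with bin coordinates
#' @param cm A `contact_matrix`.
#' @param path Output file.
#' @param which "counts" or "balanced".
#' @export
write_matrix_tsv <- function(cm, path, which = c("balanced", "counts")) {
  which <- match.arg(which)
  m <- cm[[which]]
  if (is.null(m)) stop("matrix has no ", which, " layer")
  n <- nrow(m)
  starts <- if (!is.null(cm$span))
    cm$span$start + (seq_len(n) - 1L) * cm$bin_size else seq_len(n)
  df <- cbind(data.frame(bin_start = starts), as.data.frame(m))
  names(df)[-1] <- paste0("b", starts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
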