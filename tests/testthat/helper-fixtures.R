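# Shared fixtures and independent brute-force oracles.

# Fragment map built directly from break positions (0-based half-open).
make_fm <- function(breaks, chrom = "chr1", site = "CATG") {
  stopifnot(length(breaks) >= 2, !is.unsorted(breaks))
  df <- data.frame(chrom = chrom,
                   start = breaks[-length(breaks)],
                   end = breaks[-1],
                   stringsAsFactors = FALSE)
  df$fragment_id <- seq_len(nrow(df))
  structure(df, enzyme_site = site, class = c("fragment_map", "data.frame"))
}

# Toy annotation: tdom [0,400) | cluster [400,500) | cdom [500,800) |
# next_tad [800,1200) on chr1, with one named region inside tdom.
toy_annotation <- function(pad_bp = 0) {
  domain_annotation(
    tdom = genomic_interval("chr1", 0, 400, "tdom"),
    cluster = genomic_interval("chr1", 400, 500, "cluster"),
    cdom = genomic_interval("chr1", 500, 800, "cdom"),
    next_tad = genomic_interval("chr1", 800, 1200, "next_tad"),
    named_regions = list(reg = genomic_interval("chr1", 100, 200, "reg")),
    pad_bp = pad_bp)
}

# Independent regex-scan digestion oracle: cut at each (overlapping)
# occurrence start, drop zero-length fragments.
digest_oracle <- function(seq, site) {
  len <- nchar(seq)
  occ <- gregexpr(paste0("(?=", site, ")"), seq, perl = TRUE)[[1]]
  cuts <- if (occ[1] == -1) integer(0) else as.integer(occ) - 1L
  bounds <- sort(unique(c(0L, cuts, len)))
  data.frame(start = bounds[-length(bounds)], end = bounds[-1])
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Full 2^n sign-enumeration oracle for the two-sided signed-rank test.
signed_rank_oracle <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1, function(s) sum(r[s]))
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  list(statistic = w_obs, p_value = min(1, 2 * min(p_le, p_ge)))
}

# Brute-force truncated running mean skipping NA (excluded) entries.
running_mean_oracle <- function(v, k) {
  h <- (k - 1) / 2
  n <- length(v)
  vapply(seq_len(n), function(i) {
    if (is.na(v[i])) return(NA_real_)
    win <- v[max(1, i - h):min(n, i + h)]
    win <- win[!is.na(win)]
    if (!length(win)) NA_real_ else mean(win)
  }, numeric(1))
}

# Brute-force per-read bin rasterization oracle for binned coverage.
bin_coverage_oracle <- function(reads, chrom_length, bin_size, ext) {
  n_bins <- ceiling(chrom_length / bin_size)
  values <- numeric(n_bins)
  for (i in seq_len(nrow(reads))) {
    strand <- if (is.null(reads$strand)) "+" else reads$strand[i]
    if (ext > 0) {
      if (strand == "-") {
        s <- max(0, reads$end[i] - ext); e <- reads$end[i]
      } else {
        s <- reads$start[i]; e <- min(chrom_length, reads$start[i] + ext)
      }
    } else {
      s <- reads$start[i]; e <- min(chrom_length, reads$end[i])
    }
    if (e <= s) next
    for (b in seq_len(n_bins)) {
      b0 <- (b - 1) * bin_size; b1 <- b0 + bin_size
      if (s < b1 && e > b0) values[b] <- values[b] + 1
    }
  }
  values
}

# Symmetric Poisson-noised contact matrix with a planted boundary:
# lambda ~ contrast within blocks vs 1 between, times 1/(d+1) decay.
planted_block_matrix <- function(n, boundary, base = 100, contrast = 4,
                                 alpha = 1) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  lambda <- base * (d + 1)^(-alpha)
  straddle <- outer(seq_len(n) <= boundary, seq_len(n) > boundary, "&")
  straddle <- straddle | t(straddle)
  lambda[straddle] <- lambda[straddle] / contrast
  m <- matrix(0, n, n)
  ut <- upper.tri(m, diag = TRUE)
  m[ut] <- stats::rpois(sum(ut), lambda[ut])
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# Minimal contact_matrix object around a prescribed balanced matrix.
fake_balanced_cm <- function(balanced, bin_size = 5000, span = NULL) {
  n <- nrow(balanced)
  if (is.null(span))
    span <- genomic_interval("chr1", 0, n * bin_size, "span")
  structure(list(span = span, bin_size = as.integer(bin_size),
                 counts = ifelse(is.na(balanced), 0, balanced),
                 balanced = balanced,
                 weights = rep(1, n),
                 bad_bins = apply(balanced, 1, function(r) all(is.na(r)))),
            class = "contact_matrix")
}

random_pwm <- function(L) {
  m <- matrix(stats::rgamma(4 * L, 1), nrow = 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  sweep(m, 2, colSums(m), "/")
}

pwm_consensus <- function(pwm) {
  paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
}

revcomp_str <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

small_locus_config <- function(...) {
  args <- list(
    locus_length = 6e5,
    tdom = genomic_interval("locus", 50000, 250000, "tdom"),
    cluster = genomic_interval("locus", 250000, 300000, "cluster"),
    cdom = genomic_interval("locus", 300000, 450000, "cdom"),
    next_tad = genomic_interval("locus", 450000, 580000, "next_tad"),
    bait = genomic_interval("locus", 272000, 274000, "bait"),
    enhancer_regions = list(
      CS39 = list(interval = genomic_interval("locus", 180000, 182000, "CS39"),
                  strength = c(proximal = 3, distal = 2)),
      CS93 = list(interval = genomic_interval("locus", 120000, 121000, "CS93"),
                  strength = c(proximal = 3, distal = 1))),
    boundary_pos = 272500,
    depth_fourc = 2e4, depth_chic = 5e4, depth_chip = 5e4,
    median_fragment_bp = 1000)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_locus_config, args)
}
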