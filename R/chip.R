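# ChIP-seq quantification: binned coverage with read extension, log2
# ChIP/input ratio tracks, 1x-depth normalization, region enrichment
# scores, and CTCF motif orientation calls from a PWM scan.

extend_reads <- function(reads, read_extension, chrom_length) {
  s <- reads$start; e <- reads$end
  if (read_extension > 0) {
    plus <- is.null(reads$strand) | reads$strand != "-"
    s2 <- ifelse(plus, s, pmax(0, e - read_extension))
    e2 <- ifelse(plus, pmin(chrom_length, s + read_extension), e)
    s <- s2; e <- e2
  }
  e <- pmin(e, chrom_length)
  s <- pmax(s, 0)
  data.frame(start = s, end = e)
}

#' Bin read coverage with read extension
#'
#' Each read is extended to `read_extension` bp from its 5' end in its
#' strand direction (extension 0 keeps the raw interval); a bin counts
#' the reads whose extended interval overlaps it. Coordinates are 0-based
#' half-open on a single chromosome.
#'
#' @param reads data.frame with `start`, `end` and optional `strand`
#'   ("+"/"-"; missing strand is treated as "+").
#' @param chrom_length Chromosome length in bp.
#' @param bin_size Bin width in bp (default 25).
#' @param read_extension Extension length in bp (default 300).
#' @param chrom Chromosome name carried on the track.
#' @return A `binned_track`: list with `chrom`, `bin_size`, `values`
#'   (per-bin read counts), `chrom_length`, `total_reads`, `scale_mode`,
#'   `read_extension`.
#' @export
bin_coverage <- function(reads, chrom_length, bin_size = 25,
                         read_extension = 300, chrom = "locus") {
  stopifnot(bin_size >= 1, read_extension >= 0, chrom_length > 0)
  n_bins <- as.integer(ceiling(chrom_length / bin_size))
  values <- numeric(n_bins)
  if (nrow(reads)) {
    ext <- extend_reads(reads, read_extension, chrom_length)
    keep <- ext$end > ext$start
    b0 <- pmax(0L, as.integer(floor(ext$start[keep] / bin_size)))
    b1 <- pmin(n_bins - 1L, as.integer(floor((ext$end[keep] - 1) / bin_size)))
    # difference-array accumulation of per-read bin ranges
    d0 <- tabulate(b0 + 1L, nbins = n_bins + 1L)
    d1 <- tabulate(b1 + 2L, nbins = n_bins + 1L)
    values <- cumsum(d0 - d1)[seq_len(n_bins)]
  }
  structure(list(chrom = chrom, bin_size = as.integer(bin_size),
                 values = values, chrom_length = chrom_length,
                 total_reads = nrow(reads), scale_mode = "counts",
                 read_extension = as.integer(read_extension)),
            class = "binned_track")
}

rpm_values <- function(track) {
  if (track$total_reads == 0) stop("track has zero reads")
  track$values / track$total_reads * 1e6
}

#' log2 ratio track of ChIP over input
#'
#' Each track is first scaled to reads-per-million of its own total read
#' count (making the ratio invariant to sequencing depth), then the
#' per-bin value is `log2((chip + pseudocount) / (input + pseudocount))`.
#' The pseudocount (default 0.5, applied on the RPM scale) keeps every
#' bin finite.
#'
#' @param chip,input `binned_track`s with identical binning.
#' @param pseudocount Positive pseudocount.
#' @return A `binned_track` with `scale_mode = "log2_ratio"`.
#' @export
log2_ratio_track <- function(chip, input, pseudocount = 0.5) {
  stopifnot(inherits(chip, "binned_track"), inherits(input, "binned_track"),
            pseudocount > 0)
  if (chip$bin_size != input$bin_size ||
      length(chip$values) != length(input$values))
    stop("chip and input tracks must share binning")
  out <- chip
  out$values <- log2((rpm_values(chip) + pseudocount) /
                     (rpm_values(input) + pseudocount))
  out$scale_mode <- "log2_ratio"
  out$pseudocount <- pseudocount
  out
}

#' Region enrichment as log2 ratio of normalized read counts
#'
#' Counts reads whose extended interval overlaps the region, scales each
#' library to reads-per-million, and reports
#' `log2((RPM_chip + pseudocount) / (RPM_input + pseudocount))`.
#'
#' @param chip_reads,input_reads Read data.frames (`start`, `end`,
#'   optional `strand`).
#' @param region A `genomic_interval`.
#' @param chrom_length Chromosome length in bp.
#' @param pseudocount Positive pseudocount on the RPM scale.
#' @param read_extension Read extension in bp (default 300).
#' @return A `region_enrichment`: list with `region`, `enrichment`,
#'   `chip_reads`, `input_reads` (RPM in region).
#' @export
region_enrichment <- function(chip_reads, input_reads, region, chrom_length,
                              pseudocount = 0.5, read_extension = 300) {
  stopifnot(inherits(region, "genomic_interval"), pseudocount > 0)
  count_in <- function(reads) {
    if (!nrow(reads)) return(0L)
    ext <- extend_reads(reads, read_extension, chrom_length)
    sum(ext$start < region$end & ext$end > region$start)
  }
  if (!nrow(chip_reads) || !nrow(input_reads))
    stop("chip and input read sets must be non-empty")
  rpm_c <- count_in(chip_reads) / nrow(chip_reads) * 1e6
  rpm_i <- count_in(input_reads) / nrow(input_reads) * 1e6
  structure(list(region = if (!is.null(region$name)) region$name else
                   sprintf("%s:%d-%d", region$chrom, region$start, region$end),
                 enrichment = log2((rpm_c + pseudocount) / (rpm_i + pseudocount)),
                 chip_reads = rpm_c, input_reads = rpm_i),
            class = "region_enrichment")
}

#' Scale a coverage track to 1x genome-wide depth
#'
#' Multiplies per-bin values by
#' `effective_genome_size / (total_reads * read_length)` so that the
#' genome-wide mean base coverage equals 1. The effective genome size is
#' a required input, never guessed.
#'
#' @param track A `binned_track` of counts.
#' @param read_length Read length in bp.
#' @param effective_genome_size Effective genome size in bp.
#' @return The rescaled `binned_track` (`scale_mode = "one_x"`).
#' @export
normalize_1x <- function(track, read_length, effective_genome_size) {
  stopifnot(inherits(track, "binned_track"), effective_genome_size > 0,
            read_length > 0)
  if (track$total_reads == 0) stop("track has zero reads")
  out <- track
  out$values <- track$values *
    effective_genome_size / (track$total_reads * read_length)
  out$scale_mode <- "one_x"
  out
}

#' Write a binned track as bedGraph
#' @param track A `binned_track`.
#' @param path Output file.
#' @export
write_track_bedgraph <- function(track, path) {
  n <- length(track$values)
  starts <- (seq_len(n) - 1L) * track$bin_size
  ends <- pmin(starts + track$bin_size, track$chrom_length)
  df <- data.frame(chrom = track$chrom, start = starts, end = ends)
  gr <- bed_df_to_granges(df, score = track$values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

# ---- CTCF motif orientation ------------------------------------------------

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

pwm_scan_best <- function(seq_chars, logodds) {
  L <- ncol(logodds)
  n <- length(seq_chars)
  npos <- n - L + 1L
  row_idx <- match(seq_chars, rownames(logodds))  # NA for N etc.
  scores <- rep(-Inf, npos)
  for (p in seq_len(npos)) {
    ri <- row_idx[p:(p + L - 1L)]
    if (anyNA(ri)) next
    scores[p] <- sum(logodds[cbind(ri, seq_len(L))])
  }
  best <- which.max(scores)
  list(score = scores[best], pos = best)
}

#' Call CTCF motif orientation under a peak
#'
#' Scans the peak sequence with a position-weight matrix on both strands
#' using log2-odds scores against a uniform background, and reports the
#' strand of the better hit. Calls are "ambiguous" when the best forward
#' and reverse scores differ by less than `tie_tolerance` (e.g. for
#' palindromic motifs).
#'
#' @param sequence Peak DNA sequence (string, A/C/G/T/N).
#' @param pwm 4 x L column-stochastic matrix with rownames A, C, G, T.
#' @param tie_tolerance Score difference below which the call is
#'   ambiguous (default 1e-6).
#' @param peak Optional `genomic_interval` carried on the call.
#' @return A `motif_orientation_call`: list with `strand` ("+", "-" or
#'   "ambiguous"), `score` (best log2-odds), `position` (0-based
#'   forward-strand start of the best hit on the winning strand),
#'   `peak`.
#' @export
call_motif_orientation <- function(sequence, pwm, tie_tolerance = 1e-6,
                                   peak = NULL) {
  sequence <- toupper(sequence)
  stopifnot(is.matrix(pwm), nrow(pwm) == 4)
  if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "T")
  stopifnot(setequal(rownames(pwm), c("A", "C", "G", "T")))
  pwm <- pwm[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(abs(colSums(pwm) - 1) > 1e-6)) stop("pwm must be column-stochastic")
  L <- ncol(pwm)
  n <- nchar(sequence)
  if (n < L) stop("sequence shorter than motif")
  logodds <- log2(pmax(pwm, 1e-9) / 0.25)
  fwd_chars <- strsplit(sequence, "")[[1]]
  rev_chars <- strsplit(revcomp(sequence), "")[[1]]
  fwd <- pwm_scan_best(fwd_chars, logodds)
  rev <- pwm_scan_best(rev_chars, logodds)
  if (abs(fwd$score - rev$score) < tie_tolerance) {
    strand <- "ambiguous"; score <- max(fwd$score, rev$score)
    position <- fwd$pos - 1L
  } else if (fwd$score > rev$score) {
    strand <- "+"; score <- fwd$score; position <- fwd$pos - 1L
  } else {
    strand <- "-"; score <- rev$score
    position <- n - (rev$pos - 1L) - L  # forward-strand start of reverse hit
  }
  structure(list(peak = peak, strand = strand, score = score,
                 position = position),
            class = "motif_orientation_call")
}
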