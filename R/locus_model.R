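# Genomic coordinate backbone: intervals, in-silico restriction digestion,
# domain annotations and fragment-to-domain assignment.
#
# All coordinates are 0-based half-open ([start, end)), matching BED.
# 1-based coordinates appear only at the rtracklayer/GRanges boundary.

#' Create a genomic interval
#'
#' A minimal 0-based half-open interval, the coordinate primitive used
#' throughout the package.
#'
#' @param chrom Chromosome (non-empty string).
#' @param start 0-based inclusive start.
#' @param end Exclusive end; must satisfy `start < end`.
#' @param name Optional label.
#' @return An object of class `genomic_interval` (a named list).
#' @examples
#' genomic_interval("chr7", 15920642, 16318067, "tdom")
#' @export
genomic_interval <- function(chrom, start, end, name = NULL) {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  start <- as.numeric(start); end <- as.numeric(end)
  if (!(start >= 0 && start < end))
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  structure(list(chrom = chrom, start = start, end = end, name = name),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:%s-%s%s>\n", x$chrom,
              format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE),
              if (is.null(x$name)) "" else paste0(" ", x$name)))
  invisible(x)
}

interval_midpoint <- function(x) (x$start + x$end) / 2

interval_length <- function(x) x$end - x$start

#' Symmetrically pad a genomic interval
#'
#' Expands a region by `pad_bp` on each side, clamping at position zero.
#' Named-region quantifications conventionally use a 10-kb pad.
#'
#' @param region A `genomic_interval`.
#' @param pad_bp Non-negative padding in bp.
#' @return The padded `genomic_interval`.
#' @examples
#' pad_region(genomic_interval("chr1", 100, 200), 50)
#' @export
pad_region <- function(region, pad_bp) {
  stopifnot(inherits(region, "genomic_interval"), pad_bp >= 0)
  genomic_interval(region$chrom, max(0, region$start - pad_bp),
                   region$end + pad_bp, region$name)
}

#' Digest sequences in silico at a restriction site
#'
#' Places a cut at the start coordinate of every occurrence of the
#' recognition sequence (overlapping occurrences each cut) and returns the
#' resulting fragment map. Fragments tile each chromosome without gaps;
#' zero-length fragments arising from a terminal site occurrence are
#' dropped. Typical sites are CATG (NlaIII) and GATC (DpnII).
#'
#' @param sequences A named character vector or `Biostrings::DNAStringSet`
#'   of chromosome sequences (alphabet A/C/G/T/N, case-insensitive).
#' @param site Recognition sequence (A/C/G/T only, length >= 2).
#' @return A `fragment_map`: a data.frame with columns `chrom`, `start`,
#'   `end`, `fragment_id` (dense 1-based index), carrying the enzyme site
#'   as an attribute.
#' @examples
#' digest_genome(c(chrA = "AAACATGGGGCATGTT"), "CATG")
#' @export
digest_genome <- function(sequences, site) {
  site <- toupper(site)
  if (nchar(site) < 2L) stop("site length must be >= 2")
  if (grepl("[^ACGT]", site)) stop("site must contain only A, C, G, T")
  if (inherits(sequences, "DNAStringSet")) {
    seqs <- as.character(sequences)
  } else {
    seqs <- stats::setNames(toupper(as.character(sequences)),
                            names(sequences))
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named by chromosome")
  if (any(grepl("[^ACGTN]", seqs))) stop("sequence alphabet must be A/C/G/T/N")
  frames <- lapply(names(seqs), function(chrom) {
    s <- seqs[[chrom]]
    len <- nchar(s)
    if (len == 0L) stop("empty sequence: ", chrom)
    m <- Biostrings::matchPattern(site, Biostrings::DNAString(s), fixed = TRUE)
    cuts0 <- Biostrings::start(m) - 1L  # 0-based occurrence starts
    bounds <- sort(unique(c(0L, cuts0, as.integer(len))))
    data.frame(chrom = chrom,
               start = bounds[-length(bounds)],
               end = bounds[-1L],
               stringsAsFactors = FALSE)
  })
  fm <- do.call(rbind, frames)
  fm <- fm[fm$end > fm$start, , drop = FALSE]  # drop zero-length fragments
  fm$fragment_id <- seq_len(nrow(fm))
  rownames(fm) <- NULL
  structure(fm, enzyme_site = site, class = c("fragment_map", "data.frame"))
}

#' Fragment midpoints
#'
#' @param fm A `fragment_map` (or any data.frame with `start`/`end`).
#' @return Numeric vector of fragment midpoints, (start + end) / 2.
#' @export
fragment_midpoints <- function(fm) (fm$start + fm$end) / 2

#' Build a domain annotation
#'
#' Holds the two flanking regulatory domains (centromeric `cdom`,
#' telomeric `tdom`), an optional next TAD, the gene cluster interval, and
#' named regulatory regions (e.g. CS39, CS93, island III, Prox). `cdom`
#' and `tdom` must not overlap. Named regions are quantified with a
#' symmetric pad of `pad_bp` (default 10 kb).
#'
#' @param cdom,tdom,cluster `genomic_interval`s.
#' @param next_tad Optional `genomic_interval` (used by deletion-allele
#'   style three-domain quantifications).
#' @param named_regions Named list of `genomic_interval`s.
#' @param pad_bp Symmetric padding applied to named regions.
#' @return An object of class `domain_annotation`.
#' @export
domain_annotation <- function(cdom, tdom, cluster, next_tad = NULL,
                              named_regions = list(), pad_bp = 10000) {
  stopifnot(inherits(cdom, "genomic_interval"),
            inherits(tdom, "genomic_interval"),
            inherits(cluster, "genomic_interval"),
            pad_bp >= 0)
  if (cdom$chrom == tdom$chrom &&
      cdom$start < tdom$end && tdom$start < cdom$end)
    stop("cdom and tdom overlap")
  if (!is.null(next_tad)) stopifnot(inherits(next_tad, "genomic_interval"))
  if (length(named_regions)) {
    stopifnot(!is.null(names(named_regions)), all(nzchar(names(named_regions))))
    lapply(named_regions, function(r) stopifnot(inherits(r, "genomic_interval")))
  }
  structure(list(cdom = cdom, tdom = tdom, next_tad = next_tad,
                 cluster = cluster, named_regions = named_regions,
                 pad_bp = pad_bp),
            class = "domain_annotation")
}

#' Assign positions to regulatory domains
#'
#' Points are assigned by half-open containment (`start <= pos < end`);
#' the inclusive start means a point exactly at a domain start belongs to
#' that domain. Returns `NA` for positions outside all domains.
#'
#' @param annotation A `domain_annotation`.
#' @param chrom Chromosome of the positions.
#' @param pos Numeric vector of positions (e.g. fragment midpoints).
#' @return Character vector over `c("cdom", "tdom", "next_tad")` with `NA`
#'   outside all domains.
#' @export
assign_domain <- function(annotation, chrom, pos) {
  stopifnot(inherits(annotation, "domain_annotation"))
  out <- rep(NA_character_, length(pos))
  for (lab in c("cdom", "tdom", "next_tad")) {
    d <- annotation[[lab]]
    if (is.null(d)) next
    hit <- chrom == d$chrom & pos >= d$start & pos < d$end
    out[hit & is.na(out)] <- lab
  }
  out
}

#' Assign fragments to domains by midpoint
#'
#' A fragment belongs to the unique domain containing its midpoint,
#' mirroring the fragment-middle convention used for capture Hi-C read
#' assignment; this prevents double counting of boundary-straddling
#' fragments.
#'
#' @param fm A `fragment_map`.
#' @param annotation A `domain_annotation`.
#' @return Character vector, one label (or `NA`) per fragment.
#' @export
fragment_domains <- function(fm, annotation) {
  assign_domain(annotation, fm$chrom, fragment_midpoints(fm))
}

in_interval <- function(interval, chrom, pos) {
  chrom == interval$chrom & pos >= interval$start & pos < interval$end
}

# ---- I/O -------------------------------------------------------------------

#' Read locus sequences from FASTA
#' @param path FASTA file.
#' @return A `Biostrings::DNAStringSet`.
#' @export
read_locus_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write locus sequences to FASTA
#' @param sequences Named character vector or `DNAStringSet`.
#' @param path Output file.
#' @export
write_locus_fasta <- function(sequences, path) {
  if (!inherits(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

granges_to_bed_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) as.character(gr$name) else NA_character_,
             stringsAsFactors = FALSE)
}

bed_df_to_granges <- function(df, score = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
  if (!is.null(df$name)) gr$name <- df$name
  if (!is.null(score)) gr$score <- score
  gr
}

#' Read a BED file of intervals
#' @param path BED(4) file.
#' @return data.frame with 0-based half-open `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  granges_to_bed_df(rtracklayer::import(path, format = "BED"))
}

#' Write intervals as BED
#' @param df data.frame with `chrom`, `start`, `end` (+ optional `name`).
#' @param path Output file.
#' @export
write_bed <- function(df, path) {
  rtracklayer::export(bed_df_to_granges(df), path, format = "BED")
  invisible(path)
}

#' Read a domain annotation from BED4
#'
#' Interval labels in the BED name column identify the components:
#' `cdom`, `tdom`, `next_tad` and `cluster` are reserved; every other
#' label becomes a named region. Labels are required — the annotation
#' never infers which interval is which from genomic order.
#'
#' @param path BED4 file.
#' @param pad_bp Pad applied to named regions (default 10 kb).
#' @return A `domain_annotation`.
#' @export
read_domain_annotation <- function(path, pad_bp = 10000) {
  df <- read_bed(path)
  if (any(is.na(df$name))) stop("domain BED requires a name column")
  take <- function(lab, required = TRUE) {
    i <- which(df$name == lab)
    if (!length(i)) {
      if (required) stop("domain BED missing interval labelled '", lab, "'")
      return(NULL)
    }
    genomic_interval(df$chrom[i[1]], df$start[i[1]], df$end[i[1]], lab)
  }
  rest <- df[!df$name %in% c("cdom", "tdom", "next_tad", "cluster"), ,
             drop = FALSE]
  named <- stats::setNames(
    lapply(seq_len(nrow(rest)), function(i)
      genomic_interval(rest$chrom[i], rest$start[i], rest$end[i], rest$name[i])),
    rest$name)
  domain_annotation(cdom = take("cdom"), tdom = take("tdom"),
                    cluster = take("cluster"),
                    next_tad = take("next_tad", required = FALSE),
                    named_regions = named, pad_bp = pad_bp)
}

#' Write a domain annotation as BED4
#' @param annotation A `domain_annotation`.
#' @param path Output file.
#' @export
write_domain_annotation <- function(annotation, path) {
  comps <- c(list(cdom = annotation$cdom, tdom = annotation$tdom,
                  cluster = annotation$cluster),
             if (!is.null(annotation$next_tad)) list(next_tad = annotation$next_tad),
             annotation$named_regions)
  df <- do.call(rbind, lapply(names(comps), function(lab) {
    x <- comps[[lab]]
    data.frame(chrom = x$chrom, start = x$start, end = x$end, name = lab,
               stringsAsFactors = FALSE)
  }))
  write_bed(df, path)
}

#' Write a fragment map as BED
#' @param fm A `fragment_map`.
#' @param path Output file.
#' @export
write_fragment_map_bed <- function(fm, path) {
  df <- data.frame(chrom = fm$chrom, start = fm$start, end = fm$end,
                   name = paste0("frag_", fm$fragment_id),
                   stringsAsFactors = FALSE)
  write_bed(df, path)
}
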