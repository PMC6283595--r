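# Synthetic two-TAD locus generator with known ground truth: a gene
# cluster at the boundary between a centromeric and a telomeric domain,
# distance-decaying contacts, a condition-dependent reallocation of
# viewpoint contacts between the domains, insulated contact-matrix
# blocks, and ChIP enrichment blocks over active regions.

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic two-TAD locus configuration
#'
#' Parameterizes the generative model. Defaults mirror the geometry of a
#' ~3-Mb avian capture region: a ~96-kb gene cluster flanked by a ~397-kb
#' telomeric domain (T-DOM, carrying CS39/CS93-like proximal enhancers)
#' and a ~285-kb centromeric domain (C-DOM, carrying island III /
#' Prox-like distal enhancers), with a ~1.1-Mb next TAD beyond C-DOM.
#' The two default conditions emulate the proximal-to-distal regulatory
#' switch: the viewpoint directs 26% of its domain contacts to C-DOM in
#' proximal cells (telomeric fraction 0.74) and 51% in distal cells
#' (telomeric fraction 0.49), a reallocation of 0.25.
#'
#' @param locus_length Locus length in bp.
#' @param enzyme_site Restriction site used for digestion.
#' @param chrom Chromosome name.
#' @param tdom,cluster,cdom,next_tad Component `genomic_interval`s.
#' @param bait Viewpoint interval (must lie inside the cluster).
#' @param enhancer_regions Named list of `list(interval =, strength =
#'   c(condition = multiplier, ...))`; strengths reshape signal within a
#'   domain (4C) / add enhancer-cluster stripes (CHi-C) / set ChIP fold
#'   enrichment.
#' @param decay_exponent Contact-probability distance-decay exponent
#'   (alpha; probability ~ distance^-alpha).
#' @param rho Named per-condition fraction of domain-directed viewpoint
#'   contacts allocated to cdom (remainder to tdom).
#' @param shares Expected-signal shares of total 4C depth for the domain
#'   set, the cluster, the next TAD and everything else; must sum to 1.
#' @param boundary_pos Planted TAD boundary position in bp.
#' @param insulation_factor Attenuation of contacts straddling the
#'   boundary, in (0, 1]; 1 disables insulation.
#' @param depth_fourc,depth_chic,depth_chip Expected total 4C counts,
#'   CHi-C pairs and ChIP reads.
#' @param noise "poisson" or "negative_binomial" for 4C counts.
#' @param nb_dispersion Negative-binomial dispersion (variance = mu +
#'   dispersion * mu^2).
#' @param mapq_sub_fraction Fraction of simulated CHi-C pairs given a
#'   sub-threshold MAPQ.
#' @param chic_sim_bin Cell size (bp) of the CHi-C generative lattice.
#' @param median_fragment_bp Target median restriction-fragment length.
#' @param read_length Simulated ChIP read length.
#' @param seed Default seed for all generators.
#' @return A `synthetic_locus_config` list.
#' @export
synthetic_locus_config <- function(
    locus_length = 3e6,
    enzyme_site = "CATG",
    chrom = "locus",
    tdom = genomic_interval(chrom, 974642, 1372067, "tdom"),
    cluster = genomic_interval(chrom, 1372067, 1468183, "cluster"),
    cdom = genomic_interval(chrom, 1468183, 1753172, "cdom"),
    next_tad = genomic_interval(chrom, 1753172, 2833172, "next_tad"),
    bait = genomic_interval(chrom, 1418000, 1422000, "bait"),
    enhancer_regions = list(
      CS39 = list(interval = genomic_interval(chrom, 1250000, 1252000, "CS39"),
                  strength = c(proximal = 3, distal = 2)),
      CS93 = list(interval = genomic_interval(chrom, 1158952, 1159803, "CS93"),
                  strength = c(proximal = 3, distal = 1)),
      region_a = list(interval = genomic_interval(chrom, 1050000, 1060000, "region_a"),
                      strength = c(proximal = 4, distal = 1)),
      region_b = list(interval = genomic_interval(chrom, 980000, 986000, "region_b"),
                      strength = c(proximal = 2, distal = 1)),
      island_III = list(interval = genomic_interval(chrom, 1600000, 1602000, "island_III"),
                        strength = c(proximal = 1, distal = 3)),
      Prox = list(interval = genomic_interval(chrom, 1660000, 1662000, "Prox"),
                  strength = c(proximal = 1, distal = 3))),
    decay_exponent = 1.0,
    rho = c(proximal = 0.26, distal = 0.51),
    shares = c(domains = 0.80, cluster = 0.06, next_tad = 0.06,
               elsewhere = 0.08),
    boundary_pos = 1420000,
    insulation_factor = 0.2,
    depth_fourc = 1e5,
    depth_chic = 5e5,
    depth_chip = 1e6,
    noise = c("poisson", "negative_binomial"),
    nb_dispersion = 0.1,
    mapq_sub_fraction = 0.05,
    chic_sim_bin = 5000,
    median_fragment_bp = 1500,
    read_length = 50,
    seed = 1) {
  noise <- match.arg(noise)
  cfg <- list(locus_length = locus_length, enzyme_site = enzyme_site,
              chrom = chrom, tdom = tdom, cluster = cluster, cdom = cdom,
              next_tad = next_tad, bait = bait,
              enhancer_regions = enhancer_regions,
              decay_exponent = decay_exponent, rho = rho, shares = shares,
              boundary_pos = boundary_pos,
              insulation_factor = insulation_factor,
              depth_fourc = depth_fourc, depth_chic = depth_chic,
              depth_chip = depth_chip, noise = noise,
              nb_dispersion = nb_dispersion,
              mapq_sub_fraction = mapq_sub_fraction,
              chic_sim_bin = chic_sim_bin,
              median_fragment_bp = median_fragment_bp,
              read_length = read_length, seed = seed)
  validate_config(cfg)
  structure(cfg, class = "synthetic_locus_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$locus_length > 0,
            cfg$decay_exponent > 0,
            all(cfg$rho >= 0 & cfg$rho <= 1),
            cfg$insulation_factor > 0, cfg$insulation_factor <= 1,
            abs(sum(cfg$shares) - 1) < 1e-9,
            cfg$boundary_pos > 0, cfg$boundary_pos < cfg$locus_length)
  for (x in c(list(cfg$tdom, cfg$cluster, cfg$cdom, cfg$next_tad, cfg$bait),
              lapply(cfg$enhancer_regions, `[[`, "interval"))) {
    if (x$end > cfg$locus_length)
      stop("interval ", x$name, " exceeds locus length")
  }
  if (!(interval_midpoint(cfg$bait) >= cfg$cluster$start &&
        interval_midpoint(cfg$bait) < cfg$cluster$end))
    stop("bait must lie inside the cluster")
  invisible(cfg)
}

# Random locus sequence with the enzyme site placed at target spacings.
# Filler sequence is scrubbed of accidental site occurrences so the
# fragment-length distribution follows the planned cut positions.
random_locus_sequence <- function(len, site, median_fragment_bp) {
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, len, replace = TRUE)
  site_chars <- strsplit(site, "")[[1]]
  k <- length(site_chars)
  # destroy accidental occurrences (deterministic base rotation at offset 2)
  rotate <- c(A = "C", C = "G", G = "T", T = "A")
  for (pass in 1:25) {
    str <- paste(s, collapse = "")
    occ <- gregexpr(paste0("(?=", site, ")"), str, perl = TRUE)[[1]]
    if (occ[1] == -1) break
    s[occ + 1L] <- rotate[s[occ + 1L]]
  }
  # plant cuts at log-normal spacings with the requested median
  n_guess <- ceiling(2 * len / median_fragment_bp) + 10
  spacing <- pmax(k + 1, round(stats::rlnorm(n_guess,
                                             meanlog = log(median_fragment_bp),
                                             sdlog = 0.5)))
  cuts <- cumsum(spacing)
  cuts <- cuts[cuts + k <= len]
  for (p in cuts) s[(p + 1L):(p + k)] <- site_chars
  paste(s, collapse = "")
}

#' Generate a synthetic locus
#'
#' Produces the locus sequence (with restriction sites planted at the
#' target fragment spacing), its fragment map, the domain annotation
#' mirroring the config intervals, and the ground truth. Deterministic
#' given the seed.
#'
#' @param config A `synthetic_locus_config`.
#' @param seed Seed (defaults to `config$seed`).
#' @return A list with `sequence` (named character), `fragment_map`,
#'   `annotation`, `ground_truth`.
#' @export
generate_locus <- function(config, seed = config$seed) {
  validate_config(config)
  seqs <- with_seed(seed, {
    s <- random_locus_sequence(config$locus_length, config$enzyme_site,
                               config$median_fragment_bp)
    stats::setNames(s, config$chrom)
  })
  fm <- digest_genome(seqs, config$enzyme_site)
  ann <- domain_annotation(
    cdom = config$cdom, tdom = config$tdom, cluster = config$cluster,
    next_tad = config$next_tad,
    named_regions = lapply(config$enhancer_regions, `[[`, "interval"),
    pad_bp = 10000)
  truth <- list(
    true_fractions = lapply(names(config$rho), function(cond)
      c(cdom = unname(config$rho[[cond]]),
        tdom = 1 - unname(config$rho[[cond]]))),
    true_boundary_pos = config$boundary_pos,
    enhancer_strengths = lapply(config$enhancer_regions, `[[`, "strength"),
    seed = seed)
  names(truth$true_fractions) <- names(config$rho)
  list(sequence = seqs, fragment_map = fm, annotation = ann,
       ground_truth = truth)
}

enhancer_multipliers <- function(config, condition, mids, chrom) {
  mult <- rep(1, length(mids))
  for (e in config$enhancer_regions) {
    if (!condition %in% names(e$strength)) next
    hit <- in_interval(e$interval, chrom, mids)
    mult[hit] <- mult[hit] * unname(e$strength[[condition]])
  }
  mult
}

#' Simulate a 4C viewpoint profile
#'
#' Expected fragment counts decay with distance from the bait
#' (distance^-alpha) and are partitioned in fixed expected shares:
#' the domain share is split rho : (1 - rho) between cdom and tdom, so
#' the true two-domain cdom contact fraction is exactly rho. Enhancer
#' multipliers reshape signal within a domain without changing the
#' domain total, keeping the ground truth exact. Counts are Poisson or
#' negative-binomial. Deterministic given the seed.
#'
#' @param config A `synthetic_locus_config`.
#' @param condition Condition name (must index `config$rho`).
#' @param locus Output of [generate_locus()]; generated if NULL.
#' @param seed Seed (defaults to `config$seed`).
#' @return Numeric raw count vector aligned with the locus fragment map.
#' @export
simulate_fourc <- function(config, condition, locus = NULL,
                           seed = config$seed) {
  if (!condition %in% names(config$rho))
    stop("unknown condition: ", condition)
  if (is.null(locus)) locus <- generate_locus(config, seed = seed)
  fm <- locus$fragment_map
  mids <- fragment_midpoints(fm)
  bait_mid <- interval_midpoint(config$bait)
  w <- (abs(mids - bait_mid) + 1000)^(-config$decay_exponent)
  w <- w * enhancer_multipliers(config, condition, mids, fm$chrom)
  dom <- fragment_domains(fm, locus$annotation)
  in_cluster <- in_interval(config$cluster, fm$chrom, mids)
  rho <- unname(config$rho[[condition]])
  sh <- config$shares
  group_share <- list(
    cdom = sh[["domains"]] * rho,
    tdom = sh[["domains"]] * (1 - rho),
    next_tad = sh[["next_tad"]],
    cluster = sh[["cluster"]],
    elsewhere = sh[["elsewhere"]])
  group <- ifelse(in_cluster, "cluster",
                  ifelse(is.na(dom), "elsewhere", dom))
  lambda <- numeric(nrow(fm))
  for (g in names(group_share)) {
    sel <- group == g
    if (!any(sel)) next
    lambda[sel] <- config$depth_fourc * group_share[[g]] * w[sel] / sum(w[sel])
  }
  with_seed(seed + 104729L, {
    if (config$noise == "poisson") stats::rpois(length(lambda), lambda)
    else stats::rnbinom(length(lambda), mu = lambda,
                        size = 1 / config$nb_dispersion)
  })
}

#' Simulate capture Hi-C contact pairs
#'
#' Pair probability on a `chic_sim_bin` lattice decays with distance
#' (distance^-alpha), is attenuated by `insulation_factor` when the two
#' positions straddle the planted boundary, and carries symmetric
#' enhancer-cluster stripes scaled by the condition strengths. Positions
#' are cell midpoints (fragment-middle convention); a configurable
#' fraction of pairs receives a sub-threshold MAPQ. Deterministic given
#' the seed.
#'
#' @param config A `synthetic_locus_config`.
#' @param condition Condition name.
#' @param seed Seed (defaults to `config$seed`).
#' @param depth Number of pairs (defaults to `config$depth_chic`).
#' @return Pairs data.frame (`chrom1`, `pos1`, `chrom2`, `pos2`,
#'   `mapq1`, `mapq2`).
#' @export
simulate_chic <- function(config, condition, seed = config$seed,
                          depth = config$depth_chic) {
  bs <- config$chic_sim_bin
  n <- as.integer(floor(config$locus_length / bs))
  centers <- (seq_len(n) - 0.5) * bs
  d <- abs(outer(centers, centers, "-")) / bs
  lambda <- (d + 1)^(-config$decay_exponent)
  straddle <- outer(centers < config$boundary_pos,
                    centers >= config$boundary_pos, "&")
  straddle <- straddle | t(straddle)
  lambda[straddle] <- lambda[straddle] * config$insulation_factor
  # enhancer-cluster stripes
  in_clu <- centers >= config$cluster$start & centers < config$cluster$end
  for (e in config$enhancer_regions) {
    if (!condition %in% names(e$strength)) next
    s <- unname(e$strength[[condition]])
    if (s == 1) next
    in_e <- centers >= e$interval$start & centers < e$interval$end
    block <- outer(in_clu, in_e, "&") | outer(in_e, in_clu, "&")
    lambda[block] <- lambda[block] * s
  }
  ut <- which(upper.tri(lambda, diag = TRUE), arr.ind = TRUE)
  probs <- lambda[ut]
  with_seed(seed + 15485863L, {
    counts <- stats::rmultinom(1, size = depth, prob = probs)[, 1]
    idx <- rep.int(seq_along(counts), counts)
    i <- ut[idx, 1]; j <- ut[idx, 2]
    n_pairs <- length(i)
    bad <- stats::runif(n_pairs) < config$mapq_sub_fraction
    mapq1 <- ifelse(bad, sample(0:29, n_pairs, replace = TRUE),
                    sample(30:60, n_pairs, replace = TRUE))
    mapq2 <- sample(30:60, n_pairs, replace = TRUE)
    data.frame(chrom1 = config$chrom, pos1 = centers[pmin(i, j)],
               chrom2 = config$chrom, pos2 = centers[pmax(i, j)],
               mapq1 = mapq1, mapq2 = mapq2)
  })
}

#' Simulate ChIP and input read intervals
#'
#' Input reads are uniform over the locus; ChIP reads are drawn from a
#' weight density that is 1 over background and `fold` over each region
#' in `state`, so the expected ChIP/input RPM ratio over a region is
#' close to its fold (diluted by the total weight excess, which the
#' default geometry keeps small). Deterministic given the seed.
#'
#' @param config A `synthetic_locus_config`.
#' @param state Named numeric vector of fold enrichments per enhancer
#'   region (default: the strengths of `condition`).
#' @param condition Used to derive `state` when it is NULL.
#' @param seed Seed (defaults to `config$seed`).
#' @param depth Reads per library (defaults to `config$depth_chip`).
#' @return List with `chip` and `input` read data.frames (`start`,
#'   `end`, `strand`).
#' @export
simulate_chip <- function(config, state = NULL, condition = "proximal",
                          seed = config$seed, depth = config$depth_chip) {
  if (is.null(state)) {
    state <- vapply(config$enhancer_regions, function(e)
      if (condition %in% names(e$strength))
        unname(e$strength[[condition]]) else 1, numeric(1))
  }
  L <- config$locus_length
  rl <- config$read_length
  regions <- lapply(names(state), function(lab)
    config$enhancer_regions[[lab]]$interval)
  lens <- vapply(regions, interval_length, numeric(1))
  # weight density: 1 over the whole locus plus (fold - 1) extra in each
  # region, so the in-region density is exactly `fold`
  extra <- pmax(0, (unname(state) - 1) * lens)
  Z <- L + sum(extra)
  comp_prob <- c(L, extra) / Z
  draw_reads <- function(n, weighted) {
    if (weighted) {
      comp <- sample.int(length(comp_prob), n, replace = TRUE,
                         prob = comp_prob)
      start <- numeric(n)
      bg <- comp == 1L
      start[bg] <- floor(stats::runif(sum(bg), 0, L - rl))
      for (k in seq_along(regions)) {
        sel <- comp == k + 1L
        if (!any(sel)) next
        r <- regions[[k]]
        start[sel] <- floor(stats::runif(sum(sel), r$start,
                                         max(r$start + 1, r$end - rl)))
      }
    } else {
      start <- floor(stats::runif(n, 0, L - rl))
    }
    data.frame(start = start, end = start + rl,
               strand = sample(c("+", "-"), n, replace = TRUE))
  }
  with_seed(seed + 32452843L, {
    list(chip = draw_reads(depth, weighted = TRUE),
         input = draw_reads(depth, weighted = FALSE))
  })
}

#' Write synthetic locus outputs to files
#'
#' Emits FASTA (sequence), BED (fragment map, annotation) and a
#' ground-truth JSON into a directory.
#'
#' @param locus Output of [generate_locus()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_locus_files <- function(locus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_locus_fasta(locus$sequence, file.path(dir, "locus.fa"))
  write_fragment_map_bed(locus$fragment_map, file.path(dir, "fragments.bed"))
  write_domain_annotation(locus$annotation, file.path(dir, "domains.bed"))
  jsonlite::write_json(locus$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
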