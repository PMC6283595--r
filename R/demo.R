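# Configuration and the end-to-end demo workflow: simulation of two
# conditions, 4C fractions and tests, CHi-C balance/subtract/boundaries,
# ChIP enrichments, written as provenance-stamped TSV/JSON reports.

#' Default run configuration
#'
#' All analysis parameters at their conventional values: 4C
#' normalization window 1 Mb, smoothing window 11 fragments, ChIP bin
#' 25 bp with pseudocount 0.5 and read extension 300 bp, MAPQ threshold
#' 30, CHi-C contact bins 5 kb with boundary calling at 10 kb and window
#' 28, region pad 10 kb — plus the synthetic-locus generator parameters.
#'
#' @param ... Overrides for top-level fields.
#' @return A `run_config` list with components `fourc`, `chip`, `chic`
#'   and `synthetic`.
#' @export
default_config <- function(...) {
  cfg <- list(
    fourc = list(norm_window_bp = 1e6, smooth_window_frags = 11,
                 pad_bp = 10000),
    chip = list(bin_size = 25, pseudocount = 0.5, read_extension = 300,
                read_length = 50),
    chic = list(mapq_min = 30, bin_size = 5000, boundary_bin_size = 10000,
                window_w = 28, p_threshold = 0.05, min_marginal = 10),
    synthetic = synthetic_locus_config())
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Scalar fields under `fourc`, `chip` and `chic` override the defaults;
#' synthetic-locus fields under `synthetic` override the generator
#' defaults (intervals as `[start, end]` pairs are rebuilt on the
#' configured chromosome).
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_config()
  for (section in c("fourc", "chip", "chic")) {
    for (nm in names(y[[section]])) cfg[[section]][[nm]] <- y[[section]][[nm]]
  }
  if (!is.null(y$synthetic)) {
    syn <- y$synthetic
    chrom <- if (!is.null(syn$chrom)) syn$chrom else "locus"
    args <- list()
    for (nm in names(syn)) {
      v <- syn[[nm]]
      if (nm %in% c("tdom", "cdom", "cluster", "next_tad", "bait")) {
        args[[nm]] <- genomic_interval(chrom, v[[1]], v[[2]], nm)
      } else if (nm %in% c("rho", "shares")) {
        args[[nm]] <- unlist(v)
      } else if (nm == "enhancer_regions") {
        args[[nm]] <- lapply(stats::setNames(names(v), names(v)), function(lab)
          list(interval = genomic_interval(chrom, v[[lab]]$interval[[1]],
                                           v[[lab]]$interval[[2]], lab),
               strength = unlist(v[[lab]]$strength)))
      } else {
        args[[nm]] <- v
      }
    }
    # custom geometry without explicit enhancer regions starts from none:
    # the full-scale defaults need not fit a user-specified locus
    if (is.null(args$enhancer_regions)) args$enhancer_regions <- list()
    cfg$synthetic <- do.call(synthetic_locus_config, args)
  }
  cfg
}

provenance_header <- function(seed, params) {
  c(sprintf("# tadquant %s",
            as.character(utils::packageVersion("tadquant"))),
    sprintf("# seed=%d", seed),
    sprintf("# params: %s",
            paste(names(params), unlist(params), sep = "=", collapse = " ")))
}

write_report_tsv <- function(df, path, seed, params) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_header(seed, params), con)
  utils::write.table(format(df, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the end-to-end demo workflow
#'
#' Simulates the two default conditions of the synthetic locus, then
#' runs every pipeline stage: 4C normalization, domain contact fractions
#' (both conditions) and paired region tests; CHi-C pair filtering,
#' 5-kb balanced matrices, their subtraction and a sub-matrix contact
#' test, plus 10-kb boundary calling; ChIP region enrichments. Writes
#' TSV/JSON reports (each stamped with version, seed and parameters)
#' into `out_dir` and returns the report. Byte-deterministic for a fixed
#' seed.
#'
#' @param out_dir Output directory.
#' @param config A `run_config` (default [default_config()]).
#' @param seed Master seed.
#' @return The report list, invisibly.
#' @export
run_demo <- function(out_dir, config = default_config(), seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  syn <- config$synthetic
  conditions <- names(syn$rho)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  locus <- stage("simulate_locus", generate_locus(syn, seed = seed))
  ann <- locus$annotation

  # ---- 4C ------------------------------------------------------------
  fourc <- stage("fourc", {
    profiles <- lapply(seq_along(conditions), function(k) {
      raw <- simulate_fourc(syn, conditions[k], locus = locus,
                            seed = seed + 1000L * k)
      smooth_profile(
        normalize_profile(locus$fragment_map, raw, syn$bait,
                          norm_window_bp = config$fourc$norm_window_bp),
        k = config$fourc$smooth_window_frags)
    })
    names(profiles) <- conditions
    fractions <- lapply(profiles, domain_fractions, annotation = ann)
    tests <- lapply(names(ann$named_regions), function(lab)
      compare_region_signal(profiles[[1]], profiles[[2]], lab, ann))
    names(tests) <- names(ann$named_regions)
    list(profiles = profiles, fractions = fractions, tests = tests)
  })

  # ---- CHi-C ---------------------------------------------------------
  span <- genomic_interval(syn$chrom, 0, syn$locus_length, "capture")
  chic <- stage("chic", {
    mats5 <- list(); mats10 <- list(); boundaries <- list()
    for (k in seq_along(conditions)) {
      pairs <- simulate_chic(syn, conditions[k], seed = seed + 2000L * k)
      pairs <- filter_pairs(pairs, span, mapq_min = config$chic$mapq_min)
      mats5[[k]] <- balance_ice(bin_pairs(pairs, span,
                                          config$chic$bin_size),
                                min_marginal = config$chic$min_marginal)
      mats10[[k]] <- balance_ice(bin_pairs(pairs, span,
                                           config$chic$boundary_bin_size),
                                 min_marginal = config$chic$min_marginal)
      boundaries[[k]] <- call_boundaries(mats10[[k]], w = config$chic$window_w,
                                         p_threshold = config$chic$p_threshold)
    }
    names(mats5) <- names(mats10) <- names(boundaries) <- conditions
    diffm <- subtract_matrices(mats5[[1]], mats5[[2]])
    cmp_cols <- if (length(syn$enhancer_regions)) {
      lab <- if ("CS93" %in% names(syn$enhancer_regions)) "CS93"
             else names(syn$enhancer_regions)[1]
      pad_region(syn$enhancer_regions[[lab]]$interval, 15000)
    } else syn$tdom
    cmp <- compare_submatrices(mats5[[1]], mats5[[2]],
                               rows = syn$cluster, cols = cmp_cols)
    list(mats5 = mats5, boundaries = boundaries, diff = diffm,
         compare = cmp)
  })

  # ---- ChIP ----------------------------------------------------------
  chip <- stage("chip", {
    enrich <- lapply(seq_along(conditions), function(k) {
      reads <- simulate_chip(syn, condition = conditions[k],
                             seed = seed + 3000L * k)
      vapply(names(syn$enhancer_regions), function(lab)
        region_enrichment(reads$chip, reads$input,
                          syn$enhancer_regions[[lab]]$interval,
                          chrom_length = syn$locus_length,
                          pseudocount = config$chip$pseudocount,
                          read_extension = config$chip$read_extension)$enrichment,
        numeric(1))
    })
    names(enrich) <- conditions
    enrich
  })

  # ---- reports -------------------------------------------------------
  params <- list(norm_window_bp = config$fourc$norm_window_bp,
                 smooth_k = config$fourc$smooth_window_frags,
                 pad_bp = config$fourc$pad_bp,
                 chip_bin = config$chip$bin_size,
                 pseudocount = config$chip$pseudocount,
                 extend = config$chip$read_extension,
                 mapq_min = config$chic$mapq_min,
                 chic_bin = config$chic$bin_size,
                 boundary_bin = config$chic$boundary_bin_size,
                 window_w = config$chic$window_w)

  frac_df <- do.call(rbind, lapply(conditions, function(cond) {
    f <- fourc$fractions[[cond]]
    data.frame(condition = cond, domain = names(f$fractions),
               fraction = round(unname(f$fractions), 6))
  }))
  write_report_tsv(frac_df, file.path(out_dir, "fourc_fractions.tsv"),
                   seed, params)

  test_df <- do.call(rbind, lapply(fourc$tests, function(t)
    data.frame(region = t$region, n_pairs = t$n_pairs,
               statistic = t$statistic,
               p_value = signif(t$p_value, 6),
               delta_fraction = round(t$delta_fraction, 6))))
  write_report_tsv(test_df, file.path(out_dir, "fourc_tests.tsv"),
                   seed, params)

  bnd_df <- do.call(rbind, lapply(conditions, function(cond) {
    b <- chic$boundaries[[cond]]
    if (!nrow(b)) return(NULL)
    data.frame(condition = cond, b)
  }))
  if (is.null(bnd_df))
    bnd_df <- data.frame(condition = character(0), bin_index = integer(0),
                         position = numeric(0), bin_signal = numeric(0),
                         p_value = numeric(0), window_w = integer(0))
  write_report_tsv(bnd_df, file.path(out_dir, "chic_boundaries.tsv"),
                   seed, params)

  chip_df <- do.call(rbind, lapply(conditions, function(cond)
    data.frame(condition = cond, region = names(chip[[cond]]),
               enrichment = round(unname(chip[[cond]]), 6))))
  write_report_tsv(chip_df, file.path(out_dir, "chip_enrichment.tsv"),
                   seed, params)

  report <- list(
    version = as.character(utils::packageVersion("tadquant")),
    seed = seed, params = params,
    fourc_fractions = lapply(fourc$fractions, function(f)
      as.list(round(f$fractions, 6))),
    fourc_tests = lapply(fourc$tests, function(t)
      list(n_pairs = t$n_pairs, p_value = signif(t$p_value, 6),
           delta_fraction = round(t$delta_fraction, 6))),
    chic_boundaries = lapply(chic$boundaries, function(b)
      as.list(b$position)),
    chic_compare = list(p_value = signif(chic$compare$p_value, 6),
                        n_pairs = chic$compare$n_pairs),
    chip_enrichment = lapply(chip, function(e) as.list(round(e, 6))),
    ground_truth = locus$ground_truth)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
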