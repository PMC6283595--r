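# 4C profile normalization, smoothing, contact fractions, paired tests.

# fragment map of 12 fragments of 100 bp on chr1, bait in fragment 5
fm12 <- make_fm(seq(0, 1200, by = 100))
bait12 <- genomic_interval("chr1", 440, 460, "bait")

test_that("normalization divides by the in-window mean", {
  raw <- rep(7, 12)
  p <- normalize_profile(fm12, raw, bait12, norm_window_bp = 1e6,
                         mask_bait = FALSE)
  expect_equal(p$normalized, rep(1, 12))

  fm3 <- make_fm(c(0, 100, 200, 300))
  p <- normalize_profile(fm3, c(2, 4, 6), genomic_interval("chr1", 140, 160),
                         norm_window_bp = 1e6, mask_bait = FALSE)
  expect_equal(p$normalized, c(0.5, 1.0, 1.5))
  # in-window non-excluded mean is exactly 1
  expect_equal(mean(p$normalized), 1)
})

test_that("fragments outside the window are rescaled but not averaged", {
  # window of 150 bp captures fragments 4..6 only (midpoints 350,450,550)
  raw <- c(rep(1, 12))
  raw[4:6] <- c(2, 4, 6)
  raw[12] <- 100
  p <- normalize_profile(fm12, raw, bait12, norm_window_bp = 150,
                         mask_bait = FALSE)
  expect_equal(p$normalized[4:6], c(2, 4, 6) / 4)
  expect_equal(p$normalized[12], 100 / 4)  # same constant applied
})

test_that("normalization error and exclusion contracts hold", {
  expect_error(normalize_profile(fm12, rep(0, 12), bait12, mask_bait = FALSE),
               "no signal")
  # bait masking excludes bait fragment and both flanks
  p <- normalize_profile(fm12, rep(1, 12), bait12)
  expect_equal(p$excluded, 4:6)
  # excluded fragments do not shape the mean
  raw <- rep(1, 12); raw[5] <- 1000
  p <- normalize_profile(fm12, raw, bait12)
  expect_equal(p$normalized[1], 1)
})

test_that("normalization is idempotent", {
  set.seed(11)
  raw <- rpois(12, 20)
  p1 <- normalize_profile(fm12, raw, bait12, mask_bait = FALSE)
  p2 <- normalize_profile(fm12, p1$normalized, bait12, mask_bait = FALSE)
  expect_equal(p2$normalized, p1$normalized)
})

test_that("running-mean smoothing matches the windowed-mean oracle", {
  # constant profile stays constant
  p <- normalize_profile(fm12, rep(3, 12), bait12, mask_bait = FALSE)
  p <- smooth_profile(p, k = 11)
  expect_equal(p$smoothed, rep(1, 12))

  # impulse of k at an interior fragment spreads to 1.0 over k windows
  fm21 <- make_fm(seq(0, 2100, by = 100))
  raw <- rep(0, 21); raw[11] <- 11
  pr <- structure(list(fragment_map = fm21, bait = bait12, raw = raw,
                       normalized = raw, smoothed = NULL,
                       excluded = integer(0), norm_window_bp = 1e6,
                       smooth_window_frags = NA_integer_),
                  class = "fourc_profile")
  sm <- smooth_profile(pr, k = 11)$smoothed
  expect_equal(sm[6:16], rep(1, 11))
  expect_equal(sm[c(1:3, 19:21)], c(0, 0, 0, 0, 0, 0))

  # k = 1 is the identity
  set.seed(5)
  raw <- runif(12)
  p <- normalize_profile(fm12, raw, bait12, mask_bait = FALSE)
  expect_equal(smooth_profile(p, k = 1)$smoothed, p$normalized)

  # random profiles with exclusions vs brute-force oracle
  for (rep in 1:20) {
    raw <- rpois(12, 10) + 1
    excl <- sample(1:12, 3)
    p <- normalize_profile(fm12, raw, bait12, excluded = excl,
                           mask_bait = FALSE)
    p <- smooth_profile(p, k = 5)
    v <- p$normalized
    v[excl] <- NA
    expect_equal(p$smoothed, running_mean_oracle(v, 5))
  }
})

test_that("smoothing conserves total signal away from edges", {
  fm40 <- make_fm(seq(0, 4000, by = 100))
  raw <- rep(0, 40); raw[15:25] <- rpois(11, 50) + 1
  p <- normalize_profile(fm40, raw, genomic_interval("chr1", 1990, 2010),
                         mask_bait = FALSE)
  p <- smooth_profile(p, k = 11)
  expect_equal(sum(p$smoothed), sum(p$normalized), tolerance = 1e-9)
})

test_that("domain fractions sum to one and match hand-computed sums", {
  ann <- toy_annotation()
  fm <- make_fm(seq(0, 1200, by = 100))  # midpoints 50,150,...,1150
  # tdom: frags 1-4; cluster: 5; cdom: frags 6-8; next_tad: 9-12
  raw <- rep(0, 12)
  raw[1:2] <- c(3, 2); raw[6] <- 5
  bait <- genomic_interval("chr1", 440, 460)
  p <- normalize_profile(fm, raw, bait, mask_bait = FALSE)
  rep1 <- domain_fractions(p, ann)
  expect_equal(unname(rep1$fractions["tdom"]), 0.5)
  expect_equal(unname(rep1$fractions["cdom"]), 0.5)
  expect_equal(sum(rep1$fractions), 1)

  # all signal in tdom
  raw2 <- rep(0, 12); raw2[2] <- 4
  p2 <- normalize_profile(fm, raw2, bait, mask_bait = FALSE)
  rep2 <- domain_fractions(p2, ann)
  expect_equal(unname(rep2$fractions["tdom"]), 1)

  # three-domain mode: tdom 6, cdom 2, next_tad 2
  raw3 <- rep(0, 12); raw3[1] <- 6; raw3[6] <- 2; raw3[10] <- 2
  p3 <- normalize_profile(fm, raw3, bait, mask_bait = FALSE)
  rep3 <- domain_fractions(p3, ann, domain_set = c("cdom", "tdom", "next_tad"))
  expect_equal(unname(rep3$fractions[c("tdom", "cdom", "next_tad")]),
               c(0.6, 0.2, 0.2))
  expect_equal(sum(rep3$fractions), 1)
})

test_that("cluster exclusion and named-region fractions use the domain denominator", {
  ann <- toy_annotation(pad_bp = 0)
  fm <- make_fm(seq(0, 1200, by = 100))
  raw <- rep(0, 12); raw[2] <- 6; raw[5] <- 99; raw[6] <- 2
  p <- normalize_profile(fm, raw, genomic_interval("chr1", 440, 460),
                         mask_bait = FALSE)
  rep1 <- domain_fractions(p, ann, exclude_cluster = TRUE)
  # cluster fragment is outside both domains anyway; fractions from 6 vs 2
  expect_equal(unname(rep1$fractions["tdom"]), 0.75)
  # named region [100,200) holds fragment 2 only
  expect_equal(unname(rep1$region_fractions["reg"]), 0.75)
  expect_error(domain_fractions(
    normalize_profile(fm, c(rep(0, 4), 1, rep(0, 7)),
                      genomic_interval("chr1", 440, 460), mask_bait = FALSE),
    ann), "denominator")
})

test_that("fraction conservation holds on random profiles", {
  ann <- toy_annotation()
  fm <- make_fm(seq(0, 1200, by = 50))
  set.seed(23)
  for (rep in 1:25) {
    raw <- rpois(nrow(fm), 5)
    p <- try(normalize_profile(fm, raw, genomic_interval("chr1", 440, 460),
                               mask_bait = FALSE), silent = TRUE)
    if (inherits(p, "try-error")) next
    for (ds in list(c("cdom", "tdom"), c("cdom", "tdom", "next_tad"))) {
      r <- try(domain_fractions(p, ann, domain_set = ds), silent = TRUE)
      if (inherits(r, "try-error")) next
      expect_equal(sum(r$fractions), 1, tolerance = 1e-9)
      expect_true(all(r$fractions >= 0))
    }
  }
})

test_that("paired region comparison tests fragment signal and reports deltas", {
  ann <- toy_annotation(pad_bp = 0)
  fm <- make_fm(seq(0, 1200, by = 50))  # region [100,200) = frags 3,4
  bait <- genomic_interval("chr1", 440, 460)
  set.seed(31)
  raw <- rpois(nrow(fm), 20) + 1
  pA <- normalize_profile(fm, raw, bait, mask_bait = FALSE)
  res <- compare_region_signal(pA, pA, "reg", ann)
  expect_equal(res$p_value, 1)
  expect_equal(res$n_pairs, 0L)
  expect_equal(res$delta_fraction, 0)

  # systematic doubling inside the region drives W to its maximum
  rawB <- raw
  sel <- 3:4
  rawB[sel] <- rawB[sel] * 5
  pB <- normalize_profile(fm, rawB, bait, mask_bait = FALSE)
  res <- compare_region_signal(pA, pB, "reg", ann)
  expect_equal(res$n_pairs, 2L)
  expect_true(res$delta_fraction > 0)
  # a genomic_interval region with wider support detects the shift
  wide <- genomic_interval("chr1", 0, 400, "tdom_region")
  res2 <- compare_region_signal(pA, pB, wide, ann)
  expect_true(res2$n_pairs >= 8)
  expect_true(res2$p_value <= 1)
})

test_that("profiles round-trip through bedGraph", {
  fm <- make_fm(seq(0, 1200, by = 100))
  set.seed(2)
  raw <- rpois(12, 30) + 1
  p <- normalize_profile(fm, raw, genomic_interval("chr1", 440, 460),
                         mask_bait = FALSE)
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  write_profile_bedgraph(p, bg, which = "normalized")
  back <- read_fragment_scores(bg, fm)
  expect_equal(back, p$normalized)
})
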