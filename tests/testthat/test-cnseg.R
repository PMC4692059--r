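make_track <- function(values, chrom = "chr1", spacing = 1000) {
  tibble::tibble(chrom = chrom, pos = seq_along(values) * spacing,
                 S01 = values)
}

test_that("median normalisation centres and is idempotent", {
  set.seed(1)
  x <- rnorm(200) + 0.3
  t1 <- normalize_markers(make_track(x))
  expect_equal(median(t1$S01), 0, tolerance = 1e-12)
  expect_equal(t1$S01, x - median(x))
  expect_equal(normalize_markers(t1)$S01, t1$S01)
})

test_that("lowess mode removes an intensity-dependent trend", {
  set.seed(2)
  intensity <- runif(500, 6, 14)
  bias <- 0.08 * (intensity - 10)
  x <- bias + rnorm(500, 0, 0.05)
  t1 <- normalize_markers(make_track(x), method = "lowess",
                          intensity = intensity)
  slope <- coef(lm(t1$S01 ~ intensity))[2]
  expect_lt(abs(slope), 0.01)
})

test_that("constant tracks yield one segment per chromosome", {
  mk <- tibble::tibble(chrom = rep(c("chr1", "chr2"), each = 60),
                       pos = rep(seq_len(60) * 1000, 2),
                       S01 = 0.25)
  seg <- segment_markers(mk, seg_params(n_permutations = 100), seed = 1)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$n_markers, c(60, 60))
  expect_equal(seg$seg_mean, c(0.25, 0.25))
})

test_that("a noiseless step is cut exactly at the plant boundary", {
  x <- c(rep(0, 50), rep(1, 50))
  seg <- segment_markers(make_track(x), seg_params(), seed = 1)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$n_markers, c(50, 50))
  expect_equal(seg$seg_mean, c(0, 1))
})

test_that("noisy steps are placed within 2 markers of truth and match the single-split oracle", {
  set.seed(30)
  n_ok <- 0
  for (rep in 1:5) {
    x <- c(rep(0, 30), rep(1, 30)) + rnorm(60, 0, 0.2)
    seg <- segment_markers(make_track(x), seg_params(), seed = rep)
    expect_equal(nrow(seg), 2)
    # exhaustive single-split oracle over all admissible cut points
    st <- crcpanel:::cut_t_stats(x, 10)
    oracle_cut <- st$ks[which.max(abs(st$t))]
    expect_equal(seg$n_markers[1], oracle_cut)
    if (abs(seg$n_markers[1] - 30) <= 2) n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 4)
})

test_that("segments tile each chromosome without overlap", {
  spec <- tiny_spec(seed = 8)
  cn <- gen_cn_profiles(spec)
  seg <- segment_markers(normalize_markers(cn$markers),
                         seg_params(n_permutations = 200), seed = 4)
  for (s in unique(seg$sample)) {
    for (ch in unique(seg$chrom)) {
      sub <- dplyr::arrange(seg[seg$sample == s & seg$chrom == ch, ],
                            start_bp)
      expect_equal(sum(sub$n_markers), 100)
      if (nrow(sub) > 1) {
        expect_true(all(sub$start_bp[-1] == sub$end_bp[-nrow(sub)] + 1))
      }
      pos <- cn$markers$pos[cn$markers$chrom == ch]
      expect_equal(sub$start_bp[1], min(pos))
      expect_equal(sub$end_bp[nrow(sub)], max(pos))
    }
  }
})

test_that("permutation split test is calibrated on pure noise", {
  set.seed(55)
  n_split <- 0
  n_tracks <- 200
  for (i in seq_len(n_tracks)) {
    x <- rnorm(100, 0, 0.2)
    seg <- segment_markers(make_track(x), seg_params(), seed = i)
    n_split <- n_split + (nrow(seg) - 1)
  }
  # alpha = 0.001 per track; binomial 99% upper bound on 200 trials
  upper <- qbinom(0.995, n_tracks, 0.001)
  expect_lte(n_split, max(upper, 3))
})

test_that("gain/loss calls follow the threshold semantics", {
  seg <- tibble::tibble(seg_mean = c(0.2, -0.3, 1.2, 0.15, -0.31, 1.0))
  called <- call_segments(seg)
  expect_equal(called$call,
               c("gain", "neutral", "gain", "neutral", "loss", "gain"))
  expect_equal(called$high_amp, c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_error(call_thresholds(gain = -0.1), "thresholds")
})

test_that("calls are invariant under marker reordering within segments", {
  x <- c(rep(0.5, 50), rep(0, 50))
  seg1 <- call_segments(segment_markers(make_track(x), seg_params(), seed = 1))
  x2 <- c(x[sample(1:50)], x[50 + sample(1:50)])
  seg2 <- call_segments(segment_markers(make_track(x2), seg_params(), seed = 1))
  expect_equal(seg1$call, seg2$call)
  expect_equal(seg1$seg_mean, seg2$seg_mean)
})

test_that("region size arithmetic is Mb at two decimals", {
  expect_equal(region_size_mb(144656, 25059988), 24.92)
  expect_equal(region_size_mb(88741497, 89240742), 0.5)
  expect_equal(region_size_mb(5, 5), 0)
  expect_error(region_size_mb(10, 5), ">=")
})

test_that("recurrent regions match the toy example and its per-base oracle", {
  calls <- tibble::tibble(
    sample = c("A", "B", "C"), chrom = "chr1",
    start_bp = c(100, 150, 180), end_bp = c(200, 250, 220),
    call = "gain")
  expect_warning(
    empty <- find_recurrent_regions(calls[1, ], "gain", min_support = 7),
    "min_support")
  expect_equal(nrow(empty), 0)

  reg <- find_recurrent_regions(calls, "gain", min_support = 3)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start_bp, 180)
  expect_equal(reg$end_bp, 200)
  expect_setequal(reg$supporting[[1]], c("A", "B", "C"))
  oracle <- per_base_recurrence(calls, "gain", 3, 300)
  expect_equal(reg$start_bp, oracle$start_bp)
  expect_equal(reg$end_bp, oracle$end_bp)
})

test_that("recurrent-region finder equals the per-base oracle on random instances", {
  set.seed(77)
  for (i in 1:50) {
    n_samp <- sample(3:6, 1)
    calls <- purrr::map(seq_len(n_samp), function(s) {
      k <- sample(1:3, 1)
      starts <- sort(sample(1:80, k))
      tibble::tibble(sample = paste0("S", s), chrom = "chr1",
                     start_bp = starts,
                     end_bp = pmin(starts + sample(5:40, k, replace = TRUE),
                                   100),
                     call = sample(c("gain", "loss"), k, replace = TRUE))
    }) |> purrr::list_rbind()
    # drop overlapping intervals within a sample (segments cannot overlap)
    calls <- calls |>
      dplyr::group_by(sample) |>
      dplyr::arrange(start_bp, .by_group = TRUE) |>
      dplyr::filter(dplyr::row_number() == 1 |
                      start_bp > cummax(dplyr::lag(end_bp,
                                                   default = 0L))) |>
      dplyr::ungroup()
    min_sup <- sample(2:3, 1)
    reg <- find_recurrent_regions(calls, "gain", min_support = min_sup)
    oracle <- per_base_recurrence(calls, "gain", min_sup, 120)
    expect_equal(nrow(reg), nrow(oracle))
    if (nrow(reg)) {
      expect_equal(reg$start_bp, oracle$start_bp)
      expect_equal(reg$end_bp, oracle$end_bp)
    }
  }
})

test_that("segment-profile clustering matches brute-force agglomeration", {
  segs <- purrr::map2(
    c("A", "B", "C", "D"),
    list(c(0, 0), c(0, 0), c(1, 0), c(1, 2)),
    function(s, means) {
      tibble::tibble(sample = s, chrom = "chr1",
                     start_bp = c(1, 51), end_bp = c(50, 100),
                     n_markers = 50L, seg_mean = means)
    }) |> purrr::list_rbind()
  tree <- cluster_segment_profiles(segs)
  expect_equal(tree$height[1], 0, tolerance = 1e-12)  # duplicates merge first
  mat <- rbind(A = c(0, 0), B = c(0, 0), C = c(1, 0), D = c(1, 2))
  oracle <- brute_force_agglomeration(dist(mat), "average")
  expect_equal(sort(tree$height), sort(oracle), tolerance = 1e-9)
})

test_that("a genome-wide amplified sample separates as an outgroup", {
  spec <- tiny_spec(seed = 9, planted = tibble::tibble(
    chrom = "chr1", start_marker = 1L, end_marker = 100L, level = 2,
    carriers = list("S06")))
  cn <- gen_cn_profiles(spec)
  seg <- segment_markers(normalize_markers(cn$markers),
                         seg_params(n_permutations = 200), seed = 2)
  tree <- cluster_segment_profiles(seg)
  # the outgroup joins last: it is alone on one side of the final merge
  final <- tree$merge[nrow(tree$merge), ]
  singleton <- final[final < 0]
  expect_equal(tree$labels[-singleton], "S06")
})
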