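test_that("quantile normalisation maps columns onto shared order statistics", {
  same <- tibble::tibble(gene = c("a", "b", "c"),
                         s1 = c(3, 1, 2), s2 = c(3, 1, 2))
  expect_equal(quantile_normalize(same), same)

  two <- tibble::tibble(gene = c("a", "b", "c"),
                        s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  qn <- quantile_normalize(two)
  expect_equal(qn$s1, c(2.5, 3.5, 4.5))
  expect_equal(qn$s2, c(2.5, 3.5, 4.5))

  set.seed(4)
  big <- dplyr::bind_cols(
    tibble::tibble(gene = sprintf("g%03d", 1:100)),
    tibble::as_tibble(matrix(rnorm(500), 100, 5,
                             dimnames = list(NULL, paste0("s", 1:5)))))
  qn1 <- quantile_normalize(big)
  m <- as.matrix(qn1[, -1])
  sorted <- apply(m, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  expect_equal(quantile_normalize(qn1), qn1, tolerance = 1e-12)  # idempotent
})

test_that("detection filter keeps features detected in at least one sample", {
  expr <- tibble::tibble(gene = sprintf("g%d", 1:5),
                         s1 = 1:5, s2 = 1:5, s3 = 1:5)
  det <- tibble::tibble(gene = sprintf("g%d", 1:5),
                        s1 = c(0.01, 0.50, 0.50, 0.04, 0.50),
                        s2 = c(0.01, 0.50, 0.06, 0.50, 0.50),
                        s3 = c(0.01, 0.50, 0.50, 0.50, 0.05))
  expect_equal(detection_filter(expr, det)$gene, c("g1", "g4", "g5"))
  expect_equal(detection_filter(expr, det, scope = "all")$gene, "g1")
  all_good <- dplyr::mutate(det, s1 = 0.01, s2 = 0.01, s3 = 0.01)
  expect_equal(nrow(detection_filter(expr, all_good)), 5)
  expect_error(detection_filter(expr, det[1:3, ]), "identical")
})

test_that("log2 mean centring gives zero row means and exact small cases", {
  m <- tibble::tibble(gene = c("const", "pair"),
                      s1 = c(4, 2), s2 = c(4, 8))
  ct <- log2_mean_center(m)
  expect_equal(as.numeric(ct[1, -1]), c(0, 0))
  expect_equal(as.numeric(ct[2, -1]), c(-1, 1))
  expect_error(log2_mean_center(tibble::tibble(gene = "g", s1 = -1, s2 = 2)),
               "non-positive")
})

test_that("Mann-Whitney tests match full enumeration for small groups", {
  df <- tibble::tibble(gene = "g",
                       s1 = 1, s2 = 2, s3 = 3, s4 = 10, s5 = 11, s6 = 12)
  cls <- setNames(rep(c("a", "b"), each = 3), paste0("s", 1:6))
  res <- mannwhitney_feature_tests(df, cls)
  expect_equal(res$p, 0.1)  # complete separation, 2/20 assignments as extreme
  expect_equal(res$p, mw_enumeration_p(c(1, 2, 3), c(10, 11, 12)))

  # identical (tied) groups: symmetric statistic, p = 1
  tied <- tibble::tibble(gene = "g", s1 = 5, s2 = 5, s3 = 5,
                         s4 = 5, s5 = 5, s6 = 5)
  expect_equal(mannwhitney_feature_tests(tied, cls)$p, 1)

  # random untied cases agree with the enumeration oracle exactly
  set.seed(12)
  for (i in 1:10) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    df <- dplyr::bind_cols(
      tibble::tibble(gene = "g"),
      tibble::as_tibble(as.list(setNames(c(x, y),
                                         paste0("s", seq_len(n1 + n2))))))
    cls <- setNames(rep(c("a", "b"), c(n1, n2)), paste0("s", seq_len(n1 + n2)))
    res <- mannwhitney_feature_tests(df, cls)
    expect_equal(res$p, mw_enumeration_p(x, y), tolerance = 1e-12)
  }
})

test_that("exact and normal-approximation p-values agree for 7 vs 8", {
  set.seed(13)
  diffs <- replicate(100, {
    x <- rnorm(7); y <- rnorm(8)
    p_exact <- wilcox.test(x, y, exact = TRUE)$p.value
    p_approx <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    abs(p_exact - p_approx)
  })
  expect_lt(max(diffs), 0.02)
})

test_that("Mann-Whitney type I error is controlled under the null", {
  set.seed(14)
  n_feat <- 1000
  mat <- matrix(rnorm(n_feat * 15), n_feat, 15,
                dimnames = list(sprintf("g%04d", 1:n_feat), paste0("s", 1:15)))
  df <- dplyr::bind_cols(tibble::tibble(gene = rownames(mat)),
                         tibble::as_tibble(mat))
  cls <- setNames(rep(c("a", "b"), c(8, 7)), paste0("s", 1:15))
  res <- mannwhitney_feature_tests(df, cls)
  frac <- mean(res$p < 0.05)
  # discrete exact test: attainable level is at most nominal
  bound <- 2.58 * sqrt(0.05 * 0.95 / n_feat)
  expect_lt(frac, 0.05 + bound)
  expect_gt(frac, 0.01)
})

test_that("SAM flags a planted shift and gates by fold change", {
  set.seed(15)
  n_null <- 50
  mat <- matrix(rnorm((n_null + 1) * 8, 0, 0.3), n_null + 1, 8)
  mat[1, 1:4] <- mat[1, 1:4] + 2          # 4-fold shift on the log2 scale
  df <- dplyr::bind_cols(
    tibble::tibble(gene = c("planted", sprintf("null%02d", 1:n_null))),
    tibble::as_tibble(matrix(mat, ncol = 8,
                             dimnames = list(NULL, paste0("s", 1:8)))))
  cls <- setNames(rep(c("a", "b"), each = 4), paste0("s", 1:8))
  res <- sam_differential(df, cls)
  expect_true(attr(res, "exact"))                       # 70 splits enumerated
  expect_equal(res$gene[which.max(abs(res$d))], "planted")
  expect_lt(res$q[res$gene == "planted"], min(res$q[res$gene != "planted"]))

  # independent oracle: expected false positives at the planted |d| from
  # explicit enumeration of all 70 label splits
  splits <- utils::combn(8, 4, simplify = FALSE)
  m <- as.matrix(df[, -1])
  s0 <- attr(res, "s0")
  null_abs <- sapply(splits, function(idx) {
    st <- crcpanel:::sam_stats(m, idx, setdiff(1:8, idx), s0)
    abs(st$d)
  })
  abs_d <- abs(res$d)
  q_raw <- vapply(abs_d, function(th) {
    min(1, (sum(null_abs >= th - 1e-12) / length(splits)) /
          sum(abs_d >= th - 1e-12))
  }, numeric(1))
  ord_o <- order(-abs_d)
  q_raw[ord_o] <- rev(cummin(rev(q_raw[ord_o])))
  expect_equal(res$q, q_raw, tolerance = 1e-12)

  # q is monotone non-decreasing in decreasing |d|
  ord <- order(-abs(res$d))
  expect_true(all(diff(res$q[ord]) >= -1e-12))

  # a 1.4-fold shift is excluded by the fold-change gate regardless of d
  df2 <- df
  df2[1, 2:5] <- df2[1, 2:5] - 2 + log2(1.4)
  res2 <- sam_differential(df2, cls)
  expect_false(res2$significant[res2$gene == "planted"])
})

test_that("SAM returns an empty result on class-balanced data", {
  df <- tibble::tibble(gene = c("g1", "g2"),
                       s1 = c(1, 2), s2 = c(2, 3), s3 = c(3, 4),
                       s4 = c(1, 2), s5 = c(2, 3), s6 = c(3, 4))
  cls <- setNames(rep(c("a", "b"), c(3, 3)), paste0("s", 1:6))
  res <- sam_differential(df, cls)
  expect_true(all(res$d == 0))
  expect_equal(sum(res$significant), 0)
})

test_that("RPPA preprocessing is median-based and centred", {
  spots <- tidyr::expand_grid(antibody = c("A", "B"),
                              sample = c("s1", "s2"), spot = 1:3)
  spots$intensity <- c(100, 100, 100,  90, 100, 200,
                       50, 60, 70,     80, 80, 80)
  out <- rppa_preprocess(spots)
  m <- as.matrix(out$matrix[, -1])
  expect_equal(rowMeans(m), c(0, 0), ignore_attr = TRUE)
  # medians behind the centring: (100, 100) and (60, 80)
  expect_equal(m[1, "s1"] - m[1, "s2"], log2(100 / 100), ignore_attr = TRUE)
  expect_equal(m[2, "s1"] - m[2, "s2"], log2(60 / 80), ignore_attr = TRUE)

  full <- rppa_preprocess(gen_rppa(panel_spec(seed = 6)))
  expect_equal(dim(full$matrix), c(31, 16))
  expect_true(all(abs(rowMeans(as.matrix(full$matrix[, -1]))) < 1e-12))
})

test_that("hierarchical clustering matches brute force and is scale invariant", {
  set.seed(16)
  m <- matrix(rnorm(25), 5, 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:5)))
  m[2, ] <- m[1, ]
  df <- dplyr::bind_cols(tibble::tibble(gene = rownames(m)),
                         tibble::as_tibble(m))
  for (link in c("average", "complete")) {
    tree <- hcluster(df, distance = "euclidean", linkage = link)
    oracle <- brute_force_agglomeration(dist(m), link)
    expect_equal(sort(tree$height), sort(oracle), tolerance = 1e-9)
    expect_equal(tree$height[1], 0, tolerance = 1e-12)
  }
  t1 <- hcluster(df, distance = "correlation")
  df10 <- df; df10[3, -1] <- df10[3, -1] * 10
  t2 <- hcluster(df10, distance = "correlation")
  expect_equal(t1$height, t2$height, tolerance = 1e-12)
  expect_equal(t1$merge, t2$merge)
})
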