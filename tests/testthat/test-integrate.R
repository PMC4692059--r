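test_that("gene-region overlap uses the any-overlap rule", {
  ann <- tibble::tibble(gene = c("out", "straddle", "inside"),
                        chrom = "chr1",
                        start_bp = c(500, 95, 120),
                        end_bp = c(600, 100, 150))
  reg <- tibble::tibble(chrom = "chr1", start_bp = 100, end_bp = 200)
  expect_equal(genes_in_regions(ann, reg), c("inside", "straddle"))
  expect_error(
    genes_in_regions(dplyr::mutate(ann, chrom = "1"), reg),
    "mismatch")
})

test_that("gene-region overlap equals a per-base oracle on random instances", {
  set.seed(21)
  for (i in 1:10) {
    ann <- tibble::tibble(
      gene = sprintf("g%03d", 1:100), chrom = "chr1",
      start_bp = sample(1:900, 100, replace = TRUE)) |>
      dplyr::mutate(end_bp = start_bp + sample(1:50, 100, replace = TRUE))
    reg <- tibble::tibble(
      chrom = "chr1", start_bp = sample(1:900, 10)) |>
      dplyr::mutate(end_bp = start_bp + sample(10:80, 10, replace = TRUE))
    got <- genes_in_regions(ann, reg)
    covered <- logical(1000)
    for (j in seq_len(nrow(reg))) {
      covered[reg$start_bp[j]:reg$end_bp[j]] <- TRUE
    }
    oracle <- ann$gene[purrr::map_lgl(
      seq_len(nrow(ann)),
      ~ any(covered[ann$start_bp[.x]:ann$end_bp[.x]]))]
    expect_setequal(got, oracle)
  }
})

test_that("gene-level copy number is the overlap-weighted segment mean", {
  seg <- tibble::tibble(sample = "S1", chrom = "chr1",
                        start_bp = c(1, 1001), end_bp = c(1000, 2000),
                        n_markers = 10L, seg_mean = c(0, 1))
  ann <- tibble::tibble(gene = c("in1", "half"), chrom = "chr1",
                        start_bp = c(101, 501), end_bp = c(200, 1500))
  cn <- gene_cn_values(ann, seg)
  expect_equal(cn$cn[cn$gene == "in1"], 0)
  expect_equal(cn$cn[cn$gene == "half"], 0.5)
  # weights cover the full gene for every gene inside the tiled span
  ov1 <- crcpanel:::overlap_bp(seg$start_bp, seg$end_bp, 501, 1500)
  expect_equal(sum(ov1), 1500 - 501 + 1)
  # chromosome absent from segmentation gives NA
  ann2 <- tibble::tibble(gene = "lost", chrom = "chr9",
                         start_bp = 1, end_bp = 10)
  expect_true(is.na(gene_cn_values(ann2, seg)$cn))
})

test_that("copy-number/expression correlation follows the t transform", {
  # noiseless dosage gene: r exactly 1, passes
  cn <- tibble::tibble(gene = "g", sample = paste0("s", 1:6),
                       cn = c(0, 0, 0, 1, 1, 1))
  expr <- tibble::tibble(gene = "g", s1 = 5, s2 = 5, s3 = 5,
                         s4 = 6, s5 = 6, s6 = 6)
  res <- correlate_cn_expr(cn, expr)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_true(res$passes)

  # r = 0.395 with n = 15: two-sided p from the t distribution with 13 df
  r <- 0.395; n <- 15
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p_oracle <- 2 * pt(-abs(t_stat), df = n - 2)
  expect_equal(p_oracle, 0.145, tolerance = 0.005)
  # construct data achieving that r and confirm the pipeline p agrees
  set.seed(22)
  x <- rnorm(n)
  y <- r * scale(x)[, 1] + sqrt(1 - r^2) * scale(resid(lm(rnorm(n) ~ x)))[, 1]
  got_r <- cor(x, y)
  cn2 <- tibble::tibble(gene = "g", sample = paste0("s", 1:15), cn = x)
  expr2 <- dplyr::bind_cols(
    tibble::tibble(gene = "g"),
    tibble::as_tibble(as.list(setNames(y, paste0("s", 1:15)))))
  res2 <- correlate_cn_expr(cn2, expr2, family_size = 1)
  expect_equal(res2$r, got_r, tolerance = 1e-9)
  expect_equal(res2$p,
               2 * pt(-abs(got_r * sqrt(13) / sqrt(1 - got_r^2)), 13),
               tolerance = 1e-9)
  expect_false(correlate_cn_expr(cn2, expr2, family_size = 667)$passes)
})

test_that("Bonferroni passing is monotone in family size", {
  set.seed(23)
  cn <- tibble::tibble(gene = "g", sample = paste0("s", 1:10),
                       cn = rnorm(10))
  y <- cn$cn + rnorm(10, 0, 0.2)
  expr <- dplyr::bind_cols(
    tibble::tibble(gene = "g"),
    tibble::as_tibble(as.list(setNames(y, paste0("s", 1:10)))))
  for (fam in c(1, 5, 50, 500)) {
    small <- correlate_cn_expr(cn, expr, family_size = fam)
    if (small$passes) {
      for (fam2 in c(1, 2, fam - 1)) {
        if (fam2 >= 1 && fam2 < fam) {
          expect_true(correlate_cn_expr(cn, expr, family_size = fam2)$passes)
        }
      }
    }
  }
})

test_that("treatment association flags planted response genes with exact p", {
  # 7v8 split with a clean 2-fold (1 log2 unit) shift in the sensitive class
  set.seed(24)
  samples <- paste0("s", 1:15)
  classes <- tibble::tibble(drug = "5-FU", sample = samples,
                            sensitivity = rep(c("sensitive",
                                                "less_sensitive"), c(7, 8)))
  resp_vals <- c(8 + runif(7, 0, 0.1), 7 + runif(8, 0, 0.1))
  expr <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(gene = "flat"),
                     tibble::as_tibble(as.list(setNames(rep(5, 15),
                                                        samples)))),
    dplyr::bind_cols(tibble::tibble(gene = "resp"),
                     tibble::as_tibble(as.list(setNames(resp_vals,
                                                        samples)))))
  res <- treatment_association(expr, classes)
  expect_false(res$associated[res$gene == "flat"])
  expect_true(res$associated[res$gene == "resp"])
  # complete separation at 7v8: exact two-sided p = 2 / choose(15, 7)
  expect_equal(res$p[res$gene == "resp"], 2 / choose(15, 7),
               tolerance = 1e-9)

  degenerate <- dplyr::mutate(classes, sensitivity = "sensitive")
  expect_warning(out <- treatment_association(expr, degenerate),
                 "degenerate")
  expect_equal(nrow(out), 0)
})

test_that("ledger set algebra is exact and validates membership", {
  empty <- build_ledger(character(0), list(a = character(0),
                                           b = character(0)))
  expect_equal(length(empty$union), 0)

  correlated <- c("A", "B", "C", "D", "E")
  lists <- list(d1 = c("A", "B", "C"), d2 = c("B", "C", "D"),
                d3 = c("C", "E"))
  led <- build_ledger(correlated, lists)
  expect_equal(led$union, c("A", "B", "C", "D", "E"))
  expect_equal(led$threeway, "C")
  expect_equal(led$pairwise[["d1 & d2"]], c("B", "C"))
  # brute-force check over all genes
  for (g in correlated) {
    expect_equal(g %in% led$union,
                 any(purrr::map_lgl(lists, ~ g %in% .x)))
    expect_equal(g %in% led$threeway,
                 all(purrr::map_lgl(lists, ~ g %in% .x)))
  }
  # three-way is inside every pairwise intersection
  for (pw in led$pairwise) expect_true(all(led$threeway %in% pw))

  expect_error(build_ledger(c("A", "B"), list(d1 = c("A", "Z"))), "Z")
  aliased <- build_ledger(c("A", "B"), list(d1 = c("A", "Z")),
                          aliases = c(Z = "B"))
  expect_equal(aliased$per_drug$d1, c("A", "B"))
})

test_that("codon substitution calls translate hotspot variants", {
  fx <- load_fixtures()
  expect_equal(call_codon_substitution(fx$kras_cds, 38, "G", "A"), "G13D")
  expect_equal(call_codon_substitution(fx$kras_cds, 35, "G", "T"), "G12V")
  expect_equal(call_codon_substitution(fx$kras_cds, 34, "G", "T"), "G12C")
  # third-base wobble: GGT -> GGC stays glycine
  expect_equal(call_codon_substitution(fx$kras_cds, 36, "T", "C"), "silent")
  expect_error(call_codon_substitution(fx$kras_cds, 38, "A", "T"),
               "mismatch")
})

test_that("genotype stratification reuses the exact rank test", {
  ic50 <- tibble::tibble(drug = "5-FU", sample = paste0("s", 1:6),
                         ic50 = c(1, 2, 3, 1, 2, 3))
  status <- tibble::tibble(sample = paste0("s", 1:6),
                           mutant = rep(c(TRUE, FALSE), each = 3))
  expect_equal(genotype_stratification(ic50, status)$p, 1)

  sep <- dplyr::mutate(ic50, ic50 = c(1, 2, 3, 10, 11, 12))
  expect_equal(genotype_stratification(sep, status)$p, 0.1)

  big <- tibble::tibble(drug = "5-FU", sample = paste0("s", 1:15),
                        ic50 = c(rep(50, 8), rep(5, 7)))
  st <- tibble::tibble(sample = paste0("s", 1:15),
                       mutant = rep(c(TRUE, FALSE), c(8, 7)))
  expect_lt(genotype_stratification(big, st)$p, 0.01)
  expect_error(
    genotype_stratification(big, dplyr::mutate(st, mutant = TRUE)),
    "non-empty")
})

test_that("planted dosage genes are recovered among nulls across seeds", {
  hits <- integer(0); false_pos <- integer(0)
  for (seed in 1:20) {
    spec <- panel_spec(seed = seed)
    truth <- panel_truth(spec)
    ex <- gen_expression(spec, truth)
    res <- correlate_cn_expr(truth$gene_cn, ex$expr)
    passing <- res$gene[res$passes]
    hits <- c(hits, sum(grepl("^DOSE", passing)))
    false_pos <- c(false_pos, sum(grepl("^NULL", passing)))
  }
  good_runs <- sum(hits >= 18 & false_pos == 0)
  expect_gte(good_runs, 17)
})
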