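# Shared fixtures built in code: small panel specs that keep the unit tests
# fast while exercising the same machinery as the full defaults.

tiny_spec <- function(seed = 1, marker_sd = 0.2, n_null_genes = 0,
                      planted = NULL) {
  if (is.null(planted)) {
    planted <- tibble::tibble(
      chrom = "chr1", start_marker = 40L, end_marker = 70L, level = 1,
      carriers = list(sprintf("S%02d", 1:4))
    )
  }
  panel_spec(
    n_samples = 6,
    chrom_lengths = tibble::tibble(chrom = c("chr1", "chr2"),
                                   n_markers = 100L, spacing_bp = 100000L),
    planted_segments = planted,
    marker_sd = marker_sd,
    dosage_genes = tibble::tibble(
      gene = c("DG1", "DG2"), chrom = "chr1",
      start_bp = c(4500000L, 6000000L), end_bp = c(4600000L, 6100000L),
      slope = 1, noise_sd = 0.3),
    n_null_genes = n_null_genes,
    true_ic50 = tibble::tibble(
      drug = "5-FU", sample = sprintf("S%02d", 1:6),
      ic50 = c(5, 10, 20, 40, 80, NA),
      censored = c(rep(FALSE, 5), TRUE)),
    drug_grids = tibble::tibble(
      drug = "5-FU", unit = "uM",
      conc = list(exp(seq(log(2.5), log(100), length.out = 8)))),
    curve_shape = tibble::tibble(drug = "5-FU", top = 100, bottom = 0,
                                 hill = 1),
    fish_spec = tibble::tibble(core = sprintf("c%02d", 1:10), n_nuclei = 20L,
                               mean_red = c(rep(2, 8), 4, 4),
                               mean_green = 2),
    rppa_antibodies = sprintf("AB%02d", 1:5),
    seed = seed
  )
}

# Exhaustive agglomeration oracle: at each step merge the pair with the
# smallest linkage distance (ties by first index), recomputing distances by
# brute force.  Returns the merge heights, comparable to hclust$height.
brute_force_agglomeration <- function(d, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dij <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        val <- if (linkage == "average") mean(dij) else max(dij)
        if (val < best[1] - 1e-12) best <- c(val, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

# Per-base brute-force recurrent-region oracle on small coordinates.
per_base_recurrence <- function(calls, direction, min_support, genome_max) {
  hits <- calls[calls$call == direction, ]
  counts <- matrix(0L, nrow = length(unique(calls$sample)), ncol = genome_max,
                   dimnames = list(unique(calls$sample), NULL))
  for (i in seq_len(nrow(hits))) {
    counts[hits$sample[i], hits$start_bp[i]:hits$end_bp[i]] <- 1L
  }
  tot <- colSums(counts)
  keep <- tot >= min_support
  if (!any(keep)) {
    return(tibble::tibble(start_bp = integer(0), end_bp = integer(0)))
  }
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble::tibble(start_bp = starts[r$values], end_bp = ends[r$values])
}

# All permutations of 1..n as rows of a matrix (n small).
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1
  for (i in seq_len(nrow(sub))) {
    for (k in seq_len(n)) {
      out[row, ] <- append(sub[i, ], n, after = k - 1)
      row <- row + 1
    }
  }
  out
}

# Full-enumeration two-sided Mann-Whitney oracle (no ties).
mw_enumeration_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_of <- function(idx) {
    xx <- pooled[idx]
    yy <- pooled[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * (n - n1) / 2
  splits <- utils::combn(n, n1, simplify = FALSE)
  us <- vapply(splits, u_of, numeric(1))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
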