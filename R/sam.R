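# SAM-style permutation differential expression: moderated d statistic with
# a variance fudge factor and permutation-based q-values.

sam_stats <- function(m, g1, g2, s0) {
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(m[, g1, drop = FALSE])
  m2 <- rowMeans(m[, g2, drop = FALSE])
  v1 <- apply(m[, g1, drop = FALSE], 1, var)
  v2 <- apply(m[, g2, drop = FALSE], 1, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  s <- sqrt(sp2 * (1 / n1 + 1 / n2))
  denom <- s + s0
  d <- ifelse(denom == 0, 0, (m1 - m2) / denom)
  list(d = unname(d), s = unname(s), m1 = unname(m1), m2 = unname(m2))
}

# All distinct two-class label assignments (size-n1 subsets), or a random
# sample of shuffles when enumeration would exceed `cap`.
label_permutations <- function(n, n1, n_permutations, cap = 500) {
  n_distinct <- choose(n, n1)
  if (n_distinct <= cap) {
    list(idx = combn(n, n1, simplify = FALSE), exact = TRUE)
  } else {
    list(idx = replicate(n_permutations, sample.int(n, n1), simplify = FALSE),
         exact = FALSE)
  }
}

#' SAM-style differential expression against a two-class label
#'
#' For each feature the moderated statistic
#' `d = (mean1 - mean2) / (s + s0)` is computed, with `s` the pooled
#' standard error and `s0` the median of `s` over features (the variance
#' fudge factor).  The null distribution of `|d|` comes from permuted class
#' labels: all distinct label assignments are enumerated when at most 500
#' exist (making p and q exact), otherwise `n_permutations` random shuffles
#' are used, with `s0` held at its observed-data value.  q-values are
#' expected-false-positive counts over observed-positive counts at each
#' feature's `|d|`, made monotone in the `|d|` ranking.  Features are
#' flagged significant when the linear fold change is at least `fc_min`
#' (in either direction) and `q <= q_max`.
#'
#' @param df Feature tibble (log2-scale values; feature id + sample
#'   columns).
#' @param classes Two-class labels (named vector or `sample`/`class`
#'   tibble).
#' @param n_permutations Random label shuffles when enumeration is not
#'   feasible.
#' @param fc_min Minimum linear fold change to report.
#' @param q_max Maximum q-value to report.
#' @param id_col Feature id column name.
#' @return A `sam_result`: tibble with feature id, `mean1`, `mean2`, `fc`
#'   (linear, direction-signed as mean1/mean2 on the linear scale), `d`,
#'   `p`, `q`, `direction`, `significant`, plus attributes `exact`
#'   (enumerated permutations) and `s0`.
#' @export
sam_differential <- function(df, classes, n_permutations = 1000,
                             fc_min = 1.5, q_max = 0.05, id_col = "gene") {
  m <- as_feature_matrix(df, id_col)
  cls <- normalize_classes(classes, colnames(m))
  lv <- levels(cls)
  if (length(lv) != 2) abort("exactly two classes are required")
  g1 <- which(cls == lv[1]); g2 <- which(cls == lv[2])
  if (length(g1) < 3 || length(g2) < 3) {
    warn("fewer than 3 samples in a class; d statistics will be unstable")
  }

  obs0 <- sam_stats(m, g1, g2, s0 = 0)
  s0 <- median(obs0$s)
  obs <- sam_stats(m, g1, g2, s0 = s0)
  d_obs <- obs$d
  abs_obs <- abs(d_obs)

  if (all(d_obs == 0)) {
    res <- tibble(!!id_col := rownames(m), mean1 = obs$m1, mean2 = obs$m2,
                  fc = 2^(obs$m1 - obs$m2), d = 0, p = 1, q = 1,
                  direction = "none", significant = FALSE)
    return(structure(res, class = c("sam_result", class(res)),
                     exact = TRUE, s0 = s0, n_permutations = 0L))
  }

  perms <- label_permutations(ncol(m), length(g1), n_permutations)
  cols <- seq_len(ncol(m))
  null_abs <- map(perms$idx, function(idx1) {
    st <- sam_stats(m, idx1, setdiff(cols, idx1), s0 = s0)
    abs(st$d)
  })
  n_perm <- length(null_abs)
  null_all <- sort(unlist(null_abs))
  n_null <- length(null_all)

  # count of null |d*| >= threshold via binary search on the sorted pool
  exceed_count <- function(thr) {
    n_null - findInterval(thr - 1e-12, null_all)
  }
  # per-feature p: same-feature permuted |d*| >= observed
  null_mat <- do.call(cbind, null_abs)
  p <- (rowSums(null_mat >= abs_obs - 1e-12) + !perms$exact) /
    (n_perm + !perms$exact)

  expected_fp <- map_dbl(abs_obs, exceed_count) / n_perm
  observed_pos <- map_dbl(abs_obs, ~ sum(abs_obs >= .x - 1e-12))
  q <- pmin(1, expected_fp / observed_pos)
  ord <- order(-abs_obs)
  q[ord] <- rev(cummin(rev(q[ord])))

  fc <- 2^(obs$m1 - obs$m2)
  res <- tibble(
    !!id_col := rownames(m),
    mean1 = obs$m1, mean2 = obs$m2, fc = fc, d = d_obs, p = p, q = q,
    direction = dplyr::case_when(d_obs > 0 ~ "up", d_obs < 0 ~ "down",
                                 TRUE ~ "none"),
    significant = pmax(fc, 1 / fc) >= fc_min & q <= q_max
  )
  structure(res, class = c("sam_result", class(res)),
            exact = perms$exact, s0 = s0, n_permutations = n_perm)
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf("<sam_result> %d features, %d significant (s0 = %.3g, %s)\n",
              nrow(x), sum(x$significant), attr(x, "s0"),
              if (isTRUE(attr(x, "exact"))) "exact label enumeration"
              else sprintf("%d permutations", attr(x, "n_permutations"))))
  NextMethod()
}
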