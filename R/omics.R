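# Expression / protein matrix preprocessing and rank-based testing.

as_feature_matrix <- function(df, id_col = "gene") {
  assert_cols(df, id_col, "feature matrix")
  m <- as.matrix(df[, setdiff(names(df), id_col)])
  rownames(m) <- df[[id_col]]
  if (anyDuplicated(rownames(m))) abort("duplicate feature ids")
  if (anyDuplicated(colnames(m))) abort("duplicate sample ids")
  m
}

matrix_to_tibble <- function(m, id_col = "gene") {
  bind_cols(tibble(!!id_col := rownames(m)), as_tibble(m))
}

#' Quantile-normalise a feature-by-sample matrix
#'
#' Each column's sorted values are replaced by the row-wise means of the
#' order statistics across columns; ties receive the mean of their tied
#' targets.  Delegates to [limma::normalizeQuantiles()] with `ties = TRUE`.
#'
#' @param df Tibble with a feature id column plus one column per sample.
#' @param id_col Name of the feature id column.
#' @return Tibble of the same shape, normalised.
#' @export
#' @examples
#' quantile_normalize(tibble::tibble(gene = c("a", "b", "c"),
#'                                   s1 = c(1, 2, 3), s2 = c(4, 5, 6)))
quantile_normalize <- function(df, id_col = "gene") {
  m <- as_feature_matrix(df, id_col)
  if (ncol(m) < 2) abort("need at least 2 samples to quantile normalise")
  if (any(apply(m, 2, function(x) all(is.na(x))))) {
    abort("a sample column is entirely missing")
  }
  matrix_to_tibble(limma::normalizeQuantiles(m, ties = TRUE), id_col)
}

#' Filter features by detection p-value
#'
#' Keeps a feature when its detection p-value is at most `alpha` in at
#' least one sample (`scope = "any"`), or in every sample
#' (`scope = "all"`).
#'
#' @param df Expression tibble (feature id column + sample columns).
#' @param detection Detection p-value tibble of identical shape.
#' @param alpha Detection threshold.
#' @param scope `"any"` (default) or `"all"`.
#' @param id_col Feature id column name.
#' @return The filtered expression tibble.
#' @export
detection_filter <- function(df, detection, alpha = 0.05,
                             scope = c("any", "all"), id_col = "gene") {
  scope <- match.arg(scope)
  m <- as_feature_matrix(df, id_col)
  p <- as_feature_matrix(detection, id_col)
  if (!identical(dim(m), dim(p)) ||
      !identical(rownames(m), rownames(p)) ||
      !identical(colnames(m), colnames(p))) {
    abort("expression and detection tables must have identical features and samples")
  }
  keep <- if (scope == "any") {
    apply(p <= alpha, 1, any)
  } else {
    apply(p <= alpha, 1, all)
  }
  df[keep, , drop = FALSE]
}

#' Log2-transform and mean-centre per feature
#'
#' Values must be positive; after the transform each feature's mean log2
#' value is zero, giving relative values across samples.
#'
#' @inheritParams quantile_normalize
#' @return Tibble of the same shape on the centred log2 scale.
#' @export
log2_mean_center <- function(df, id_col = "gene") {
  m <- as_feature_matrix(df, id_col)
  bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "non-positive values cannot be log2 transformed (first offender: feature %s, sample %s)",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  lm2 <- log2(m)
  lm2 <- lm2 - rowMeans(lm2, na.rm = TRUE)
  matrix_to_tibble(lm2, id_col)
}

#' Per-feature Mann-Whitney U tests against a two-class label
#'
#' Two-sided tests of each feature between the two classes: exact
#' enumeration when both groups have at most 8 observations and the feature
#' has no ties, a tie-corrected normal approximation with continuity
#' correction otherwise.  A feature that is constant across all samples
#' gets U at its null mean and p = 1.
#'
#' @param df Feature tibble (feature id column + sample columns).
#' @param classes Named character/factor vector (names = sample ids) or a
#'   tibble with `sample` and `class` columns; exactly two classes.
#' @param id_col Feature id column name.
#' @return Tibble: feature id, `n1`, `n2`, `u`, `p`.
#' @export
mannwhitney_feature_tests <- function(df, classes, id_col = "gene") {
  m <- as_feature_matrix(df, id_col)
  cls <- normalize_classes(classes, colnames(m))
  lv <- levels(cls)
  if (length(lv) != 2) abort("exactly two classes are required")
  g1 <- which(cls == lv[1]); g2 <- which(cls == lv[2])
  if (!length(g1) || !length(g2)) abort("both classes must be non-empty")
  res <- map(seq_len(nrow(m)), function(i) {
    mw_u_test(m[i, g1], m[i, g2])
  }) |> list_rbind()
  bind_cols(tibble(!!id_col := rownames(m)), res)
}

normalize_classes <- function(classes, samples) {
  if (is.data.frame(classes)) {
    assert_cols(classes, c("sample", "class"), "class table")
    classes <- setNames(as.character(classes$class), classes$sample)
  }
  if (is.null(names(classes))) {
    if (length(classes) != length(samples)) {
      abort("unnamed class vector must match the number of samples")
    }
    names(classes) <- samples
  }
  missing <- setdiff(samples, names(classes))
  if (length(missing)) {
    abort(sprintf("no class label for sample(s): %s",
                  paste(missing, collapse = ", ")))
  }
  factor(unname(classes[samples]))
}

# One two-sided Mann-Whitney U test; engine is stats::wilcox.test.
mw_u_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (sd(c(x, y)) == 0) {
    return(tibble(n1 = n1, n2 = n2, u = n1 * n2 / 2, p = 1))
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- !has_ties && n1 <= 8 && n2 <= 8
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  tibble(n1 = n1, n2 = n2, u = unname(wt$statistic), p = min(1, wt$p.value))
}

#' Collapse RPPA triplicate spots into a centred log2 protein matrix
#'
#' Per (antibody, sample) the replicate spot median is taken (robust to a
#' single aberrant spot), then values are log2 transformed and mean-centred
#' per antibody.  Pairs with fewer than 2 usable replicate spots are flagged
#' low-confidence.
#'
#' @param spots Long tibble: `antibody`, `sample`, `intensity` (one row per
#'   replicate spot).
#' @return A list with `matrix` (tibble: `antibody` + sample columns, log2
#'   centred) and `low_confidence` (tibble of flagged pairs).
#' @export
rppa_preprocess <- function(spots) {
  assert_cols(spots, c("antibody", "sample", "intensity"), "spot table")
  agg <- spots |>
    filter(is.finite(.data$intensity)) |>
    summarise(value = median(.data$intensity), n_spots = n(),
              .by = c("antibody", "sample"))
  low <- filter(agg, .data$n_spots < 2) |>
    select("antibody", "sample", "n_spots")
  wide <- agg |>
    select("antibody", "sample", "value") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "value")
  list(matrix = log2_mean_center(wide, id_col = "antibody"),
       low_confidence = low)
}

#' Hierarchical clustering with centred-correlation or Euclidean distance
#'
#' Rows of the feature matrix are the items clustered.  Correlation-centred
#' distance is `1 - Pearson r` between mean-centred rows (scale-invariant);
#' zero-variance items are dropped with a warning.  Items are sorted by id
#' first so agglomeration ties resolve deterministically.
#'
#' @param df Tibble (item id column + value columns).
#' @param distance `"correlation"` or `"euclidean"`.
#' @param linkage `"average"` or `"complete"`.
#' @param id_col Item id column name.
#' @return An [stats::hclust] tree over items.
#' @export
hcluster <- function(df, distance = c("correlation", "euclidean"),
                     linkage = c("average", "complete"), id_col = "gene") {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  m <- as_feature_matrix(df, id_col)
  m <- m[order(rownames(m)), , drop = FALSE]
  if (nrow(m) < 2) abort("need at least 2 items to cluster")
  if (distance == "correlation") {
    v <- apply(m, 1, var)
    if (any(v == 0)) {
      warn(sprintf("dropping zero-variance item(s): %s",
                   paste(rownames(m)[v == 0], collapse = ", ")))
      m <- m[v > 0, , drop = FALSE]
    }
    d <- as.dist(1 - cor(t(m), method = "pearson"))
  } else {
    d <- dist(m, method = "euclidean")
  }
  hclust(d, method = linkage)
}
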