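# Two-colour FISH core scoring, cohort summary, probe-pair correlation and
# the Bonferroni-corrected protein correlation network.

#' FISH scoring configuration
#'
#' Cores need at least `min_nuclei` scorable nuclei to be evaluable; at most
#' `max_nuclei` nuclei (the first in input order) enter the score.  A core
#' is amplified when its red/green ratio is at or above `cutoff` (scores
#' below the cutoff are negative).
#'
#' @param min_nuclei,max_nuclei Nuclei bounds (default 10 and 20).
#' @param cutoff Amplification ratio cutoff (default 1.8, inclusive).
#' @return A `fish_config` list.
#' @export
fish_config <- function(min_nuclei = 10, max_nuclei = 20, cutoff = 1.8) {
  if (!(min_nuclei > 0 && min_nuclei <= max_nuclei)) {
    abort("need 0 < min_nuclei <= max_nuclei")
  }
  if (cutoff <= 1) abort("amplification cutoff must exceed 1")
  structure(list(min_nuclei = as.integer(min_nuclei),
                 max_nuclei = as.integer(max_nuclei), cutoff = cutoff),
            class = "fish_config")
}

#' Score FISH cores
#'
#' Per core, the score is the summed red signal divided by the summed green
#' signal over the first `max_nuclei` nuclei in input order.  Cores with
#' fewer than `min_nuclei` nuclei, or zero total green signal, are marked
#' not evaluable; evaluable cores at or above the cutoff are amplified.
#'
#' @param counts Long tibble: `core`, `nucleus`, `red`, `green`.
#' @param cfg A [fish_config()].
#' @return Tibble: `core`, `n_nuclei`, `score`, `evaluable`, `amplified`,
#'   `reason` (NA when evaluable).
#' @export
score_fish_cores <- function(counts, cfg = fish_config()) {
  assert_cols(counts, c("core", "nucleus", "red", "green"), "nuclei counts")
  if (any(counts$red < 0 | counts$green < 0)) {
    abort("signal counts must be non-negative")
  }
  counts |>
    group_by(.data$core) |>
    summarise(
      n_nuclei = n(),
      red_sum = sum(head(.data$red, cfg$max_nuclei)),
      green_sum = sum(head(.data$green, cfg$max_nuclei)),
      .groups = "drop"
    ) |>
    mutate(
      evaluable = .data$n_nuclei >= cfg$min_nuclei & .data$green_sum > 0,
      score = if_else(.data$evaluable, .data$red_sum / .data$green_sum,
                      NA_real_),
      amplified = .data$evaluable & .data$score >= cfg$cutoff,
      reason = dplyr::case_when(
        .data$n_nuclei < cfg$min_nuclei ~ "too few nuclei",
        .data$green_sum <= 0 ~ "no green signal",
        TRUE ~ NA_character_)
    ) |>
    select("core", "n_nuclei", "score", "evaluable", "amplified", "reason")
}

#' Summarise a scored FISH cohort
#'
#' Median, IQR (Q3 - Q1 with linear-interpolation quantiles), mean, SD,
#' range, counts of evaluable and amplified cores, and the amplified
#' fraction, over evaluable cores only.
#'
#' @param scores Output of [score_fish_cores()].
#' @return One-row tibble of cohort statistics.
#' @export
summarize_fish_cohort <- function(scores) {
  assert_cols(scores, c("score", "evaluable", "amplified"), "core scores")
  ev <- scores[scores$evaluable, ]
  if (!nrow(ev)) abort("no evaluable cores")
  q <- quantile(ev$score, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble(
    n_evaluable = nrow(ev),
    n_amplified = sum(ev$amplified),
    fraction_amplified = sum(ev$amplified) / nrow(ev),
    median = q[2], iqr = q[3] - q[1],
    mean = mean(ev$score), sd = sd(ev$score),
    min = min(ev$score), max = max(ev$score)
  )
}

#' Correlate two probes' core scores
#'
#' Spearman rank correlation over cores evaluable for both probes
#' (pairwise complete), with the exact permutation p for small n and the
#' t approximation otherwise (as implemented by [stats::cor.test()]).
#'
#' @param scores_a,scores_b Score tibbles from [score_fish_cores()] for the
#'   two probes (matched by `core`).
#' @param method Correlation method (default `"spearman"`).
#' @return One-row tibble: `n`, `rho`, `p`.
#' @export
probe_pair_correlation <- function(scores_a, scores_b,
                                   method = c("spearman", "pearson")) {
  method <- match.arg(method)
  joined <- inner_join(
    filter(scores_a, .data$evaluable) |> select("core", a = "score"),
    filter(scores_b, .data$evaluable) |> select("core", b = "score"),
    by = "core")
  if (nrow(joined) < 3) abort("need at least 3 cores evaluable for both probes")
  if (sd(joined$a) == 0 || sd(joined$b) == 0) {
    abort("constant scores: correlation undefined")
  }
  ct <- suppressWarnings(
    cor.test(joined$a, joined$b, method = method,
             exact = method == "spearman" && nrow(joined) <= 9))
  tibble(n = nrow(joined), rho = unname(ct$estimate), p = ct$p.value)
}

#' Bonferroni-corrected protein correlation network
#'
#' All pairwise correlations between markers (rows) across cases (columns),
#' pairwise-complete; the Bonferroni family is the number of pairs actually
#' tested and an edge is retained when its adjusted p is at most `alpha`.
#' Markers with fewer than 4 paired observations against every partner are
#' excluded with a warning.  Edges are ordered deterministically by marker
#' names.
#'
#' @param df Marker-by-case tibble (marker id column + case columns).
#' @param method `"spearman"` (default, matching rank-based scoring) or
#'   `"pearson"`.
#' @param alpha Family-wise threshold.
#' @param id_col Marker id column name.
#' @return Tibble: `marker1`, `marker2`, `n`, `estimate`, `p`, `p_adj`,
#'   `edge`; attribute `family_size`.
#' @export
aqua_correlation_network <- function(df, method = c("spearman", "pearson"),
                                     alpha = 0.05, id_col = "marker") {
  method <- match.arg(method)
  m <- as_feature_matrix(df, id_col)
  if (ncol(m) < 4) abort("need at least 4 cases")
  usable <- rowSums(is.finite(m)) >= 4
  if (any(!usable)) {
    warn(sprintf("excluding marker(s) with < 4 observations: %s",
                 paste(rownames(m)[!usable], collapse = ", ")))
    m <- m[usable, , drop = FALSE]
  }
  markers <- sort(rownames(m))
  pairs <- combn(markers, 2, simplify = FALSE)
  res <- map(pairs, function(pr) {
    x <- m[pr[1], ]; y <- m[pr[2], ]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 4) return(NULL)
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = method))
    tibble(marker1 = pr[1], marker2 = pr[2], n = sum(ok),
           estimate = unname(ct$estimate), p = ct$p.value)
  }) |> list_rbind()
  family <- nrow(res)
  res <- mutate(res, p_adj = pmin(1, .data$p * family),
                edge = .data$p_adj <= alpha)
  attr(res, "family_size") <- family
  res
}
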