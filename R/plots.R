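# ggplot2 visualisations for the main result types.

#' Plot a fitted dose-response curve
#'
#' Observed viability points and the fitted 4PL curve on a log
#' concentration axis, with the 50% line and the IC50 marked.
#'
#' @param object A `dose_response_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dose_response_fit
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  rng <- range(object$data$conc)
  grid <- tibble(conc = exp(seq(log(rng[1]), log(rng[2]), length.out = 200)))
  grid$viability <- four_pl(grid$conc, object$top, object$bottom,
                            object$hill, object$ic50_param)
  ggplot(object$data, aes(x = .data$conc, y = .data$viability)) +
    geom_hline(yintercept = 50, linetype = "dashed", colour = "grey60") +
    geom_line(data = grid, colour = "#2166ac") +
    geom_point() +
    scale_x_log10() +
    labs(x = "concentration", y = "viability (% of control)",
         title = sprintf("IC50 = %.3g%s", object$ic50,
                         if (object$censored) " (censored)" else "")) +
    theme_bw()
}

#' Plot a marker track with its segmentation
#'
#' Marker-level log2 ratios for one sample with fitted segment means
#' overlaid, faceted by chromosome.
#'
#' @param markers Marker tibble (`chrom`, `pos`, sample columns).
#' @param segments Segment tibble from [segment_markers()].
#' @param sample Sample id to plot.
#' @return A ggplot.
#' @export
plot_cn_profile <- function(markers, segments, sample) {
  assert_cols(markers, c("chrom", "pos", sample), "marker table")
  seg <- segments[segments$sample == sample, ]
  df <- tibble(chrom = markers$chrom, pos = markers$pos,
               log2ratio = markers[[sample]])
  ggplot(df, aes(x = .data$pos / 1e6, y = .data$log2ratio)) +
    geom_point(size = 0.3, alpha = 0.4) +
    geom_segment(data = seg,
                 aes(x = .data$start_bp / 1e6, xend = .data$end_bp / 1e6,
                     y = .data$seg_mean, yend = .data$seg_mean),
                 colour = "#b2182b", linewidth = 1) +
    facet_wrap(~chrom, scales = "free_x") +
    labs(x = "position (Mb)", y = "log2 ratio", title = sample) +
    theme_bw()
}

#' Plot a SAM result
#'
#' Moderated d statistic against log2 fold change, highlighting features
#' passing the fold-change and q-value gates.
#'
#' @param object A `sam_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sam_result
#' @export
autoplot.sam_result <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = log2(.data$fc), y = .data$d,
                 colour = .data$significant)) +
    geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#b2182b")) +
    labs(x = "log2 fold change", y = "SAM d statistic",
         colour = "significant") +
    theme_bw()
}

#' Plot candidate-ledger set sizes
#'
#' Per-drug association list sizes alongside the union and the three-way
#' intersection.
#'
#' @param object A `candidate_ledger`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot candidate_ledger
#' @export
autoplot.candidate_ledger <- function(object, ...) {
  df <- tibble(
    set = c(names(object$per_drug), "union", "all three"),
    n = c(lengths(object$per_drug), length(object$union),
          length(object$threeway))
  )
  df$set <- factor(df$set, levels = df$set)
  ggplot(df, aes(x = .data$set, y = .data$n)) +
    geom_col(fill = "#2166ac") +
    labs(x = NULL, y = "genes") +
    theme_bw()
}

#' Plot FISH cohort scores
#'
#' Histogram of evaluable core scores with the amplification cutoff line.
#'
#' @param scores Output of [score_fish_cores()].
#' @param cfg The [fish_config()] used (for the cutoff line).
#' @return A ggplot.
#' @export
plot_fish_scores <- function(scores, cfg = fish_config()) {
  ev <- scores[scores$evaluable, ]
  ggplot(ev, aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = cfg$cutoff, colour = "#b2182b",
                        linetype = "dashed") +
    labs(x = "red/green ratio", y = "cores") +
    theme_bw()
}
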