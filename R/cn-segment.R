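# Copy-number segmentation: marker normalisation, CBS-style recursive binary
# splitting with permutation split testing, and gain/loss calling.

#' Segmentation parameters
#'
#' Parameters of the CBS-style segmentation: `min_markers` is the minimum
#' number of markers in a child segment, `alpha` the permutation p-value a
#' split must reach to be accepted, `snr` the minimum between-segment mean
#' difference in units of the robust marker noise SD, and `n_permutations`
#' the number of within-interval marker shuffles in the split test.
#'
#' @param min_markers Minimum child-segment marker count (>= 2).
#' @param alpha Split acceptance p-value (0 < alpha < 1).
#' @param snr Minimum standardised mean difference (>= 0).
#' @param n_permutations Marker shuffles per split test.
#' @return A `seg_params` list.
#' @export
seg_params <- function(min_markers = 10, alpha = 0.001, snr = 0.03,
                       n_permutations = 1000) {
  if (min_markers < 2) abort("min_markers must be at least 2")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  if (snr < 0) abort("snr must be non-negative")
  structure(list(min_markers = as.integer(min_markers), alpha = alpha,
                 snr = snr, n_permutations = as.integer(n_permutations)),
            class = "seg_params")
}

#' Gain/loss call thresholds
#'
#' A segment is called lost when its mean log2 ratio is strictly below
#' `loss`, gained when strictly above `gain`, and flagged as a high-level
#' amplification when at or above `high_amp` (which implies gain).
#'
#' @param gain,loss,high_amp Log2-ratio thresholds with
#'   `loss < 0 < gain <= high_amp`.
#' @return A `call_thresholds` list.
#' @export
call_thresholds <- function(gain = 0.15, loss = -0.3, high_amp = 1.0) {
  if (!(loss < 0 && 0 < gain && gain <= high_amp)) {
    abort("thresholds must satisfy loss < 0 < gain <= high_amp")
  }
  structure(list(gain = gain, loss = loss, high_amp = high_amp),
            class = "call_thresholds")
}

#' Normalise marker-level log2 ratios
#'
#' Default mode subtracts each sample's global median log2 ratio (the
#' centring stand-in used when only ratio-level data are available).  When a
#' per-marker mean-intensity column is supplied, `method = "lowess"`
#' additionally removes the intensity-dependent trend (lowess of ratio
#' versus intensity), the ratio-level analogue of print-tip loess.
#'
#' @param markers Tibble: `chrom`, `pos`, one column per sample.
#' @param method `"median"` or `"lowess"`.
#' @param intensity Numeric vector (one value per marker) for lowess mode.
#' @return The markers tibble with normalised sample columns.
#' @export
normalize_markers <- function(markers, method = c("median", "lowess"),
                              intensity = NULL) {
  method <- match.arg(method)
  assert_cols(markers, c("chrom", "pos"), "marker table")
  samples <- setdiff(names(markers), c("chrom", "pos"))
  if (nrow(markers) < 100) abort("need at least 100 markers to normalise")
  for (s in samples) {
    x <- markers[[s]]
    if (all(is.na(x))) abort(sprintf("sample %s has no finite markers", s))
    if (method == "lowess") {
      if (is.null(intensity)) abort("lowess mode needs an intensity vector")
      ok <- is.finite(x) & is.finite(intensity)
      fit <- stats::lowess(intensity[ok], x[ok], f = 2 / 3)
      trend <- stats::approx(fit$x, fit$y, xout = intensity, rule = 2)$y
      x <- x - trend
    }
    markers[[s]] <- x - median(x, na.rm = TRUE)
  }
  markers
}

# t statistics for every admissible cut of x (left block 1..k).
cut_t_stats <- function(x, min_markers) {
  n <- length(x)
  ks <- seq.int(min_markers, n - min_markers)
  if (!length(ks) || n < 2 * min_markers) return(NULL)
  cs <- cumsum(x)
  css <- cumsum(x * x)
  nl <- ks
  nr <- n - ks
  ml <- cs[ks] / nl
  mr <- (cs[n] - cs[ks]) / nr
  ssl <- css[ks] - cs[ks]^2 / nl
  ssr <- (css[n] - css[ks]) - (cs[n] - cs[ks])^2 / nr
  sp2 <- (ssl + ssr) / (n - 2)
  se <- sqrt(sp2 * (1 / nl + 1 / nr))
  t <- (ml - mr) / se
  # zero pooled variance: identical children give t = 0, a clean step gives
  # an infinite statistic
  degen <- !is.finite(t)
  t[degen] <- ifelse(ml[degen] == mr[degen], 0, Inf * sign(ml - mr)[degen])
  list(ks = ks, t = t)
}

max_abs_cut_t <- function(x, min_markers) {
  st <- cut_t_stats(x, min_markers)
  if (is.null(st)) return(-Inf)
  max(abs(st$t))
}

# Permutation p-value for the best split of x; early exit once the exceedance
# count can no longer reach alpha.
split_p_value <- function(x, t_obs, params) {
  n_perm <- params$n_permutations
  limit <- floor(params$alpha * (n_perm + 1))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (max_abs_cut_t(sample(x), params$min_markers) >= t_obs) {
      exceed <- exceed + 1L
      if (exceed > limit) return((1 + exceed) / (1 + b))
    }
  }
  (1 + exceed) / (1 + n_perm)
}

segment_vector <- function(x, params, sigma) {
  breaks <- integer(0)
  recurse <- function(lo, hi) {
    n <- hi - lo + 1
    if (n < 2 * params$min_markers) return(invisible())
    seg <- x[lo:hi]
    st <- cut_t_stats(seg, params$min_markers)
    if (is.null(st)) return(invisible())
    best <- which.max(abs(st$t))
    k <- st$ks[best]
    t_obs <- abs(st$t[best])
    if (t_obs == 0) return(invisible())
    mdiff <- abs(mean(seg[1:k]) - mean(seg[(k + 1):n]))
    if (mdiff < params$snr * sigma) return(invisible())
    p <- split_p_value(seg, t_obs, params)
    if (p > params$alpha) return(invisible())
    cut <- lo + k - 1
    breaks <<- c(breaks, cut)
    recurse(lo, cut)
    recurse(cut + 1, hi)
  }
  recurse(1, length(x))
  sort(breaks)
}

# Merge adjacent segments whose mean difference falls below the snr
# criterion; repeats until stable.
merge_breaks <- function(x, breaks, params, sigma) {
  repeat {
    if (!length(breaks)) return(breaks)
    bounds <- c(0, breaks, length(x))
    means <- map_dbl(seq_len(length(bounds) - 1),
                     ~ mean(x[(bounds[.x] + 1):bounds[.x + 1]]))
    weak <- which(abs(diff(means)) < params$snr * sigma)
    if (!length(weak)) return(breaks)
    breaks <- breaks[-weak[1]]
  }
}

#' Segment marker-level copy-number profiles
#'
#' CBS-style recursive binary splitting per sample and chromosome: the
#' breakpoint maximising the two-sample t statistic is accepted only when
#' its within-interval permutation p-value is at most `alpha`, both children
#' carry at least `min_markers` markers, and the between-segment mean
#' difference is at least `snr` times the robust marker noise SD (MAD of
#' lag-1 marker differences / sqrt(2)).  Adjacent segments violating the snr
#' criterion after recursion are merged.  Segments tile each chromosome's
#' marker span; boundaries between breakpoints fall midway between the
#' flanking markers.  Coordinates are reported 1-based inclusive.
#'
#' @param markers Normalised marker tibble (`chrom`, `pos`, sample columns).
#' @param params A [seg_params()].
#' @param seed Seed for the permutation split tests, so segmentations are
#'   reproducible.
#' @return Tibble: `sample`, `chrom`, `start_bp`, `end_bp`, `n_markers`,
#'   `seg_mean`, `terminal_short` (segment shorter than `min_markers`
#'   because the chromosome itself was short).
#' @export
segment_markers <- function(markers, params = seg_params(), seed = 0L) {
  assert_cols(markers, c("chrom", "pos"), "marker table")
  samples <- setdiff(names(markers), c("chrom", "pos"))
  out <- with_substream(seed, "cnseg/permutations", segment_all(
    markers, samples, params))
  out
}

segment_all <- function(markers, samples, params) {
  out <- list()
  for (s in samples) {
    for (ch in unique(markers$chrom)) {
      sel <- markers$chrom == ch
      pos <- markers$pos[sel]
      x <- markers[[s]][sel]
      o <- order(pos)
      pos <- pos[o]; x <- x[o]
      if (length(x) < params$min_markers) {
        warn(sprintf("chromosome %s has fewer than min_markers markers; %s",
                     ch, "kept as a single segment"))
        breaks <- integer(0)
      } else {
        sigma <- robust_noise_sd(x)
        breaks <- segment_vector(x, params, sigma)
        breaks <- merge_breaks(x, breaks, params, sigma)
      }
      bounds <- c(0, breaks, length(x))
      # segment bp bounds: midpoints between flanking markers at breakpoints
      starts <- pos[head(bounds, -1) + 1]
      ends <- pos[bounds[-1]]
      if (length(breaks)) {
        mids <- floor((pos[breaks] + pos[breaks + 1]) / 2)
        ends[seq_along(mids)] <- mids
        starts[seq_along(mids) + 1] <- mids + 1
      }
      nm <- diff(bounds)
      out[[length(out) + 1]] <- tibble(
        sample = s, chrom = ch,
        start_bp = starts, end_bp = ends, n_markers = nm,
        seg_mean = map_dbl(seq_len(length(bounds) - 1),
                           ~ mean(x[(bounds[.x] + 1):bounds[.x + 1]])),
        terminal_short = nm < params$min_markers
      )
    }
  }
  list_rbind(out)
}

#' Call segments as gained, lost or neutral
#'
#' Strict inequalities for gain and loss; the high-level amplification flag
#' is inclusive at its threshold and implies a gain call.
#'
#' @param segments Segment tibble with a `seg_mean` column.
#' @param thresholds A [call_thresholds()].
#' @return The segments with `call` (`"gain"`, `"loss"`, `"neutral"`) and
#'   `high_amp` (logical) columns.
#' @export
call_segments <- function(segments, thresholds = call_thresholds()) {
  assert_cols(segments, "seg_mean", "segment table")
  mutate(segments,
         call = dplyr::case_when(
           .data$seg_mean > thresholds$gain ~ "gain",
           .data$seg_mean < thresholds$loss ~ "loss",
           TRUE ~ "neutral"),
         high_amp = .data$seg_mean >= thresholds$high_amp)
}

#' Region size in megabases
#'
#' `(end - start) / 1e6`, rounded to two decimals (the arithmetic used by
#' the published region tables on their self-consistent rows).
#'
#' @param start_bp,end_bp 1-based inclusive bounds with `end_bp >= start_bp`.
#' @return Size in Mb.
#' @export
#' @examples
#' region_size_mb(144656, 25059988)
region_size_mb <- function(start_bp, end_bp) {
  if (any(end_bp < start_bp)) abort("end_bp must be >= start_bp")
  round((end_bp - start_bp) / 1e6, 2)
}

#' Cluster samples by segmented copy-number profiles
#'
#' Resamples per-sample segment means onto the union of all samples'
#' breakpoints (each elementary interval contributes one coordinate),
#' then agglomerates with Euclidean distance and average linkage.  Samples
#' are ordered by id before clustering so ties resolve deterministically.
#'
#' @param segments Segment tibble (`sample`, `chrom`, `start_bp`, `end_bp`,
#'   `seg_mean`).
#' @return An [stats::hclust] tree over samples.
#' @export
cluster_segment_profiles <- function(segments) {
  assert_cols(segments, c("sample", "chrom", "start_bp", "end_bp", "seg_mean"),
              "segment table")
  samples <- sort(unique(segments$sample))
  if (length(samples) < 2) abort("need at least 2 samples to cluster")
  feats <- list()
  for (ch in unique(segments$chrom)) {
    seg <- segments[segments$chrom == ch, ]
    bounds <- sort(unique(c(seg$start_bp, seg$end_bp + 1)))
    starts <- head(bounds, -1)
    m <- matrix(NA_real_, nrow = length(samples), ncol = length(starts),
                dimnames = list(samples, NULL))
    for (i in seq_len(nrow(seg))) {
      cols <- which(starts >= seg$start_bp[i] & starts <= seg$end_bp[i])
      m[seg$sample[i], cols] <- seg$seg_mean[i]
    }
    feats[[ch]] <- m
  }
  mat <- do.call(cbind, feats)
  mat[is.na(mat)] <- 0
  hclust(dist(mat, method = "euclidean"), method = "average")
}
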