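# Recurrent gain/loss regions across samples.

#' Find regions recurrently gained or lost across samples
#'
#' Over the union of all segment breakpoints on each chromosome, counts per
#' elementary interval the samples whose segment call matches `direction`,
#' and emits maximal runs of intervals whose count is at least
#' `min_support`.  The supporting-sample set of a region is the intersection
#' of the matching samples over the whole run (the strict reading: samples
#' altered across the entire region).  Coordinates are 1-based inclusive.
#'
#' @param calls Called segment tibble (`sample`, `chrom`, `start_bp`,
#'   `end_bp`, `call`), as from [call_segments()].
#' @param direction `"gain"` or `"loss"`.
#' @param min_support Minimum number of matching samples (default 7,
#'   the at-least-7-of-15 rule).
#' @return Tibble: `chrom`, `start_bp`, `end_bp`, `direction`, `n_support`,
#'   `size_mb`, and list-column `supporting` (sorted sample ids in the
#'   run-wide intersection).
#' @export
find_recurrent_regions <- function(calls, direction = c("gain", "loss"),
                                   min_support = 7) {
  direction <- match.arg(direction)
  assert_cols(calls, c("sample", "chrom", "start_bp", "end_bp", "call"),
              "called segments")
  n_samples <- length(unique(calls$sample))
  if (min_support > n_samples) {
    warn("min_support exceeds the number of samples; no recurrent regions")
    return(empty_regions(direction))
  }
  hits <- calls[calls$call == direction, , drop = FALSE]
  if (!nrow(hits)) return(empty_regions(direction))

  out <- list()
  for (ch in sort(unique(hits$chrom))) {
    seg <- hits[hits$chrom == ch, ]
    bounds <- sort(unique(c(seg$start_bp, seg$end_bp + 1)))
    starts <- head(bounds, -1)
    ends <- bounds[-1] - 1
    covers <- vector("list", length(starts))
    for (i in seq_len(nrow(seg))) {
      idx <- which(starts >= seg$start_bp[i] & ends <= seg$end_bp[i])
      for (j in idx) covers[[j]] <- c(covers[[j]], seg$sample[i])
    }
    counts <- lengths(lapply(covers, unique))
    keep <- counts >= min_support
    if (!any(keep)) next
    # maximal runs of kept intervals that are genomically adjacent
    n_int <- length(starts)
    new_run <- c(TRUE, !keep[-n_int] | !keep[-1] |
                   starts[-1] != ends[-n_int] + 1)
    run_id <- cumsum(new_run)
    for (r in unique(run_id[keep])) {
      idx <- which(run_id == r & keep)
      if (!length(idx)) next
      supp <- Reduce(intersect, lapply(covers[idx], unique))
      out[[length(out) + 1]] <- tibble(
        chrom = ch, start_bp = min(starts[idx]), end_bp = max(ends[idx]),
        direction = direction,
        n_support = min(counts[idx]),
        size_mb = region_size_mb(min(starts[idx]), max(ends[idx])),
        supporting = list(sort(supp))
      )
    }
  }
  if (!length(out)) return(empty_regions(direction))
  list_rbind(out) |> arrange(.data$chrom, .data$start_bp)
}

empty_regions <- function(direction) {
  tibble(chrom = character(), start_bp = numeric(), end_bp = numeric(),
         direction = character(), n_support = integer(), size_mb = numeric(),
         supporting = list())
}
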