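# broom-style tidiers for fitted objects.

#' Tidy a 4PL dose-response fit
#'
#' @param x A `dose_response_fit`.
#' @param ... Unused.
#' @return Tibble with one row per curve parameter.
#' @method tidy dose_response_fit
#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble(term = c("top", "bottom", "hill", "ic50"),
         estimate = c(x$top, x$bottom, x$hill, x$ic50))
}

#' One-row summary of a 4PL dose-response fit
#'
#' @param x A `dose_response_fit`.
#' @param ... Unused.
#' @return One-row tibble: `ic50`, `censored`, `rss`, `n_conc`.
#' @method glance dose_response_fit
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble(ic50 = x$ic50, censored = x$censored, rss = x$rss,
         n_conc = nrow(x$data))
}

#' Tidy a candidate ledger into per-gene membership rows
#'
#' @param x A `candidate_ledger`.
#' @param ... Unused.
#' @return Tibble with one row per correlated gene and one logical column
#'   per drug list, plus `in_union` and `in_all`.
#' @method tidy candidate_ledger
#' @export
tidy.candidate_ledger <- function(x, ...) {
  out <- tibble(gene = x$correlated)
  for (d in names(x$per_drug)) {
    out[[d]] <- out$gene %in% x$per_drug[[d]]
  }
  out$in_union <- out$gene %in% x$union
  out$in_all <- out$gene %in% x$threeway
  out
}

#' One-row summary of a candidate ledger
#'
#' @param x A `candidate_ledger`.
#' @param ... Unused.
#' @return One-row tibble of set sizes.
#' @method glance candidate_ledger
#' @export
glance.candidate_ledger <- function(x, ...) {
  out <- tibble(n_correlated = length(x$correlated),
                n_union = length(x$union),
                n_threeway = length(x$threeway))
  for (d in names(x$per_drug)) {
    out[[paste0("n_", gsub("[^A-Za-z0-9]", "_", d))]] <-
      length(x$per_drug[[d]])
  }
  out
}

#' Tidy a SAM result
#'
#' @param x A `sam_result`.
#' @param ... Unused.
#' @return The per-feature result tibble without the result class.
#' @method tidy sam_result
#' @export
tidy.sam_result <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a SAM result
#'
#' @param x A `sam_result`.
#' @param ... Unused.
#' @return One-row tibble: feature and significant counts, `s0`, whether
#'   permutations were enumerated exactly.
#' @method glance sam_result
#' @export
glance.sam_result <- function(x, ...) {
  tibble(n_features = nrow(x), n_significant = sum(x$significant),
         s0 = attr(x, "s0"), exact = isTRUE(attr(x, "exact")),
         n_permutations = attr(x, "n_permutations"))
}

#' One-row summary of a pipeline run
#'
#' @param x A `panel_run`.
#' @param ... Unused.
#' @return One-row tibble of the run's headline counts.
#' @method glance panel_run
#' @export
glance.panel_run <- function(x, ...) {
  tibble(n_curves = nrow(x$ic50_calls),
         n_segments = nrow(x$segments),
         n_recurrent_gains = nrow(x$recurrent_gains),
         n_region_genes = x$n_region_genes,
         n_correlated = sum(x$correlations$passes),
         n_union = length(x$ledger$union))
}
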