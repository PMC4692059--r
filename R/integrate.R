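# Stepwise copy-number x expression integration into the candidate ledger.

#' Genes overlapping recurrent regions
#'
#' A gene is included when its interval overlaps any region by at least one
#' base (1-based inclusive coordinates on both sides).
#'
#' @param annotation Tibble: `gene`, `chrom`, `start_bp`, `end_bp`.
#' @param regions Tibble: `chrom`, `start_bp`, `end_bp` (e.g. from
#'   [find_recurrent_regions()]).
#' @return Sorted character vector of gene symbols.
#' @export
genes_in_regions <- function(annotation, regions) {
  assert_cols(annotation, c("gene", "chrom", "start_bp", "end_bp"),
              "annotation")
  assert_cols(regions, c("chrom", "start_bp", "end_bp"), "regions")
  if (!nrow(regions)) return(character(0))
  shared <- intersect(unique(annotation$chrom), unique(regions$chrom))
  if (!length(shared)) {
    abort(sprintf(
      "chromosome naming mismatch: annotation has %s; regions have %s",
      paste(unique(annotation$chrom), collapse = ","),
      paste(unique(regions$chrom), collapse = ",")))
  }
  hits <- inner_join(annotation, regions, by = "chrom",
                     suffix = c("", ".region"),
                     relationship = "many-to-many") |>
    filter(.data$start_bp <= .data$end_bp.region,
           .data$end_bp >= .data$start_bp.region)
  sort(unique(hits$gene))
}

#' Gene-level copy number from segment profiles
#'
#' The per-sample gene-level log2 copy number is the overlap-length-weighted
#' mean of the means of the segments overlapping the gene interval.  Genes
#' on chromosomes absent from a sample's segmentation get `NA`.
#'
#' @param annotation Tibble: `gene`, `chrom`, `start_bp`, `end_bp`.
#' @param segments Segment tibble (`sample`, `chrom`, `start_bp`, `end_bp`,
#'   `seg_mean`) tiling each chromosome.
#' @return Tibble: `gene`, `sample`, `cn`.
#' @export
gene_cn_values <- function(annotation, segments) {
  assert_cols(annotation, c("gene", "chrom", "start_bp", "end_bp"),
              "annotation")
  assert_cols(segments, c("sample", "chrom", "start_bp", "end_bp", "seg_mean"),
              "segments")
  samples <- sort(unique(segments$sample))
  out <- tidyr::expand_grid(gene = annotation$gene, sample = samples) |>
    left_join(annotation, by = "gene")
  out$cn <- purrr::pmap_dbl(
    list(out$sample, out$chrom, out$start_bp, out$end_bp),
    function(s, ch, a, b) {
      seg <- segments[segments$sample == s & segments$chrom == ch, ]
      if (!nrow(seg)) return(NA_real_)
      ov <- overlap_bp(seg$start_bp, seg$end_bp, a, b)
      if (sum(ov) == 0) return(NA_real_)
      sum(seg$seg_mean * ov) / sum(ov)
    })
  select(out, "gene", "sample", "cn")
}

#' Correlate gene-level copy number with expression
#'
#' Pearson correlation per gene between its per-sample log2 copy number and
#' its expression, with a two-sided p from the t transform and a Bonferroni
#' adjustment over the family of genes tested.  A gene passes when its
#' adjusted p is at most 0.05 and the correlation is positive (the
#' amplified-and-over-expressed direction).
#'
#' @param gene_cn Tibble `gene`, `sample`, `cn` (from [gene_cn_values()]).
#' @param expr Expression tibble (gene id + sample columns, log2 scale).
#' @param family_size Bonferroni family; defaults to the number of genes
#'   actually tested (those with both copy number and expression).
#' @param id_col Feature id column of `expr`.
#' @return Tibble: `gene`, `n`, `r`, `p`, `p_adj`, `passes`; attribute
#'   `family_size`.
#' @export
correlate_cn_expr <- function(gene_cn, expr, family_size = NULL,
                              id_col = "gene") {
  assert_cols(gene_cn, c("gene", "sample", "cn"), "gene CN table")
  m <- as_feature_matrix(expr, id_col)
  genes <- intersect(unique(gene_cn$gene), rownames(m))
  if (is.null(family_size)) family_size <- length(genes)
  res <- map(genes, function(g) {
    cn <- gene_cn[gene_cn$gene == g, ]
    sm <- intersect(cn$sample, colnames(m))
    x <- setNames(cn$cn, cn$sample)[sm]
    y <- m[g, sm]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) {
      return(tibble(gene = g, n = length(x), r = NA_real_, p = NA_real_))
    }
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(gene = g, n = length(x), r = NA_real_, p = NA_real_))
    }
    ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
    tibble(gene = g, n = length(x), r = unname(ct$estimate),
           p = ct$p.value)
  }) |> list_rbind()
  res <- mutate(res,
                p_adj = pmin(1, .data$p * family_size),
                passes = !is.na(.data$r) & .data$r > 0 &
                  !is.na(.data$p_adj) & .data$p_adj <= 0.05)
  attr(res, "family_size") <- family_size
  res
}

#' Test expression against per-drug sensitivity classes
#'
#' For each drug, two-sided Mann-Whitney U tests of each gene's expression
#' between the sensitive and less-sensitive lines; genes with unadjusted
#' p at most `alpha` are flagged associated (matching per-gene reporting
#' without multiplicity adjustment).  Drugs whose class split is degenerate
#' (zero or all samples sensitive) are skipped with a warning.
#'
#' @param expr Expression tibble (gene id + sample columns).
#' @param classes Tibble: `drug`, `sample`, `sensitivity`.
#' @param genes Gene subset to test (e.g. the correlated genes).
#' @param alpha Per-gene significance threshold.
#' @param id_col Feature id column.
#' @return Tibble: `drug`, gene id, `u`, `p`, `associated`.
#' @export
treatment_association <- function(expr, classes, genes = NULL, alpha = 0.05,
                                  id_col = "gene") {
  assert_cols(classes, c("drug", "sample", "sensitivity"), "class table")
  if (!is.null(genes)) {
    expr <- expr[expr[[id_col]] %in% genes, , drop = FALSE]
  }
  out <- list()
  for (d in unique(classes$drug)) {
    cl <- classes[classes$drug == d, ]
    lv <- unique(cl$sensitivity)
    if (length(lv) != 2) {
      warn(sprintf("drug %s has a degenerate sensitivity split; skipped", d))
      next
    }
    sub <- expr[, c(id_col, intersect(names(expr), cl$sample))]
    res <- mannwhitney_feature_tests(
      sub, setNames(cl$sensitivity, cl$sample), id_col = id_col)
    out[[d]] <- mutate(res, drug = d, associated = .data$p <= alpha) |>
      select("drug", dplyr::all_of(id_col), "u", "p", "associated")
  }
  list_rbind(out)
}

#' Assemble the candidate-biomarker ledger
#'
#' Exact set algebra over the correlated-gene set and the per-drug
#' association lists: union, all pairwise intersections, and the three-way
#' intersection.  Every per-drug list must be a subset of the correlated
#' set; printed synonyms can be supplied as `aliases`
#' (`c(printed = "canonical")`).  All reported sets are alphabetical.
#'
#' @param correlated Character vector of correlated gene symbols.
#' @param drug_lists Named list of per-drug gene character vectors.
#' @param aliases Optional named character vector mapping synonyms in the
#'   drug lists onto symbols in `correlated`.
#' @return A `candidate_ledger` list: `correlated`, `per_drug`, `union`,
#'   `pairwise`, `threeway`.
#' @export
build_ledger <- function(correlated, drug_lists, aliases = NULL) {
  correlated <- sort(unique(correlated))
  drug_lists <- map(drug_lists, function(g) {
    if (!is.null(aliases)) {
      hit <- g %in% names(aliases)
      g[hit] <- aliases[g[hit]]
    }
    sort(unique(g))
  })
  for (d in names(drug_lists)) {
    extra <- setdiff(drug_lists[[d]], correlated)
    if (length(extra)) {
      abort(sprintf("gene(s) in the %s list are not in the correlated set: %s",
                    d, paste(extra, collapse = ", ")))
    }
  }
  drugs <- names(drug_lists)
  pairwise <- list()
  if (length(drugs) >= 2) {
    for (pair in combn(drugs, 2, simplify = FALSE)) {
      pairwise[[paste(pair, collapse = " & ")]] <-
        sort(intersect(drug_lists[[pair[1]]], drug_lists[[pair[2]]]))
    }
  }
  structure(
    list(
      correlated = correlated,
      per_drug = drug_lists,
      union = sort(Reduce(union, drug_lists, accumulate = FALSE)),
      pairwise = pairwise,
      threeway = if (length(drugs) >= 3) {
        sort(Reduce(intersect, drug_lists))
      } else character(0)
    ),
    class = "candidate_ledger"
  )
}

#' @export
print.candidate_ledger <- function(x, ...) {
  cat("<candidate_ledger>\n")
  cat(sprintf("  correlated genes: %d\n", length(x$correlated)))
  for (d in names(x$per_drug)) {
    cat(sprintf("  %-18s %d gene(s)\n", paste0(d, ":"),
                length(x$per_drug[[d]])))
  }
  cat(sprintf("  union: %d   three-way: %s\n", length(x$union),
              if (length(x$threeway)) paste(x$threeway, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Compare IC50s between genotype groups
#'
#' Per drug, a two-sided Mann-Whitney U test of IC50 values between mutant
#' and wild-type lines (censored IC50s are expected already imputed at the
#' maximum tested concentration, which is how they are reported).
#'
#' @param ic50_calls Tibble: `drug`, `sample`, `ic50`.
#' @param status Tibble: `sample`, `mutant` (logical).
#' @return Tibble: `drug`, `n_mutant`, `n_wildtype`, `u`, `p`.
#' @export
genotype_stratification <- function(ic50_calls, status) {
  assert_cols(ic50_calls, c("drug", "sample", "ic50"), "IC50 table")
  assert_cols(status, c("sample", "mutant"), "mutation status")
  joined <- inner_join(ic50_calls, status, by = "sample")
  out <- list()
  for (d in unique(joined$drug)) {
    sub <- joined[joined$drug == d, ]
    x <- sub$ic50[sub$mutant]
    y <- sub$ic50[!sub$mutant]
    if (!length(x) || !length(y)) {
      abort(sprintf("drug %s: both genotype groups must be non-empty", d))
    }
    res <- mw_u_test(x, y)
    out[[d]] <- tibble(drug = d, n_mutant = length(x),
                       n_wildtype = length(y), u = res$u, p = res$p)
  }
  list_rbind(out)
}
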