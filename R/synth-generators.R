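# Synthetic-panel generators.  Every generator derives its own random
# substream from the spec's single seed (keyed by module name), so outputs
# are bit-reproducible and mutually independent.

plant_bp <- function(spec) {
  sp <- setNames(spec$chrom_lengths$spacing_bp, spec$chrom_lengths$chrom)
  ps <- spec$planted_segments
  if (!nrow(ps)) return(mutate(ps, start_bp = integer(), end_bp = integer()))
  mutate(ps,
         start_bp = (.data$start_marker - 1L) * unname(sp[.data$chrom]) + 1L,
         end_bp = .data$end_marker * unname(sp[.data$chrom]))
}

# Mean planted log2 level over a 1-based inclusive bp interval for one sample
# (bp-weighted; overlapping equal-level plants accumulate).
planted_level_over <- function(plants_bp, sample, chrom, start_bp, end_bp) {
  rows <- plants_bp[plants_bp$chrom == chrom, , drop = FALSE]
  if (!nrow(rows)) return(0)
  keep <- map_lgl(rows$carriers, ~ sample %in% .x)
  rows <- rows[keep, , drop = FALSE]
  if (!nrow(rows)) return(0)
  ov <- overlap_bp(rows$start_bp, rows$end_bp, start_bp, end_bp)
  sum(rows$level * ov) / (end_bp - start_bp + 1)
}

#' Ground truth realised from a panel spec
#'
#' Expands the spec's planted segments per carrier sample, lays out the gene
#' panel (dosage genes from the spec plus randomly placed null genes with
#' zero slope), computes each gene's true copy-number value per sample
#' (bp-weighted mean planted log2 over the gene interval), and records true
#' IC50s and true FISH ratios.  Regeneration with the same seed is
#' bit-identical.
#'
#' @param spec A [panel_spec()].
#' @return A `panel_truth` list with tibbles `segments`, `genes`, `gene_cn`,
#'   `ic50`, `fish_ratio`, plus the `seed`.
#' @export
panel_truth <- function(spec) {
  pbp <- plant_bp(spec)
  segments <- if (nrow(pbp)) {
    tidyr::unnest(mutate(pbp, sample = .data$carriers), "sample") |>
      select("sample", "chrom", "start_marker", "end_marker",
             "start_bp", "end_bp", "level") |>
      arrange(.data$sample, .data$chrom, .data$start_bp)
  } else {
    tibble(sample = character(), chrom = character(),
           start_marker = integer(), end_marker = integer(),
           start_bp = integer(), end_bp = integer(), level = numeric())
  }

  null_genes <- with_substream(spec$seed, "synthio/genes", {
    n <- spec$n_null_genes
    if (n == 0) {
      tibble(gene = character(), chrom = character(), start_bp = integer(),
             end_bp = integer(), slope = numeric(), noise_sd = numeric())
    } else {
      cl <- spec$chrom_lengths
      idx <- sample.int(nrow(cl), n, replace = TRUE)
      span <- cl$n_markers[idx] * cl$spacing_bp[idx]
      start <- floor(runif(n, 1, span - 50000)) + 1
      tibble(gene = sprintf("NULL%03d", seq_len(n)),
             chrom = cl$chrom[idx],
             start_bp = start, end_bp = start + 50000,
             slope = 0, noise_sd = 0.3)
    }
  })
  genes <- bind_rows(spec$dosage_genes, null_genes)

  gene_cn <- tidyr::expand_grid(gene = genes$gene, sample = spec$samples) |>
    left_join(genes, by = "gene") |>
    mutate(cn = purrr::pmap_dbl(
      list(.data$sample, .data$chrom, .data$start_bp, .data$end_bp),
      function(s, c, a, b) planted_level_over(pbp, s, c, a, b))) |>
    select("gene", "sample", "cn")

  structure(
    list(
      segments = segments,
      genes = genes,
      gene_cn = gene_cn,
      ic50 = spec$true_ic50,
      fish_ratio = mutate(spec$fish_spec,
                          ratio = .data$mean_red / .data$mean_green) |>
        select("core", "ratio"),
      seed = spec$seed
    ),
    class = "panel_truth"
  )
}

#' Serialise / restore a panel truth set
#'
#' Plain-text JSON round-trip for [panel_truth()] objects so planted ground
#' truth can be stored next to generated data files.
#'
#' @param truth A `panel_truth`.
#' @param path File path.
#' @return `read_panel_truth()` returns the restored `panel_truth`.
#' @export
write_panel_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_panel_truth
#' @export
read_panel_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(
    segments = as_tibble(raw$segments),
    genes = as_tibble(raw$genes),
    gene_cn = as_tibble(raw$gene_cn),
    ic50 = as_tibble(raw$ic50),
    fish_ratio = as_tibble(raw$fish_ratio),
    seed = as.integer(raw$seed)
  )
  structure(out, class = "panel_truth")
}

#' Generate marker-level copy-number profiles
#'
#' Emits one log2-ratio value per marker per sample: the sum of planted
#' segment levels covering that marker for that sample plus Gaussian marker
#' noise.  Markers lie on a regular per-chromosome grid and are emitted in
#' genomic order.
#'
#' @param spec A [panel_spec()].
#' @return A list with `markers` (tibble: `chrom`, `pos`, one column per
#'   sample) and `truth` (the [panel_truth()]).
#' @export
#' @examples
#' cn <- gen_cn_profiles(panel_spec(n_null_genes = 0, seed = 7))
#' head(cn$markers)
gen_cn_profiles <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  truth <- panel_truth(spec)
  cl <- spec$chrom_lengths
  grid <- purrr::pmap(cl, function(chrom, n_markers, spacing_bp) {
    tibble(chrom = chrom, marker = seq_len(n_markers),
           pos = seq_len(n_markers) * spacing_bp)
  }) |> list_rbind()

  ps <- spec$planted_segments
  base <- matrix(0, nrow = nrow(grid), ncol = spec$n_samples,
                 dimnames = list(NULL, spec$samples))
  if (nrow(ps)) {
    for (i in seq_len(nrow(ps))) {
      rows <- which(grid$chrom == ps$chrom[i] &
                      grid$marker >= ps$start_marker[i] &
                      grid$marker <= ps$end_marker[i])
      base[rows, ps$carriers[[i]]] <- base[rows, ps$carriers[[i]], drop = FALSE] +
        ps$level[i]
    }
  }
  noisy <- with_substream(spec$seed, "synthio/cn", {
    base + matrix(rnorm(length(base), 0, spec$marker_sd),
                  nrow = nrow(base))
  })
  markers <- bind_cols(select(grid, "chrom", "pos"), as_tibble(noisy))
  list(markers = markers, truth = truth)
}

#' Generate a dosage-model expression matrix
#'
#' Expression (log2 scale) of each gene in each sample is a gene-specific
#' baseline plus `slope` times the sample's true copy-number level over the
#' gene interval, plus Gaussian noise.  Null genes have zero slope, so their
#' expression is independent of copy number.  Detection p-values are drawn
#' small for all expressed genes.
#'
#' @param spec A [panel_spec()].
#' @param truth The matching [panel_truth()].
#' @return A list with `expr` (tibble: `gene` plus one column per sample,
#'   log2 scale), `detection` (same shape, detection p-values) and
#'   `annotation` (tibble: `gene`, `chrom`, `start_bp`, `end_bp`).
#' @export
gen_expression <- function(spec, truth) {
  stopifnot(inherits(spec, "panel_spec"), inherits(truth, "panel_truth"))
  genes <- truth$genes
  cn <- tidyr::pivot_wider(truth$gene_cn, names_from = "sample",
                           values_from = "cn")
  cn_mat <- as.matrix(cn[, spec$samples])
  rownames(cn_mat) <- cn$gene
  cn_mat <- cn_mat[genes$gene, , drop = FALSE]

  out <- with_substream(spec$seed, "synthio/expr", {
    baseline <- runif(nrow(genes), 6, 10)
    noise <- matrix(rnorm(nrow(genes) * spec$n_samples), nrow = nrow(genes)) *
      genes$noise_sd
    expr <- baseline + genes$slope * cn_mat + noise
    det <- matrix(runif(length(expr), 0.0001, 0.04), nrow = nrow(expr))
    list(expr = expr, det = det)
  })
  dimnames(out$expr) <- dimnames(out$det) <-
    list(genes$gene, spec$samples)
  list(
    expr = bind_cols(tibble(gene = genes$gene), as_tibble(out$expr)),
    detection = bind_cols(tibble(gene = genes$gene), as_tibble(out$det)),
    annotation = select(genes, "gene", "chrom", "start_bp", "end_bp")
  )
}

#' Generate dose-response plate readings
#'
#' Expected viability follows the four-parameter logistic
#' `v(c) = bottom + (top - bottom) / (1 + (c / IC50)^hill)`; each well reads
#' `control_level * v(c)/100 * (1 + N(0, well_cv))`, with six replicate
#' wells per concentration and six untreated control wells by default.
#' Samples whose true IC50 is censored are generated from an IC50 placed at
#' four times the top tested concentration, so no 50% crossing occurs within
#' the grid.
#'
#' @param spec A [panel_spec()].
#' @param control_level Mean control-well RFU.
#' @return Long tibble: `drug`, `unit`, `sample`, `conc` (`NA` for control
#'   wells), `well`, `rfu`, `is_control`.
#' @export
gen_dose_response <- function(spec, control_level = 10000) {
  stopifnot(inherits(spec, "panel_spec"))
  grids <- spec$drug_grids
  shape <- spec$curve_shape
  nwell <- spec$n_replicate_wells

  with_substream(spec$seed, "synthio/dose", {
    purrr::pmap(spec$true_ic50, function(drug, sample, ic50, censored) {
      g <- grids[grids$drug == drug, ]
      sh <- shape[shape$drug == drug, ]
      conc <- g$conc[[1]]
      ic50_gen <- if (censored) 4 * max(conc) else ic50
      v <- four_pl(conc, sh$top, sh$bottom, sh$hill, ic50_gen)
      nc <- length(conc)
      treated <- tibble(
        drug = drug, unit = g$unit, sample = sample,
        conc = rep(conc, each = nwell),
        well = rep(seq_len(nwell), times = nc),
        rfu = control_level * rep(v, each = nwell) / 100 *
          (1 + rnorm(nc * nwell, 0, spec$well_cv)),
        is_control = FALSE
      )
      control <- tibble(
        drug = drug, unit = g$unit, sample = sample,
        conc = NA_real_, well = seq_len(nwell),
        rfu = control_level * (1 + rnorm(nwell, 0, spec$well_cv)),
        is_control = TRUE
      )
      bind_rows(treated, control)
    }) |> list_rbind()
  })
}

#' Generate per-nucleus two-colour FISH counts
#'
#' Per-nucleus red/green signal counts per core, drawn from Poisson
#' distributions with the spec's per-core means (`noise = "poisson"`) or set
#' exactly to the means (`noise = "none"`).
#'
#' @param spec A [panel_spec()].
#' @param noise `"poisson"` or `"none"`.
#' @return Long tibble: `core`, `nucleus`, `red`, `green`.
#' @export
gen_fish_cores <- function(spec, noise = c("poisson", "none")) {
  stopifnot(inherits(spec, "panel_spec"))
  noise <- match.arg(noise)
  fs <- spec$fish_spec
  with_substream(spec$seed, "synthio/fish", {
    purrr::pmap(fs, function(core, n_nuclei, mean_red, mean_green) {
      if (noise == "poisson") {
        red <- rpois(n_nuclei, mean_red)
        green <- rpois(n_nuclei, mean_green)
      } else {
        red <- rep(mean_red, n_nuclei)
        green <- rep(mean_green, n_nuclei)
      }
      tibble(core = core, nucleus = seq_len(n_nuclei),
             red = red, green = green)
    }) |> list_rbind()
  })
}

#' Generate an RPPA triplicate spot table
#'
#' Log-normal spot intensities around a per-(antibody, sample) mean, spotted
#' in triplicate.  `spot_sdlog = 0` gives identical replicates.
#'
#' @param spec A [panel_spec()].
#' @param spot_sdlog Log-scale SD of replicate spots.
#' @return Long tibble: `antibody`, `sample`, `spot`, `intensity`.
#' @export
gen_rppa <- function(spec, spot_sdlog = 0.1) {
  stopifnot(inherits(spec, "panel_spec"), spot_sdlog >= 0)
  ab <- spec$rppa_antibodies
  with_substream(spec$seed, "synthio/rppa", {
    grid <- tidyr::expand_grid(antibody = ab, sample = spec$samples)
    grid$mean <- exp(rnorm(nrow(grid), log(1000), 0.5))
    grid |>
      tidyr::expand_grid(spot = 1:3) |>
      mutate(intensity = .data$mean * exp(rnorm(n(), 0, spot_sdlog))) |>
      select("antibody", "sample", "spot", "intensity")
  })
}
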