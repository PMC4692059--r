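#' Specify a synthetic colorectal cell-line panel
#'
#' A `panel_spec` bundles every parameter of the synthetic multi-omic panel:
#' the marker grid per chromosome, planted copy-number segments with their
#' carrier samples, dosage-driven and null genes for the expression layer,
#' per-drug true IC50s and 4PL curve shape, plate noise, FISH core
#' composition and the RPPA antibody panel.  All generators
#' ([gen_cn_profiles()], [gen_expression()], [gen_dose_response()],
#' [gen_fish_cores()], [gen_rppa()]) consume the same spec and derive
#' independent random substreams from its single `seed`, so regenerating any
#' one layer is reproducible and independent of the others.
#'
#' The defaults emulate a 15-line colorectal panel: recurrent gains and
#' losses carried by at least 7 of 15 lines, marker noise typical of tiling
#' aCGH, dosage genes whose expression tracks planted copy number with unit
#' slope, eight-point dose grids spanning 2.5-100 uM for the cytotoxics and
#' 2.5-80 nM for the PI3K/mTOR inhibitor with six replicate wells, and a
#' 118-core FISH cohort with 15% planted amplification prevalence.
#'
#' @param n_samples Number of cell lines in the panel.
#' @param chrom_lengths Tibble with columns `chrom`, `n_markers`,
#'   `spacing_bp` describing a regular marker grid per chromosome.
#' @param planted_segments Tibble with columns `chrom`, `start_marker`,
#'   `end_marker`, `level` (log2 ratio) and list-column `carriers`
#'   (character vectors of sample ids).
#' @param marker_sd Marker-level log2-ratio noise SD.
#' @param dosage_genes Tibble with columns `gene`, `chrom`, `start_bp`,
#'   `end_bp`, `slope`, `noise_sd`.
#' @param n_null_genes Number of additional genes with zero dosage slope.
#' @param true_ic50 Tibble with columns `drug`, `sample`, `ic50`
#'   (concentration in the drug's unit) and `censored` (logical; true IC50
#'   above the tested range).
#' @param drug_grids Tibble with columns `drug`, `unit` and list-column
#'   `conc` (strictly increasing tested concentrations).
#' @param curve_shape Tibble with columns `drug`, `top`, `bottom`, `hill`.
#' @param well_cv Relative (coefficient-of-variation) well noise.
#' @param n_replicate_wells Replicate wells per concentration (and controls).
#' @param fish_spec Tibble with columns `core`, `n_nuclei`, `mean_red`,
#'   `mean_green`.
#' @param rppa_antibodies Character vector of antibody names.
#' @param seed Single top-level integer seed.
#'
#' @return An object of class `panel_spec` (a validated list).
#' @export
#' @examples
#' spec <- panel_spec(seed = 1)
#' spec$marker_sd
panel_spec <- function(n_samples = 15,
                       chrom_lengths = default_chrom_lengths(),
                       planted_segments = default_planted_segments(),
                       marker_sd = 0.2,
                       dosage_genes = default_dosage_genes(),
                       n_null_genes = 500,
                       true_ic50 = default_true_ic50(),
                       drug_grids = default_drug_grids(),
                       curve_shape = default_curve_shape(),
                       well_cv = 0.05,
                       n_replicate_wells = 6,
                       fish_spec = default_fish_spec(),
                       rppa_antibodies = default_rppa_antibodies(),
                       seed = 1L) {
  samples <- sprintf("S%02d", seq_len(n_samples))
  spec <- structure(
    list(
      n_samples = n_samples,
      samples = samples,
      chrom_lengths = as_tibble(chrom_lengths),
      planted_segments = as_tibble(planted_segments),
      marker_sd = marker_sd,
      dosage_genes = as_tibble(dosage_genes),
      n_null_genes = n_null_genes,
      true_ic50 = as_tibble(true_ic50),
      drug_grids = as_tibble(drug_grids),
      curve_shape = as_tibble(curve_shape),
      well_cv = well_cv,
      n_replicate_wells = n_replicate_wells,
      fish_spec = as_tibble(fish_spec),
      rppa_antibodies = rppa_antibodies,
      seed = as.integer(seed)
    ),
    class = "panel_spec"
  )
  validate_panel_spec(spec)
}

validate_panel_spec <- function(spec) {
  assert_cols(spec$chrom_lengths, c("chrom", "n_markers", "spacing_bp"),
              "chrom_lengths")
  if (any(spec$chrom_lengths$n_markers < 1)) {
    abort("every chromosome needs at least one marker")
  }
  if (spec$marker_sd < 0) abort("marker_sd must be non-negative")
  if (spec$well_cv < 0) abort("well_cv must be non-negative")

  ps <- spec$planted_segments
  if (nrow(ps)) {
    assert_cols(ps, c("chrom", "start_marker", "end_marker", "level",
                      "carriers"), "planted_segments")
    bad_chrom <- setdiff(ps$chrom, spec$chrom_lengths$chrom)
    if (length(bad_chrom)) {
      abort(sprintf("planted segments reference unknown chromosome(s): %s",
                    paste(bad_chrom, collapse = ", ")))
    }
    carriers <- unique(unlist(ps$carriers))
    if (!all(carriers %in% spec$samples)) {
      abort("planted-segment carriers must be a subset of panel samples")
    }
    n_mark <- setNames(spec$chrom_lengths$n_markers, spec$chrom_lengths$chrom)
    if (any(ps$start_marker < 1) ||
        any(ps$end_marker > n_mark[ps$chrom]) ||
        any(ps$start_marker > ps$end_marker)) {
      abort("planted segment marker indices out of range")
    }
    # Overlapping plants on one sample with conflicting levels are rejected;
    # equal-level overlaps accumulate (marker value is the sum of covering
    # plant levels).
    for (i in seq_len(nrow(ps))) {
      for (j in seq_len(nrow(ps))) {
        if (j <= i || ps$chrom[i] != ps$chrom[j]) next
        if (ps$start_marker[i] <= ps$end_marker[j] &&
            ps$start_marker[j] <= ps$end_marker[i] &&
            ps$level[i] != ps$level[j] &&
            length(intersect(ps$carriers[[i]], ps$carriers[[j]]))) {
          abort(sprintf(
            "planted segments %d and %d overlap on shared carrier(s) with conflicting levels",
            i, j))
        }
      }
    }
  }

  dg <- spec$dosage_genes
  if (nrow(dg)) {
    assert_cols(dg, c("gene", "chrom", "start_bp", "end_bp", "slope",
                      "noise_sd"), "dosage_genes")
    span <- spec$chrom_lengths
    span$max_bp <- span$n_markers * span$spacing_bp
    dg2 <- left_join(dg, span, by = "chrom")
    if (anyNA(dg2$max_bp) || any(dg2$start_bp < 1) ||
        any(dg2$end_bp > dg2$max_bp) || any(dg2$start_bp > dg2$end_bp)) {
      abort("dosage gene intervals must lie within chromosome spans")
    }
    if (anyDuplicated(dg$gene)) abort("dosage gene symbols must be unique")
  }

  assert_cols(spec$true_ic50, c("drug", "sample", "ic50", "censored"),
              "true_ic50")
  assert_cols(spec$drug_grids, c("drug", "unit", "conc"), "drug_grids")
  if (any(map_lgl(spec$drug_grids$conc, ~ any(.x <= 0)))) {
    abort("tested concentrations must be positive")
  }
  assert_cols(spec$curve_shape, c("drug", "top", "bottom", "hill"),
              "curve_shape")
  assert_cols(spec$fish_spec, c("core", "n_nuclei", "mean_red", "mean_green"),
              "fish_spec")
  spec
}

#' @export
print.panel_spec <- function(x, ...) {
  cat("<panel_spec>\n")
  cat("  samples:      ", x$n_samples, "\n")
  cat("  chromosomes:  ", nrow(x$chrom_lengths), " (",
      sum(x$chrom_lengths$n_markers), " markers)\n", sep = "")
  cat("  planted segs: ", nrow(x$planted_segments), "\n")
  cat("  genes:        ", nrow(x$dosage_genes), " dosage + ",
      x$n_null_genes, " null\n", sep = "")
  cat("  drugs:        ", paste(unique(x$drug_grids$drug), collapse = ", "),
      "\n")
  cat("  seed:         ", x$seed, "\n")
  invisible(x)
}

# ---- defaults: the study conditions -----------------------------------------

#' Default synthetic panel conditions
#'
#' Building blocks for the default [panel_spec()]: a six-chromosome regular
#' marker grid, recurrent planted gains/losses carried by 7-9 of 15 lines
#' (one aligned with the 5-FU-sensitive class so dosage genes inside it are
#' also response-associated, plus a focal high-level amplification), twenty
#' unit-slope dosage genes, per-drug true IC50s spanning the sensitive and
#' less-sensitive ranges with censoring above the top tested dose, and a
#' 118-core FISH cohort with 15% planted amplification.
#'
#' @return Tibbles (or a character vector for the antibody panel) consumed by
#'   [panel_spec()].
#' @name panel_defaults
NULL

#' @rdname panel_defaults
#' @export
default_chrom_lengths <- function() {
  tibble(
    chrom = paste0("chr", 1:6),
    n_markers = 400L,
    spacing_bp = 100000L
  )
}

fu_sensitive <- function() sprintf("S%02d", 1:8)
lohp_sensitive <- function() sprintf("S%02d", 1:8)
bez_sensitive <- function() sprintf("S%02d", 1:7)

#' @rdname panel_defaults
#' @export
default_planted_segments <- function() {
  tibble(
    chrom = c("chr1", "chr2", "chr3", "chr4", "chr5"),
    start_marker = c(100L, 200L, 50L, 300L, 150L),
    end_marker = c(180L, 260L, 140L, 340L, 210L),
    level = c(1.2, 1.2, -0.5, 1.5, 0.4),
    carriers = list(
      fu_sensitive(),                       # gain aligned with 5-FU class
      sprintf("S%02d", c(1:3, 9:12)),       # recurrent gain, mixed carriers
      sprintf("S%02d", c(2, 4:8, 11:13)),   # recurrent loss
      sprintf("S%02d", 13:15),              # focal high-level amplification
      sprintf("S%02d", c(1, 3, 5, 7, 9, 11, 13)) # recurrent gain
    )
  )
}

#' @rdname panel_defaults
#' @export
default_dosage_genes <- function() {
  # 10 genes inside the chr1 gain (markers 100-180 => 10.0-18.0 Mb) and 10
  # inside the chr2 gain (markers 200-260 => 20.0-26.0 Mb); unit slope,
  # expression noise SD 0.3.
  tibble(
    gene = sprintf("DOSE%02d", 1:20),
    chrom = rep(c("chr1", "chr2"), each = 10),
    start_bp = c(seq(10100000L, 17300000L, by = 800000L),
                 seq(20100000L, 25500000L, by = 600000L)),
    end_bp = c(seq(10100000L, 17300000L, by = 800000L),
               seq(20100000L, 25500000L, by = 600000L)) + 50000L,
    slope = 1,
    noise_sd = 0.3
  )
}

#' @rdname panel_defaults
#' @export
default_true_ic50 <- function() {
  s <- sprintf("S%02d", 1:15)
  bind_rows(
    tibble(drug = "5-FU", sample = s,
           ic50 = c(3.1, 5, 8, 12, 15, 19.6, 24, 28,
                    40, 55, 60, 75, 90, NA, NA),
           censored = c(rep(FALSE, 13), TRUE, TRUE)),
    tibble(drug = "L-OHP", sample = s,
           ic50 = c(3, 4, 5, 6, 7, 8, 9, 9.5,
                    12, 15, 18, 22, 25, 28, 31.1),
           censored = FALSE),
    tibble(drug = "BEZ235", sample = s,
           ic50 = c(13.4, 18, 22, 23.6, 30, 45, 60, rep(NA, 8)),
           censored = c(rep(FALSE, 7), rep(TRUE, 8)))
  )
}

#' @rdname panel_defaults
#' @export
default_drug_grids <- function() {
  tibble(
    drug = c("5-FU", "L-OHP", "BEZ235"),
    unit = c("uM", "uM", "nM"),
    conc = list(
      exp(seq(log(2.5), log(100), length.out = 8)),
      exp(seq(log(2.5), log(100), length.out = 8)),
      exp(seq(log(2.5), log(80), length.out = 8))
    )
  )
}

#' @rdname panel_defaults
#' @export
default_curve_shape <- function() {
  tibble(drug = c("5-FU", "L-OHP", "BEZ235"), top = 100, bottom = 0, hill = 1)
}

#' @rdname panel_defaults
#' @export
default_fish_spec <- function(n_cores = 118, prevalence = 0.15) {
  amplified <- rep(FALSE, n_cores)
  amplified[seq_len(round(prevalence * n_cores))] <- TRUE
  tibble(
    core = sprintf("core%03d", seq_len(n_cores)),
    n_nuclei = 20L,
    mean_red = if_else(amplified, 6, 2),
    mean_green = 2
  )
}

#' @rdname panel_defaults
#' @export
default_rppa_antibodies <- function() sprintf("AB%02d", 1:31)
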