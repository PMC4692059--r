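# End-to-end orchestration: synthetic panel -> dose response -> copy-number
# segmentation -> differential expression -> integration ledger.

#' Assemble and validate a run configuration
#'
#' Collects every tunable parameter of the pipeline in one validated
#' object: either a synthetic [panel_spec()] or a set of input file paths
#' (exactly one of the two), plus segmentation parameters, call thresholds,
#' sensitivity cutoffs, differential-expression settings, FISH scoring
#' configuration, the recurrence support threshold and the seed.
#'
#' @param seed Integer seed driving every random substream.
#' @param spec A [panel_spec()] (synthetic route), or `NULL`.
#' @param input_paths Named list with elements `markers`, `expression`,
#'   `detection`, `annotation`, `plates` (file-input route), or `NULL`.
#' @param seg A [seg_params()].
#' @param thresholds A [call_thresholds()].
#' @param cutoffs Sensitivity cutoff tibble ([sensitivity_cutoffs()]).
#' @param de List with `fc_min`, `q_max`, `n_permutations`.
#' @param fish A [fish_config()].
#' @param min_support Recurrent-region support threshold.
#' @param outdir Output directory, or `NULL` to skip writing files.
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       spec = panel_spec(seed = seed),
                       input_paths = NULL,
                       seg = seg_params(),
                       thresholds = call_thresholds(),
                       cutoffs = sensitivity_cutoffs(),
                       de = list(fc_min = 1.5, q_max = 0.05,
                                 n_permutations = 1000),
                       fish = fish_config(),
                       min_support = 7,
                       outdir = NULL) {
  if (is.null(spec) == is.null(input_paths)) {
    abort("exactly one of `spec` or `input_paths` must be supplied")
  }
  if (!is.null(input_paths)) {
    needed <- c("markers", "expression", "detection", "annotation", "plates")
    missing <- setdiff(needed, names(input_paths))
    if (length(missing)) {
      abort(sprintf("input_paths is missing: %s",
                    paste(missing, collapse = ", ")))
    }
    absent <- unlist(input_paths[needed])[!file.exists(unlist(input_paths[needed]))]
    if (length(absent)) {
      abort(sprintf("input file(s) not found: %s",
                    paste(absent, collapse = ", ")))
    }
  }
  stopifnot(inherits(seg, "seg_params"), inherits(thresholds, "call_thresholds"),
            inherits(fish, "fish_config"))
  if (!all(c("fc_min", "q_max", "n_permutations") %in% names(de))) {
    abort("de settings need fc_min, q_max and n_permutations")
  }
  if (de$fc_min < 1) abort("fc_min must be at least 1")
  if (de$q_max <= 0 || de$q_max > 1) abort("q_max must lie in (0, 1]")
  if (min_support < 1) abort("min_support must be positive")
  structure(
    list(seed = as.integer(seed), spec = spec, input_paths = input_paths,
         seg = seg, thresholds = thresholds, cutoffs = cutoffs, de = de,
         fish = fish, min_support = min_support, outdir = outdir),
    class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' Serialises a synthetic-route [run_config()] to plain JSON and restores
#' it; reading applies full validation, so a round trip yields an
#' equivalent validated configuration.
#'
#' @param config A `run_config` (synthetic route).
#' @param path File path.
#' @return `read_run_config()` returns the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$spec)) {
    abort("only synthetic-route configurations are serialised")
  }
  s <- config$spec
  payload <- list(
    seed = config$seed,
    seg = unclass(config$seg),
    thresholds = unclass(config$thresholds),
    cutoffs = as.data.frame(config$cutoffs),
    de = config$de,
    fish = unclass(config$fish),
    min_support = config$min_support,
    outdir = config$outdir,
    spec = list(
      n_samples = s$n_samples,
      chrom_lengths = as.data.frame(s$chrom_lengths),
      planted_segments = as.data.frame(
        mutate(s$planted_segments,
               carriers = map_chr(.data$carriers, paste, collapse = ";"))),
      marker_sd = s$marker_sd,
      dosage_genes = as.data.frame(s$dosage_genes),
      n_null_genes = s$n_null_genes,
      true_ic50 = as.data.frame(s$true_ic50),
      drug_grids = as.data.frame(
        mutate(s$drug_grids,
               conc = map_chr(.data$conc, paste, collapse = ";"))),
      curve_shape = as.data.frame(s$curve_shape),
      well_cv = s$well_cv,
      n_replicate_wells = s$n_replicate_wells,
      fish_spec = as.data.frame(s$fish_spec),
      rppa_antibodies = s$rppa_antibodies,
      seed = s$seed
    ))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("seed", "seg", "thresholds", "cutoffs", "de", "fish",
             "min_support", "outdir", "spec")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  s <- raw$spec
  spec <- panel_spec(
    n_samples = s$n_samples,
    chrom_lengths = as_tibble(s$chrom_lengths),
    planted_segments = as_tibble(s$planted_segments) |>
      mutate(carriers = strsplit(.data$carriers, ";", fixed = TRUE)),
    marker_sd = s$marker_sd,
    dosage_genes = as_tibble(s$dosage_genes),
    n_null_genes = s$n_null_genes,
    true_ic50 = as_tibble(s$true_ic50),
    drug_grids = as_tibble(s$drug_grids) |>
      mutate(conc = map(strsplit(.data$conc, ";", fixed = TRUE),
                        as.numeric)),
    curve_shape = as_tibble(s$curve_shape),
    well_cv = s$well_cv,
    n_replicate_wells = s$n_replicate_wells,
    fish_spec = as_tibble(s$fish_spec),
    rppa_antibodies = s$rppa_antibodies,
    seed = s$seed
  )
  run_config(
    seed = raw$seed, spec = spec,
    seg = do.call(seg_params, raw$seg),
    thresholds = do.call(call_thresholds, raw$thresholds),
    cutoffs = as_tibble(raw$cutoffs),
    de = raw$de,
    fish = do.call(fish_config, raw$fish),
    min_support = raw$min_support,
    outdir = raw$outdir
  )
}

# Flat, serialisable view of every tunable parameter; used for the manifest
# so any parameter change is visible there.
config_manifest <- function(config) {
  spec_digest <- if (!is.null(config$spec)) {
    s <- config$spec
    list(n_samples = s$n_samples,
         chrom_lengths = as.data.frame(s$chrom_lengths),
         planted_segments = as.data.frame(
           mutate(s$planted_segments,
                  carriers = map_chr(.data$carriers, paste, collapse = ";"))),
         marker_sd = s$marker_sd,
         dosage_genes = as.data.frame(s$dosage_genes),
         n_null_genes = s$n_null_genes,
         well_cv = s$well_cv,
         n_replicate_wells = s$n_replicate_wells,
         seed = s$seed)
  } else {
    config$input_paths
  }
  list(
    package_version = as.character(packageVersion("crcpanel")),
    seed = config$seed,
    seg = unclass(config$seg),
    thresholds = unclass(config$thresholds),
    cutoffs = as.data.frame(config$cutoffs),
    de = config$de,
    fish = unclass(config$fish),
    min_support = config$min_support,
    inputs = spec_digest
  )
}

#' Run the full panel analysis
#'
#' Orchestrates the pipeline on one configuration: generate (or load) the
#' panel; fit dose-response curves and classify per-drug sensitivity;
#' normalise, segment and call the copy-number profiles and find recurrent
#' gains; filter the expression matrix by detection; map genes into the
#' recurrent gained regions, correlate gene-level copy number with
#' expression (Bonferroni over the genes tested), test the correlated genes
#' against each drug's sensitivity classes, and assemble the candidate
#' ledger.  All randomness derives from the config seed, so two runs with
#' the same config produce identical outputs (byte-identical files when
#' `outdir` is set).
#'
#' @param config A [run_config()].
#' @return A `panel_run` list: `truth`, `ic50_calls`, `classes`,
#'   `segments`, `recurrent_gains`, `correlations`, `associations`,
#'   `ledger`, `manifest`.
#' @export
run_panel_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  if (!is.null(config$spec)) {
    cn <- stage("synthesis", gen_cn_profiles(config$spec))
    truth <- cn$truth
    exprs <- stage("synthesis", gen_expression(config$spec, truth))
    plates <- stage("synthesis", gen_dose_response(config$spec))
    markers <- cn$markers
    expr <- exprs$expr
    detection <- exprs$detection
    annotation <- exprs$annotation
  } else {
    truth <- NULL
    markers <- as_tibble(read.delim(config$input_paths$markers,
                                    check.names = FALSE))
    expr <- as_tibble(read.delim(config$input_paths$expression,
                                 check.names = FALSE))
    detection <- as_tibble(read.delim(config$input_paths$detection,
                                      check.names = FALSE))
    annotation <- as_tibble(read.delim(config$input_paths$annotation,
                                       check.names = FALSE))
    plates <- as_tibble(read.delim(config$input_paths$plates,
                                   check.names = FALSE))
  }

  ic50_calls <- stage("dose-response",
                      fit_panel_ic50(plates, cutoffs = config$cutoffs))
  classes <- select(ic50_calls, "drug", "sample", "sensitivity")

  normalized <- stage("cn-normalise", normalize_markers(markers))
  segments <- stage("cn-segment",
                    segment_markers(normalized, config$seg,
                                    seed = config$seed))
  called <- stage("cn-call", call_segments(segments, config$thresholds))
  gains <- stage("cn-recurrent",
                 find_recurrent_regions(called, "gain",
                                        min_support = config$min_support))

  expr_detected <- stage("expression-filter",
                         detection_filter(expr, detection))

  region_genes <- stage("integration",
                        genes_in_regions(annotation, gains))
  gene_cn <- stage("integration",
                   gene_cn_values(
                     annotation[annotation$gene %in% region_genes, ],
                     called))
  correlations <- stage("integration",
                        correlate_cn_expr(gene_cn, expr_detected))
  correlated <- correlations$gene[correlations$passes]

  associations <- stage("integration",
                        treatment_association(expr_detected, classes,
                                              genes = correlated))
  drug_lists <- if (nrow(associations)) {
    assoc <- filter(associations, .data$associated)
    split(assoc$gene, assoc$drug)
  } else {
    list()
  }
  ledger <- stage("integration", build_ledger(correlated, drug_lists))

  manifest <- config_manifest(config)
  run <- structure(
    list(truth = truth, ic50_calls = ic50_calls, classes = classes,
         segments = segments, called_segments = called,
         recurrent_gains = gains, n_region_genes = length(region_genes),
         correlations = correlations, associations = associations,
         ledger = ledger, manifest = manifest),
    class = "panel_run")

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$outdir, f)
    write_seg(segments, out("segments.seg"))
    write_tsv_deterministic(select(gains, -"supporting") |>
                              mutate(supporting = map_chr(gains$supporting,
                                                          paste,
                                                          collapse = ";")),
                            out("recurrent_gains.tsv"))
    write_tsv_deterministic(ic50_calls, out("sensitivity_calls.tsv"))
    write_tsv_deterministic(correlations, out("cn_expr_correlations.tsv"))
    write_tsv_deterministic(associations, out("treatment_associations.tsv"))
    writeLines(ledger_lines(ledger), out("ledger.txt"))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  run
}

ledger_lines <- function(ledger) {
  c(sprintf("correlated\t%s", paste(ledger$correlated, collapse = ";")),
    map_chr(names(ledger$per_drug),
            ~ sprintf("drug\t%s\t%s", .x,
                      paste(ledger$per_drug[[.x]], collapse = ";"))),
    sprintf("union\t%s", paste(ledger$union, collapse = ";")),
    map_chr(names(ledger$pairwise),
            ~ sprintf("pairwise\t%s\t%s", .x,
                      paste(ledger$pairwise[[.x]], collapse = ";"))),
    sprintf("threeway\t%s", paste(ledger$threeway, collapse = ";")))
}

#' @export
print.panel_run <- function(x, ...) {
  cat("<panel_run>\n")
  cat(sprintf("  IC50 calls: %d  segments: %d  recurrent gains: %d\n",
              nrow(x$ic50_calls), nrow(x$segments),
              nrow(x$recurrent_gains)))
  cat(sprintf("  genes in gained regions: %d  correlated: %d  ledger union: %d\n",
              x$n_region_genes, sum(x$correlations$passes),
              length(x$ledger$union)))
  invisible(x)
}
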