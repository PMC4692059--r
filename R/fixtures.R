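# Packaged fixture tables: the published gained/lost region tables, the
# per-drug differential gene lists, and the hotspot substitution calls with
# their reference CDS fragment.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "crcpanel", mustWork = FALSE)
  if (!nzchar(p) || !file.exists(p)) {
    abort(sprintf("fixture file %s is missing from the installed package",
                  file))
  }
  p
}

split_list <- function(x) {
  map(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) character(0)
    else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

#' Load the packaged fixture tables
#'
#' Reads and validates the packaged transcriptions of the recurrent-gain
#' table (24 regions with their supporting cell-line lists and correlated
#' over-expressed genes), the recurrent-loss table, the per-drug
#' differential gene lists, the hotspot codon-12/13 substitution calls with
#' the reference CDS fragment, and the printed-synonym alias map.  Each
#' region row carries both the printed size and the size recomputed from
#' its own coordinates, because several printed cells disagree with their
#' coordinates.  File checksums are verified against the packaged manifest
#' to guard against silent edits.
#'
#' @return A `fixture_tables` list: `gains`, `losses`, `drug_lists`,
#'   `kras_calls`, `kras_cds`, `aliases`.
#' @export
#' @examples
#' fx <- load_fixtures()
#' nrow(fx$gains)
load_fixtures <- function() {
  manifest <- read.delim(fixture_path("fixture_checksums.tsv"),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(manifest))) {
    got <- unname(tools::md5sum(fixture_path(manifest$file[i])))
    if (!identical(got, manifest$md5[i])) {
      abort(sprintf("fixture checksum mismatch for %s", manifest$file[i]))
    }
  }

  gains <- as_tibble(read.delim(fixture_path("table1_gains.tsv"),
                                stringsAsFactors = FALSE))
  losses <- as_tibble(read.delim(fixture_path("table2_losses.tsv"),
                                 stringsAsFactors = FALSE))
  for (tab in list(gains, losses)) {
    assert_cols(tab, c("cytoband", "start_bp", "end_bp", "size_mb_printed",
                       "cn_range", "cell_lines"), "region fixture")
    if (any(tab$end_bp < tab$start_bp)) {
      abort("fixture region has end before start")
    }
  }
  gains <- gains |>
    mutate(cell_lines = split_list(.data$cell_lines),
           correlated_genes = split_list(.data$correlated_genes),
           size_mb_recomputed = region_size_mb(.data$start_bp, .data$end_bp))
  losses <- losses |>
    mutate(cell_lines = split_list(.data$cell_lines),
           size_mb_recomputed = region_size_mb(.data$start_bp, .data$end_bp))

  drug_lists <- as_tibble(read.delim(fixture_path("drug_gene_lists.tsv"),
                                     stringsAsFactors = FALSE))
  assert_cols(drug_lists, c("drug", "gene", "p_printed"), "drug gene lists")

  kras <- as_tibble(read.delim(fixture_path("kras_calls.tsv"),
                               stringsAsFactors = FALSE))
  assert_cols(kras, c("sample", "cds_pos", "ref", "alt", "label_printed"),
              "substitution calls")

  cds_lines <- readLines(fixture_path("kras_cds_5prime.txt"))
  cds <- paste(cds_lines[!startsWith(cds_lines, "#")], collapse = "")

  aliases_df <- read.delim(fixture_path("gene_aliases.tsv"),
                           stringsAsFactors = FALSE)
  aliases <- setNames(aliases_df$canonical, aliases_df$printed)

  structure(
    list(gains = gains, losses = losses, drug_lists = drug_lists,
         kras_calls = kras, kras_cds = cds, aliases = aliases),
    class = "fixture_tables"
  )
}

#' Drug lists from the fixtures as a named list
#'
#' @param fixtures Output of [load_fixtures()].
#' @return Named list of per-drug gene character vectors.
#' @export
fixture_drug_lists <- function(fixtures = load_fixtures()) {
  split(fixtures$drug_lists$gene, fixtures$drug_lists$drug)
}
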