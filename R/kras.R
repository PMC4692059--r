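# Hotspot codon substitution calling against a reference CDS.

#' Call the protein change of a coding substitution
#'
#' Translates the affected codon before and after a single-base
#' substitution at a 1-based CDS position and labels the change in the
#' usual `X<codon>Y` form (e.g. `G13D`), or `"silent"` when the amino acid
#' is unchanged.  The supplied reference base must match the CDS, guarding
#' transcription errors in variant tables.
#'
#' @param cds Reference coding sequence (character string, ACGT, read in
#'   frame from position 1; a 5' fragment long enough to cover the queried
#'   codon is sufficient).
#' @param pos 1-based position within the CDS (e.g. 38 for c.38).
#' @param ref,alt Reference and substituted bases.
#' @return The protein-change label, or `"silent"`.
#' @export
#' @examples
#' kras <- paste0("ATGACTGAATATAAACTTGTGGTAGTTGGAGCTGGTGGCGTAGGCAAGAGTGCC")
#' call_codon_substitution(kras, 38, "G", "A") # G13D
call_codon_substitution <- function(cds, pos, ref, alt) {
  cds <- toupper(gsub("[^ACGTacgt]", "", cds))
  pos <- as.integer(pos)
  if (pos < 1 || pos > nchar(cds)) {
    abort("substitution position lies outside the reference CDS")
  }
  have <- substr(cds, pos, pos)
  if (have != toupper(ref)) {
    abort(sprintf("reference mismatch at CDS position %d: CDS has %s, variant says %s",
                  pos, have, ref))
  }
  codon_i <- (pos - 1L) %/% 3L + 1L
  codon_start <- (codon_i - 1L) * 3L + 1L
  if (codon_start + 2L > nchar(cds)) {
    abort("reference CDS fragment does not cover the full affected codon")
  }
  codon_ref <- substr(cds, codon_start, codon_start + 2L)
  codon_alt <- codon_ref
  substr(codon_alt, pos - codon_start + 1L, pos - codon_start + 1L) <-
    toupper(alt)
  aa_ref <- unname(Biostrings::GENETIC_CODE[codon_ref])
  aa_alt <- unname(Biostrings::GENETIC_CODE[codon_alt])
  if (aa_ref == aa_alt) "silent" else sprintf("%s%d%s", aa_ref, codon_i, aa_alt)
}
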