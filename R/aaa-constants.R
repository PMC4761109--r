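## Residue alphabet: the 20 standard amino acids plus selenocysteine (U).
## U is a first-class residue and never aliases C; J is reserved as the
## placeholder that I/L collapse to under il_equivalent normalization.
AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWYU"

EXISTENCE_LEVELS <- c("protein_level", "transcript_level", "homology",
                      "predicted", "uncertain")

FEATURE_KINDS <- c("VARIANT", "CHAIN", "PEPTIDE", "SIGNAL", "PROPEP",
                   "TRANSMEM", "MOD_RES", "ALIGN")

#' Evidence code attached to integrated high-throughput proteomics sites
#'
#' Sites derived from combined experimental and computational analysis are
#' labelled with the evidence ontology code ECO:0000244 so that users can
#' distinguish them from literature-curated experimental evidence.
#' @keywords internal
ECO_COMBINED_EVIDENCE <- "ECO:0000244"

is_valid_residues <- function(x) {
  !grepl(sprintf("[^%s]", AA_ALPHABET), x)
}

first_bad_residue <- function(x) {
  m <- regexpr(sprintf("[^%s]", AA_ALPHABET), x)
  if (m < 0) NA_integer_ else as.integer(m)
}

abort_input <- function(msg, class = "unicityr_input_error") {
  abort(msg, class = c(class, "unicityr_error"))
}
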