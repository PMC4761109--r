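# Small hand-built objects reused across test files.

# two single-gene entries sharing the tryptic peptide CCR
two_entry_proteome <- function() {
  proteome(list(
    protein_entry("P00001", "AAKCCR", gene_symbol = "GENEA"),
    protein_entry("P00002", "DDKCCR", gene_symbol = "GENEB")))
}

short_spec <- function(...) digest_spec(max_missed = 0L, min_len = 1L, ...)

# one PSM row in the in-memory shape read_psm_table() produces
make_psm <- function(peptide, mascot = NA_real_, pep = NA_real_,
                     mods = list(), dataset_id = "DS1",
                     spectrum_id = "SP1") {
  m <- if (length(mods) == 0) {
    tibble::tibble(pep_pos = integer(), ptm_name = character(),
                   ascore = double())
  } else {
    tibble::tibble(pep_pos = vapply(mods, `[[`, numeric(1), 1),
                   ptm_name = vapply(mods, `[[`, character(1), 2),
                   ascore = vapply(mods, `[[`, numeric(1), 3))
  }
  out <- tibble::tibble(dataset_id = dataset_id, spectrum_id = spectrum_id,
                        peptide = peptide, mascot = mascot, pep = pep)
  out$mods <- list(m)
  out
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
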