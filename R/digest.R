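## In-silico proteolytic digestion.
##
## Classical trypsin cleaves C-terminal to K or R except when the next
## residue is proline; many search engines use the unconditional rule, here
## called trypsin_p. Only fully specific peptides are generated: both
## termini must be cleavage boundaries (or the ends of the form). The
## digestion dialect must match the upstream search engine, so the spec used
## to build a unicity table is stamped into the table and every report.

#' Digestion specification
#'
#' @param enzyme `"trypsin"` (no cleavage before proline), `"trypsin_p"`
#'   (cleave after every K/R) or `"none"` (the whole form is one peptide).
#' @param max_missed Maximum number of missed cleavages per peptide.
#' @param min_len,max_len Peptide length bounds (residues), applied last.
#'   Peptides shorter than 7 residues are rarely informative for unicity,
#'   hence the default lower bound.
#' @return A list of class `unicityr_digest_spec`.
#' @export
digest_spec <- function(enzyme = c("trypsin", "trypsin_p", "none"),
                        max_missed = 2L, min_len = 7L, max_len = 45L) {
  enzyme <- match.arg(enzyme)
  max_missed <- as.integer(max_missed)
  min_len <- as.integer(min_len)
  max_len <- as.integer(max_len)
  if (max_missed < 0) abort_input("max_missed must be >= 0")
  if (min_len < 1) abort_input("min_len must be >= 1")
  if (max_len < min_len) abort_input("max_len must be >= min_len")
  structure(list(enzyme = enzyme, max_missed = max_missed,
                 min_len = min_len, max_len = max_len),
            class = "unicityr_digest_spec")
}

#' @export
format.unicityr_digest_spec <- function(x, ...) {
  sprintf("%s/missed<=%d/len%d-%d", x$enzyme, x$max_missed, x$min_len,
          x$max_len)
}

#' Positions after which the enzyme cuts
#'
#' @param seq Amino-acid string.
#' @param enzyme Enzyme name as in [digest_spec()].
#' @return Integer vector of internal cleavage positions `i` (the cut falls
#'   between residues `i` and `i + 1`); the C-terminus is never listed.
#' @export
cleavage_sites <- function(seq, enzyme = "trypsin") {
  n <- nchar(seq)
  if (n < 2 || identical(enzyme, "none")) return(integer(0))
  ch <- strsplit(seq, "")[[1]]
  kr <- which(ch[-n] %in% c("K", "R"))
  if (identical(enzyme, "trypsin")) kr <- kr[ch[kr + 1L] != "P"]
  kr
}

#' Digest one amino-acid string
#'
#' @param seq Amino-acid string.
#' @param spec A [digest_spec()].
#' @return Tibble of fully specific peptides with columns `start`, `end`
#'   (1-based inclusive within `seq`), `seq`, `missed`; ordered by
#'   (start, end).
#' @export
digest_sequence <- function(seq, spec = digest_spec()) {
  n <- nchar(seq)
  empty <- tibble(start = integer(), end = integer(), seq = character(),
                  missed = integer())
  if (n == 0) return(empty)
  sites <- cleavage_sites(seq, spec$enzyme)
  bounds <- c(0L, sites, n)
  starts <- head(bounds, -1) + 1L
  ends <- bounds[-1]
  m <- length(starts)
  pieces <- list()
  for (k in 0:min(spec$max_missed, m - 1L)) {
    i <- seq_len(m - k)
    pieces[[k + 1L]] <- tibble(start = starts[i], end = ends[i + k],
                               missed = k)
  }
  pep <- bind_rows(pieces)
  len <- pep$end - pep$start + 1L
  pep <- pep[len >= spec$min_len & len <= spec$max_len, , drop = FALSE]
  if (nrow(pep) == 0) return(empty)
  pep$seq <- substring(seq, pep$start, pep$end)
  pep[order(pep$start, pep$end), c("start", "end", "seq", "missed")]
}

#' Digest one sequence form, keeping provenance
#'
#' @param form A one-row form tibble from [enumerate_sequence_forms()].
#' @param spec A [digest_spec()].
#' @return Tibble of theoretical peptides: peptide columns of
#'   [digest_sequence()] plus the form's provenance columns and
#'   `carries_variant` (`TRUE` only when the peptide actually covers the
#'   substituted position).
#' @export
digest <- function(form, spec = digest_spec()) {
  stopifnot(nrow(form) == 1)
  pep <- digest_sequence(form$seq, spec)
  pep$accession <- form$accession
  pep$form_id <- form$form_id
  pep$form_kind <- form$form_kind
  pep$base <- form$base
  pep$offset <- form$offset
  pep$carries_variant <- !is.na(form$variant_pos) &
    pep$start <= form$variant_pos & pep$end >= form$variant_pos
  pep
}

#' Digest a set of sequence forms
#'
#' Concatenation of per-form digests, form order preserved.
#'
#' @param forms Form tibble from [enumerate_sequence_forms()] or
#'   [enumerate_proteome_forms()].
#' @param spec A [digest_spec()].
#' @return Tibble of theoretical peptides across all forms.
#' @export
digest_proteome <- function(forms, spec = digest_spec()) {
  if (nrow(forms) == 0) {
    return(tibble(start = integer(), end = integer(), seq = character(),
                  missed = integer(), accession = character(),
                  form_id = character(), form_kind = character(),
                  base = character(), offset = integer(),
                  carries_variant = logical()))
  }
  bind_rows(lapply(seq_len(nrow(forms)), function(i) {
    digest(forms[i, ], spec)
  }))
}
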