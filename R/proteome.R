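## Data model: gene-centric protein entries.
##
## One entry describes all protein products of one gene: a single canonical
## sequence (the coordinate anchor for every annotation), zero or more splice
## isoforms with explicit alignment blocks back to the canonical, and a table
## of sequence features (variants, processed chains/peptides, signal and
## propeptides, transmembrane regions, modified residues).

#' Create an empty feature table
#'
#' Features are stored as a tibble with one row per feature. Coordinates are
#' 1-based inclusive and refer to `target_form` (the canonical sequence or an
#' isoform id). `payload` is kind-specific: `A>V` for a VARIANT, a
#' controlled-vocabulary PTM name for MOD_RES, and
#' `canonical_start,iso_start,length` for ALIGN rows in the on-disk table.
#'
#' @return A zero-row tibble with columns `kind`, `target_form`, `begin`,
#'   `end`, `payload`.
#' @export
empty_features <- function() {
  tibble(kind = character(), target_form = character(),
         begin = integer(), end = integer(), payload = character())
}

empty_alignment <- function() {
  tibble(canonical_start = integer(), iso_start = integer(),
         length = integer())
}

#' Construct a splice isoform
#'
#' @param iso_id Isoform identifier, conventionally `ACC-n`.
#' @param seq Amino-acid sequence of the isoform.
#' @param alignment Tibble of identical stretches shared with the canonical
#'   sequence: columns `canonical_start`, `iso_start`, `length`; blocks must
#'   be non-overlapping and sorted on both coordinate systems.
#' @param derived `TRUE` when the alignment was computed (e.g. for a pure
#'   deletion isoform) rather than supplied; computed alignments are never
#'   silently trusted, so the provenance flag travels with the isoform.
#' @return An object of class `unicityr_isoform`.
#' @export
isoform <- function(iso_id, seq, alignment = empty_alignment(),
                    derived = FALSE) {
  structure(
    list(iso_id = iso_id, seq = toupper(seq),
         alignment = as_tibble(alignment), derived = isTRUE(derived)),
    class = "unicityr_isoform"
  )
}

#' Construct a protein entry
#'
#' @param accession Primary accession (unique within a proteome).
#' @param canonical_seq Canonical amino-acid sequence; alphabet
#'   `ACDEFGHIKLMNPQRSTVWY` plus `U` (selenocysteine).
#' @param gene_symbol Gene symbol, or `""` when unknown.
#' @param existence Protein existence level, one of `protein_level`,
#'   `transcript_level`, `homology`, `predicted`, `uncertain`.
#' @param entry_name Entry name used in FASTA headers (defaults to the
#'   accession).
#' @param isoforms List of [isoform()] objects.
#' @param features Feature tibble as in [empty_features()].
#' @return An object of class `unicityr_entry`.
#' @export
protein_entry <- function(accession, canonical_seq, gene_symbol = "",
                          existence = "predicted",
                          entry_name = accession,
                          isoforms = list(), features = empty_features()) {
  existence <- match.arg(existence, EXISTENCE_LEVELS)
  names(isoforms) <- vapply(isoforms, `[[`, character(1), "iso_id")
  structure(
    list(accession = accession, entry_name = entry_name,
         gene_symbol = gene_symbol %||% "",
         canonical_seq = toupper(canonical_seq),
         existence = existence, isoforms = isoforms,
         features = as_tibble(features)),
    class = "unicityr_entry"
  )
}

#' Construct a proteome
#'
#' @param entries List of [protein_entry()] objects.
#' @param release_tag Free-form tag identifying the proteome build; stamped
#'   into unicity tables and output headers.
#' @return An object of class `unicityr_proteome`.
#' @export
proteome <- function(entries, release_tag = "") {
  accs <- vapply(entries, `[[`, character(1), "accession")
  if (anyDuplicated(accs)) {
    abort_input(sprintf("duplicate accession(s): %s",
                        paste(unique(accs[duplicated(accs)]), collapse = ", ")))
  }
  names(entries) <- accs
  structure(list(entries = entries, release_tag = release_tag),
            class = "unicityr_proteome")
}

#' @export
print.unicityr_proteome <- function(x, ...) {
  n_iso <- sum(vapply(x$entries, function(e) length(e$isoforms), integer(1)))
  n_feat <- sum(vapply(x$entries, function(e) nrow(e$features), integer(1)))
  cat(sprintf("<unicityr_proteome> %d entries, %d isoforms, %d features",
              length(x$entries), n_iso, n_feat))
  if (nzchar(x$release_tag)) cat(sprintf(" [release %s]", x$release_tag))
  cat("\n")
  invisible(x)
}

#' @export
print.unicityr_entry <- function(x, ...) {
  cat(sprintf("<unicityr_entry> %s (%s) %d aa, %d isoform(s), %d feature(s), PE=%s\n",
              x$accession,
              if (nzchar(x$gene_symbol)) x$gene_symbol else "no gene symbol",
              nchar(x$canonical_seq), length(x$isoforms), nrow(x$features),
              x$existence))
  invisible(x)
}

form_length <- function(entry, target_form) {
  if (identical(target_form, "canonical")) {
    nchar(entry$canonical_seq)
  } else if (target_form %in% names(entry$isoforms)) {
    nchar(entry$isoforms[[target_form]]$seq)
  } else {
    NA_integer_
  }
}

form_sequence <- function(entry, target_form) {
  if (identical(target_form, "canonical")) {
    entry$canonical_seq
  } else if (target_form %in% names(entry$isoforms)) {
    entry$isoforms[[target_form]]$seq
  } else {
    NA_character_
  }
}

parse_variant_payload <- function(payload) {
  m <- str_match(payload, "^([A-Z])>([A-Z])$")
  if (is.na(m[1, 1])) return(NULL)
  list(original = m[1, 2], alternate = m[1, 3])
}

#' Validate a protein entry against the model invariants
#'
#' Checks the sequence alphabet, feature coordinate bounds, VARIANT payload
#' consistency (the recorded original residue must equal the residue at the
#' variant position in the target form) and isoform alignment-block
#' invariants (sorted, non-overlapping on both coordinate systems, and
#' spanning identical substrings).
#'
#' @param entry A [protein_entry()].
#' @return `entry`, invisibly, or an error describing the first violation.
#' @export
validate_entry <- function(entry) {
  if (!nzchar(entry$canonical_seq)) {
    abort_input(sprintf("%s: canonical sequence is empty", entry$accession))
  }
  bad <- first_bad_residue(entry$canonical_seq)
  if (!is.na(bad)) {
    abort_input(sprintf("%s: illegal residue '%s' at position %d",
                        entry$accession,
                        substr(entry$canonical_seq, bad, bad), bad),
                class = "unicityr_alphabet_error")
  }
  for (iso in entry$isoforms) {
    bad <- first_bad_residue(iso$seq)
    if (!is.na(bad)) {
      abort_input(sprintf("%s: illegal residue '%s' at position %d",
                          iso$iso_id, substr(iso$seq, bad, bad), bad),
                  class = "unicityr_alphabet_error")
    }
    validate_alignment(entry$canonical_seq, iso)
  }
  ft <- entry$features
  for (i in seq_len(nrow(ft))) {
    kind <- ft$kind[i]
    len <- form_length(entry, ft$target_form[i])
    if (is.na(len)) {
      abort_input(sprintf("%s: feature %s targets unknown form '%s'",
                          entry$accession, kind, ft$target_form[i]),
                  class = "unicityr_reference_error")
    }
    if (!(ft$begin[i] >= 1 && ft$begin[i] <= ft$end[i] && ft$end[i] <= len)) {
      abort_input(sprintf("%s: %s feature has out-of-bounds span %d-%d (form length %d)",
                          entry$accession, kind, ft$begin[i], ft$end[i], len))
    }
    if (kind == "VARIANT") {
      if (ft$begin[i] != ft$end[i]) {
        abort_input(sprintf("%s: VARIANT must be a single position", entry$accession))
      }
      pv <- parse_variant_payload(ft$payload[i])
      if (is.null(pv)) {
        abort_input(sprintf("%s: VARIANT payload '%s' is not of form X>Y",
                            entry$accession, ft$payload[i]))
      }
      actual <- substr(form_sequence(entry, ft$target_form[i]),
                       ft$begin[i], ft$begin[i])
      if (!identical(actual, pv$original)) {
        abort_input(sprintf("%s: VARIANT at %d records original '%s' but sequence has '%s'",
                            entry$accession, ft$begin[i], pv$original, actual),
                    class = "unicityr_consistency_error")
      }
    }
  }
  invisible(entry)
}

validate_alignment <- function(canonical_seq, iso) {
  bl <- iso$alignment
  if (nrow(bl) == 0) return(invisible(iso))
  if (is.unsorted(bl$canonical_start, strictly = TRUE) ||
      is.unsorted(bl$iso_start, strictly = TRUE)) {
    abort_input(sprintf("%s: alignment blocks are not sorted", iso$iso_id))
  }
  can_end <- bl$canonical_start + bl$length - 1L
  iso_end <- bl$iso_start + bl$length - 1L
  if (any(head(can_end, -1) >= tail(bl$canonical_start, -1)) ||
      any(head(iso_end, -1) >= tail(bl$iso_start, -1))) {
    abort_input(sprintf("%s: alignment blocks overlap", iso$iso_id))
  }
  if (any(can_end > nchar(canonical_seq)) || any(iso_end > nchar(iso$seq))) {
    abort_input(sprintf("%s: alignment block exceeds sequence bounds", iso$iso_id))
  }
  for (i in seq_len(nrow(bl))) {
    a <- substr(canonical_seq, bl$canonical_start[i], can_end[i])
    b <- substr(iso$seq, bl$iso_start[i], iso_end[i])
    if (!identical(a, b)) {
      abort_input(sprintf("%s: alignment block %d spans non-identical substrings",
                          iso$iso_id, i),
                  class = "unicityr_consistency_error")
    }
  }
  invisible(iso)
}

#' Validate every entry of a proteome
#'
#' @param x A [proteome()].
#' @return `x`, invisibly.
#' @export
validate_proteome <- function(x) {
  if (length(x$entries) == 0) abort_input("proteome has no entries")
  for (e in x$entries) validate_entry(e)
  invisible(x)
}

#' Accession to gene-symbol lookup for a proteome
#' @param x A [proteome()].
#' @return Named character vector, accession -> gene symbol ("" if unknown).
#' @keywords internal
gene_map <- function(x) {
  vapply(x$entries, `[[`, character(1), "gene_symbol")
}
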