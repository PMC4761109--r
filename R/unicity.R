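## The unicity table.
##
## Search engines report a parsimonious protein list, which does not permit
## unambiguous assignment of a peptide to a protein. The unicity table
## resolves ambiguity exhaustively instead: it indexes every theoretical
## peptide of the proteome (over all sequence forms) together with every
## possible assignment, so an observed peptide can be classified as
## protein-unique, gene-unique, shared or absent.
##
## Peptide keys default to I/L-equivalent normalization (isoleucine and
## leucine are isobaric and indistinguishable by standard MS): every I and L
## is replaced by the placeholder J before keying. Exact keys are available
## for non-MS uses. A table never mixes modes; the mode is stamped into the
## table and checked at lookup time.

UNICITY_CLASSES <- c("unique_protein", "unique_gene", "shared", "absent")

#' Normalize a peptide into its table key
#'
#' @param x Character vector of peptide sequences.
#' @param mode `"il_equivalent"` (I and L collapse to J) or `"exact"`.
#' @return Character vector of keys.
#' @export
normalize_peptide <- function(x, mode = c("il_equivalent", "exact")) {
  mode <- match.arg(mode)
  x <- toupper(x)
  if (identical(mode, "il_equivalent")) chartr("IL", "JJ", x) else x
}

check_peptide_alphabet <- function(peptide) {
  bad <- first_bad_residue(peptide)
  if (!is.na(bad)) {
    abort_input(sprintf("peptide contains illegal character '%s' at position %d",
                        substr(peptide, bad, bad), bad),
                class = "unicityr_alphabet_error")
  }
  invisible(peptide)
}

#' Build the unicity table of a proteome
#'
#' Digests every sequence form of every entry under `spec`, keys the
#' resulting theoretical peptides under `normalization`, computes canonical
#' coordinates for every assignment (present iff the peptide's span maps
#' contiguously inside isoform alignment blocks; always present for
#' canonical-based forms) and deduplicates assignments on
#' (key, accession, form, start). Construction is deterministic for fixed
#' inputs.
#'
#' @param x A validated [proteome()].
#' @param spec A [digest_spec()]; stamped into the table so tables are never
#'   mixed across digestion dialects.
#' @param opts A [form_options()].
#' @param normalization Peptide key mode, see [normalize_peptide()].
#' @return An object of class `unicityr_table`.
#' @export
build_unicity_table <- function(x, spec = digest_spec(),
                                opts = form_options(),
                                normalization = c("il_equivalent", "exact")) {
  normalization <- match.arg(normalization)
  if (length(x$entries) == 0) abort_input("cannot build a unicity table from an empty proteome")

  forms <- enumerate_proteome_forms(x, opts)
  pep <- digest_proteome(forms, spec)
  if (nrow(pep) == 0) {
    assignments <- tibble(key = character(), peptide = character(),
                          accession = character(), gene_symbol = character(),
                          form_id = character(), form_kind = character(),
                          base = character(), offset = integer(),
                          start = integer(), end = integer(),
                          canonical_start = integer(),
                          canonical_end = integer(),
                          carries_variant = logical())
  } else {
    pep$key <- normalize_peptide(pep$seq, normalization)
    # canonical coordinates per assignment
    pep$canonical_start <- NA_integer_
    pep$canonical_end <- NA_integer_
    can <- pep$base == "canonical"
    pep$canonical_start[can] <- pep$start[can] + pep$offset[can]
    pep$canonical_end[can] <- pep$end[can] + pep$offset[can]
    iso_rows <- which(!can)
    if (length(iso_rows) > 0) {
      grp <- split(iso_rows, paste(pep$accession[iso_rows],
                                   pep$base[iso_rows], sep = "\r"))
      for (g in grp) {
        entry <- x$entries[[pep$accession[g[1]]]]
        blocks <- entry$isoforms[[pep$base[g[1]]]]$alignment
        cs <- map_block_positions(blocks, pep$start[g] + pep$offset[g])
        ce <- map_block_positions(blocks, pep$end[g] + pep$offset[g])
        # contiguity: the whole span must sit inside alignment blocks
        ok <- !is.na(cs) & !is.na(ce) & (ce - cs == pep$end[g] - pep$start[g])
        pep$canonical_start[g[ok]] <- cs[ok]
        pep$canonical_end[g[ok]] <- ce[ok]
      }
    }
    gm <- gene_map(x)
    pep$gene_symbol <- unname(gm[pep$accession])
    pep$peptide <- pep$seq
    assignments <- as_tibble(pep[, c("key", "peptide", "accession",
                                     "gene_symbol", "form_id", "form_kind",
                                     "base", "offset", "start", "end",
                                     "canonical_start", "canonical_end",
                                     "carries_variant")])
    assignments <- distinct(assignments, .data$key, .data$accession,
                            .data$form_id, .data$start, .keep_all = TRUE)
  }

  index <- new.env(parent = emptyenv(), hash = TRUE,
                   size = max(nrow(assignments), 29L))
  if (nrow(assignments) > 0) {
    split_list <- split(assignments,
                        factor(assignments$key,
                               levels = unique(assignments$key)))
    list2env(split_list, envir = index)
  }
  structure(list(index = index, assignments = assignments, spec = spec,
                 opts = opts, normalization = normalization,
                 release_tag = x$release_tag, genes = gene_map(x),
                 n_keys = length(ls(index))),
            class = "unicityr_table")
}

#' @export
print.unicityr_table <- function(x, ...) {
  cat(sprintf("<unicityr_table> %d peptide keys [%s keys, digest %s%s]\n",
              x$n_keys, x$normalization, format(x$spec),
              if (nzchar(x$release_tag))
                paste0(", release ", x$release_tag) else ""))
  invisible(x)
}

#' Look up all assignments of an observed peptide
#'
#' @param table A [build_unicity_table()] result.
#' @param peptide Peptide sequence (plain amino acids; normalization is
#'   applied internally with the table's mode).
#' @return Assignment tibble (zero rows when the peptide is absent from the
#'   table).
#' @export
unicity_lookup <- function(table, peptide) {
  check_peptide_alphabet(toupper(peptide))
  key <- normalize_peptide(peptide, table$normalization)
  hit <- get0(key, envir = table$index, inherits = FALSE)
  if (is.null(hit)) {
    tibble(key = character(), peptide = character(), accession = character(),
           gene_symbol = character(), form_id = character(),
           form_kind = character(), base = character(), offset = integer(),
           start = integer(), end = integer(), canonical_start = integer(),
           canonical_end = integer(), carries_variant = logical())
  } else {
    hit
  }
}

classify_assignments <- function(assignments) {
  if (nrow(assignments) == 0) return("absent")
  accs <- unique(assignments$accession)
  if (length(accs) == 1) return("unique_protein")
  genes <- unique(assignments$gene_symbol)
  if (length(genes) == 1 && nzchar(genes)) return("unique_gene")
  "shared"
}

#' Classify an observed peptide by ambiguity of assignment
#'
#' Uniqueness is evaluated at the entry (accession) level: an entry is
#' gene-centric, so a peptide matching only the isoforms, processed products
#' or variants of one entry still identifies that entry uniquely.
#'
#' @inheritParams unicity_lookup
#' @return One of `"unique_protein"` (all assignments in one entry),
#'   `"unique_gene"` (several entries, one non-empty gene symbol),
#'   `"shared"` (several genes) or `"absent"`.
#' @export
unicity_classify <- function(table, peptide) {
  classify_assignments(unicity_lookup(table, peptide))
}

#' Serialize a unicity table to a sorted two-column-style TSV
#'
#' Writes one row per assignment, sorted by (key, accession, form, start),
#' plus a JSON sidecar (`<path>.meta.json`) recording the digest spec,
#' normalization mode and proteome release tag. The sorted text form is
#' diff-friendly and byte-stable across builds from identical inputs.
#'
#' @param table A [build_unicity_table()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_unicity_table <- function(table, path) {
  a <- table$assignments
  rows <- a[order(a$key, a$accession, a$form_id, a$start), , drop = FALSE]
  hdr <- paste(c("key", "peptide", "accession", "gene_symbol", "form_id",
                 "form_kind", "start", "end", "canonical_start",
                 "canonical_end", "carries_variant"), collapse = "\t")
  fmt_int <- function(v) ifelse(is.na(v), "NA", as.character(v))
  body <- if (nrow(rows) == 0) character(0) else
    sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s",
            rows$key, rows$peptide, rows$accession, rows$gene_symbol,
            rows$form_id, rows$form_kind, rows$start, rows$end,
            fmt_int(rows$canonical_start), fmt_int(rows$canonical_end),
            ifelse(rows$carries_variant, "true", "false"))
  write_lines(c(hdr, body), path)
  meta <- list(digest = unclass(table$spec),
               apply_variants = table$opts$apply_variants,
               normalization = table$normalization,
               release_tag = table$release_tag, n_keys = table$n_keys)
  write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
             pretty = TRUE)
  invisible(path)
}
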