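## Sequence-form enumeration.
##
## A "form" is one concrete digestible amino-acid string derived from an
## entry: the canonical sequence, an isoform, a processed product (mature
## chain, signal peptide, propeptide, ...) or a single-variant substituted
## copy of any of those. The unicity table is built over all forms so that
## isoform differences, sequence processing events and natural variants are
## all visible to peptide assignment.
##
## Form bookkeeping columns:
##   base    - coordinate system the form lives in ("canonical" or iso_id)
##   offset  - shift of form position 1 within `base` (processed products)
## so that base position = form position + offset, and canonical coordinates
## follow directly (identity for canonical bases, alignment blocks for
## isoform bases).

PROCESSING_KINDS <- c("CHAIN", "PEPTIDE", "PROPEP", "SIGNAL")

#' Options controlling sequence-form enumeration
#'
#' @param apply_variants Also emit single-variant substituted forms (one
#'   VARIANT per emitted form; multi-variant proteoforms are never
#'   combined).
#' @return A list of class `unicityr_form_options`.
#' @export
form_options <- function(apply_variants = TRUE) {
  structure(list(apply_variants = isTRUE(apply_variants)),
            class = "unicityr_form_options")
}

form_row <- function(accession, form_id, form_kind, base, offset, seq,
                     variant_id = NA_character_, variant_pos = NA_integer_) {
  tibble(accession = accession, form_id = form_id, form_kind = form_kind,
         base = base, offset = as.integer(offset), seq = seq,
         variant_id = variant_id, variant_pos = as.integer(variant_pos),
         carries_variant = !is.na(variant_id))
}

#' Enumerate all sequence forms of an entry
#'
#' Emits, in deterministic order: the canonical form; one form per isoform
#' (sorted by isoform id); one form per processing feature
#' (CHAIN/PEPTIDE/PROPEP/SIGNAL, sorted by kind then begin), each the
#' subsequence the feature spans with coordinates remembered relative to its
#' parent; and, when `opts$apply_variants`, one form per VARIANT feature
#' (sorted by position) applied to its target form and to every processing
#' form that contains the variant position. At most one variant is applied
#' per form.
#'
#' @param entry A validated [protein_entry()].
#' @param opts A [form_options()].
#' @return Tibble with one row per form: `accession`, `form_id`,
#'   `form_kind` (canonical/isoform/processed/variant), `base`, `offset`,
#'   `seq`, `variant_id`, `variant_pos`, `carries_variant`.
#' @export
enumerate_sequence_forms <- function(entry, opts = form_options()) {
  out <- list(form_row(entry$accession, entry$accession, "canonical",
                       "canonical", 0L, entry$canonical_seq))

  iso_ids <- sort(names(entry$isoforms))
  for (iso_id in iso_ids) {
    out[[length(out) + 1L]] <- form_row(entry$accession, iso_id, "isoform",
                                        iso_id, 0L,
                                        entry$isoforms[[iso_id]]$seq)
  }

  ft <- entry$features
  proc <- ft[ft$kind %in% PROCESSING_KINDS, , drop = FALSE]
  if (nrow(proc) > 0) {
    proc <- proc[order(proc$kind, proc$begin, proc$end), , drop = FALSE]
  }
  proc_rows <- list()
  for (i in seq_len(nrow(proc))) {
    base <- proc$target_form[i]
    base_id <- if (identical(base, "canonical")) "canonical" else base
    seq <- substr(form_sequence(entry, base), proc$begin[i], proc$end[i])
    fid <- sprintf("%s:%s:%d-%d",
                   if (identical(base, "canonical")) entry$accession else base,
                   proc$kind[i], proc$begin[i], proc$end[i])
    r <- form_row(entry$accession, fid, "processed", base_id,
                  proc$begin[i] - 1L, seq)
    proc_rows[[length(proc_rows) + 1L]] <- r
    out[[length(out) + 1L]] <- r
  }

  if (opts$apply_variants) {
    vars <- ft[ft$kind == "VARIANT", , drop = FALSE]
    if (nrow(vars) > 0) vars <- vars[order(vars$begin), , drop = FALSE]
    for (i in seq_len(nrow(vars))) {
      pv <- parse_variant_payload(vars$payload[i])
      pos <- vars$begin[i]
      target <- vars$target_form[i]
      vid <- sprintf("p.%s%d%s", pv$original, pos, pv$alternate)
      # variant applied to its target base form
      base_seq <- form_sequence(entry, target)
      vseq <- base_seq
      substr(vseq, pos, pos) <- pv$alternate
      parent_id <- if (identical(target, "canonical")) entry$accession else target
      out[[length(out) + 1L]] <- form_row(
        entry$accession, paste0(parent_id, "|", vid), "variant",
        target, 0L, vseq, variant_id = vid, variant_pos = pos)
      # ... and to every processing form of the same target containing pos
      for (j in seq_along(proc_rows)) {
        pr <- proc_rows[[j]]
        pr_target <- proc$target_form[j]
        if (!identical(pr_target, target)) next
        local_pos <- pos - pr$offset
        if (local_pos < 1 || local_pos > nchar(pr$seq)) next
        vseq2 <- pr$seq
        substr(vseq2, local_pos, local_pos) <- pv$alternate
        out[[length(out) + 1L]] <- form_row(
          entry$accession, paste0(pr$form_id, "|", vid), "variant",
          pr$base, pr$offset, vseq2, variant_id = vid,
          variant_pos = local_pos)
      }
    }
  }
  bind_rows(out)
}

#' Enumerate forms for every entry of a proteome
#'
#' @param x A [proteome()].
#' @param opts A [form_options()].
#' @return Tibble of forms, entries in proteome order.
#' @export
enumerate_proteome_forms <- function(x, opts = form_options()) {
  bind_rows(lapply(x$entries, enumerate_sequence_forms, opts = opts))
}

#' Map form-local positions to canonical coordinates
#'
#' @param entry The owning [protein_entry()].
#' @param base Coordinate system of the form (`"canonical"` or an iso_id).
#' @param offset Offset of form position 1 within `base`.
#' @param pos Integer vector of 1-based positions within the form.
#' @return Integer vector of canonical positions (`NA` where unmapped).
#' @keywords internal
map_form_positions <- function(entry, base, offset, pos) {
  base_pos <- as.integer(pos) + as.integer(offset)
  if (identical(base, "canonical")) return(base_pos)
  map_block_positions(entry$isoforms[[base]]$alignment, base_pos)
}
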