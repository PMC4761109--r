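## Isoform <-> canonical coordinate mapping.
##
## All annotation anchors to the canonical sequence of an entry. Isoform
## positions are translated through the explicit alignment blocks; positions
## in isoform-specific regions (between blocks) have no canonical image.

map_block_positions <- function(blocks, pos) {
  # vectorized: canonical image of isoform positions, NA outside blocks
  out <- rep(NA_integer_, length(pos))
  if (nrow(blocks) == 0 || length(pos) == 0) return(out)
  iso_end <- blocks$iso_start + blocks$length - 1L
  for (i in seq_len(nrow(blocks))) {
    hit <- !is.na(pos) & pos >= blocks$iso_start[i] & pos <= iso_end[i]
    out[hit] <- blocks$canonical_start[i] + (pos[hit] - blocks$iso_start[i])
  }
  out
}

#' Map an isoform position onto the canonical sequence
#'
#' @param entry A [protein_entry()].
#' @param iso_id Identifier of one of the entry's isoforms.
#' @param pos 1-based position(s) within the isoform sequence.
#' @return Integer vector of canonical positions; `NA` where the position
#'   falls in an isoform-specific region (no alignment block covers it).
#' @export
map_isoform_position_to_canonical <- function(entry, iso_id, pos) {
  iso <- entry$isoforms[[iso_id]]
  if (is.null(iso)) {
    abort_input(sprintf("%s: unknown isoform '%s'", entry$accession, iso_id),
                class = "unicityr_reference_error")
  }
  if (any(pos < 1 | pos > nchar(iso$seq))) {
    abort_input(sprintf("%s: position out of range 1..%d", iso_id,
                        nchar(iso$seq)),
                class = "unicityr_bounds_error")
  }
  map_block_positions(iso$alignment, as.integer(pos))
}

#' Derive alignment blocks for a pure-deletion isoform
#'
#' Convenience for isoforms that are the canonical sequence with one internal
#' stretch removed. The resulting blocks carry the `derived` provenance flag
#' on the isoform; supplied alignments are always preferred to computed ones.
#'
#' @param canonical_seq Canonical sequence.
#' @param iso_seq Isoform sequence (must be canonical minus one contiguous
#'   internal stretch).
#' @return Alignment tibble, or `NULL` when the isoform is not a single
#'   contiguous deletion of the canonical.
#' @export
derive_deletion_alignment <- function(canonical_seq, iso_seq) {
  n <- nchar(canonical_seq); m <- nchar(iso_seq)
  if (m >= n) return(NULL)
  can <- strsplit(canonical_seq, "")[[1]]
  iso <- strsplit(iso_seq, "")[[1]]
  # longest common prefix / suffix
  p <- 0L
  while (p < m && can[p + 1L] == iso[p + 1L]) p <- p + 1L
  s <- 0L
  while (s < m - p && can[n - s] == iso[m - s]) s <- s + 1L
  if (p + s != m) return(NULL)
  bl <- empty_alignment()
  if (p > 0) bl <- add_row(bl, canonical_start = 1L, iso_start = 1L, length = p)
  if (s > 0) bl <- add_row(bl, canonical_start = n - s + 1L,
                           iso_start = m - s + 1L, length = s)
  bl
}
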