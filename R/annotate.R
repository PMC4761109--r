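## Site annotation.
##
## Accepted, localized site candidates are mapped through the unicity table.
## Only protein-unique peptides contribute to site annotation (the strictest
## reading of "unambiguous"); gene-unique and shared peptides are reported
## but never annotated. Mapped sites must also be biologically plausible -
## the default rule rejects phosphorylation sites that fall inside a
## transmembrane region. Surviving sites are merged per (accession,
## canonical position, PTM) into evidence records carrying ECO:0000244.

#' Resolve a peptide against the unicity table
#'
#' @param peptide Observed peptide sequence.
#' @param table A [build_unicity_table()] result.
#' @return List with `status` (`"unique"`, `"rejected_ambiguous"`,
#'   `"rejected_absent"`), `class` (the [unicity_classify()] value) and
#'   `assignments` (tibble; populated only for unique peptides).
#' @export
resolve_peptide <- function(peptide, table) {
  assignments <- unicity_lookup(table, peptide)
  cls <- classify_assignments(assignments)
  status <- switch(cls,
                   unique_protein = "unique",
                   absent = "rejected_absent",
                   "rejected_ambiguous")
  list(status = status, class = cls,
       assignments = if (identical(status, "unique")) assignments else
         assignments[0, ])
}

#' Is a PTM name in the phosphorylation class?
#' @param ptm_name Character vector of controlled-vocabulary PTM names.
#' @return Logical vector.
#' @export
is_phospho <- function(ptm_name) {
  grepl("^Phospho", ptm_name)
}

#' Default biological-relevance rule set
#'
#' Each rule is a function `(entry, canonical_pos, ptm_name)` returning a
#' rejection verdict string or `NULL` to accept. The default set contains a
#' single rule: a phosphorylation site must not be located in a
#' transmembrane region (inclusive interval check against TRANSMEM
#' features on the canonical sequence). Other PTM classes pass the rule;
#' users can register additional rules for additional classes.
#'
#' @return Named list of rule functions.
#' @export
relevance_rules <- function() {
  list(
    transmembrane_phospho = function(entry, canonical_pos, ptm_name) {
      if (!is_phospho(ptm_name)) return(NULL)
      tm <- entry$features[entry$features$kind == "TRANSMEM" &
                             entry$features$target_form == "canonical", ,
                           drop = FALSE]
      if (nrow(tm) > 0 &&
          any(canonical_pos >= tm$begin & canonical_pos <= tm$end)) {
        return("rejected_transmembrane")
      }
      NULL
    }
  )
}

#' Check the biological relevance of a mapped PTM site
#'
#' @param entry The [protein_entry()] the site maps to.
#' @param canonical_pos Canonical position of the site (`NA` when the site
#'   could not be mapped to canonical coordinates).
#' @param ptm_name PTM name.
#' @param rules Rule registry as in [relevance_rules()].
#' @return One of `"accepted"`, `"rejected_transmembrane"`,
#'   `"rejected_unmappable"` (or another rule's verdict string).
#' @export
check_biological_relevance <- function(entry, canonical_pos, ptm_name,
                                       rules = relevance_rules()) {
  if (is.na(canonical_pos)) return("rejected_unmappable")
  for (rule in rules) {
    verdict <- rule(entry, canonical_pos, ptm_name)
    if (!is.null(verdict)) return(verdict)
  }
  "accepted"
}

#' Merge accepted site candidates into evidence records
#'
#' Groups by (accession, canonical position, PTM name); supporting spectra
#' are deduplicated on (dataset_id, spectrum_id); output is sorted by
#' accession then position then PTM name.
#'
#' @param sites Tibble of accepted sites with columns `accession`,
#'   `canonical_position`, `ptm_name`, `dataset_id`, `spectrum_id`,
#'   `peptide`.
#' @return Tibble of class-like evidence rows: `accession`,
#'   `canonical_position`, `ptm_name`, `evidence_code` (ECO:0000244),
#'   `n_datasets`, `n_spectra`, `peptides` (unique supporting peptides,
#'   comma-separated) and a list-column `supporting`.
#' @export
merge_site_evidence <- function(sites) {
  empty <- tibble(accession = character(), canonical_position = integer(),
                  ptm_name = character(), evidence_code = character(),
                  n_datasets = integer(), n_spectra = integer(),
                  peptides = character(), supporting = list())
  if (is.null(sites) || nrow(sites) == 0) return(empty)
  sites |>
    distinct(.data$accession, .data$canonical_position, .data$ptm_name,
             .data$dataset_id, .data$spectrum_id, .keep_all = TRUE) |>
    group_by(.data$accession, .data$canonical_position, .data$ptm_name) |>
    summarise(
      evidence_code = ECO_COMBINED_EVIDENCE,
      n_datasets = n_distinct(.data$dataset_id),
      n_spectra = n(),
      peptides = paste(sort(unique(.data$peptide)), collapse = ","),
      supporting = list(pick(dataset_id, spectrum_id, peptide)),
      .groups = "drop") |>
    arrange(.data$accession, .data$canonical_position, .data$ptm_name)
}

#' Promote the existence level of an entry on peptide evidence
#'
#' When an entry whose existence is below `protein_level` is supported by at
#' least `k` distinct validated protein-unique peptides, its existence is
#' promoted to `protein_level`. The change is returned with an audit note
#' and never applied silently.
#'
#' @param entry A [protein_entry()].
#' @param peptides Character vector of distinct validated unique peptides
#'   supporting the entry.
#' @param k Minimum number of distinct peptides required (default 2).
#' @return List: `entry` (possibly updated), `promoted` (logical), `note`.
#' @export
promote_protein_existence <- function(entry, peptides, k = 2L) {
  peptides <- unique(peptides)
  if (identical(entry$existence, "protein_level")) {
    return(list(entry = entry, promoted = FALSE,
                note = sprintf("%s: already at protein_level",
                               entry$accession)))
  }
  if (length(peptides) < k) {
    return(list(entry = entry, promoted = FALSE,
                note = sprintf("%s: insufficient peptides (%d < %d)",
                               entry$accession, length(peptides), k)))
  }
  old <- entry$existence
  entry$existence <- "protein_level"
  list(entry = entry, promoted = TRUE,
       note = sprintf("%s: %s -> protein_level on %d distinct unique peptides",
                      entry$accession, old, length(peptides)))
}

#' Write merged site evidence to an annotation TSV
#'
#' Columns: `accession`, `position`, `ptm_name`, `evidence_code`,
#' `n_datasets`, `n_spectra`, `peptides`. Header comment lines record the
#' proteome release tag, digestion spec and filter policy so a table can
#' never be mistaken for one produced under different settings. Output is
#' deterministically ordered.
#'
#' @param sites Tibble from [merge_site_evidence()].
#' @param path Output path.
#' @param release_tag,spec,policy Provenance stamped into the header.
#' @param position_column Name of the coordinate column in `sites`
#'   (canonical by default; isoform-section outputs use `iso_position` with
#'   accession column carrying the iso id).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(sites, path, release_tag = "",
                              spec = digest_spec(),
                              policy = filter_policy(),
                              position_column = "canonical_position") {
  header <- c(
    sprintf("# unicityr annotations; release=%s", release_tag),
    sprintf("# digest=%s", format(spec)),
    sprintf("# policy=%s", format(policy)),
    paste(c("accession", "position", "ptm_name", "evidence_code",
            "n_datasets", "n_spectra", "peptides"), collapse = "\t"))
  body <- if (is.null(sites) || nrow(sites) == 0) character(0) else
    sprintf("%s\t%d\t%s\t%s\t%d\t%d\t%s", sites$accession,
            sites[[position_column]], sites$ptm_name, sites$evidence_code,
            sites$n_datasets, sites$n_spectra, sites$peptides)
  write_lines(c(header, body), path)
  invisible(path)
}
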