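## PSM ingestion and score filtering.
##
## Spectra are never re-searched: the published peptide-spectrum matches are
## reprocessed by applying stringent cut-offs to the scores the publication
## provides. Identification passes on Mascot score OR posterior error
## probability; PTM site localization additionally requires an Ascore,
## because Ascore measures localization confidence, not identification.
## "Minimum of 40 / 19" thresholds are inclusive (>=); "< 1%" is strict.
## Missing scores never default to 0 - missingness is its own rejection
## reason, to keep audit trails honest.

#' Controlled vocabulary of PTM names
#'
#' A compact subset of the UniProt controlled vocabulary for modified
#' residues, sufficient for phosphorylation, acetylation and methylation
#' evidence. Extend via the `extra` argument of [read_psm_table()].
#'
#' @return Character vector of PTM names.
#' @export
ptm_vocabulary <- function() {
  c("Phosphoserine", "Phosphothreonine", "Phosphotyrosine",
    "Phosphohistidine", "N6-acetyllysine", "N-acetylmethionine",
    "N-acetylserine", "N-acetylalanine", "Omega-N-methylarginine",
    "Asymmetric dimethylarginine", "Symmetric dimethylarginine",
    "N6-methyllysine", "N6,N6-dimethyllysine", "N6,N6,N6-trimethyllysine",
    "N6-succinyllysine", "N6-malonyllysine", "Citrulline",
    "S-nitrosocysteine", "4-hydroxyproline", "Sulfotyrosine")
}

parse_mods_field <- function(mods, peptide_len) {
  # "pos:NAME:ascore;pos:NAME:ascore" - ascore may be empty or NA (missing)
  if (is.na(mods) || !nzchar(mods)) {
    return(tibble(pep_pos = integer(), ptm_name = character(),
                  ascore = double()))
  }
  parts <- strsplit(mods, ";", fixed = TRUE)[[1]]
  out <- lapply(parts, function(p) {
    f <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(f) < 2 || length(f) > 3) {
      abort_input(sprintf("malformed mod '%s'", p), "unicityr_row_error")
    }
    pos <- suppressWarnings(as.integer(f[1]))
    if (is.na(pos)) {
      abort_input(sprintf("malformed mod position in '%s'", p),
                  "unicityr_row_error")
    }
    if (pos < 1 || pos > peptide_len) {
      abort_input(sprintf("mod position %d outside peptide of length %d",
                          pos, peptide_len), "unicityr_row_error")
    }
    ascore <- if (length(f) < 3 || !nzchar(f[3]) || identical(f[3], "NA"))
      NA_real_ else suppressWarnings(as.numeric(f[3]))
    if (length(f) == 3 && nzchar(f[3]) && !identical(f[3], "NA") &&
        is.na(ascore)) {
      abort_input(sprintf("malformed ascore in '%s'", p), "unicityr_row_error")
    }
    tibble(pep_pos = pos, ptm_name = f[2], ascore = ascore)
  })
  bind_rows(out)
}

#' Read a PSM table
#'
#' Canonical tab-separated dialect with header columns `dataset_id`,
#' `spectrum_id`, `peptide`, `mods`, `mascot`, `pep`. The `mods` field
#' encodes modifications as `pos:NAME:ascore;...` (positions 1-based within
#' the peptide; ascore empty or `NA` when not reported; whole field empty
#' for unmodified peptides). Missing numeric scores are preserved as `NA`,
#' never coerced to zero. Rows that fail to parse (malformed mods, mod
#' position out of range, unknown PTM name, illegal peptide characters) are
#' skipped and reported, or abort under `strict = TRUE`.
#'
#' @param path Path to the PSM TSV.
#' @param strict Abort on the first bad row instead of skip-and-report.
#' @param vocabulary Allowed PTM names; defaults to [ptm_vocabulary()].
#' @param extra Additional PTM names to allow.
#' @return Tibble with one row per PSM (`dataset_id`, `spectrum_id`,
#'   `peptide`, `mascot`, `pep`) and a list-column `mods` of per-PSM mod
#'   tibbles (`pep_pos`, `ptm_name`, `ascore`). Skipped rows are recorded in
#'   `attr(, "problems")`.
#' @export
read_psm_table <- function(path, strict = FALSE,
                           vocabulary = ptm_vocabulary(), extra = character()) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  vocabulary <- c(vocabulary, extra)
  tab <- read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = cols(dataset_id = col_character(),
                                   spectrum_id = col_character(),
                                   peptide = col_character(),
                                   mods = col_character(),
                                   mascot = col_double(),
                                   pep = col_double()))
  problems <- tibble(line = integer(), reason = character())
  keep <- logical(nrow(tab))
  mods_list <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    res <- tryCatch({
      pepseq <- toupper(tab$peptide[i])
      bad <- first_bad_residue(pepseq)
      if (!is.na(bad)) {
        abort_input(sprintf("illegal peptide character '%s'",
                            substr(pepseq, bad, bad)), "unicityr_row_error")
      }
      if (!is.na(tab$pep[i]) && (tab$pep[i] < 0 || tab$pep[i] > 1)) {
        abort_input(sprintf("pep %g outside [0, 1]", tab$pep[i]),
                    "unicityr_row_error")
      }
      m <- parse_mods_field(tab$mods[i], nchar(pepseq))
      unknown <- setdiff(m$ptm_name, vocabulary)
      if (length(unknown) > 0) {
        abort_input(sprintf("PTM name(s) not in controlled vocabulary: %s",
                            paste(unknown, collapse = ", ")),
                    "unicityr_row_error")
      }
      m
    }, unicityr_row_error = function(cnd) {
      if (strict) abort_input(sprintf("PSM table row %d: %s", i,
                                      conditionMessage(cnd)))
      problems <<- add_row(problems, line = i,
                           reason = conditionMessage(cnd))
      NULL
    })
    if (!is.null(res)) {
      keep[i] <- TRUE
      mods_list[[i]] <- res
    }
  }
  out <- tab[keep, c("dataset_id", "spectrum_id", "peptide", "mascot", "pep")]
  out$peptide <- toupper(out$peptide)
  out$mods <- mods_list[keep]
  if (nrow(problems) > 0) {
    warn(sprintf("PSM table %s: skipped %d row(s); see attr(, 'problems')",
                 basename(path), nrow(problems)))
  }
  attr(out, "problems") <- problems
  out
}

#' Score-threshold policy
#'
#' Defaults are the integration thresholds: Mascot score >= 40, posterior
#' error probability < 1%, Ascore >= 19.
#'
#' @param mascot_min Minimum Mascot score (inclusive).
#' @param pep_max Posterior-error-probability cut-off (strict: `pep <
#'   pep_max` passes).
#' @param ascore_min Minimum PTM localization score (inclusive).
#' @param combination `"any"`: identification passes on Mascot OR PEP;
#'   `"all"`: both must be present and pass.
#' @return A list of class `unicityr_filter_policy`.
#' @export
filter_policy <- function(mascot_min = 40, pep_max = 0.01, ascore_min = 19,
                          combination = c("any", "all")) {
  combination <- match.arg(combination)
  if (!all(is.finite(c(mascot_min, pep_max, ascore_min))) ||
      any(c(mascot_min, pep_max, ascore_min) < 0)) {
    abort_input("policy thresholds must be finite and >= 0")
  }
  structure(list(mascot_min = mascot_min, pep_max = pep_max,
                 ascore_min = ascore_min, combination = combination),
            class = "unicityr_filter_policy")
}

#' @export
format.unicityr_filter_policy <- function(x, ...) {
  sprintf("mascot>=%g %s pep<%g; ascore>=%g", x$mascot_min,
          if (x$combination == "any") "OR" else "AND", x$pep_max,
          x$ascore_min)
}

#' Apply the identification filter
#'
#' A record is accepted iff (Mascot present and >= `mascot_min`) OR (PEP
#' present and < `pep_max`) under the default `"any"` combination; under
#' `"all"`, both scores must be present and pass. Records with both scores
#' missing are always rejected with reason `"no usable score"`. The
#' partition is exhaustive and disjoint.
#'
#' @param records PSM tibble from [read_psm_table()].
#' @param policy A [filter_policy()].
#' @return List with tibbles `accepted` and `rejected` (the latter with a
#'   `reason` column).
#' @export
apply_identification_filter <- function(records, policy = filter_policy()) {
  mascot_ok <- !is.na(records$mascot) & records$mascot >= policy$mascot_min
  pep_ok <- !is.na(records$pep) & records$pep < policy$pep_max
  no_score <- is.na(records$mascot) & is.na(records$pep)
  pass <- if (identical(policy$combination, "any")) {
    mascot_ok | pep_ok
  } else {
    mascot_ok & pep_ok
  }
  pass <- pass & !no_score
  rejected <- records[!pass, , drop = FALSE]
  rejected$reason <- ifelse(no_score[!pass], "no usable score",
                            "below identification thresholds")
  list(accepted = records[pass, , drop = FALSE], rejected = rejected)
}

#' Expand accepted PSMs into PTM site candidates
#'
#' Each modification on an identification-accepted PSM yields one site
#' candidate. A candidate is localized iff its Ascore is present and
#' >= `ascore_min`; non-localized candidates are retained (the peptide still
#' counts as existence evidence) but excluded from site annotation.
#'
#' @param accepted Accepted PSM tibble from [apply_identification_filter()].
#' @param policy A [filter_policy()].
#' @return Tibble with one row per (PSM, mod): `dataset_id`, `spectrum_id`,
#'   `peptide`, `pep_pos`, `ptm_name`, `ascore`, `localized`, `reason`
#'   (`NA` when localized).
#' @export
apply_site_filter <- function(accepted, policy = filter_policy()) {
  empty <- tibble(dataset_id = character(), spectrum_id = character(),
                  peptide = character(), pep_pos = integer(),
                  ptm_name = character(), ascore = double(),
                  localized = logical(), reason = character())
  if (nrow(accepted) == 0) return(empty)
  rows <- lapply(seq_len(nrow(accepted)), function(i) {
    m <- accepted$mods[[i]]
    if (is.null(m) || nrow(m) == 0) return(NULL)
    tibble(dataset_id = accepted$dataset_id[i],
           spectrum_id = accepted$spectrum_id[i],
           peptide = accepted$peptide[i],
           pep_pos = m$pep_pos, ptm_name = m$ptm_name, ascore = m$ascore)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  out$localized <- !is.na(out$ascore) & out$ascore >= policy$ascore_min
  out$reason <- ifelse(out$localized, NA_character_,
                       ifelse(is.na(out$ascore), "no localization score",
                              "ascore below threshold"))
  out
}

#' Read dataset metadata (MIAPE-style checklist fields)
#'
#' Accepts JSON (a single object or an array of objects) or TSV with header
#' `dataset_id raw_data_location instrument search_software enzyme
#' reported_fdr`.
#'
#' @param path Path to the metadata file.
#' @return Tibble with one row per dataset.
#' @export
read_dataset_metadata <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  fields <- c("dataset_id", "raw_data_location", "instrument",
              "search_software", "enzyme", "reported_fdr")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- read_json(path, simplifyVector = TRUE)
    if (!is.data.frame(obj)) obj <- as_tibble(obj[lengths(obj) > 0])
    obj <- as_tibble(obj)
  } else {
    obj <- read_tsv(path, comment = "#", show_col_types = FALSE)
  }
  for (f in fields) {
    if (!f %in% names(obj)) {
      obj[[f]] <- if (f == "reported_fdr") NA_real_ else NA_character_
    }
  }
  obj$reported_fdr <- suppressWarnings(as.numeric(obj$reported_fdr))
  obj[, fields]
}

#' Validate dataset metadata against the reporting checklist
#'
#' The dataset fails (and is gated out of the pipeline unless
#' `allow_unverified` is set there) when `raw_data_location`, `instrument`
#' or `search_software` is empty; a missing `reported_fdr` only downgrades
#' to a warning.
#'
#' @param meta One-row metadata tibble (or list) as from
#'   [read_dataset_metadata()].
#' @return List of class `unicityr_metadata_report`: `dataset_id`, `checks`
#'   (tibble `field`/`status`), `verdict` (`"pass"` or `"fail"`),
#'   `warnings`.
#' @export
validate_dataset_metadata <- function(meta) {
  meta <- as.list(meta)
  if (is.null(meta$dataset_id) || is.na(meta$dataset_id) ||
      !nzchar(meta$dataset_id)) {
    abort_input("dataset_id must be non-empty")
  }
  required <- c("raw_data_location", "instrument", "search_software")
  present <- vapply(required, function(f) {
    v <- meta[[f]]
    !is.null(v) && !is.na(v) && nzchar(as.character(v))
  }, logical(1))
  fdr_present <- !is.null(meta$reported_fdr) && !is.na(meta$reported_fdr)
  checks <- tibble(
    field = c(required, "reported_fdr"),
    status = c(unname(ifelse(present, "pass", "fail")),
               if (fdr_present) "pass" else "warn"))
  structure(list(dataset_id = meta$dataset_id, checks = checks,
                 verdict = if (all(present)) "pass" else "fail",
                 warnings = if (fdr_present) character(0) else
                   "reported_fdr missing"),
            class = "unicityr_metadata_report")
}

#' @export
print.unicityr_metadata_report <- function(x, ...) {
  cat(sprintf("<metadata check> dataset %s: %s\n", x$dataset_id, x$verdict))
  for (i in seq_len(nrow(x$checks))) {
    cat(sprintf("  %-18s %s\n", x$checks$field[i], x$checks$status[i]))
  }
  invisible(x)
}
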