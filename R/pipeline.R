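## End-to-end orchestration.
##
## Stage order: dataset metadata check -> identification filter -> site
## (localization) filter -> unicity resolution -> biological-relevance
## check -> evidence merge -> outputs. Every rejection is written to an
## audit log (JSON lines, one record per rejection with stage and reason),
## totals are conserved at every stage boundary, and re-running an
## unchanged config produces byte-identical outputs.

REJECTION_KEYS <- c("identification_below_threshold",
                    "identification_no_usable_score",
                    "site_not_localized",
                    "peptide_ambiguous", "peptide_absent",
                    "site_on_ambiguous_peptide", "site_on_absent_peptide",
                    "site_position_ambiguous", "site_transmembrane",
                    "site_unmappable", "datasets_skipped_metadata")

#' Construct a run summary
#'
#' Fixed-shape record of the pipeline's counting triple and per-stage
#' rejection counts. Peptide-level counters count distinct normalized
#' peptide keys, not PSMs; PSM-level counts are reported alongside for
#' transparency.
#'
#' @param n_input_psms Rows read across all PSM tables.
#' @param n_accepted_identifications PSMs passing the identification filter.
#' @param n_distinct_accepted_peptides Distinct peptide keys among accepted
#'   PSMs (regardless of unicity).
#' @param n_validated_unique_peptides Distinct accepted peptide keys that
#'   resolve to a single entry in the unicity table.
#' @param n_localized_sites Localized site candidates on accepted PSMs.
#' @param n_annotated_sites Merged canonical-coordinate evidence records.
#' @param n_isoform_sites Merged isoform-coordinate evidence records
#'   (isoform-specific regions, reported separately).
#' @param n_entries_covered Distinct accessions in canonical site evidence.
#' @param n_entries_promoted Entries promoted to protein-level existence.
#' @param rejections Named list of per-stage rejection counts; missing keys
#'   default to 0.
#' @return List of class `unicityr_run_summary`.
#' @export
run_summary <- function(n_input_psms = 0L, n_accepted_identifications = 0L,
                        n_distinct_accepted_peptides = 0L,
                        n_validated_unique_peptides = 0L,
                        n_localized_sites = 0L, n_annotated_sites = 0L,
                        n_isoform_sites = 0L, n_entries_covered = 0L,
                        n_entries_promoted = 0L, rejections = list()) {
  rej <- setNames(as.list(rep(0L, length(REJECTION_KEYS))), REJECTION_KEYS)
  for (k in names(rejections)) {
    if (!k %in% REJECTION_KEYS) {
      abort_input(sprintf("unknown rejection key '%s'", k))
    }
    rej[[k]] <- as.integer(rejections[[k]])
  }
  structure(list(
    n_input_psms = as.integer(n_input_psms),
    n_accepted_identifications = as.integer(n_accepted_identifications),
    n_distinct_accepted_peptides = as.integer(n_distinct_accepted_peptides),
    n_validated_unique_peptides = as.integer(n_validated_unique_peptides),
    n_localized_sites = as.integer(n_localized_sites),
    n_annotated_sites = as.integer(n_annotated_sites),
    n_isoform_sites = as.integer(n_isoform_sites),
    n_entries_covered = as.integer(n_entries_covered),
    n_entries_promoted = as.integer(n_entries_promoted),
    rejections = rej), class = "unicityr_run_summary")
}

#' @export
print.unicityr_run_summary <- function(x, ...) {
  cat("<run summary>\n")
  for (k in setdiff(names(x), "rejections")) {
    cat(sprintf("  %-32s %d\n", k, x[[k]]))
  }
  cat("  rejections:\n")
  for (k in names(x$rejections)) {
    if (x$rejections[[k]] > 0) {
      cat(sprintf("    %-32s %d\n", k, x$rejections[[k]]))
    }
  }
  invisible(x)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort_input(sprintf("config file not found: %s", config),
                  "unicityr_config_error")
    }
    config <- read_yaml(config)
  }
  defaults <- list(digest = list(), policy = list(),
                   normalization = "il_equivalent", apply_variants = TRUE,
                   allow_unverified = FALSE, promote_k = 2L,
                   write_unicity = FALSE, strict = FALSE, release_tag = "",
                   metadata = list())
  config <- modifyList(defaults, config)
  for (key in c("fasta", "features", "psm_tables", "out_dir")) {
    if (is.null(config[[key]])) {
      abort_input(sprintf("config is missing required key '%s'", key),
                  "unicityr_config_error")
    }
  }
  for (f in c(config$fasta, config$features, unlist(config$psm_tables),
              unlist(config$metadata))) {
    if (!file.exists(f)) {
      abort_input(sprintf("config references missing file: %s", f),
                  "unicityr_config_error")
    }
  }
  config$spec <- do.call(digest_spec, config$digest)
  config$policy_obj <- do.call(filter_policy, config$policy)
  config$opts <- form_options(config$apply_variants)
  config
}

resolve_site_positions <- function(assignments, pep_pos) {
  # canonical placements of the modified residue over all assignments
  can <- unique(assignments$canonical_start[!is.na(assignments$canonical_start)] +
                  pep_pos - 1L)
  if (length(can) == 1) {
    return(list(status = "canonical", position = can))
  }
  if (length(can) > 1) {
    return(list(status = "ambiguous"))
  }
  iso <- assignments[assignments$base != "canonical", , drop = FALSE]
  ipos <- unique(tibble(iso_id = iso$base,
                        position = iso$start + iso$offset + pep_pos - 1L))
  if (nrow(ipos) == 1) {
    return(list(status = "isoform", iso_id = ipos$iso_id,
                position = ipos$position))
  }
  list(status = "unmappable")
}

#' Run the integration pipeline end to end
#'
#' Reads the proteome and features, builds the unicity table, then for each
#' dataset: checks metadata (failing datasets are skipped and logged unless
#' `allow_unverified`), applies the identification and localization
#' filters; resolves accepted peptides and localized sites through the
#' unicity table, applies biological-relevance rules, merges evidence and
#' writes all outputs under `out_dir`:
#' `annotations.tsv` (canonical sites), `isoform_annotations.tsv`
#' (isoform-specific sites), `audit.jsonl`, `summary.json`, and optionally
#' `unicity.tsv`.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#'   Required keys: `fasta`, `features`, `psm_tables` (list), `out_dir`;
#'   optional: `metadata` (list, parallel to `psm_tables`), `digest`,
#'   `policy`, `normalization`, `apply_variants`, `allow_unverified`,
#'   `promote_k`, `write_unicity`, `strict`, `release_tag`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list: `summary` (a [run_summary()]), `sites`,
#'   `isoform_sites`, `promotions`, `paths`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- read_pipeline_config(config)
  say <- function(...) if (!quiet) inform(sprintf(...))
  audit <- list()
  log_reject <- function(stage, reason, ...) {
    audit[[length(audit) + 1L]] <<- c(list(stage = stage, reason = reason),
                                      list(...))
  }

  say("reading proteome from %s", cfg$fasta)
  prot <- read_proteome_fasta(cfg$fasta, release_tag = cfg$release_tag)
  prot <- read_feature_table(cfg$features, prot, strict = cfg$strict)
  validate_proteome(prot)

  say("building unicity table (%s, %s keys)", format(cfg$spec),
      cfg$normalization)
  utab <- build_unicity_table(prot, cfg$spec, cfg$opts, cfg$normalization)
  say("unicity table: %d peptide keys", utab$n_keys)

  n_input <- 0L
  n_skipped_meta <- 0L
  accepted_all <- list()
  rej_id_threshold <- 0L
  rej_id_noscore <- 0L

  meta_paths <- unlist(cfg$metadata)
  for (i in seq_along(cfg$psm_tables)) {
    psm_path <- cfg$psm_tables[[i]]
    dataset_id <- NULL
    if (length(meta_paths) >= i) {
      meta <- read_dataset_metadata(meta_paths[i])
      report <- validate_dataset_metadata(meta[1, ])
      dataset_id <- report$dataset_id
      if (identical(report$verdict, "fail") && !isTRUE(cfg$allow_unverified)) {
        failed <- report$checks$field[report$checks$status == "fail"]
        log_reject("metadata", "metadata checklist failed",
                   dataset_id = report$dataset_id,
                   fields = paste(failed, collapse = ","))
        n_skipped_meta <- n_skipped_meta + 1L
        say("dataset %s: metadata check failed (%s); skipped",
            report$dataset_id, paste(failed, collapse = ", "))
        next
      }
    }
    psms <- read_psm_table(psm_path, strict = cfg$strict)
    n_input <- n_input + nrow(psms)
    flt <- apply_identification_filter(psms, cfg$policy_obj)
    for (j in seq_len(nrow(flt$rejected))) {
      log_reject("identification", flt$rejected$reason[j],
                 dataset_id = flt$rejected$dataset_id[j],
                 spectrum_id = flt$rejected$spectrum_id[j])
    }
    rej_id_noscore <- rej_id_noscore +
      sum(flt$rejected$reason == "no usable score")
    rej_id_threshold <- rej_id_threshold +
      sum(flt$rejected$reason != "no usable score")
    accepted_all[[length(accepted_all) + 1L]] <- flt$accepted
    say("dataset %s: %d PSMs, %d accepted", dataset_id %||% basename(psm_path),
        nrow(psms), nrow(flt$accepted))
  }
  accepted <- bind_rows(accepted_all)
  if (!"peptide" %in% names(accepted)) {   # no dataset survived the gate
    accepted <- tibble(dataset_id = character(), spectrum_id = character(),
                       peptide = character(), mascot = double(),
                       pep = double(), mods = list())
  }

  # --- peptide-level resolution over distinct accepted keys -------------
  keys <- unique(normalize_peptide(accepted$peptide, cfg$normalization))
  reps <- accepted$peptide[!duplicated(normalize_peptide(accepted$peptide,
                                                         cfg$normalization))]
  resolutions <- lapply(reps, resolve_peptide, table = utab)
  names(resolutions) <- keys
  res_status <- vapply(resolutions, `[[`, character(1), "status")
  n_validated <- sum(res_status == "unique")
  n_pep_ambiguous <- sum(res_status == "rejected_ambiguous")
  n_pep_absent <- sum(res_status == "rejected_absent")
  for (k in keys[res_status != "unique"]) {
    log_reject("unicity", sub("rejected_", "peptide_", res_status[[k]]),
               peptide_key = k, class = resolutions[[k]]$class)
  }

  # --- site-level processing -------------------------------------------
  cand <- apply_site_filter(accepted, cfg$policy_obj)
  n_localized <- sum(cand$localized)
  not_loc <- cand[!cand$localized, , drop = FALSE]
  for (j in seq_len(nrow(not_loc))) {
    log_reject("localization", not_loc$reason[j],
               dataset_id = not_loc$dataset_id[j],
               spectrum_id = not_loc$spectrum_id[j],
               ptm = not_loc$ptm_name[j])
  }

  canonical_sites <- list()
  iso_sites <- list()
  n_site_amb_pep <- 0L; n_site_absent <- 0L; n_site_pos_amb <- 0L
  n_site_unmap <- 0L; tm_rejected <- 0L; other_relevance <- 0L
  loc <- cand[cand$localized, , drop = FALSE]
  for (j in seq_len(nrow(loc))) {
    key <- normalize_peptide(loc$peptide[j], cfg$normalization)
    res <- resolutions[[key]]
    if (is.null(res)) res <- resolve_peptide(loc$peptide[j], utab)
    if (!identical(res$status, "unique")) {
      if (identical(res$status, "rejected_absent")) {
        n_site_absent <- n_site_absent + 1L
        log_reject("site_resolution", "site_on_absent_peptide",
                   spectrum_id = loc$spectrum_id[j])
      } else {
        n_site_amb_pep <- n_site_amb_pep + 1L
        log_reject("site_resolution", "site_on_ambiguous_peptide",
                   spectrum_id = loc$spectrum_id[j])
      }
      next
    }
    placement <- resolve_site_positions(res$assignments, loc$pep_pos[j])
    acc <- res$assignments$accession[1]
    if (identical(placement$status, "ambiguous")) {
      n_site_pos_amb <- n_site_pos_amb + 1L
      log_reject("site_resolution", "site_position_ambiguous",
                 spectrum_id = loc$spectrum_id[j], accession = acc)
      next
    }
    if (identical(placement$status, "unmappable")) {
      n_site_unmap <- n_site_unmap + 1L
      log_reject("site_resolution", "site_unmappable",
                 spectrum_id = loc$spectrum_id[j], accession = acc)
      next
    }
    if (identical(placement$status, "isoform")) {
      iso_sites[[length(iso_sites) + 1L]] <- tibble(
        accession = placement$iso_id, canonical_position = placement$position,
        ptm_name = loc$ptm_name[j], dataset_id = loc$dataset_id[j],
        spectrum_id = loc$spectrum_id[j], peptide = loc$peptide[j])
      next
    }
    verdict <- check_biological_relevance(prot$entries[[acc]],
                                          placement$position,
                                          loc$ptm_name[j])
    if (identical(verdict, "rejected_transmembrane")) {
      tm_rejected <- tm_rejected + 1L
      log_reject("relevance", "site_transmembrane",
                 spectrum_id = loc$spectrum_id[j], accession = acc,
                 position = placement$position)
      next
    }
    if (!identical(verdict, "accepted")) {
      other_relevance <- other_relevance + 1L
      log_reject("relevance", verdict, spectrum_id = loc$spectrum_id[j],
                 accession = acc, position = placement$position)
      next
    }
    canonical_sites[[length(canonical_sites) + 1L]] <- tibble(
      accession = acc, canonical_position = placement$position,
      ptm_name = loc$ptm_name[j], dataset_id = loc$dataset_id[j],
      spectrum_id = loc$spectrum_id[j], peptide = loc$peptide[j])
  }

  sites <- merge_site_evidence(bind_rows(canonical_sites))
  isoform_sites <- merge_site_evidence(bind_rows(iso_sites))

  # --- existence promotion ---------------------------------------------
  promotions <- list()
  uniq_keys <- keys[res_status == "unique"]
  if (length(uniq_keys) > 0) {
    by_acc <- split(uniq_keys, vapply(uniq_keys, function(k) {
      resolutions[[k]]$assignments$accession[1]
    }, character(1)))
    for (acc in sort(names(by_acc))) {
      pr <- promote_protein_existence(prot$entries[[acc]], by_acc[[acc]],
                                      k = cfg$promote_k)
      if (pr$promoted) {
        prot$entries[[acc]] <- pr$entry
        promotions[[length(promotions) + 1L]] <-
          list(accession = acc, note = pr$note)
        audit[[length(audit) + 1L]] <- list(stage = "existence",
                                            reason = "promoted",
                                            accession = acc, note = pr$note)
      }
    }
  }

  summary <- run_summary(
    n_input_psms = n_input,
    n_accepted_identifications = nrow(accepted),
    n_distinct_accepted_peptides = length(keys),
    n_validated_unique_peptides = n_validated,
    n_localized_sites = n_localized,
    n_annotated_sites = nrow(sites),
    n_isoform_sites = nrow(isoform_sites),
    n_entries_covered = length(unique(sites$accession)),
    n_entries_promoted = length(promotions),
    rejections = list(
      identification_below_threshold = rej_id_threshold,
      identification_no_usable_score = rej_id_noscore,
      site_not_localized = nrow(not_loc),
      peptide_ambiguous = n_pep_ambiguous,
      peptide_absent = n_pep_absent,
      site_on_ambiguous_peptide = n_site_amb_pep,
      site_on_absent_peptide = n_site_absent,
      site_position_ambiguous = n_site_pos_amb,
      site_transmembrane = tm_rejected,
      site_unmappable = n_site_unmap,
      datasets_skipped_metadata = n_skipped_meta))

  # --- outputs ----------------------------------------------------------
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    annotations = file.path(cfg$out_dir, "annotations.tsv"),
    isoform_annotations = file.path(cfg$out_dir, "isoform_annotations.tsv"),
    audit = file.path(cfg$out_dir, "audit.jsonl"),
    summary = file.path(cfg$out_dir, "summary.json"))
  write_annotations(sites, paths$annotations, release_tag = cfg$release_tag,
                    spec = cfg$spec, policy = cfg$policy_obj)
  write_annotations(isoform_sites, paths$isoform_annotations,
                    release_tag = cfg$release_tag, spec = cfg$spec,
                    policy = cfg$policy_obj)
  audit_lines <- vapply(audit, function(rec) {
    as.character(toJSON(rec, auto_unbox = TRUE, null = "null"))
  }, character(1))
  write_lines(audit_lines, paths$audit)
  write_json(unclass(summary), paths$summary, auto_unbox = TRUE,
             pretty = TRUE, digits = NA)
  if (isTRUE(cfg$write_unicity)) {
    paths$unicity <- file.path(cfg$out_dir, "unicity.tsv")
    write_unicity_table(utab, paths$unicity)
  }
  say("annotated %d site(s) in %d entr(ies); summary written to %s",
      summary$n_annotated_sites, summary$n_entries_covered, paths$summary)
  invisible(list(summary = summary, sites = sites,
                 isoform_sites = isoform_sites, promotions = promotions,
                 paths = paths))
}

#' Read back and print the summary of a pipeline run
#'
#' @param out_dir The pipeline output directory.
#' @return The [run_summary()], invisibly.
#' @export
report_show <- function(out_dir) {
  path <- file.path(out_dir, "summary.json")
  if (!file.exists(path)) abort_input(sprintf("no summary at %s", path))
  raw <- read_json(path, simplifyVector = TRUE)
  s <- do.call(run_summary, c(raw[setdiff(names(raw), "rejections")],
                              list(rejections = as.list(raw$rejections))))
  print(s)
  invisible(s)
}
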