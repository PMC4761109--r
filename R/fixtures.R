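## Synthetic fixtures with planted ground truth.
##
## The generator emulates the structures the pipeline must reason about -
## splice isoforms (pure internal deletions with explicit alignment blocks),
## single amino-acid variants, signal/chain processing, transmembrane
## segments, and tryptic-boundary-compatible sequence blocks shared across
## entries (to guarantee ambiguous peptides). PSM datasets plant true sites,
## decoys and ambiguous identifications with scores drawn well clear of the
## filter thresholds (margin >= 0.5 score units / 0.005 PEP), so fixture
## correctness never hinges on threshold inclusivity semantics; those are
## unit-tested separately with exact boundary values.

## approximate human amino-acid composition (no U: selenocysteine is
## represented in hand-built test entries, not in random fixtures)
AA_FREQ <- c(A = 7.0, R = 5.6, N = 3.6, D = 4.7, C = 2.3, E = 7.1, Q = 4.8,
             G = 6.6, H = 2.6, I = 4.3, L = 10.0, K = 5.7, M = 2.1, F = 3.7,
             P = 6.3, S = 8.3, T = 5.3, W = 1.2, Y = 2.7, V = 6.0)

random_residues <- function(n, exclude = character(0)) {
  freq <- AA_FREQ[setdiff(names(AA_FREQ), exclude)]
  sample(names(freq), n, replace = TRUE, prob = freq)
}

random_seq <- function(n, exclude = character(0)) {
  paste(random_residues(n, exclude), collapse = "")
}

## A shared cassette: two guaranteed tryptic peptides (no internal K/R/P),
## first ending in K, second in R. Inserted after an R and before a non-P
## residue, it digests identically in every entry that carries it.
make_shared_block <- function() {
  p1 <- paste0(random_seq(sample(8:11, 1), exclude = c("K", "R", "P")), "K")
  p2 <- paste0(random_seq(sample(8:11, 1), exclude = c("K", "R", "P")), "R")
  list(block = paste0(p1, p2), peptides = c(p1, p2))
}

insert_block <- function(seq, block) {
  n <- nchar(seq)
  i <- sample(10:(n - 10), 1)              # insert after position i
  pre <- substr(seq, 1, i)
  post <- substr(seq, i + 1, n)
  substr(pre, i, i) <- "R"                 # tryptic boundary before block
  if (substr(post, 1, 1) == "P") substr(post, 1, 1) <- "A"
  paste0(pre, block, post)
}

#' Generate a synthetic proteome with known structure
#'
#' Reproducible for a fixed seed. Entries get unique accessions and gene
#' symbols; with the given probabilities an entry receives a pure-deletion
#' splice isoform (with explicit alignment blocks), a single amino-acid
#' VARIANT, one or two TRANSMEM segments (length 21), and a SIGNAL/CHAIN
#' processing pair. `shared_block_prob` controls the fraction of entries
#' that carry an identical tryptic-boundary-compatible cassette (placed in
#' groups of two or three entries), guaranteeing peptides shared across
#' genes; every planted structure is recorded in the manifest.
#'
#' @param n_entries Number of entries (>= 1).
#' @param isoform_prob,variant_prob,tm_prob,chain_prob,shared_block_prob
#'   Per-entry probabilities in `[0, 1]`.
#' @param length_range Canonical sequence length range (inclusive).
#' @param seed Integer seed; the generator never touches the global RNG
#'   state outside this call.
#' @return List with `proteome` (a validated [proteome()]) and `manifest`
#'   (params, seed, shared groups with their guaranteed shared peptides).
#' @export
generate_proteome <- function(n_entries, isoform_prob = 0.3,
                              variant_prob = 0.4, tm_prob = 0.3,
                              chain_prob = 0.3, shared_block_prob = 0.15,
                              length_range = c(120L, 360L), seed = 1L) {
  probs <- c(isoform_prob, variant_prob, tm_prob, chain_prob,
             shared_block_prob)
  if (n_entries < 1) abort_input("n_entries must be >= 1",
                                 "unicityr_parameter_error")
  if (any(probs < 0 | probs > 1)) {
    abort_input("probabilities must be in [0, 1]",
                "unicityr_parameter_error")
  }
  if (length_range[1] < 60) {
    abort_input("length_range lower bound must be >= 60",
                "unicityr_parameter_error")
  }
  with_seed(as.integer(seed), {
    # which entries share a cassette, and in which groups
    n_shared <- round(shared_block_prob * n_entries)
    if (n_shared == 1 && n_entries >= 2) n_shared <- 2L
    shared_idx <- if (n_shared >= 2) sort(sample(n_entries, n_shared)) else
      integer(0)
    groups <- list()
    i <- 1L
    while (i <= length(shared_idx)) {
      size <- min(sample(2:3, 1), length(shared_idx) - i + 1L)
      if (size < 2) {  # fold a trailing singleton into the previous group
        groups[[length(groups)]] <- c(groups[[length(groups)]],
                                      shared_idx[i])
        break
      }
      groups[[length(groups) + 1L]] <- shared_idx[i:(i + size - 1L)]
      i <- i + size
    }
    block_of <- integer(0)
    blocks <- lapply(seq_along(groups), function(g) make_shared_block())
    for (g in seq_along(groups)) block_of[as.character(groups[[g]])] <- g

    entries <- vector("list", n_entries)
    for (e in seq_len(n_entries)) {
      acc <- sprintf("P%05d", e)
      len <- sample(length_range[1]:length_range[2], 1)
      seq <- random_seq(len)
      gidx <- block_of[as.character(e)]
      if (!is.na(gidx) && length(gidx) == 1 && gidx > 0) {
        seq <- insert_block(seq, blocks[[gidx]]$block)
      }
      len <- nchar(seq)
      feats <- empty_features()
      isoforms <- list()

      if (runif(1) < isoform_prob && len >= 80) {
        a <- sample(15:(len %/% 3), 1)               # deletion start
        dlen <- sample(10:min(40L, len - a - 15L), 1)
        b <- a + dlen - 1L                           # deletion end
        iso_seq <- paste0(substr(seq, 1, a - 1L), substr(seq, b + 1L, len))
        iso_id <- paste0(acc, "-2")
        aln <- tibble(canonical_start = c(1L, b + 1L),
                      iso_start = c(1L, a),
                      length = c(a - 1L, len - b))
        isoforms[[iso_id]] <- isoform(iso_id, iso_seq, aln)
      }

      if (runif(1) < tm_prob) {
        for (k in seq_len(sample(1:2, 1))) {
          tm_start <- sample(5:(len - 25L), 1)
          feats <- add_row(feats, kind = "TRANSMEM",
                           target_form = "canonical", begin = tm_start,
                           end = tm_start + 20L, payload = NA_character_)
        }
      }
      if (runif(1) < chain_prob && len >= 60) {
        s <- sample(15:25, 1)
        feats <- add_row(feats, kind = "SIGNAL", target_form = "canonical",
                         begin = 1L, end = s, payload = NA_character_)
        feats <- add_row(feats, kind = "CHAIN", target_form = "canonical",
                         begin = s + 1L, end = len, payload = NA_character_)
      }
      if (runif(1) < variant_prob) {
        vpos <- sample(2:(len - 1L), 1)
        orig <- substr(seq, vpos, vpos)
        alt <- sample(setdiff(strsplit(AA_ALPHABET, "")[[1]],
                              c(orig, "U")), 1)
        feats <- add_row(feats, kind = "VARIANT", target_form = "canonical",
                         begin = vpos, end = vpos,
                         payload = paste0(orig, ">", alt))
      }

      entries[[e]] <- protein_entry(
        accession = acc, canonical_seq = seq,
        gene_symbol = sprintf("GENE%04d", e),
        existence = sample(EXISTENCE_LEVELS, 1,
                           prob = c(0.5, 0.25, 0.15, 0.05, 0.05)),
        entry_name = sprintf("SYN%04d_HUMAN", e),
        isoforms = isoforms, features = feats)
    }
    prot <- proteome(entries,
                     release_tag = sprintf("synthetic-%d-%d", n_entries,
                                           as.integer(seed)))
    validate_proteome(prot)
    manifest <- list(
      seed = as.integer(seed),
      params = list(n_entries = n_entries, isoform_prob = isoform_prob,
                    variant_prob = variant_prob, tm_prob = tm_prob,
                    chain_prob = chain_prob,
                    shared_block_prob = shared_block_prob,
                    length_range = as.integer(length_range)),
      shared_groups = lapply(seq_along(groups), function(g) {
        list(accessions = sprintf("P%05d", groups[[g]]),
             block = blocks[[g]]$block,
             shared_peptides = blocks[[g]]$peptides)
      }))
    list(proteome = prot, manifest = manifest)
  })
}

residue_to_phospho <- c(S = "Phosphoserine", T = "Phosphothreonine",
                        Y = "Phosphotyrosine")

tm_intervals <- function(prot) {
  lapply(prot$entries, function(e) {
    e$features[e$features$kind == "TRANSMEM" &
                 e$features$target_form == "canonical",
               c("begin", "end"), drop = FALSE]
  })
}

in_tm <- function(tm, pos) {
  nrow(tm) > 0 && any(pos >= tm$begin & pos <= tm$end)
}

## per-key candidate sites: unique-protein keys with a single canonical
## placement, no variant dependence, expanded over their S/T/Y positions
candidate_sites <- function(table, prot) {
  a <- table$assignments
  stats <- a |>
    group_by(.data$key) |>
    summarise(n_acc = n_distinct(.data$accession),
              n_gene = n_distinct(.data$gene_symbol),
              accession = first(.data$accession),
              peptide = first(.data$peptide),
              all_canon = all(!is.na(.data$canonical_start)),
              n_pos = n_distinct(.data$canonical_start),
              canonical_start = first(.data$canonical_start),
              any_var = any(.data$carries_variant),
              .groups = "drop")
  uniq <- stats |>
    filter(.data$n_acc == 1, .data$all_canon, .data$n_pos == 1,
           !.data$any_var)
  hits <- gregexpr("[STY]", uniq$peptide)
  n_hits <- vapply(hits, function(h) if (h[1] == -1L) 0L else length(h),
                   integer(1))
  idx <- rep(seq_len(nrow(uniq)), n_hits)
  pep_pos <- unlist(lapply(hits, function(h) if (h[1] == -1L) integer(0)
                           else as.integer(h)))
  sites <- tibble(key = uniq$key[idx], peptide = uniq$peptide[idx],
                  accession = uniq$accession[idx], pep_pos = pep_pos,
                  canonical_pos = uniq$canonical_start[idx] + pep_pos - 1L)
  sites$residue <- substr(sites$peptide, sites$pep_pos, sites$pep_pos)
  tms <- tm_intervals(prot)
  sites$in_tm <- vapply(seq_len(nrow(sites)), function(i) {
    in_tm(tms[[sites$accession[i]]], sites$canonical_pos[i])
  }, logical(1))
  list(sites = sites, stats = stats)
}

#' Generate a PSM dataset with planted ground truth
#'
#' Plants four PSM populations against a proteome's unicity table:
#' * true sites: protein-unique peptides with one canonical placement,
#'   phosphosite outside every transmembrane region, scores well above all
#'   thresholds (Mascot ~ U\[45, 90\], PEP ~ U\[0, 0.005\],
#'   Ascore ~ U\[20, 40\]) - the pipeline must annotate exactly these;
#' * transmembrane plants (`n_tm_sites`): same scores but the phosphosite
#'   lies inside a TRANSMEM interval - accepted and localized, then
#'   rejected by the biological-relevance rule;
#' * decoys: half fail identification (Mascot ~ U\[10, 35\],
#'   PEP ~ U\[0.02, 0.2\]), half pass identification but carry a
#'   sub-threshold Ascore ~ U\[5, 18.4\] and are never localized;
#' * ambiguous: unmodified PSMs on peptides shared across entries
#'   (rejected for unicity, still counted as shared evidence).
#'
#' Each planted site uses a distinct peptide key; the manifest records every
#' plant and the expected end-to-end run summary, computed from the planting
#' ledger (not by running the pipeline).
#'
#' @param prot A [proteome()], typically from [generate_proteome()].
#' @param n_true_sites,n_decoys,n_ambiguous,n_tm_sites Population sizes.
#' @param dataset_id Dataset identifier stamped on every PSM.
#' @param seed Integer seed.
#' @param spec,opts,normalization Unicity-table settings; recorded in the
#'   manifest so pipeline runs use the same table dialect.
#' @param promote_k Existence-promotion threshold mirrored into the
#'   expected summary.
#' @return List: `psms` (PSM tibble in the canonical dialect), `metadata`
#'   (dataset metadata list), `manifest` (planted truth + expected summary).
#' @export
generate_psm_dataset <- function(prot, n_true_sites = 50L, n_decoys = 50L,
                                 n_ambiguous = 20L, n_tm_sites = 0L,
                                 dataset_id = "DS1", seed = 1L,
                                 spec = digest_spec(),
                                 opts = form_options(),
                                 normalization = "il_equivalent",
                                 promote_k = 2L) {
  stopifnot(n_true_sites >= 0, n_decoys >= 0, n_ambiguous >= 0,
            n_tm_sites >= 0)
  utab <- build_unicity_table(prot, spec, opts, normalization)
  with_seed(as.integer(seed) + 1L, {
    cand <- candidate_sites(utab, prot)
    sites <- cand$sites

    pick <- function(pool, n, what) {
      if (nrow(pool) < n) {
        abort_input(sprintf(
          "infeasible params: need %d %s but only %d eligible candidates",
          n, what, nrow(pool)), "unicityr_parameter_error")
      }
      pool[sample(nrow(pool), n), , drop = FALSE]
    }
    # one candidate row per key and per (accession, canonical position)
    dedupe <- function(x) {
      x <- x[!duplicated(x$key), , drop = FALSE]
      x[!duplicated(x[, c("accession", "canonical_pos")]), , drop = FALSE]
    }

    out_pool <- dedupe(sites[!sites$in_tm, , drop = FALSE])
    true_rows <- pick(out_pool, n_true_sites, "outside-TM true sites")
    used <- true_rows$key

    in_pool <- dedupe(sites[sites$in_tm & !(sites$key %in% used), ,
                            drop = FALSE])
    tm_rows <- pick(in_pool, n_tm_sites, "inside-TM planted sites")
    used <- c(used, tm_rows$key)

    n_loc <- n_decoys %/% 2L
    n_id <- n_decoys - n_loc
    decoy_pool <- dedupe(sites[!(sites$key %in% used), , drop = FALSE])
    decoy_rows <- pick(decoy_pool, n_decoys, "decoy sites")
    loc_rows <- decoy_rows[seq_len(n_loc), , drop = FALSE]
    id_rows <- decoy_rows[n_loc + seq_len(n_id), , drop = FALSE]

    shared_pool <- cand$stats |> filter(.data$n_acc >= 2)
    if (n_ambiguous > 0 && nrow(shared_pool) == 0) {
      abort_input(paste("infeasible params: n_ambiguous > 0 but the",
                        "proteome yields no shared peptides"),
                  "unicityr_parameter_error")
    }
    amb_idx <- if (n_ambiguous > 0)
      sample(nrow(shared_pool), n_ambiguous, replace = TRUE) else integer(0)
    amb_rows <- shared_pool[amb_idx, , drop = FALSE]

    good_scores <- function(n) {
      tibble(mascot = round(runif(n, 45, 90), 2),
             pep = round(runif(n, 0, 0.005), 6))
    }
    psm_block <- function(rows, kind, mascot, pep, ascore) {
      n <- nrow(rows)
      tibble(kind = kind, peptide = rows$peptide,
             mods = if (is.null(ascore)) rep("", n) else
               sprintf("%d:%s:%.2f", rows$pep_pos,
                       unname(residue_to_phospho[rows$residue]), ascore),
             mascot = mascot, pep = pep)
    }
    gs <- good_scores(n_true_sites)
    blocks <- list(
      psm_block(true_rows, "true", gs$mascot, gs$pep,
                round(runif(n_true_sites, 20, 40), 2)))
    gs <- good_scores(n_tm_sites)
    blocks$tm <- psm_block(tm_rows, "tm", gs$mascot, gs$pep,
                           round(runif(n_tm_sites, 20, 40), 2))
    gs <- good_scores(n_loc)
    blocks$loc <- psm_block(loc_rows, "decoy_localization", gs$mascot,
                            gs$pep, round(runif(n_loc, 5, 18.4), 2))
    blocks$id <- psm_block(id_rows, "decoy_identification",
                           round(runif(n_id, 10, 35), 2),
                           round(runif(n_id, 0.02, 0.2), 6),
                           round(runif(n_id, 20, 40), 2))
    gs <- good_scores(n_ambiguous)
    blocks$amb <- psm_block(amb_rows |>
                              mutate(pep_pos = NA_integer_,
                                     residue = NA_character_),
                            "ambiguous", gs$mascot, gs$pep, NULL)
    psms <- bind_rows(blocks)
    psms <- psms[sample(nrow(psms)), , drop = FALSE]
    psms$dataset_id <- dataset_id
    psms$spectrum_id <- sprintf("%s_SP%06d", dataset_id, seq_len(nrow(psms)))
    psm_tab <- psms[, c("dataset_id", "spectrum_id", "peptide", "mods",
                        "mascot", "pep", "kind")]

    # expected end-to-end summary, from the planting ledger
    n_amb_keys <- length(unique(amb_rows$key))
    promo_keys <- bind_rows(true_rows, tm_rows, loc_rows)
    promo_by_acc <- base::table(promo_keys$accession)
    promotable <- vapply(names(promo_by_acc), function(acc) {
      prot$entries[[acc]]$existence != "protein_level" &&
        promo_by_acc[[acc]] >= promote_k
    }, logical(1))
    expected <- run_summary(
      n_input_psms = nrow(psm_tab),
      n_accepted_identifications = n_true_sites + n_tm_sites + n_loc +
        n_ambiguous,
      n_distinct_accepted_peptides = n_true_sites + n_tm_sites + n_loc +
        n_amb_keys,
      n_validated_unique_peptides = n_true_sites + n_tm_sites + n_loc,
      n_localized_sites = n_true_sites + n_tm_sites,
      n_annotated_sites = n_true_sites,
      n_isoform_sites = 0L,
      n_entries_covered = length(unique(true_rows$accession)),
      n_entries_promoted = sum(promotable),
      rejections = list(
        identification_below_threshold = n_id,
        identification_no_usable_score = 0L,
        site_not_localized = n_loc,
        peptide_ambiguous = n_amb_keys,
        peptide_absent = 0L,
        site_on_ambiguous_peptide = 0L,
        site_on_absent_peptide = 0L,
        site_position_ambiguous = 0L,
        site_transmembrane = n_tm_sites,
        site_unmappable = 0L,
        datasets_skipped_metadata = 0L))

    manifest <- list(
      seed = as.integer(seed),
      dataset_id = dataset_id,
      digest = unclass(spec),
      apply_variants = opts$apply_variants,
      normalization = normalization,
      promote_k = as.integer(promote_k),
      planted_sites = true_rows[, c("accession", "canonical_pos", "residue",
                                    "key", "peptide")] |>
        mutate(ptm_name = unname(residue_to_phospho[.data$residue])) |>
        arrange(.data$accession, .data$canonical_pos),
      tm_sites = tm_rows[, c("accession", "canonical_pos", "residue",
                             "key", "peptide")] |>
        mutate(ptm_name = unname(residue_to_phospho[.data$residue])) |>
        arrange(.data$accession, .data$canonical_pos),
      decoy_psms = psm_tab$spectrum_id[psm_tab$kind %in%
                                         c("decoy_identification",
                                           "decoy_localization")],
      ambiguous_peptides = sort(unique(amb_rows$peptide)),
      expected_summary = expected)

    metadata <- list(
      dataset_id = dataset_id,
      raw_data_location = sprintf("https://example.org/synthetic/%s/raw",
                                  dataset_id),
      instrument = "synthetic Orbitrap profile",
      search_software = "synthetic Mascot-style scores",
      enzyme = spec$enzyme,
      reported_fdr = 0.01)

    list(psms = psm_tab[, c("dataset_id", "spectrum_id", "peptide", "mods",
                            "mascot", "pep")],
         psm_kinds = psm_tab$kind, metadata = metadata, manifest = manifest)
  })
}

#' Write a PSM tibble in the canonical TSV dialect
#'
#' @param psms PSM tibble with columns `dataset_id`, `spectrum_id`,
#'   `peptide`, `mods`, `mascot`, `pep` (`mods` already serialized as
#'   `pos:NAME:ascore;...`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  hdr <- paste(c("dataset_id", "spectrum_id", "peptide", "mods", "mascot",
                 "pep"), collapse = "\t")
  fmt <- function(v) ifelse(is.na(v), "NA", as.character(v))
  body <- if (nrow(psms) == 0) character(0) else
    sprintf("%s\t%s\t%s\t%s\t%s\t%s", psms$dataset_id, psms$spectrum_id,
            psms$peptide, psms$mods, fmt(psms$mascot), fmt(psms$pep))
  write_lines(c(hdr, body), path)
  invisible(path)
}

#' Materialize a complete fixture on disk
#'
#' Writes FASTA, feature table, PSM table, dataset metadata, manifest and a
#' ready-to-run pipeline config under one directory.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed driving both generators.
#' @param n_entries Proteome size.
#' @param n_true_sites,n_decoys,n_ambiguous,n_tm_sites PSM population
#'   sizes, see [generate_psm_dataset()].
#' @param ... Further arguments passed to [generate_proteome()].
#' @return List with `paths` (named file paths) and `manifest`.
#' @export
fixture_make <- function(dir, seed = 1L, n_entries = 60L,
                         n_true_sites = 50L, n_decoys = 50L,
                         n_ambiguous = 20L, n_tm_sites = 0L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gp <- generate_proteome(n_entries, seed = seed, ...)
  ds <- generate_psm_dataset(gp$proteome, n_true_sites = n_true_sites,
                             n_decoys = n_decoys, n_ambiguous = n_ambiguous,
                             n_tm_sites = n_tm_sites, seed = seed)
  paths <- list(
    fasta = file.path(dir, "proteome.fasta"),
    features = file.path(dir, "features.tsv"),
    psms = file.path(dir, "psms.tsv"),
    metadata = file.path(dir, "metadata.json"),
    manifest = file.path(dir, "manifest.json"),
    config = file.path(dir, "config.yaml"))
  write_proteome_fasta(gp$proteome, paths$fasta)
  write_feature_table(gp$proteome, paths$features)
  write_psm_table(ds$psms, paths$psms)
  write_json(ds$metadata, paths$metadata, auto_unbox = TRUE, pretty = TRUE)
  manifest <- c(ds$manifest, list(proteome = gp$manifest))
  json_manifest <- manifest
  json_manifest$expected_summary <- unclass(manifest$expected_summary)
  write_json(json_manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE,
             digits = NA)
  config <- list(
    fasta = paths$fasta, features = paths$features,
    psm_tables = list(paths$psms), metadata = list(paths$metadata),
    out_dir = file.path(dir, "run"),
    digest = unclass(ds$manifest$digest),
    policy = list(mascot_min = 40, pep_max = 0.01, ascore_min = 19,
                  combination = "any"),
    normalization = ds$manifest$normalization,
    apply_variants = ds$manifest$apply_variants,
    allow_unverified = FALSE, promote_k = ds$manifest$promote_k,
    release_tag = gp$proteome$release_tag)
  write_yaml(config, paths$config)
  list(paths = paths, manifest = manifest)
}
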