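test_that("peptide resolution gates site annotation on protein-unicity", {
  utab <- build_unicity_table(two_entry_proteome(), short_spec())
  res <- resolve_peptide("AAK", utab)
  expect_equal(res$status, "unique")
  expect_equal(unique(res$assignments$accession), "P00001")
  expect_equal(resolve_peptide("CCR", utab)$status, "rejected_ambiguous")
  expect_equal(resolve_peptide("WWWW", utab)$status, "rejected_absent")
})

test_that("phosphosites inside transmembrane regions are rejected, others pass", {
  entry <- protein_entry(
    "P00001", random_aa_seq(40),
    features = tibble::tibble(kind = "TRANSMEM", target_form = "canonical",
                              begin = 5L, end = 25L, payload = NA_character_))
  # interval is inclusive on both boundaries
  expect_equal(check_biological_relevance(entry, 10L, "Phosphoserine"),
               "rejected_transmembrane")
  expect_equal(check_biological_relevance(entry, 5L, "Phosphoserine"),
               "rejected_transmembrane")
  expect_equal(check_biological_relevance(entry, 25L, "Phosphothreonine"),
               "rejected_transmembrane")
  expect_equal(check_biological_relevance(entry, 26L, "Phosphoserine"),
               "accepted")
  expect_equal(check_biological_relevance(entry, 4L, "Phosphotyrosine"),
               "accepted")
  # the default rule names the phosphorylation class only
  expect_equal(check_biological_relevance(entry, 10L, "N6-acetyllysine"),
               "accepted")
  # unmapped positions cannot be judged
  expect_equal(check_biological_relevance(entry, NA_integer_,
                                          "Phosphoserine"),
               "rejected_unmappable")
  # the registry is extensible
  no_nterm <- c(relevance_rules(), list(function(e, pos, ptm)
    if (pos == 1) "rejected_nterm" else NULL))
  expect_equal(check_biological_relevance(entry, 1L, "Phosphoserine",
                                          rules = no_nterm),
               "rejected_nterm")
})

test_that("site evidence merges by site with spectrum-level deduplication", {
  sites <- tibble::tibble(
    accession = c("P1", "P1", "P1", "P1", "P2"),
    canonical_position = c(10L, 10L, 10L, 12L, 10L),
    ptm_name = "Phosphoserine",
    dataset_id = c("DS1", "DS1", "DS2", "DS1", "DS1"),
    spectrum_id = c("S1", "S1", "S9", "S2", "S3"),   # S1 duplicated
    peptide = c("AASK", "AASK", "AASKR", "TTSK", "GGSK"))
  ev <- merge_site_evidence(sites)
  expect_equal(nrow(ev), 3)
  s10 <- ev[ev$accession == "P1" & ev$canonical_position == 10, ]
  expect_equal(s10$n_datasets, 2L)
  expect_equal(s10$n_spectra, 2L)       # S1 deduplicated
  expect_equal(s10$peptides, "AASK,AASKR")
  expect_equal(unique(ev$evidence_code), "ECO:0000244")
  expect_equal(ev$accession, c("P1", "P1", "P2"))   # sorted output
  expect_equal(nrow(merge_site_evidence(sites[0, ])), 0)
})

test_that("existence promotion needs K distinct unique peptides and is idempotent", {
  e <- protein_entry("P00001", "AAKCCR", existence = "transcript_level")
  pr <- promote_protein_existence(e, c("AAK", "CCR"), k = 2)
  expect_true(pr$promoted)
  expect_equal(pr$entry$existence, "protein_level")
  # already at protein level: unchanged
  pr2 <- promote_protein_existence(pr$entry, c("AAK", "CCR"), k = 2)
  expect_false(pr2$promoted)
  # one peptide under K = 2: unchanged, note says why
  pr3 <- promote_protein_existence(e, "AAK", k = 2)
  expect_false(pr3$promoted)
  expect_equal(pr3$entry$existence, "transcript_level")
  expect_match(pr3$note, "insufficient peptides")
  # duplicated peptides count once
  pr4 <- promote_protein_existence(e, c("AAK", "AAK"), k = 2)
  expect_false(pr4$promoted)
})

test_that("annotation files carry provenance headers and deterministic rows", {
  ev <- merge_site_evidence(tibble::tibble(
    accession = "P1", canonical_position = 10L, ptm_name = "Phosphoserine",
    dataset_id = "DS1", spectrum_id = "S1", peptide = "AASK"))
  path <- tempfile(fileext = ".tsv")
  write_annotations(ev, path, release_tag = "test-1")
  lines <- readLines(path)
  expect_match(lines[1], "release=test-1")
  expect_match(lines[2], "digest=trypsin")
  expect_equal(lines[4], paste(c("accession", "position", "ptm_name",
                                 "evidence_code", "n_datasets", "n_spectra",
                                 "peptides"), collapse = "\t"))
  expect_equal(lines[5], "P1\t10\tPhosphoserine\tECO:0000244\t1\t1\tAASK")
  # empty evidence: header-only file
  write_annotations(merge_site_evidence(NULL), path)
  expect_length(readLines(path), 4)
})
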