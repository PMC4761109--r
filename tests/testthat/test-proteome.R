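test_that("FASTA parsing handles canonical records, isoforms and header metadata", {
  path <- write_lines_tmp(c(
    ">sp|P00001|TEST1_HUMAN Test protein GN=TST1 PE=2",
    "MKAAR",
    ">P00001-2",
    "MKR",
    ">sp|P00002|TEST2_HUMAN",
    "mkaay*"), ext = ".fasta")
  prot <- read_proteome_fasta(path)
  expect_length(prot$entries, 2)
  e <- prot$entries$P00001
  expect_equal(e$canonical_seq, "MKAAR")
  expect_equal(e$gene_symbol, "TST1")
  expect_equal(e$existence, "transcript_level")
  expect_length(e$isoforms, 1)
  expect_equal(e$isoforms[["P00001-2"]]$seq, "MKR")
  # case-folding, stop stripping, PE default
  e2 <- prot$entries$P00002
  expect_equal(e2$canonical_seq, "MKAAY")
  expect_equal(e2$existence, "predicted")
})

test_that("FASTA parse errors name the offending record", {
  orphan <- write_lines_tmp(c(">P00009-2", "MKR"), ext = ".fasta")
  expect_error(read_proteome_fasta(orphan),
               class = "unicityr_orphan_isoform_error")
  badhdr <- write_lines_tmp(c(">sp|P00001|OK", "MKAAR", ">not a header",
                              "MKR"), ext = ".fasta")
  expect_error(read_proteome_fasta(badhdr), "line 3",
               class = "unicityr_parse_error")
  badres <- write_lines_tmp(c(">sp|P00001|OK", "MKXAR"), ext = ".fasta")
  expect_error(read_proteome_fasta(badres), "position 3",
               class = "unicityr_alphabet_error")
})

test_that("feature table attaches features and rejects inconsistent variants", {
  fasta <- write_lines_tmp(c(">sp|P00001|T", "MKAAR"), ext = ".fasta")
  prot <- read_proteome_fasta(fasta)
  ft <- write_lines_tmp(c(
    "accession\ttarget_form\tkind\tbegin\tend\tpayload",
    "P00001\tcanonical\tTRANSMEM\t2\t4\t-",
    "P00001\tcanonical\tVARIANT\t3\t3\tA>V",
    "P00001\tcanonical\tVARIANT\t3\t3\tG>V",
    "P99999\tcanonical\tCHAIN\t1\t2\t-"))
  expect_warning(prot2 <- read_feature_table(ft, prot), "skipped 2")
  feats <- prot2$entries$P00001$features
  expect_equal(nrow(feats), 2)
  expect_setequal(feats$kind, c("TRANSMEM", "VARIANT"))
  problems <- attr(prot2, "problems")
  expect_match(problems$reason[problems$line == 3], "original 'G'")
  expect_match(problems$reason[problems$line == 4], "unknown accession")
  # strict mode aborts instead
  expect_error(read_feature_table(ft, prot, strict = TRUE),
               class = "unicityr_input_error")
})

test_that("proteome round-trips through FASTA + feature table unchanged", {
  gp <- generate_proteome(15, seed = 42, isoform_prob = 0.5,
                          variant_prob = 0.6, tm_prob = 0.5,
                          chain_prob = 0.5, shared_block_prob = 0.2)
  p1 <- gp$proteome
  fasta <- tempfile(fileext = ".fasta")
  feats <- tempfile(fileext = ".tsv")
  write_proteome_fasta(p1, fasta)
  write_feature_table(p1, feats)
  p2 <- read_feature_table(feats, read_proteome_fasta(fasta,
                                                      p1$release_tag))
  attr(p2, "problems") <- NULL
  for (acc in names(p1$entries)) {
    e1 <- p1$entries[[acc]]
    e2 <- p2$entries[[acc]]
    expect_identical(e1$canonical_seq, e2$canonical_seq)
    expect_identical(e1$gene_symbol, e2$gene_symbol)
    expect_identical(e1$existence, e2$existence)
    expect_identical(names(e1$isoforms), names(e2$isoforms))
    for (iso in names(e1$isoforms)) {
      expect_identical(e1$isoforms[[iso]]$seq, e2$isoforms[[iso]]$seq)
      expect_equal(as.data.frame(e1$isoforms[[iso]]$alignment),
                   as.data.frame(e2$isoforms[[iso]]$alignment))
    }
    o1 <- e1$features[order(e1$features$kind, e1$features$begin), ]
    o2 <- e2$features[order(e2$features$kind, e2$features$begin), ]
    expect_equal(as.data.frame(o1), as.data.frame(o2),
                 ignore_attr = TRUE)
  }
})

test_that("isoform positions map through alignment blocks, gaps return NA", {
  # canonical MAGCDEFTH, isoform MAGCFTH: shares M A G C then F T H
  entry <- protein_entry(
    "P00001", "MAGCDEFTH",
    isoforms = list(isoform("P00001-2", "MAGCFTH",
                            tibble::tibble(canonical_start = c(1L, 7L),
                                           iso_start = c(1L, 5L),
                                           length = c(4L, 3L)))))
  validate_entry(entry)
  expect_equal(map_isoform_position_to_canonical(entry, "P00001-2", 5), 7L)
  expect_equal(map_isoform_position_to_canonical(entry, "P00001-2", 1), 1L)
  expect_equal(map_isoform_position_to_canonical(entry, "P00001-2", 4), 4L)
  expect_error(map_isoform_position_to_canonical(entry, "P00001-3", 1),
               class = "unicityr_reference_error")
  expect_error(map_isoform_position_to_canonical(entry, "P00001-2", 8),
               class = "unicityr_bounds_error")
  # a gap position: isoform with an insertion
  entry2 <- protein_entry(
    "P00002", "MKAAR",
    isoforms = list(isoform("P00002-2", "MKWWAAR",
                            tibble::tibble(canonical_start = c(1L, 3L),
                                           iso_start = c(1L, 5L),
                                           length = c(2L, 3L)))))
  validate_entry(entry2)
  expect_true(is.na(map_isoform_position_to_canonical(entry2, "P00002-2", 3)))
  expect_true(is.na(map_isoform_position_to_canonical(entry2, "P00002-2", 4)))
})

test_that("alignment validation rejects unsorted, overlapping or mismatched blocks", {
  bad_sub <- protein_entry(
    "P1", "MAGCDEFTH",
    isoforms = list(isoform("P1-2", "MAGCFTH",
                            tibble::tibble(canonical_start = 1L,
                                           iso_start = 1L, length = 5L))))
  expect_error(validate_entry(bad_sub), "non-identical",
               class = "unicityr_consistency_error")
  bad_sort <- protein_entry(
    "P1", "MAGCDEFTH",
    isoforms = list(isoform("P1-2", "MAGCFTH",
                            tibble::tibble(canonical_start = c(7L, 1L),
                                           iso_start = c(5L, 1L),
                                           length = c(3L, 4L)))))
  expect_error(validate_entry(bad_sort), "not sorted")
})

test_that("sequence form enumeration follows the emission rule and count law", {
  feats <- tibble::tibble(
    kind = c("CHAIN", "VARIANT"), target_form = "canonical",
    begin = c(3L, 4L), end = c(5L, 4L), payload = c(NA, "A>V"))
  entry <- protein_entry("P00001", "MKAAR", features = feats)
  validate_entry(entry)

  forms <- enumerate_sequence_forms(entry, form_options(apply_variants = TRUE))
  expect_equal(forms$seq, c("MKAAR", "AAR", "MKAVR", "AVR"))
  expect_equal(forms$form_kind,
               c("canonical", "processed", "variant", "variant"))
  expect_equal(forms$carries_variant, c(FALSE, FALSE, TRUE, TRUE))

  forms0 <- enumerate_sequence_forms(entry,
                                     form_options(apply_variants = FALSE))
  expect_equal(nrow(forms0), 2)

  bare <- protein_entry("P00002", "MKAAR")
  expect_equal(nrow(enumerate_sequence_forms(bare)), 1)

  # count law on random fixtures:
  # 1 + #isoforms + #processing + #variants x (1 + #processing covering it)
  gp <- generate_proteome(20, seed = 99, isoform_prob = 0.5,
                          variant_prob = 0.7, tm_prob = 0.3,
                          chain_prob = 0.6)
  for (e in gp$proteome$entries) {
    ft <- e$features
    n_proc <- sum(ft$kind %in% c("CHAIN", "PEPTIDE", "PROPEP", "SIGNAL"))
    vars <- ft[ft$kind == "VARIANT", ]
    n_var_forms <- 0L
    for (i in seq_len(nrow(vars))) {
      proc <- ft[ft$kind %in% c("CHAIN", "PEPTIDE", "PROPEP", "SIGNAL"), ]
      covering <- sum(proc$target_form == vars$target_form[i] &
                        proc$begin <= vars$begin[i] &
                        proc$end >= vars$begin[i])
      n_var_forms <- n_var_forms + 1L + covering
    }
    expected <- 1L + length(e$isoforms) + n_proc + n_var_forms
    expect_equal(nrow(enumerate_sequence_forms(e)), expected)
  }
})

test_that("selenocysteine is a first-class residue distinct from cysteine", {
  entry <- protein_entry("P00001", "MKUUUCCR")
  expect_silent(validate_entry(entry))
  utab <- build_unicity_table(proteome(list(entry)), short_spec())
  expect_equal(nrow(unicity_lookup(utab, "UUUCCR")), 1)
  expect_equal(nrow(unicity_lookup(utab, "CCCCCR")), 0)
})
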