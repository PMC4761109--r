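test_that("the table indexes shared and unique peptides with all assignments", {
  prot <- two_entry_proteome()   # P00001 AAKCCR / P00002 DDKCCR
  utab <- build_unicity_table(prot, short_spec())
  ccr <- unicity_lookup(utab, "CCR")
  expect_equal(sort(unique(ccr$accession)), c("P00001", "P00002"))
  aak <- unicity_lookup(utab, "AAK")
  expect_equal(unique(aak$accession), "P00001")
  expect_equal(unicity_classify(utab, "AAK"), "unique_protein")
  expect_equal(unicity_classify(utab, "CCR"), "shared")
  expect_equal(unicity_classify(utab, "WWWW"), "absent")
  expect_equal(nrow(unicity_lookup(utab, "WWWW")), 0)
  expect_error(unicity_lookup(utab, "CC1R"),
               class = "unicityr_alphabet_error")
  expect_error(build_unicity_table(proteome(list()), short_spec()))
})

test_that("I/L equivalence merges isobaric peptides; exact mode separates them", {
  prot <- proteome(list(protein_entry("P00001", "AAKILK", gene_symbol = "GA"),
                        protein_entry("P00002", "DDKLIK", gene_symbol = "GB")))
  il <- build_unicity_table(prot, short_spec(),
                            normalization = "il_equivalent")
  hits <- unicity_lookup(il, "ILK")
  expect_setequal(unique(hits$accession), c("P00001", "P00002"))
  expect_equal(unique(hits$key), "JJK")
  expect_equal(unicity_lookup(il, "LIK")$key, hits$key)

  ex <- build_unicity_table(prot, short_spec(), normalization = "exact")
  expect_equal(unique(unicity_lookup(ex, "ILK")$accession), "P00001")
  expect_equal(unique(unicity_lookup(ex, "LIK")$accession), "P00002")
})

test_that("unique_gene separates several accessions of one gene from true sharing", {
  prot <- proteome(list(
    protein_entry("P00001", "AAKCCR", gene_symbol = "SAME"),
    protein_entry("P00002", "DDKCCR", gene_symbol = "SAME"),
    protein_entry("P00003", "EEKGGR", gene_symbol = "OTHER")))
  utab <- build_unicity_table(prot, short_spec())
  expect_equal(unicity_classify(utab, "CCR"), "unique_gene")
  expect_equal(unicity_classify(utab, "GGR"), "unique_protein")
})

test_that("peptides on variant or isoform-specific forms keep NA canonical coordinates", {
  entry <- protein_entry(
    "P00001", "MKAAACCR",
    isoforms = list(isoform("P00001-2", "MKWWWWWWWR",
                            tibble::tibble(canonical_start = 1L,
                                           iso_start = 1L, length = 2L))),
    features = tibble::tibble(kind = "VARIANT", target_form = "canonical",
                              begin = 4L, end = 4L, payload = "A>W"))
  validate_entry(entry)
  utab <- build_unicity_table(proteome(list(entry)), short_spec())
  # isoform-specific peptide: only on the isoform, outside alignment blocks
  iso_pep <- unicity_lookup(utab, "WWWWWWWR")
  expect_equal(nrow(iso_pep), 1)
  expect_true(is.na(iso_pep$canonical_start))
  # variant-only peptide: flagged, with canonical coordinates preserved
  var_pep <- unicity_lookup(utab, "AWACCR")
  expect_true(all(var_pep$carries_variant))
  expect_equal(unique(var_pep$canonical_start), 3L)
  # canonical peptide spanning the whole entry start
  can_pep <- unicity_lookup(utab, "MK")
  expect_true(any(!can_pep$carries_variant))
})

test_that("serialized tables are byte-identical across rebuilds", {
  gp <- generate_proteome(10, seed = 5, shared_block_prob = 0.3)
  t1 <- build_unicity_table(gp$proteome)
  t2 <- build_unicity_table(gp$proteome)
  f1 <- tempfile(); f2 <- tempfile()
  write_unicity_table(t1, f1)
  write_unicity_table(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(paste0(f1, ".meta.json")),
                   readLines(paste0(f2, ".meta.json")))
})

test_that("adding an entry never shrinks any peptide's assignment list", {
  gp <- generate_proteome(8, seed = 21, shared_block_prob = 0.4)
  prot_small <- proteome(gp$proteome$entries[1:6],
                         release_tag = gp$proteome$release_tag)
  spec <- digest_spec()
  t_small <- build_unicity_table(prot_small, spec)
  t_full <- build_unicity_table(gp$proteome, spec)
  keys <- ls(t_small$index)
  for (k in sample(keys, min(200, length(keys)))) {
    small <- t_small$index[[k]]
    full <- t_full$index[[k]]
    expect_true(!is.null(full))
    expect_gte(nrow(full), nrow(small))
    both <- merge(small[, c("accession", "form_id", "start")],
                  full[, c("accession", "form_id", "start")])
    expect_equal(nrow(both), nrow(small))
  }
})
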