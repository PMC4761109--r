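test_that("PSM tables parse mods, preserve missing scores and report bad rows", {
  path <- write_lines_tmp(c(
    "dataset_id\tspectrum_id\tpeptide\tmods\tmascot\tpep",
    "DS1\tSP1\tSAMPK\t\t55.0\tNA",
    "DS1\tSP2\tSAMPK\t3:Phosphoserine:25.0\t55.0\t0.001",
    "DS1\tSP3\tSAMPK\t1:Phosphoserine:\tNA\t0.002",
    "DS1\tSP4\tSAMPK\t9:Phosphoserine:25.0\t55.0\t0.001",
    "DS1\tSP5\tSAMPK\t2:Madeupmod:10.0\t55.0\t0.001"))
  expect_warning(psms <- read_psm_table(path), "skipped 2")
  expect_equal(nrow(psms), 3)
  expect_equal(nrow(psms$mods[[1]]), 0)
  expect_true(is.na(psms$pep[1]))          # missing stays missing, not 0
  m2 <- psms$mods[[2]]
  expect_equal(m2$pep_pos, 3L)
  expect_equal(m2$ptm_name, "Phosphoserine")
  expect_equal(m2$ascore, 25.0)
  expect_true(is.na(psms$mods[[3]]$ascore))  # missing localization score
  probs <- attr(psms, "problems")
  expect_match(probs$reason[probs$line == 4], "outside peptide")
  expect_match(probs$reason[probs$line == 5], "controlled vocabulary")
  expect_error(read_psm_table(path, strict = TRUE), "row 4")
})

test_that("identification thresholds are inclusive for Mascot, strict for PEP", {
  policy <- filter_policy()
  run1 <- function(mascot, pep) {
    flt <- apply_identification_filter(make_psm("AAAK", mascot, pep), policy)
    nrow(flt$accepted) == 1
  }
  expect_true(run1(40.0, NA))      # minimum Mascot score of 40: inclusive
  expect_false(run1(39.999, NA))
  expect_false(run1(NA, 0.01))     # PEP < 1%: strict at the boundary
  expect_true(run1(NA, 0.00999))
  expect_true(run1(39.0, 0.005))   # PEP branch rescues a low Mascot
  expect_false(run1(39.0, 0.02))   # both branches fail
  # no usable score is its own rejection reason
  flt <- apply_identification_filter(make_psm("AAAK", NA, NA), policy)
  expect_equal(flt$rejected$reason, "no usable score")
  # conjunctive mode requires both scores to pass
  all_policy <- filter_policy(combination = "all")
  expect_equal(nrow(apply_identification_filter(
    make_psm("AAAK", 55, NA), all_policy)$accepted), 0)
  expect_equal(nrow(apply_identification_filter(
    make_psm("AAAK", 55, 0.001), all_policy)$accepted), 1)
})

test_that("site localization requires Ascore >= 19, inclusive", {
  policy <- filter_policy()
  run1 <- function(ascore) {
    psm <- make_psm("SAAAK", 55, 0.001,
                    mods = list(list(1, "Phosphoserine", ascore)))
    apply_site_filter(psm, policy)
  }
  expect_true(run1(19.0)$localized)
  expect_false(run1(18.999)$localized)
  missing <- run1(NA_real_)
  expect_false(missing$localized)
  expect_equal(missing$reason, "no localization score")
  # non-localized candidates are retained, not dropped
  expect_equal(nrow(run1(5)), 1)
})

test_that("filtering partitions its input and is idempotent", {
  set.seed(501)
  n <- 2000
  psms <- tibble::tibble(
    dataset_id = "DS1", spectrum_id = sprintf("SP%04d", 1:n),
    peptide = "AAAK",
    mascot = ifelse(runif(n) < 0.15, NA, runif(n, 0, 80)),
    pep = ifelse(runif(n) < 0.15, NA, runif(n, 0, 0.05)))
  psms$mods <- rep(list(tibble::tibble(pep_pos = integer(),
                                       ptm_name = character(),
                                       ascore = double())), n)
  policy <- filter_policy()
  flt <- apply_identification_filter(psms, policy)
  expect_equal(nrow(flt$accepted) + nrow(flt$rejected), n)
  expect_length(intersect(flt$accepted$spectrum_id,
                          flt$rejected$spectrum_id), 0)
  again <- apply_identification_filter(flt$accepted, policy)
  expect_equal(again$accepted, flt$accepted)
  expect_equal(nrow(again$rejected), 0)
})

test_that("raising any threshold never gains acceptances", {
  set.seed(502)
  n <- 3000
  psms <- tibble::tibble(
    dataset_id = "DS1", spectrum_id = sprintf("SP%04d", 1:n),
    peptide = "AAAK",
    mascot = ifelse(runif(n) < 0.2, NA, runif(n, 0, 80)),
    pep = ifelse(runif(n) < 0.2, NA, runif(n, 0, 0.05)))
  psms$mods <- rep(list(tibble::tibble(pep_pos = integer(),
                                       ptm_name = character(),
                                       ascore = double())), n)
  for (i in 1:20) {
    m1 <- runif(1, 20, 60); m2 <- m1 + runif(1, 0, 20)
    p1 <- runif(1, 0.005, 0.04); p2 <- p1 * runif(1, 0.1, 1)
    a1 <- apply_identification_filter(psms, filter_policy(m1, p1))$accepted
    a2 <- apply_identification_filter(psms, filter_policy(m2, p2))$accepted
    expect_true(all(a2$spectrum_id %in% a1$spectrum_id))
  }
})

test_that("metadata checklist gates on raw data, instrument and software", {
  ok <- list(dataset_id = "DS1", raw_data_location = "https://x/raw",
             instrument = "QE", search_software = "Mascot",
             enzyme = "trypsin", reported_fdr = 0.01)
  expect_equal(validate_dataset_metadata(ok)$verdict, "pass")

  no_raw <- ok; no_raw$raw_data_location <- ""
  rep <- validate_dataset_metadata(no_raw)
  expect_equal(rep$verdict, "fail")
  expect_equal(rep$checks$status[rep$checks$field == "raw_data_location"],
               "fail")

  no_fdr <- ok; no_fdr$reported_fdr <- NA
  rep2 <- validate_dataset_metadata(no_fdr)
  expect_equal(rep2$verdict, "pass")
  expect_match(rep2$warnings, "reported_fdr")

  expect_error(validate_dataset_metadata(list(dataset_id = "")))
})

test_that("metadata round-trips through JSON and TSV readers", {
  meta <- list(dataset_id = "DS9", raw_data_location = "ftp://x",
               instrument = "TOF", search_software = "Andromeda",
               enzyme = "trypsin", reported_fdr = 0.01)
  pj <- tempfile(fileext = ".json")
  jsonlite::write_json(meta, pj, auto_unbox = TRUE)
  got <- read_dataset_metadata(pj)
  expect_equal(got$dataset_id, "DS9")
  expect_equal(got$reported_fdr, 0.01)
  pt <- write_lines_tmp(paste(
    c("dataset_id\traw_data_location\tinstrument\tsearch_software\tenzyme\treported_fdr",
      "DS9\tftp://x\tTOF\tAndromeda\ttrypsin\t0.01"), collapse = "\n"))
  got2 <- read_dataset_metadata(pt)
  expect_equal(as.list(got2), as.list(got))
})
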