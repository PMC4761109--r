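## On-disk formats.
##
## Proteomes travel as two plain-text files:
##   * FASTA in the UniProt header dialect: `>sp|ACC|NAME desc GN=SYM PE=n`
##     for canonical sequences and `>ACC-n desc` for isoforms. PE maps 1..5 to
##     protein_level / transcript_level / homology / predicted / uncertain.
##   * a 6-column tab-separated feature table
##     (# coordinates are 1-based inclusive):
##     accession  target_form  kind  begin  end  payload
##     Isoform alignments ride in the same file as kind=ALIGN rows, one block
##     per row, payload `canonical_start,iso_start,length`.

PE_TO_EXISTENCE <- setNames(EXISTENCE_LEVELS, as.character(1:5))
EXISTENCE_TO_PE <- setNames(as.character(1:5), EXISTENCE_LEVELS)

parse_fasta_header <- function(name) {
  # canonical: db|ACC|NAME [description]; isoform: ACC-n [description]
  m <- str_match(name, "^([A-Za-z]{2})\\|([A-Z0-9]+)\\|(\\S+)\\s*(.*)$")
  if (!is.na(m[1, 1])) {
    desc <- m[1, 5]
    gn <- str_match(desc, "(?:^|\\s)GN=(\\S+)")[1, 2]
    pe <- str_match(desc, "(?:^|\\s)PE=([1-5])")[1, 2]
    return(list(type = "canonical", accession = m[1, 3], entry_name = m[1, 4],
                gene_symbol = if (is.na(gn)) "" else gn,
                existence = if (is.na(pe)) "predicted" else
                  unname(PE_TO_EXISTENCE[pe])))
  }
  m <- str_match(name, "^([A-Z0-9]+)-(\\d+)\\s*(.*)$")
  if (!is.na(m[1, 1])) {
    return(list(type = "isoform", accession = m[1, 2],
                iso_id = paste0(m[1, 2], "-", m[1, 3])))
  }
  NULL
}

#' Read a proteome from a FASTA file
#'
#' Parses the UniProt header dialect: canonical records as
#' `>db|ACCESSION|NAME ... GN=SYMBOL PE=n` and isoforms as `>ACCESSION-n`.
#' Sequences are upper-cased and trailing `*` stop characters stripped.
#' Isoform records attach to their parent entry with an empty alignment
#' (alignments come from the feature table, see [read_feature_table()]).
#'
#' @param path Path to a FASTA file.
#' @param release_tag Optional release tag to stamp on the proteome.
#' @return A [proteome()] with features empty.
#' @export
read_proteome_fasta <- function(path, release_tag = "") {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  aas <- readAAStringSet(path)
  seqs <- unname(toupper(sub("\\*+$", "", as.character(aas))))
  hdrs <- names(aas)

  header_lines <- function() {
    lines <- readLines(path, warn = FALSE)
    which(startsWith(lines, ">"))
  }

  entries <- list()
  iso_buffer <- list()
  for (i in seq_along(hdrs)) {
    h <- parse_fasta_header(hdrs[i])
    if (is.null(h)) {
      abort_input(sprintf("malformed FASTA header at line %d: '>%s'",
                          header_lines()[i], hdrs[i]),
                  class = "unicityr_parse_error")
    }
    bad <- first_bad_residue(seqs[i])
    if (!is.na(bad)) {
      id <- if (h$type == "canonical") h$accession else h$iso_id
      abort_input(sprintf("%s: illegal residue '%s' at position %d",
                          id, substr(seqs[i], bad, bad), bad),
                  class = "unicityr_alphabet_error")
    }
    if (h$type == "canonical") {
      entries[[h$accession]] <- protein_entry(
        accession = h$accession, canonical_seq = seqs[i],
        gene_symbol = h$gene_symbol, existence = h$existence,
        entry_name = h$entry_name)
    } else {
      iso_buffer[[length(iso_buffer) + 1L]] <-
        list(accession = h$accession, iso = isoform(h$iso_id, seqs[i]))
    }
  }
  for (b in iso_buffer) {
    if (is.null(entries[[b$accession]])) {
      abort_input(sprintf("isoform %s has no parent entry %s in the file",
                          b$iso$iso_id, b$accession),
                  class = "unicityr_orphan_isoform_error")
    }
    entries[[b$accession]]$isoforms[[b$iso$iso_id]] <- b$iso
  }
  proteome(unname(entries), release_tag = release_tag)
}

#' Write a proteome to FASTA (UniProt header dialect)
#'
#' @param x A [proteome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(x, path) {
  recs <- character(0)
  nms <- character(0)
  for (e in x$entries) {
    nms <- c(nms, sprintf("sp|%s|%s GN=%s PE=%s", e$accession, e$entry_name,
                          e$gene_symbol, EXISTENCE_TO_PE[e$existence]))
    recs <- c(recs, e$canonical_seq)
    for (iso in e$isoforms) {
      nms <- c(nms, iso$iso_id)
      recs <- c(recs, iso$seq)
    }
  }
  set <- AAStringSet(recs)
  names(set) <- nms
  writeXStringSet(set, path)
  invisible(path)
}

#' Attach features and isoform alignments from a tab-separated table
#'
#' The table has columns `accession`, `target_form`, `kind`, `begin`, `end`,
#' `payload` (tab-separated, `#` comment lines allowed; coordinates 1-based
#' inclusive). Rows of kind `ALIGN` populate isoform alignment blocks; their
#' payload is `canonical_start,iso_start,length`. All attached features are
#' validated against the model invariants; under the default lenient mode,
#' rows that fail validation are skipped and reported (as a warning and in
#' the returned problems attribute), under `strict = TRUE` they abort.
#'
#' @param path Path to the feature table.
#' @param proteome A [proteome()] from [read_proteome_fasta()].
#' @param strict Abort on the first bad row instead of skip-and-report.
#' @return The proteome with features and alignments attached; skipped rows
#'   are recorded in `attr(, "problems")` (tibble with `line`, `reason`).
#' @export
read_feature_table <- function(path, proteome, strict = FALSE) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  tab <- read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = cols(accession = col_character(),
                                   target_form = col_character(),
                                   kind = col_character(),
                                   begin = col_integer(),
                                   end = col_integer(),
                                   payload = col_character()))
  problems <- tibble(line = integer(), reason = character())
  note <- function(i, reason) {
    if (strict) abort_input(sprintf("feature table row %d: %s", i, reason))
    problems <<- add_row(problems, line = i, reason = reason)
  }

  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    e <- proteome$entries[[row$accession]]
    if (is.null(e)) {
      note(i, sprintf("unknown accession '%s'", row$accession)); next
    }
    if (!row$kind %in% FEATURE_KINDS) {
      note(i, sprintf("unknown feature kind '%s'", row$kind)); next
    }
    if (row$kind == "ALIGN") {
      if (!row$target_form %in% names(e$isoforms)) {
        note(i, sprintf("ALIGN targets unknown isoform '%s'", row$target_form))
        next
      }
      nums <- suppressWarnings(as.integer(strsplit(row$payload, ",")[[1]]))
      if (length(nums) != 3 || anyNA(nums)) {
        note(i, sprintf("bad ALIGN payload '%s'", row$payload)); next
      }
      iso <- e$isoforms[[row$target_form]]
      iso$alignment <- add_row(iso$alignment, canonical_start = nums[1],
                               iso_start = nums[2], length = nums[3])
      e$isoforms[[row$target_form]] <- iso
      proteome$entries[[row$accession]] <- e
      next
    }
    candidate <- e
    candidate$features <- add_row(
      e$features, kind = row$kind, target_form = row$target_form,
      begin = row$begin, end = row$end,
      payload = if (is.na(row$payload) || identical(row$payload, "-"))
        NA_character_ else row$payload)
    ok <- tryCatch({ validate_entry(candidate); TRUE },
                   unicityr_error = function(cnd) {
                     note(i, conditionMessage(cnd)); FALSE
                   })
    if (ok) proteome$entries[[row$accession]] <- candidate
  }
  # alignments arrive block-by-block; validate them once assembled
  for (acc in names(proteome$entries)) {
    e <- proteome$entries[[acc]]
    for (iso_id in names(e$isoforms)) {
      iso <- e$isoforms[[iso_id]]
      ord <- order(iso$alignment$iso_start)
      iso$alignment <- iso$alignment[ord, ]
      proteome$entries[[acc]]$isoforms[[iso_id]] <- iso
      tryCatch(validate_alignment(e$canonical_seq, iso),
               unicityr_error = function(cnd) {
                 if (strict) abort_input(conditionMessage(cnd))
                 warn(conditionMessage(cnd))
               })
    }
  }
  if (nrow(problems) > 0) {
    warn(sprintf("feature table: skipped %d row(s); see attr(, 'problems')",
                 nrow(problems)))
  }
  attr(proteome, "problems") <- problems
  proteome
}

#' Write the feature table (and isoform alignments) of a proteome
#'
#' @param x A [proteome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  rows <- list()
  for (e in x$entries) {
    ft <- e$features
    if (nrow(ft) > 0) {
      rows[[length(rows) + 1L]] <- tibble(
        accession = e$accession, target_form = ft$target_form,
        kind = ft$kind, begin = ft$begin, end = ft$end,
        payload = ifelse(is.na(ft$payload), "-", ft$payload))
    }
    for (iso in e$isoforms) {
      bl <- iso$alignment
      if (nrow(bl) > 0) {
        rows[[length(rows) + 1L]] <- tibble(
          accession = e$accession, target_form = iso$iso_id, kind = "ALIGN",
          begin = bl$iso_start, end = bl$iso_start + bl$length - 1L,
          payload = sprintf("%d,%d,%d", bl$canonical_start, bl$iso_start,
                            bl$length))
      }
    }
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(accession = character(), target_form = character(),
           kind = character(), begin = integer(), end = integer(),
           payload = character())
  header <- c("# unicityr feature table; coordinates are 1-based inclusive",
              paste(c("accession", "target_form", "kind", "begin", "end",
                      "payload"), collapse = "\t"))
  body <- sprintf("%s\t%s\t%s\t%d\t%d\t%s", out$accession, out$target_form,
                  out$kind, out$begin, out$end, out$payload)
  write_lines(c(header, body), path)
  invisible(path)
}
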