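# Independent oracles, deliberately written with a different algorithm than
# the package: digestion by exhaustive substring enumeration over valid
# cleavage boundaries, and peptide assignment by scanning every sequence
# form of every entry.

oracle_sites <- function(seq, enzyme) {
  n <- nchar(seq)
  if (n < 2 || enzyme == "none") return(integer(0))
  ch <- strsplit(seq, "")[[1]]
  out <- integer(0)
  for (i in 1:(n - 1)) {
    if (ch[i] %in% c("K", "R") && (enzyme == "trypsin_p" || ch[i + 1] != "P")) {
      out <- c(out, i)
    }
  }
  out
}

# all substrings whose boundaries are valid cleavage boundaries and that
# contain at most max_missed internal sites
oracle_digest <- function(seq, spec) {
  n <- nchar(seq)
  sites <- oracle_sites(seq, spec$enzyme)
  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  grid <- expand.grid(start = starts, end = ends)
  grid <- grid[grid$end >= grid$start, , drop = FALSE]
  # internal missed sites via prefix sums over the site indicator
  is_site <- integer(n)
  is_site[sites] <- 1L
  cum <- c(0L, cumsum(is_site))
  grid$missed <- cum[grid$end] - cum[grid$start]  # sites in [start, end-1]
  len <- grid$end - grid$start + 1L
  grid <- grid[grid$missed <= spec$max_missed &
                 len >= spec$min_len & len <= spec$max_len, , drop = FALSE]
  grid <- grid[order(grid$start, grid$end), , drop = FALSE]
  grid$seq <- if (nrow(grid) == 0) character(0) else
    substring(seq, grid$start, grid$end)
  rownames(grid) <- NULL
  grid[, c("start", "end", "seq", "missed")]
}

# key -> data.frame(accession, gene_symbol, form_id, start, end) over every
# form of every entry
oracle_unicity_map <- function(prot, spec, opts, normalization) {
  rows <- list()
  for (e in prot$entries) {
    forms <- enumerate_sequence_forms(e, opts)
    for (i in seq_len(nrow(forms))) {
      pep <- oracle_digest(forms$seq[i], spec)
      if (nrow(pep) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        key = normalize_peptide(pep$seq, normalization),
        accession = e$accession, gene_symbol = e$gene_symbol,
        form_id = forms$form_id[i], start = pep$start, end = pep$end)
    }
  }
  env <- new.env(parent = emptyenv())
  if (length(rows) == 0) return(env)
  big <- do.call(rbind, rows)
  # deduplicate like the table contract: one row per (key, accession, form,
  # start), then fix a deterministic order
  big <- big[!duplicated(big[, c("key", "accession", "form_id", "start")]), ,
             drop = FALSE]
  big <- big[order(big$key, big$accession, big$form_id, big$start), ,
             drop = FALSE]
  rownames(big) <- NULL
  list2env(split(big, factor(big$key, levels = unique(big$key))), envir = env)
  env
}

oracle_assignments_frame <- function(env) {
  big <- do.call(rbind, lapply(sort(ls(env)), function(k) env[[k]]))
  rownames(big) <- NULL
  big
}

oracle_classify <- function(assignments) {
  if (is.null(assignments) || nrow(assignments) == 0) return("absent")
  if (length(unique(assignments$accession)) == 1) return("unique_protein")
  g <- unique(assignments$gene_symbol)
  if (length(g) == 1 && nzchar(g)) return("unique_gene")
  "shared"
}

random_absent_peptides <- function(env, n, len_range = c(7L, 12L)) {
  out <- character(0)
  while (length(out) < n) {
    pep <- paste(sample(strsplit("ACDEFGHKMNPQSTVWY", "")[[1]],
                        sample(len_range[1]:len_range[2], 1),
                        replace = TRUE), collapse = "")
    if (is.null(env[[normalize_peptide(pep, "il_equivalent")]]) &&
        is.null(env[[pep]])) {
      out <- c(out, pep)
    }
  }
  out
}

# ground-truth isoform layout: builds an isoform from a canonical sequence by
# recording, for every isoform position, which canonical position it was
# copied from (NA for insertions) - the construction ledger is the oracle
random_isoform_layout <- function(canonical_seq) {
  L <- nchar(canonical_seq)
  cpos <- 1L
  iso_chars <- character(0)
  src <- integer(0)
  blocks <- list()
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  while (cpos <= L) {
    action <- sample(c("align", "del", "ins"), 1, prob = c(0.6, 0.2, 0.2))
    if (action == "align") {
      len <- min(sample(3:20, 1), L - cpos + 1L)
      blocks[[length(blocks) + 1L]] <-
        data.frame(canonical_start = cpos,
                   iso_start = length(iso_chars) + 1L, length = len)
      iso_chars <- c(iso_chars,
                     strsplit(substr(canonical_seq, cpos,
                                     cpos + len - 1L), "")[[1]])
      src <- c(src, cpos:(cpos + len - 1L))
      cpos <- cpos + len
    } else if (action == "del") {
      cpos <- cpos + min(sample(1:10, 1), L - cpos + 1L)
    } else {
      k <- sample(1:6, 1)
      iso_chars <- c(iso_chars, sample(alphabet, k, replace = TRUE))
      src <- c(src, rep(NA_integer_, k))
    }
  }
  if (length(iso_chars) == 0) {  # degenerate: force one aligned residue
    blocks <- list(data.frame(canonical_start = 1L, iso_start = 1L,
                              length = 1L))
    iso_chars <- substr(canonical_seq, 1, 1)
    src <- 1L
  }
  # merge adjacent blocks (adjacent on both axes) so blocks stay strictly
  # monotone after random draws
  merged <- list()
  for (b in blocks) {
    m <- length(merged)
    if (m > 0 &&
        merged[[m]]$canonical_start + merged[[m]]$length == b$canonical_start &&
        merged[[m]]$iso_start + merged[[m]]$length == b$iso_start) {
      merged[[m]]$length <- merged[[m]]$length + b$length
    } else {
      merged[[m + 1L]] <- b
    }
  }
  list(iso_seq = paste(iso_chars, collapse = ""),
       alignment = do.call(rbind, merged), src = src)
}

random_aa_seq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
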