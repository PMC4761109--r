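---
title: "Integrating proteomics evidence into a curated proteome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating proteomics evidence into a curated proteome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unicityr)
```

## The problem

High-throughput mass-spectrometry studies report peptide identifications
and PTM sites at volumes no curation team can read paper by paper, with
heterogeneous quality and up to ~1 % tolerated false positives per
dataset. Integrating them naively into a reviewed knowledgebase
accumulates and propagates errors. `unicityr` implements the conservative
alternative: never re-search spectra, but re-filter the *reported* scores
with stringent cut-offs, demand unambiguous protein assignment through an
exhaustive peptide index, and screen sites for biological plausibility
before anything is written into the annotation.

The cost of this stringency is deliberate: valid identifications near the
thresholds are discarded so that what remains is gold-standard. The
pipeline reports every rejection with a reason, so nothing disappears
silently.

## Data model

An entry is gene-centric: one accession, one **canonical sequence** that
anchors all coordinates, optional splice isoforms, and a feature table.
Isoform sequences carry explicit alignment blocks
`(canonical_start, iso_start, length)` — maximal identical stretches,
strictly monotone on both coordinate systems. A position inside a block
maps to `canonical_start + (pos - iso_start)`; a position between blocks
is isoform-specific and maps to nothing. Alignments are *supplied*, not
computed; a helper can derive blocks for pure-deletion isoforms, but a
derived alignment keeps a provenance flag and is never silently trusted.

Sequence features use 1-based inclusive coordinates and are validated on
load: a VARIANT is a single-residue substitution whose recorded original
must match the sequence (mismatches are rejected row-wise and reported);
processing features (CHAIN, PEPTIDE, SIGNAL, PROPEP) and TRANSMEM are
intervals within their target form. Selenocysteine (`U`) is a first-class
residue and never aliases cysteine.

## Sequence forms and the unicity table

Peptides are assigned against every *form* an entry can produce:

1. the canonical sequence;
2. each isoform;
3. each processed product (the subsequence a processing feature spans,
   with its offset remembered);
4. when variant expansion is on (the default), each VARIANT applied to its
   target form and to every processed form containing it — **one variant
   per form**. Combinatorial multi-variant proteoforms are never
   enumerated: their number explodes, and single-variant expansion covers
   the intent of indexing natural variants. This is a documented
   limitation rather than an option.

All forms are digested in silico and the resulting peptides keyed into the
unicity table. Two key modes exist, stamped into the table and checked at
lookup: `il_equivalent` (default; I and L collapse to a placeholder `J`,
because standard MS cannot distinguish the isobaric pair) and `exact` (for
non-MS uses). A lookup returns every assignment — accession, form, position,
canonical coordinates where the span maps contiguously inside alignment
blocks, and a `carries_variant` flag set only when the peptide actually
covers the substituted residue. Classification is evaluated at the entry
(accession) level, matching gene-centric curation: a peptide seen only in
one entry's isoform or variant forms is still `unique_protein`. Several
accessions under one gene symbol give `unique_gene`; several genes,
`shared`.

The in-memory index is a hashed environment keyed by normalized peptide;
the serialized form is a sorted TSV plus a JSON sidecar carrying the digest
spec, key mode and proteome release tag, so tables built under different
dialects can never be mixed unnoticed.

## Digestion parameters

Defaults: classical trypsin (cleave after K/R, never before proline), at
most 2 missed cleavages, peptide length 7–45 residues. The proline rule is
the classical enzyme specificity; `trypsin_p` (unconditional cleavage) is
provided because several search engines use it — the dialect must match
the upstream search engine, which is why the spec used is recorded in
every output header. The 7-residue floor reflects that shorter peptides
are rarely informative for unicity; 45 is a generous tryptic upper bound.
No digestion parameters are prescribed by the integration procedure
itself, so these defaults are surfaced everywhere rather than hidden.
N-terminal methionine-cleaved forms are not auto-generated; if needed they
can be supplied as CHAIN features.

## Score filtering

Identification and localization are filtered separately, because the
scores measure different things:

* **identification**: accepted iff Mascot ≥ 40 *or* PEP < 0.01. The
  "minimum score of 40" is inclusive; "< 1 %" is strict. The disjunctive
  reading reflects that the two scores are alternative evidence of a
  correct identification from different search pipelines; a conjunctive
  mode (`combination: "all"`) is available for stricter audits since the
  source procedure's wording admits either reading.
* **localization**: a PTM site on an accepted PSM is localized iff
  Ascore ≥ 19 (inclusive). Ascore is a localization score, not an
  identification score, so it gates site annotation only — a peptide with
  a non-localized modification still counts as existence evidence.

Missing scores never default to zero. A PSM with neither score is rejected
with the distinct reason "no usable score"; a modification without an
Ascore is "no localization score". These are kept separate from
below-threshold rejections so audit trails stay honest.

## From peptide to annotated site

Localized candidates go through, in order: **unicity resolution** (only
`unique_protein` peptides proceed; `shared` and `unique_gene` are counted
as shared evidence but never annotated — the strictest reading of
"unambiguous"); **position resolution** (all assignments must agree on one
canonical position; peptides occurring at several positions of their entry
are rejected as position-ambiguous; peptides mapping only to
isoform-specific regions are emitted in a separate isoform-coordinate
section rather than dropped, since isoforms are first-class curated
products); **biological relevance** (the default rule rejects
phosphorylation-class PTMs inside TRANSMEM intervals, boundaries
inclusive; the rule registry is extensible, and the rule deliberately
scopes to phosphorylation only — other PTM classes pass). Surviving sites
are merged per (accession, position, PTM), deduplicated at spectrum level,
and written with evidence code `ECO:0000244` — the code marking knowledge
derived from combined experimental and computational analysis.

Entries below protein-level existence are promoted when at least K = 2
distinct validated unique peptides support them. No number is prescribed
for K by the integration procedure; 2 follows common proteomics practice
("two-peptide rule"), is configurable, and every promotion is logged.

Peptide-level counters in the run summary count distinct normalized
peptide keys, not PSMs ("peptides passed" in curation reports means
distinct peptides); PSM-level counts are reported alongside.

## The synthetic-fixture generator

The generator exists so every stage is testable with known ground truth.
A synthetic proteome plants: pure-deletion isoforms with exact alignment
blocks, single-residue variants, 21-residue transmembrane segments,
SIGNAL/CHAIN processing pairs, and identical tryptic-boundary-compatible
cassettes copied across groups of entries to guarantee shared peptides.
Amino-acid composition follows approximate human frequencies (so tryptic
peptides average realistic lengths); sequence lengths default to 120–360
residues.

A PSM dataset plants four populations: true phosphosites (on
protein-unique, single-placement, variant-independent peptides, outside
every TM segment) with Mascot ~ U[45, 90], PEP ~ U[0, 0.005],
Ascore ~ U[20, 40]; optional TM plants with the same scores but positions
inside TM segments; decoys split between identification failures
(Mascot ~ U[10, 35], PEP ~ U[0.02, 0.2]) and localization failures
(passing identification, Ascore ~ U[5, 18.4]); and ambiguous PSMs on the
planted shared peptides, carrying no modifications. Every score is at
least 0.5 score units (0.005 for PEP) away from its threshold, so fixture
correctness cannot hinge on boundary-inclusivity semantics — those are
unit-tested separately with exact boundary values. The manifest records
every plant and the expected end-to-end summary, computed from the
planting ledger itself, never by running the pipeline — so a fixture run
is a genuine cross-check.

What the generator does *not* emulate: realistic score distributions and
their correlation structure, spectra, retention times, mass errors,
shared peptides arising from homology rather than planted cassettes,
multi-variant proteoforms, and non-tryptic contaminants. Passing the
planted-truth checks therefore demonstrates the bookkeeping — filtering,
assignment, coordinate mapping, conservation of counts — is exact; it
does not validate threshold choices against real instrument behaviour.

## Numerical and engineering choices

* Construction and outputs are deterministic: forms, peptides and
  annotations have total, documented orderings; rerunning an unchanged
  config reproduces every output byte for byte.
* All generator randomness flows through a caller-supplied seed and never
  leaks into the global RNG state.
* Degenerate inputs are defined, not accidental: an empty PSM table yields
  an all-zero summary and header-only outputs; an empty proteome is an
  error; a dataset failing the metadata checklist (missing raw-data
  location, instrument or search software) is skipped and logged unless
  explicitly allowed; malformed rows are skipped with reported reasons, or
  abort under strict mode.
* Verification scales used by the test suite: 100 random proteomes
  (≤ 20 entries, ≤ 200 residues) checked against an independent
  scan-every-form oracle; the missed-cleavage count law up to 30 cleavage
  sites; policy monotonicity on a 10 000-PSM table over 50 policy pairs;
  planted-truth recovery at 240 entries / 1200 PSMs (500 true, 500 decoy,
  200 ambiguous); 1000 random isoform alignment layouts. These sizes were
  chosen as the package's own verification conditions and are encoded in
  `tests/testthat/test-acceptance.R` and `scripts/acceptance.R`.

## Known limitations

* Multi-variant proteoforms are not enumerated (see above).
* Whether curated unicity tables key peptides with or without I/L
  equivalence is not documented upstream; both modes ship, il-equivalent
  by default.
* Sites supported only by gene-unique (not protein-unique) peptides are
  never annotated here; they are reported distinctly so a curator can
  decide.
* The PSM dialect is a fixed canonical TSV; extracting tables from PDFs
  or spreadsheets — the messy reality of published supplements — is out
  of scope by design.
* Real UniProtKB flat files / XML are not parsed; the FASTA header dialect
  plus the 6-column feature TSV are the interchange formats.
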