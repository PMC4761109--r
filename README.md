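# unicityr

Expert-curated protein knowledgebases integrate high-throughput
mass-spectrometry evidence only after stringent reprocessing: published
peptide-spectrum matches (PSMs) are re-filtered on their reported scores,
every PTM site is checked for biological plausibility, and — critically — a
peptide only counts if its protein assignment is *unambiguous*. Search
engines report parsimonious protein lists, which cannot guarantee that; the
curators' answer is a **unicity table**: an exhaustive index of every
theoretical tryptic peptide of the proteome, over every sequence form an
entry can produce (canonical sequence, splice isoforms, processed chains
and signal/propeptides, single amino-acid variants), with every possible
assignment recorded.

`unicityr` is a standalone, fully testable implementation of that
integration pipeline for anyone building or auditing a curated proteome:

* **proteome model** — gene-centric entries with one canonical sequence,
  isoforms carrying explicit alignment blocks (so isoform positions map
  deterministically onto canonical coordinates, or to *none* in
  isoform-specific regions), and validated sequence features
  (VARIANT/CHAIN/PEPTIDE/SIGNAL/PROPEP/TRANSMEM/MOD_RES);
* **in-silico digestion** — classical trypsin (no cleavage before proline)
  or `trypsin_p`, fully specific peptides with configurable missed
  cleavages and length bounds;
* **unicity table** — peptide keys (I/L-equivalent by default, because
  isoleucine and leucine are isobaric in MS) mapped to all assignments and
  classified `unique_protein` / `unique_gene` / `shared` / `absent`;
* **PSM filtering** — identification passes on Mascot score ≥ 40 **or**
  posterior error probability < 1 %; a PTM site is localized only with
  Ascore ≥ 19; missing scores are never coerced to zero;
* **site annotation** — localized sites on protein-unique peptides are
  mapped to canonical coordinates, screened by biological-relevance rules
  (a phosphosite must not lie inside a transmembrane segment), merged per
  site, and emitted with evidence code `ECO:0000244`; protein existence is
  promoted when enough distinct unique peptides support an entry;
* **synthetic fixtures** — seeded generators that plant true sites, decoys
  and ambiguous peptides with known ground truth, so the whole pipeline is
  verifiable end to end without any external download.

## Worked example

```r
library(unicityr)

fx  <- fixture_make("demo", seed = 101, n_entries = 30, n_true_sites = 15,
                    n_decoys = 10, n_ambiguous = 5, n_tm_sites = 3,
                    tm_prob = 0.5)
res <- run_pipeline(fx$paths$config, quiet = TRUE)
res$summary
#> <run summary>
#>   n_input_psms                     33
#>   n_accepted_identifications       28
#>   n_distinct_accepted_peptides     27
#>   n_validated_unique_peptides      23
#>   n_localized_sites                18
#>   n_annotated_sites                15
#>   n_isoform_sites                  0
#>   n_entries_covered                11
#>   n_entries_promoted               3
#>   rejections:
#>     identification_below_threshold   5
#>     site_not_localized               5
#>     peptide_ambiguous                4
#>     site_transmembrane               3
```

The fixture planted 15 true phosphosites, 10 decoys (5 failing
identification, 5 failing localization), 5 ambiguous PSMs on peptides
shared across genes, and 3 well-scored phosphosites inside transmembrane
segments. The run recovers exactly the 15 true sites (on 11 entries) and
rejects everything else for the right reasons; 3 entries gain
protein-level existence. The annotation table records provenance in its
header:

```
# unicityr annotations; release=synthetic-30-101
# digest=trypsin/missed<=2/len7-45
# policy=mascot>=40 OR pep<0.01; ascore>=19
accession  position  ptm_name       evidence_code  n_datasets  n_spectra  peptides
P00002     116       Phosphoserine  ECO:0000244    1           1          QDAGWQNAVPHGSAER
```

The unicity table behind that decision indexes every proteoform of the
entry — a supporting peptide is unique because *all* of its assignments
(canonical, isoform, mature chain, variant form) fall in one entry:

```r
prot <- read_feature_table(fx$paths$features,
                           read_proteome_fasta(fx$paths$fasta))
utab <- build_unicity_table(prot)
unicity_classify(utab, "QDAGWQNAVPHGSAER")
#> [1] "unique_protein"
unicity_lookup(utab, "QDAGWQNAVPHGSAER")[, c("form_id", "start", "canonical_start")]
#>   form_id              start  canonical_start
#> 1 P00002                 104              104
#> 2 P00002-2                90              104
#> 3 P00002:CHAIN:23-133     82              104
#> 4 P00002|p.L22W          104              104
```

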