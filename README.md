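# domfam

Identify and categorize plant **transcription factor (TF)**,
**transcriptional regulator (TR)** and **chromatin regulator (CR)** genes
from genome-scale protein or nucleic-acid sequences by analysing their
protein domain signatures.

Genome projects routinely need the regulatory gene complement of a newly
sequenced plant annotated. BLAST against a reference TF database finds
homologues but cannot tell apart families that share a conserved domain:
a protein carrying both the B3 and AP2 DNA-binding domains is a RAV family
member, yet BLAST-style searches happily label it B3, AP2-EREBP, or ARF.
`domfam` instead evaluates curated boolean **prediction logics** over the
set of domain accessions observed on each protein (InterPro entries plus
member-database signatures such as Pfam, PROSITE and SMART):

* a **must-have pattern** — a boolean expression over accessions, e.g. the
  ARF family's `(IPR010525|IPR011525)&IPR003340` ("one of the two
  ARF-specific domains AND the B3 DNA-binding domain"), that the protein's
  accession set must satisfy, and
* an optional **prohibited pattern** whose satisfaction vetoes the
  assignment — this splits superfamilies sharing core domains (the
  keratin-like K-box `IPR002487` excludes a MADS-box protein from the
  MADS type1 family and routes it to MADS-MICK).

A protein is assigned to every family whose must-have pattern is true and
whose prohibited pattern is false. Nucleic-acid input is first translated
in all six reading frames into stop-free segments. The package is aimed at
plant genome annotators and comparative genomicists; domain scanning
itself stays external (any scanner emitting the InterProScan 5 TSV dialect
plugs in).

## Worked example

```r
library(domfam)
library(dplyr)

ann <- tibble::tribble(
  ~protein_id, ~accession,
  "AT1G01530", "IPR002100",               # MADS box only
  "AT5G60910", "IPR002100",
  "AT5G60910", "IPR002487",               # MADS box + K-box
  "At3g25730", "IPR003340",
  "At3g25730", "IPR001471"                # B3 + AP2: the classic ambiguity
)

classify_proteins(ann, builtin_rules()) %>%
  select(sequence_id, family, category)
#> # A tibble: 3 × 3
#>   sequence_id family     category
#>   <chr>       <chr>      <chr>
#> 1 AT1G01530   MADS type1 TF
#> 2 AT5G60910   MADS-MICK  TF
#> 3 At3g25730   RAV        TF
```

The MADS-box-only protein lands in MADS type1; adding the K-box moves it
to MADS-MICK (the type1 rule's prohibited pattern fires); and the dual
B3+AP2 protein is assigned to RAV *only* — the B3 and AP2-EREBP rules veto
each other's featured domain. Every verdict can be audited:

```r
ex <- explain_rule(c("IPR002100", "IPR002487"), builtin_rules(), "MADS type1")
ex
#> # A tibble: 2 × 3
#>   clause     atom      present
#>   <chr>      <chr>     <lgl>
#> 1 must_have  IPR002100 TRUE
#> 2 prohibited IPR002487 TRUE
attr(ex, "verdict")
#> [1] "excluded_prohibited"
```

The full pipeline — FASTA in, predictions out — is `classify_batch()`
(protein or nucleotide input; six-frame translation with a 50-aa minimum
segment length by default), and `compare_assignments()` benchmarks a
prediction table against a reference as **matches / conflicts / missed /
newly predicted** gene counts. Two rule tables ship with the package: a
small curated starter table (`builtin_rules()`) and a 108-family
full-scale reconstruction (`plant108_rules_path()`, labelled synthetic —
see its header). `simulate_*()` functions generate rule tables, annotation
sets, and protein/nucleotide FASTA with planted ground truth.

## Command line

```sh
domfam classify --input genes.fasta --annotations interproscan.tsv \
    --rules builtin --out-dir results/
domfam compare --pred results/predictions.tsv --ref reference_families.tsv \
    --synonyms synonyms.tsv --out-dir bench/
domfam rules validate --rules my_rules.tsv
domfam fixtures --out-dir fx/ --n-families 10 --seed 1
```

`classify` writes `predictions.tsv`, per-family/per-category summaries
(TSV + JSON) and a run log with the rule-table checksum.

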