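---
title: "Classifying plant regulatory gene families from domain signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying plant regulatory gene families from domain signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domfam)
library(dplyr)
```

## The model

`domfam` assigns proteins to plant transcription factor (TF),
transcriptional regulator (TR) and chromatin regulator (CR) families by
set logic over domain annotations, not by sequence similarity. The unit of
evidence is the **accession set** of a protein: the union of every domain
accession reported on it by an external scanner — both integrated InterPro
entries (`IPR003340`) and member-database signatures (Pfam `PF02362`,
PROSITE `PS50097`, SMART `SM00225`). Both tiers are kept because some
families' featured domains exist only in a member database (the BTB/POZ-like
domain, for instance, has no Pfam model), so rule atoms may come from any
tier.

Each family carries a *prediction logic* with two clauses:

* **must-have pattern** — a boolean expression over accessions that the
  protein's set must satisfy. The language is
  `expr := term ('|' term)* ; term := factor ('&' factor)* ;
  factor := ACCESSION | '(' expr ')'`.
* **prohibited pattern** — an optional expression in the same language;
  if it evaluates true the family is vetoed. Prohibitions are how
  superfamilies sharing a core domain are split: the K-box excludes the
  MADS type1 family, the B3 and AP2 domains exclude each other's
  single-domain families so that a dual-domain protein reaches only RAV.

A protein is reported for *every* family whose must-have is true and
whose prohibited is false. We deliberately do not rank or collapse
multiple assignments: ambiguity is a property of the curated table, and a
residual double assignment is a curation signal that
`validate_rule_table()` surfaces (subset-overlap and orphan-prohibition
lint), not something a heuristic should hide.

Assumptions worth stating: classification is presence/absence only — hit
coordinates and scores are carried through for reporting but never
filtered on, on the grounds that the upstream scanner already applied its
own significance model; and accession comparison is case-insensitive and
version-less because user files vary in case while the identifiers
themselves are case-stable.

## Design decisions in the rule language

The published family logics are always fully parenthesized, which leaves
operator precedence open. We give `&` tighter binding than `|`
(conventional), and recommend curated tables parenthesize anyway. The
prohibited clause's grammar is likewise unspecified in the literature —
known examples are single accessions — so we let it be the full
expression language: a bare alternation `A|B` covers every published case
and costs nothing. Evaluation is total and monotone (no negation), which
gives a useful property test: if a set satisfies an expression, every
superset does.

Parse errors report 0-based character offsets; a dangling operator at the
end of input is reported at the end-of-input offset. Accession tokens are
1–4 letters followed by 4–7 digits.

## Six-frame translation

Nucleic-acid input (detected when ≥ 95% of non-gap characters are
`A/C/G/T/U/N`; a `declared_type` override is available) is translated in
all three frames of both strands with the standard genetic code. We use
stop-to-stop segments with **no initiator-codon requirement**: a domain
scan on a fragment does not need an ATG, and requiring one would silently
drop 5'-truncated models. The `min_orf_len` parameter (default **50 aa**)
removes segments too short to carry a domain; setting it to 1 scans every
translated fragment, so the single parameter exposes both plausible
behaviours of a translate-then-scan pipeline. Codons containing `N`
translate to `X`, which never terminates a segment and counts toward its
length. Frames are labelled `+1..+3 / -1..-3`; `nt_start` is the 1-based
forward-strand position of the first base of a segment's first codon (for
minus-strand segments, the position where the minus-strand codon begins —
the 3'-most base on the forward strand).

When several translated segments of one record match the same family, the
batch classifier keeps one row per (record, family): the segment with the
most satisfied must-have atoms, ties broken by smallest `nt_start`. One
gene should not inflate family counts, and this collapse is what makes
nucleotide-mode output equal protein-mode output modulo the frame field —
an invariant the tests enforce for all six frames.

## Benchmarking

`compare_assignments()` reduces a prediction table and a reference table
to per-gene family sets and buckets every gene into exactly one of
**match** (sets intersect), **conflict** (both present, disjoint),
**missed** (reference only) or **newly predicted** (prediction only), so
`matches + conflicts + missed = |reference|` by construction. A gene
counts as a match when the sets *intersect* rather than coincide: since
predictions may legitimately carry several families, requiring equality
would manufacture conflicts. Family names fold through an optional
synonym map before comparison (reference databases and rule tables rarely
share a naming scheme), and a `strip_transcript` flag removes trailing
`.N` suffixes — off by default, because silently munging identifiers is
worse than an explicit mismatch.

## What the synthetic generator emulates — and what it does not

The fixture generator exists so that every stage is testable without an
external scanner. `simulate_rule_table()` draws random expressions over a
reserved accession namespace (`ZZ#####`; noise uses `ZZN####`) that cannot
collide with real identifiers. Per-family atom pools are **disjoint**, so
a planted positive can satisfy only its own family; prohibited patterns
borrow sibling families' atoms; subset-overlap pairs can be planted
deliberately to exercise the validator. `simulate_annotations()` plants
positives (one satisfying branch of each OR), *miss* decoys (one
must-have atom removed, verified to falsify the expression) and
*prohibited* decoys (satisfying set plus atoms firing the veto), with
optional noise accessions that no rule references.
`encode_protein_to_dna()` reverse-translates with uniform synonymous-codon
choice (no codon-usage model) and stop-delimits the planted coding
stretch in the requested frame, re-verifying unique recovery.

This means a perfect score on synthetic data shows the *machinery* is
correct — parsing, evaluation, translation, attribution, scoring — not
that any curated table is biologically right. Real proteomes have
correlated domain architectures, shared domains across families,
incomplete scanner coverage and genuinely ambiguous proteins; none of
that is simulated. The package's guarantees on real data are exactly the
rule semantics, nothing more.

The generators' default study conditions, used by the acceptance script
and tests, are: 20 families of up to 6 atoms with 5 positives per family
and 3 noise accessions for recovery checks (40 decoys when decoys are
enabled); 200 random expressions of up to 6 atoms, checked against a
brute-force truth-table oracle on all `2^k` atom subsets; 100
(peptide, frame) encode/translate round trips with peptides of 10–25
residues and flanks of up to 20 nt; and 100 random prediction/reference
tables of 20–400 genes over 40 family labels for the partition identity.
These sizes exercise every code path with comfortable margins while
keeping the whole suite fast.

## Rule tables shipped

The built-in starter table (`builtin_rules()`) contains the well-worked
logics: ARF (`(IPR010525|IPR011525)&IPR003340`), the MADS pair split by
the K-box, the B3 / AP2-EREBP / RAV triangle, and the BTB/POZ split by
companion domain (MATH vs ankyrin). The scaffold entries beyond ARF and
the MADS pair are a curator's best effort and are flagged as such in the
file header.

`plant108_rules_path()` points to a full-scale, 108-family table
covering the classic plant TF/TR/CR roster (WRKY, NAC, bZIP, bHLH, GRAS,
HSF, …). It is a **synthetic reconstruction** assembled from the
published family/domain literature — accession choices for the less
common families are approximate — and is labelled accordingly; it
demonstrates full-scale loading, validation and classification rather
than reproducing any published curation.

## Degenerate inputs and numerical choices

Empty FASTA files, records with empty sequences, duplicate ids, malformed
scanner rows and duplicate family names are hard errors with file/line
context; an empty two-column domain table is a warning plus an empty
result (a scan that found nothing is data, not a defect). Records with no
annotation available classify as no-hit with one summary warning and are
counted in the prediction table's `n_unannotated` attribute. Sequences
shorter than one codon translate to nothing, with a warning. There are no
tolerances anywhere in the pipeline — every decision is exact set logic —
so determinism is byte-level: identical inputs give identical prediction
and summary files, which the CLI tests assert.

## Known limitations

* Classification quality is bounded by the curated table and by the
  upstream scanner's domain calls; the package validates table structure,
  not biology.
* Only the standard genetic code is supported (plastid/mitochondrial
  codes are out of scope), and translation is not splice-aware.
* Six-frame segments are scanned independently; a domain split across a
  stop codon (sequencing error, frameshift) will be missed.
* The benchmark comparator treats family names as opaque strings; synonym
  mapping is the user's responsibility.
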