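---
title: "Curating somatic cancer variants with the MVLD standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating somatic cancer variants with the MVLD standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvldr)
```

## The problem

Clinical interpretation of somatic cancer variants is scattered across
knowledge bases that collect similar information in incompatible shapes:
the same BRAF V600E assertion may appear with different gene spellings,
coordinate conventions, evidence language and cancer-type terminology in
each resource. Minimal Variant Level Data (MVLD) is a consensus field set
for describing *one* clinically interpreted somatic variant, organized in
three blocks:

* **Allele descriptive** — where the variant is: genome build (GRCh37/GRCh38,
  patch-level), HUGO gene symbol, chromosome, 1-based genomic position,
  RefSeq transcript(s) and protein.
* **Allele interpretive** — what the variant is: somatic classification
  ("Confirmed somatic", "Confirmed germline", "Unknown"), HGVS DNA and
  protein descriptions, variant type (SNV/MNV/INS/DEL), molecular
  consequence (a twelve-term vocabulary), supporting PMIDs.
* **Cancer interpretive** — what the variant means clinically: cancer type
  as an ontology term (NCI Thesaurus or Oncotree), biomarker class
  (Diagnostic/Prognostic/Predictive), therapeutic context (drugs), effect
  (resistant, responsive, not-responsive, sensitive, reduced sensitivity,
  or a free-text "other"), a level of evidence under a named schema, and
  sub-level evidence assertions in six categories with mandated citations.

One record is one assertion: one variant x one cancer type x one biomarker
class x one therapeutic context. A variant asserted against two drug
contexts is two records; this keeps records atomic for submission-style
exports.

`mvldr` implements the standard as a validating library: a typed record
model, a syntax-level HGVS checker, a rule engine with frozen rule ids,
CanDL tier assignment, TSV/JSON serialization, a ClinVar-style export, and
a seeded fixture generator. A thin `mvld` command-line wrapper binds the
pieces together.

## Where the rules live, and how strict they are

Validation is stratified deliberately:

* **Construction-time rejection** is reserved for hard domain violations
  that no curated record should ever carry: a genome build that is not
  GRCh37/GRCh38, a chromosome outside 1-22/X/Y/MT, a position below 1, a
  RefSeq identifier without its `NM_`/`NR_`/`NP_` prefix, an NCT id that is
  not `NCT` + 8 digits, an evidence category outside 1-6, an enumerated
  term (passed to a constructor) outside its vocabulary.
* **Validator findings** cover everything else: missing required fields
  (`REQ.*`), conditional cross-field logic (`COND.*`), vocabulary
  membership of values that arrived through files (`VOC.*`), HGVS grammar
  (`HGVS.*`), advisory consistency (`CONS.*`, always warnings) and
  evidence-citation requirements (`EVID.*`).

The split exists because the validator must be able to *observe* and
report nonconforming data: a TSV exported from a legacy system with
`biomarker_class = "Theranostic"` should produce a machine-readable finding
at a field path, not an exception that aborts the batch. Internally an
unchecked construction path carries such raw values; user-facing
constructors always check.

Two profiles differ in exactly one way: the standard *strongly suggests*
(but does not require) both DNA and protein HGVS forms for coding variants
and supporting PMIDs. Under the `submission` profile these are warnings
(`SUG.*`); under `strict` they are errors. Everything else is identical,
which gives the ordering guarantee that strict errors are a superset of
submission errors. Noncoding variants — genomic (`g.`) or noncoding-
transcript (`n.`) descriptions, or consequences in {3UTR, 5UTR, Splice,
Splice-region, Intronic, Upstream, Downstream} — may carry the DNA
description alone with no finding; the standard does not pin down the
noncoding set precisely, so this package fixes it as above and documents
it here.

Somatic classification `"Unknown"` is fully conformant: it is the
designated placeholder for submitters without matched-normal sequencing.

```{r}
r <- mvld_record(
  allele_descriptor("GRCh37", "BRAF", "chr7", 140453136,
                    transcripts = "NM_004333.6", protein_id = "NP_004324.2"),
  allele_interpretation("Confirmed somatic", dna_hgvs = "c.1799T>A",
                        protein_hgvs = "p.V600E", variant_type = "SNV",
                        variant_consequence = "Missense",
                        pmids = c(12068308, 20818844)),
  cancer_interpretation(
    cancer_type = lookup_cancer_term("MEL"),
    biomarker_class = "Predictive",
    therapeutic_context = "vemurafenib",
    effect = list(term = "sensitive", free_text = ""),
    level_of_evidence = list(schema_name = "CanDL", level_label = "Tier 1"),
    sub_level = list(evidence_assertion(1, trial_ids = "NCT01006980"))
  )
)
validate_record(r, "strict")
```

## HGVS checking is syntactic on purpose

`check_dna_hgvs()` and `check_protein_hgvs()` validate grammar only: no
transcript or genome sequence is consulted, so the package needs no
downloads and cannot tell you that `c.1799T>A` has the wrong reference
base on some transcript. The grammar subset is the substitution / del /
dup / ins / delins core common to all HGVS versions (the standard names
HGVS but not a version), plus intronic offsets (`c.88+2T>G`) and UTR
anchors (`c.*12`, `c.-14`) on transcript molecules, and protein
substitutions, frameshifts and extensions in one- or three-letter code.
Exotic constructs — inversions, alleles in cis, repeats, `=` — are rejected
with a distinct "unsupported HGVS construct" error so that callers can
distinguish "outside the subset" from "malformed".

Parsing is total (any input yields a parse or a structured error object)
and round-trips: `format_hgvs(check_dna_hgvs(s))` is the canonical form of
`s` (one-letter amino acids, no leading zeros), and re-parsing a canonical
form reproduces the parse exactly.

Variant-type inference follows the length rule on the parsed alleles: a
one-base substitution is an SNV; a pure insertion or duplication is an INS
(a duplication adds bases, which is what the four-way type vocabulary
distinguishes); a pure deletion is a DEL; everything else — multi-base
substitutions and deletion-insertions, the "deletion plus substitution"
complex case — is an MNV. Coordinates are HGVS 1-based, fully closed,
throughout.

```{r}
infer_variant_type(check_dna_hgvs("c.76_78delinsTT"))
check_dna_hgvs("c.76insA")   # structured error: insertions need a range
```

## Tiers and evidence sub-levels

The built-in level-of-evidence schema is CanDL's four tiers, each with its
verbatim structured sentence (`candl_tiers()`); the schema slot is
deliberately pluggable (`schema_name` + `level_label`) because any
well-described framework may substitute, and foreign labels are stored
verbatim and never re-tiered. `assign_tier()` returns the strongest
applicable tier:

| Tier | Trigger |
|------|---------|
| 1 | `fda_approved` or `nccn_recommended` flag |
| 2 | any category 1, 2 or 4 evidence (trials, retrospective studies, case reports / exceptional responders) |
| 3 | any category 5 evidence (preclinical) |
| 4 | `pathway_driver` flag or category 6 evidence (inferential / in silico) |

Three mapping choices were genuinely open and are fixed here: category 2
(retrospective trials/studies and metadata analysis) maps to Tier 2
because retrospective trials are trials; category 6 maps to Tier 4, the
inferential bucket, alongside the pathway-driver flag; and FDA/NCCN status
is an explicit caller-supplied flag because no computable drug-registry
linkage exists at desk scale. Expert opinion (category 3) substantiates an
assertion but carries no tier of its own, so expert-only evidence is "no
tierable evidence" rather than a guess. Adding evidence or enabling a flag
can only strengthen (never weaken) the tier; the test suite checks this
exhaustively over all 2^3 flag x 2^6 category combinations against a
brute-force minimum-applicable-tier oracle.

Citation requirements per sub-level category are findings, not
exceptions: trials need an NCT id or PMID, expert opinion needs name, date
and affiliation, case reports and preclinical data always need at least
the PMID, and in silico predictions need a PMID or the program names.

## Serialization and the table dialect

The TSV dialect is: UTF-8, tab-separated, one header row with the exact
canonical column names in block order (`mvld_columns()`), `";"` as the
list delimiter inside a cell (commas occur in drug names and tier
sentences), and an empty cell for an absent optional. Sub-level evidence
assertions are structured objects; a `";"`-joined scalar cannot carry
them, so they travel inside their cell as minified JSON. Unknown columns
are preserved into the record's `extensions` map (never validated) and
written back after the canonical columns. Writes are deterministic: the
same records give byte-identical files, and `read(write(R))` reproduces
`R` exactly in both TSV and JSON. The JSON document carries a top-level
`"mvld_version": "1.0"` because the standard is expected to evolve.

The ClinVar-style export (`to_clinvar_row()`, `write_clinvar_table()`)
renders a *conformant* record — a record with submission-profile errors is
refused, and a corpus is refused atomically before any output — into a
flat row: the condition as `"source:code (label)"`, a
clinical-significance analog assembled from biomarker class, effect and
therapeutic context, and the level of evidence in the assertion-method
field (with the verbatim tier sentence for CanDL). No dated ClinVar
template version is targeted; the layout is a documented generic mapping,
and `clinvar_row_to_record()` inverts it losslessly for the required
fields. The citations column carries the record's PMIDs plus sub-level NCT
ids; sub-level PMIDs stay inside the record so that the inverse rebuilds
the interpretive block exactly.

Cancer-type resolution (`lookup_cancer_term()`) consults a packaged,
hand-curated ~55-term subset pairing Oncotree-style short codes with
labels and NCI Thesaurus codes. It is a static fixture for offline,
desk-scale testing — not a live ontology export — and unknown gene symbols
likewise warn (against a packaged 20-gene subset) rather than error,
since verifying HUGO symbols properly requires a live HGNC service.

## The fixture generator

`generate_records(n, seed, error_spec)` is first-class, tested code: it is
the test corpus for every other module. Record `i` is drawn from a
pseudo-random sub-stream keyed by `(seed, i)`, so corpora are stable under
changes of `n` (the first ten records of a 200-record corpus equal the
ten-record corpus). Clean records sample uniformly from the valid spaces —
all twelve consequences, all four variant types (with the HGVS edit
generated to *match* the declared type), all three biomarker classes and
somatic classifications, all six effect terms (on predictive records,
which are the ones that carry a therapeutic context), all six evidence
categories with their mandated citations, and all four CanDL tiers — and a
clean corpus passes strict validation with zero errors. Violations are
injected after generation, at most one per selected record (records
chosen without replacement) so that injected faults cannot mask each
other, and logged in a manifest of (index, rule id, field path) triples.
Under the submission profile the validator's error set equals the
manifest exactly — recall and precision 1.0 — which is the package's own
end-to-end check that rules fire exactly where violations were planted.

What the generator does *not* emulate: realistic mutation spectra, linked
positions and alleles (the genomic position and the HGVS edit are drawn
independently), real drug-variant pairings, or case-level structure
(multiple variants per sample are out of the standard's scope). Passing
tests therefore demonstrate that the machinery is correct on
schema-conformant data, not that any biological claim holds on real tumor
sequencing.

## Numerical and interface choices

* Problem sizes in the checks are chosen to be exhaustive where the space
  is small (512 tier combinations; 7224 ref/alt edits up to length 3) and
  200 records for corpus-level properties, which exercises every
  vocabulary term with ample margin while running in seconds.
* Seeds: one integer seed drives everything; sub-stream seeds are derived
  as `(seed + 7919 * i) mod (2^31 - 1)` to stay within R's integer range.
* Term matching is case-insensitive with whitespace/underscore folding and
  a small declared synonym table (`"3'UTR"` and Sequence Ontology
  spellings map onto the printed `"3UTR"`/`"5UTR"` forms, which are stored
  exactly as the standard prints them); the canonical spelling is always
  what is stored and written. Chromosomes are stored without the `"chr"`
  prefix — one canonical spelling makes round-trip identity meaningful.
* Sequence Ontology accessions for the consequence vocabulary ship as an
  inert annotation table (`consequence_so_annotations()`) that no rule
  consults; drug names in the therapeutic context are free text, not
  resolved against DrugBank.
* Exit codes (`mvld` CLI): 0 = no errors, 1 = errors present or a refused
  conversion, 2 = unreadable input or bad invocation; data to stdout or
  `--output`, logging to stderr; no command mutates its input.

## Known limitations

Syntax-only HGVS checking cannot catch wrong reference alleles or
un-normalized (non-3'-shifted) descriptions; transcript projection and
normalization are out of scope. The ClinVar export approximates no
specific dated submission template. The packaged ontology and gene-symbol
subsets are deliberately small; production use would swap in fuller local
copies. Case-level data relating multiple variants in one sample, RNA and
structural variation, and outcomes data are outside the standard's current
scope and therefore outside this package's.
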