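# mvldr — Minimal Variant Level Data for somatic cancer variant curation

Clinical knowledge about somatic cancer variants is curated in many places
— institutional logs, crowd-sourced knowledge bases, ClinVar — and each
collects similar facts in a different shape. **MVLD (Minimal Variant Level
Data)** is a consensus field set that describes one clinically interpreted
somatic variant in three blocks: *allele descriptive* (genome build, HUGO
gene symbol, chromosome, position, RefSeq identifiers), *allele
interpretive* (somatic classification, HGVS DNA/protein descriptions,
variant type, molecular consequence, PMIDs) and *cancer interpretive*
(cancer type as an ontology term, biomarker class, therapeutic context,
effect, level of evidence, sub-level evidence with mandated citations).
One record is one assertion: one variant × one cancer type × one biomarker
class × one therapeutic context.

`mvldr` is for curators and pipeline authors who need to **parse,
normalize, validate, tier and export** such records:

* a typed record model with controlled vocabularies for every enumerated
  field (`vocabulary()`, `normalize_term()`, constructors that reject hard
  domain violations at construction);
* syntax-level HGVS validation for DNA (`g.`/`c.`/`n.`) and protein (`p.`)
  descriptions, with canonical serialization and variant-type inference by
  the length rule (one-base substitution → SNV, pure insertion/duplication
  → INS, pure deletion → DEL, everything else including delins → MNV);
* a rule engine (`validate_record()`) that emits machine-readable findings
  with frozen rule ids (`REQ.*`, `COND.*`, `VOC.*`, `HGVS.*`, `SUG.*`,
  `CONS.*`, `EVID.*`) under a `submission` or `strict` profile;
* CanDL four-tier level-of-evidence assignment (`assign_tier()`) with the
  verbatim tier sentences, and six-way evidence sub-level categorization;
* deterministic TSV/JSON round-trip serialization, a ClinVar-style export
  that refuses nonconformant records, and cancer-type lookup against a
  packaged Oncotree/NCI-Thesaurus subset;
* a seeded fixture generator (`generate_records()`) producing conformant
  corpora and deliberately violating corpora with an exact manifest;
* an `mvld` command line (`validate | convert | tier | fixtures`) with a
  fixed 0/1/2 exit-code contract.

## Worked example

```r
library(mvldr)

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
r
#> <mvld_record>
#>   BRAF c.1799T>A / p.V600E
#>   GRCh37 chr7:140453136
#>   SNV / Missense / Confirmed somatic
#>   Oncotree:MEL (Melanoma) | Predictive | CanDL Tier 1

validate_record(r, "strict")
#> <mvld validation report> 0 error(s), 0 warning(s)
```

The record is conformant even under the strict profile: every required
field is present, both HGVS forms are given and grammatical, all terms are
canonical, and the effect comes with its therapeutic context. Break two of
those rules and the validator reports findings (never exceptions), each
with a stable rule id and the field path it concerns:

```r
r$interpretation$dna_hgvs <- "1799T>A"        # molecule prefix lost
r$cancer$therapeutic_context <- character()   # effect left dangling
validate_record(r)
#> <mvld validation report> 2 error(s), 0 warning(s)
#>   [error] COND.EFFECT_CONTEXT at cancer.therapeutic_context - an Effect is given but the Therapeutic Context it depends on is empty
#>   [error] HGVS.DNA at interpretation.dna_hgvs - '1799T>A': missing molecule prefix (expected g., c. or n.)
```

Tier assignment returns the strongest tier whose trigger holds, with the
verbatim CanDL sentence — here preclinical-only evidence (sub-level
category 5) lands on Tier 3:

```r
assign_tier(list(evidence_assertion(5, pmids = 21639808)))
#> <CanDL Tier 3> Alteration predicts for response or resistance to therapy based on evidence from pre-clinical data (in vitro or in vivo models)
#>   (1 supporting item(s))
```

A conformant record renders into a ClinVar-submission-style row; the
condition, significance analog and assertion method come out as:

```r
row <- to_clinvar_row(r)   # with the original, conformant record
row[["condition"]]               # "Oncotree:MEL (Melanoma)"
row[["clinical_significance"]]   # "Predictive; sensitive to vemurafenib"
row[["assertion_method"]]
#> "CanDL: Tier 1 - Alteration has matching FDA approved or NCCN recommended therapy"
```

From the shell, the same machinery (after `R CMD INSTALL`, the `mvld`
script lives in the package's `exec/` directory):

```sh
mvld fixtures --n 100 --seed 1 --output corpus.tsv   # + corpus.tsv.manifest.json
mvld validate corpus.tsv --profile strict --output report.json   # exit 0
mvld convert corpus.tsv --output clinvar.tsv
```

## Documentation

The methods vignette (`vignettes/mvld-standard.Rmd`) explains the field
logic, the two validation profiles, the HGVS grammar subset, the tier
mapping choices, the table dialect, what the fixture generator does and
does not emulate, and the package's known limitations.
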