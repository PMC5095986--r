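# Shared fixtures: a fully conformant record (zero findings even under the
# strict profile) and small builders used across the test files.

make_descriptor <- function(...) {
  args <- list(genome_build = "GRCh37", gene_symbol = "BRAF",
               chromosome = "7", genomic_position = 140453136L,
               transcripts = "NM_004333.6", protein_id = "NP_004324.2")
  args[names(list(...))] <- list(...)
  do.call(allele_descriptor, args)
}

make_interpretation <- function(...) {
  args <- list(somatic_classification = "Confirmed somatic",
               dna_hgvs = "c.1799T>A", protein_hgvs = "p.V600E",
               variant_type = "SNV", variant_consequence = "Missense",
               pmids = c(12068308L, 20818844L))
  args[names(list(...))] <- list(...)
  do.call(allele_interpretation, args)
}

make_cancer <- function(...) {
  args <- list(
    cancer_type = ontology_term("Oncotree", "MEL", "Melanoma"),
    biomarker_class = "Predictive",
    therapeutic_context = "vemurafenib",
    effect = list(term = "sensitive", free_text = ""),
    level_of_evidence = list(schema_name = "CanDL", level_label = "Tier 1"),
    sub_level = list(
      evidence_assertion(1, trial_ids = "NCT01006980"),
      evidence_assertion(4, pmids = 20818844L)
    )
  )
  args[names(list(...))] <- list(...)
  do.call(cancer_interpretation, args)
}

make_record <- function(descriptor = make_descriptor(),
                        interpretation = make_interpretation(),
                        cancer = make_cancer(), ...) {
  mvld_record(descriptor, interpretation, cancer, ...)
}

error_rules <- function(report) {
  f <- report$findings
  f$rule_id[f$severity == "error"]
}

# (record index, rule id) pairs for error findings of a corpus report
error_pairs <- function(report) {
  f <- report$findings
  f <- f[f$severity == "error", , drop = FALSE]
  sort(paste(f$record, f$rule_id))
}
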