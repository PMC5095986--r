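test_that("a complete record is conformant under both profiles", {
  r <- make_record()
  for (profile in c("submission", "strict")) {
    rep <- validate_record(r, profile)
    expect_identical(rep$error_count, 0L)
    expect_identical(rep$warning_count, 0L)
    expect_identical(nrow(rep$findings), 0L)
  }
})

test_that("deleting each required field yields exactly one REQ error naming it", {
  deleters <- list(
    REQ.GENOME_BUILD = function(r) { r$descriptor$genome_build <- NA_character_; r },
    REQ.GENE_NAME = function(r) { r$descriptor$gene_symbol <- NA_character_; r },
    REQ.CHROMOSOME = function(r) { r$descriptor$chromosome <- NA_character_; r },
    REQ.DNA_POSITION = function(r) { r$descriptor$genomic_position <- NA_integer_; r },
    REQ.TRANSCRIPT = function(r) { r$descriptor$transcripts <- character(); r },
    REQ.SOMATIC_CLASS = function(r) { r$interpretation$somatic_classification <- NA_character_; r },
    REQ.VARIANT_TYPE = function(r) { r$interpretation$variant_type <- NA_character_; r },
    REQ.CONSEQUENCE = function(r) { r$interpretation$variant_consequence <- NA_character_; r },
    REQ.CANCER_TYPE = function(r) { r$cancer["cancer_type"] <- list(NULL); r },
    REQ.BIOMARKER_CLASS = function(r) { r$cancer$biomarker_class <- NA_character_; r },
    REQ.EVIDENCE_LEVEL = function(r) { r$cancer["level_of_evidence"] <- list(NULL); r }
  )
  paths <- stats::setNames(
    c("descriptor.genome_build", "descriptor.gene_symbol",
      "descriptor.chromosome", "descriptor.genomic_position",
      "descriptor.transcripts", "interpretation.somatic_classification",
      "interpretation.variant_type", "interpretation.variant_consequence",
      "cancer.cancer_type", "cancer.biomarker_class",
      "cancer.level_of_evidence"),
    names(deleters)
  )
  for (rule in names(deleters)) {
    r <- deleters[[rule]](make_record())
    rep <- validate_record(r, "submission")
    errs <- rep$findings[rep$findings$severity == "error", , drop = FALSE]
    expect_identical(nrow(errs), 1L, info = rule)
    expect_identical(errs$rule_id, rule, info = rule)
    expect_identical(errs$field_path, unname(paths[[rule]]), info = rule)
  }
})

test_that("adding optional fields never introduces a required-field error", {
  base <- mvld_record(
    make_descriptor(protein_id = NA),
    allele_interpretation("Unknown", dna_hgvs = "c.1799T>A",
                          protein_hgvs = "p.V600E",
                          variant_type = "SNV",
                          variant_consequence = "Missense"),
    cancer_interpretation(
      cancer_type = ontology_term("Oncotree", "MEL", "Melanoma"),
      biomarker_class = "Prognostic",
      level_of_evidence = list(schema_name = "CanDL", level_label = "Tier 3")
    )
  )
  expect_length(grep("^REQ\\.", error_rules(validate_record(base))), 0L)
  additions <- list(
    function(r) { r$descriptor$protein_id <- "NP_004324.2"; r },
    function(r) { r$interpretation$pmids <- 12068308L; r },
    function(r) { r$cancer$therapeutic_context <- "vemurafenib"; r },
    function(r) { r$cancer$therapeutic_context <- "vemurafenib"
                  r$cancer$effect <- list(term = "resistant", free_text = ""); r },
    function(r) { r$cancer$sub_level <- list(evidence_assertion(5, pmids = 1L)); r },
    function(r) { r$extensions <- list(curator = "x"); r }
  )
  for (add in additions) {
    rep <- validate_record(add(base), "submission")
    expect_length(grep("^REQ\\.", error_rules(rep)), 0L)
  }
})

test_that("at least one HGVS description is required, either form suffices", {
  r <- make_record(interpretation = make_interpretation(dna_hgvs = NA,
                                                        protein_hgvs = NA))
  expect_true("COND.HGVS_PRESENT" %in% error_rules(validate_record(r)))
  # protein-only coding record: conformant under submission (warning only)
  r2 <- make_record(interpretation = make_interpretation(dna_hgvs = NA))
  rep2 <- validate_record(r2, "submission")
  expect_identical(rep2$error_count, 0L)
  expect_true("SUG.BOTH_HGVS" %in% rep2$findings$rule_id)
})

test_that("noncoding variants may carry the DNA description only", {
  r <- make_record(
    descriptor = make_descriptor(protein_id = NA),
    interpretation = make_interpretation(
      dna_hgvs = "c.88+2T>G", protein_hgvs = NA,
      variant_consequence = "Intronic", variant_type = "SNV"
    ),
    cancer = make_cancer(effect = NULL, therapeutic_context = character())
  )
  rep <- validate_record(r, "strict")
  expect_identical(rep$error_count, 0L)
  expect_false("SUG.BOTH_HGVS" %in% rep$findings$rule_id)
})

test_that("an effect is conditional on a non-empty therapeutic context", {
  r <- make_record(cancer = make_cancer(therapeutic_context = character(),
                                        effect = list(term = "sensitive")))
  expect_true("COND.EFFECT_CONTEXT" %in% error_rules(validate_record(r)))
  # and the free text is tied to the 'other' escape, both directions
  r2 <- make_record(cancer = make_cancer(effect = list(term = "other",
                                                       free_text = "")))
  expect_true("COND.EFFECT_OTHER_TEXT" %in% error_rules(validate_record(r2)))
  r3 <- make_record(cancer = make_cancer(
    effect = list(term = "sensitive", free_text = "unexpected note")))
  expect_true("COND.EFFECT_OTHER_TEXT" %in% error_rules(validate_record(r3)))
  r4 <- make_record(cancer = make_cancer(
    effect = list(term = "other", free_text = "partial response only")))
  expect_false("COND.EFFECT_OTHER_TEXT" %in% error_rules(validate_record(r4)))
})

test_that("a CanDL level label must be one of the four tiers", {
  r <- make_record(cancer = make_cancer(
    level_of_evidence = list(schema_name = "CanDL", level_label = "Tier 9")))
  expect_true("COND.CANDL_LABEL" %in% error_rules(validate_record(r)))
  # a foreign schema's labels are stored verbatim and never re-tiered
  r2 <- make_record(cancer = make_cancer(
    level_of_evidence = list(schema_name = "AMP-2017", level_label = "Level A")))
  expect_identical(validate_record(r2)$error_count, 0L)
})

test_that("somatic classification 'Unknown' is fully conformant", {
  r <- make_record(interpretation = make_interpretation(
    somatic_classification = "Unknown"))
  expect_identical(validate_record(r, "strict")$error_count, 0L)
})

test_that("HGVS grammar violations surface as findings, not exceptions", {
  r <- make_record()
  r$interpretation$dna_hgvs <- "1799T>A"
  r$interpretation$protein_hgvs <- "p.600E"
  rep <- validate_record(r)
  expect_setequal(error_rules(rep), c("HGVS.DNA", "HGVS.PROTEIN"))
})

test_that("unknown gene symbols warn but never error", {
  r <- make_record(descriptor = make_descriptor(gene_symbol = "NOTAGENE1"))
  rep <- validate_record(r, "strict")
  expect_identical(rep$error_count, 0L)
  expect_true("WARN.GENE_SYMBOL" %in% rep$findings$rule_id)
})

test_that("strict errors are a superset of submission errors", {
  gen <- generate_records(30, seed = 11, error_spec = list(
    REQ.GENE_NAME = 2, HGVS.DNA = 2, COND.EFFECT_CONTEXT = 1,
    VOC.CONSEQUENCE = 1, EVID.PMID_REQUIRED = 1
  ))
  for (r in gen$records) {
    sub <- validate_record(r, "submission")$findings
    str <- validate_record(r, "strict")$findings
    sub_err <- paste(sub$rule_id, sub$field_path)[sub$severity == "error"]
    str_err <- paste(str$rule_id, str$field_path)[str$severity == "error"]
    expect_true(all(sub_err %in% str_err))
  }
})

test_that("identical records produce byte-identical reports", {
  r <- make_record(cancer = make_cancer(therapeutic_context = character(),
                                        effect = list(term = "sensitive")))
  j1 <- report_to_json(validate_record(r, "strict"))
  j2 <- report_to_json(validate_record(r, "strict"))
  expect_identical(j1, j2)
})

test_that("cross-field consistency mismatches warn", {
  r <- make_record(interpretation = make_interpretation(variant_type = "DEL"))
  f <- check_consistency(r)       # dna says SNV, declared DEL
  expect_identical(f$rule_id, "CONS.TYPE_MISMATCH")
  expect_identical(unique(f$severity), "warning")
  expect_identical(nrow(check_consistency(make_record())), 0L)

  r2 <- make_record(interpretation = make_interpretation(
    variant_consequence = "Intronic"))
  expect_true("CONS.INTRONIC_PROTEIN" %in% check_consistency(r2)$rule_id)

  r3 <- make_record(interpretation = make_interpretation(
    variant_consequence = "Frame shift"))
  expect_true("CONS.FRAMESHIFT_SNV" %in% check_consistency(r3)$rule_id)
  # consistency findings are part of the full report, as warnings
  rep <- validate_record(r3, "strict")
  expect_identical(rep$error_count, 0L)
  expect_true("CONS.FRAMESHIFT_SNV" %in% rep$findings$rule_id)
})

test_that("each evidence category mandates its citations", {
  cases <- list(
    list(evidence_assertion(1), "EVID.TRIAL_OR_PMID_REQUIRED"),
    list(evidence_assertion(1, trial_ids = "NCT01234567"), NA),
    list(evidence_assertion(2), "EVID.TRIAL_OR_PMID_REQUIRED"),
    list(evidence_assertion(2, pmids = 123L), NA),
    list(evidence_assertion(3), "EVID.EXPERT_REQUIRED"),
    list(evidence_assertion(3, expert = c(name = "A. Expert",
                                          date = "2016-05-01",
                                          affiliation = "Tumor Board")), NA),
    list(evidence_assertion(4), "EVID.PMID_REQUIRED"),
    list(evidence_assertion(4, pmids = 26479923L), NA),
    list(evidence_assertion(5), "EVID.PMID_REQUIRED"),
    list(evidence_assertion(5, pmids = 26479923L), NA),
    list(evidence_assertion(6), "EVID.PMID_OR_TOOL_REQUIRED"),
    list(evidence_assertion(6, tools = "PolyPhen"), NA),
    list(evidence_assertion(6, pmids = 1L), NA)
  )
  for (case in cases) {
    f <- check_evidence_citations(case[[1]])
    if (is.na(case[[2]])) {
      expect_identical(nrow(f), 0L, info = case[[1]]$category)
    } else {
      expect_identical(f$rule_id, case[[2]], info = case[[1]]$category)
    }
  }
  # findings carry the sub-level position when validated inside a record
  r <- make_record(cancer = make_cancer(sub_level = list(
    evidence_assertion(1, trial_ids = "NCT01234567"),
    evidence_assertion(4)
  )))
  rep <- validate_record(r)
  f <- rep$findings[rep$findings$rule_id == "EVID.PMID_REQUIRED", ]
  expect_identical(f$field_path, "cancer.sub_level[2].pmids")
})

test_that("the rule registry is frozen and findings reference it", {
  rules <- mvld_rules()
  expect_false(anyDuplicated(rules$rule_id) > 0)
  gen <- generate_records(25, seed = 5, error_spec = list(
    REQ.CHROMOSOME = 1, VOC.EFFECT = 1, HGVS.PROTEIN = 1
  ))
  rep <- validate_records(gen$records, "strict")
  expect_true(all(rep$findings$rule_id %in% rules$rule_id))
  expect_identical(rep$error_count,
                   sum(rep$findings$severity == "error"))
  expect_identical(rep$warning_count,
                   sum(rep$findings$severity == "warning"))
})
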