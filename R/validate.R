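# Rule engine for MVLD required / optional / conditional field logic.
#
# Every problem is a finding (severity error or warning) with a frozen rule
# id and a dotted field path; validation itself never throws. The rule ids
# form a published registry (see mvld_rules()) so that fixture manifests and
# downstream tooling can reference them.

.mvld_env <- new.env(parent = emptyenv())

.required_fields <- data.frame(
  rule_id = c(
    "REQ.GENOME_BUILD", "REQ.GENE_NAME", "REQ.CHROMOSOME",
    "REQ.DNA_POSITION", "REQ.TRANSCRIPT", "REQ.SOMATIC_CLASS",
    "REQ.VARIANT_TYPE", "REQ.CONSEQUENCE", "REQ.CANCER_TYPE",
    "REQ.BIOMARKER_CLASS", "REQ.EVIDENCE_LEVEL"
  ),
  field_path = c(
    "descriptor.genome_build", "descriptor.gene_symbol",
    "descriptor.chromosome", "descriptor.genomic_position",
    "descriptor.transcripts", "interpretation.somatic_classification",
    "interpretation.variant_type", "interpretation.variant_consequence",
    "cancer.cancer_type", "cancer.biomarker_class",
    "cancer.level_of_evidence"
  ),
  label = c(
    "Genome Build", "Gene Name", "Chromosome", "DNA Position",
    "RefSeq Transcript", "Somatic Classification", "Variant Type",
    "Variant Consequence", "Cancer Type", "Biomarker Class",
    "Level of Evidence"
  ),
  stringsAsFactors = FALSE
)

#' Registry of validation rules
#'
#' Every finding a validator can emit carries one of these frozen rule ids.
#' `REQ.*` rules cover the required MVLD fields, `COND.*` the conditional
#' cross-field logic, `VOC.*` controlled-vocabulary membership, `HGVS.*` the
#' HGVS grammar, `SUG.*` the strongly-suggested items (warnings under the
#' `submission` profile, errors under `strict`), `CONS.*` cross-field
#' consistency (always warnings), `EVID.*` the per-category citation
#' requirements of sub-level evidence, and `IO.*` table-reading issues.
#' Rules marked `injectable` can be requested from the fixture generator
#' ([generate_records()]).
#'
#' @return A data.frame with columns `rule_id`, `severity` (under the
#'   submission profile), `severity_strict`, `injectable`, `description`.
#' @export
mvld_rules <- function() {
  req <- data.frame(
    rule_id = .required_fields$rule_id,
    severity = "error", severity_strict = "error", injectable = TRUE,
    description = paste0("required field ", .required_fields$label,
                         " (", .required_fields$field_path, ") is missing"),
    stringsAsFactors = FALSE
  )
  oth <- data.frame(
    rule_id = c(
      "COND.HGVS_PRESENT", "COND.EFFECT_CONTEXT", "COND.EFFECT_OTHER_TEXT",
      "COND.CANDL_LABEL",
      "VOC.SOMATIC_CLASS", "VOC.VARIANT_TYPE", "VOC.CONSEQUENCE",
      "VOC.BIOMARKER_CLASS", "VOC.EFFECT",
      "HGVS.DNA", "HGVS.PROTEIN",
      "SUG.BOTH_HGVS", "SUG.PMIDS",
      "WARN.GENE_SYMBOL",
      "CONS.TYPE_MISMATCH", "CONS.FRAMESHIFT_SNV", "CONS.INTRONIC_PROTEIN",
      "EVID.TRIAL_OR_PMID_REQUIRED", "EVID.EXPERT_REQUIRED",
      "EVID.PMID_REQUIRED", "EVID.PMID_OR_TOOL_REQUIRED",
      "IO.UNKNOWN_COLUMN", "IO.ROW_SKIPPED"
    ),
    severity = c(
      rep("error", 4L), rep("error", 5L), rep("error", 2L),
      rep("warning", 2L), "warning", rep("warning", 3L),
      rep("error", 4L), "warning", "error"
    ),
    severity_strict = c(
      rep("error", 4L), rep("error", 5L), rep("error", 2L),
      rep("error", 2L), "warning", rep("warning", 3L),
      rep("error", 4L), "warning", "error"
    ),
    injectable = c(
      rep(TRUE, 4L), rep(TRUE, 5L), rep(TRUE, 2L),
      rep(FALSE, 2L), FALSE, rep(FALSE, 3L),
      rep(TRUE, 4L), FALSE, FALSE
    ),
    description = c(
      "at least one of the DNA and protein HGVS descriptions is required",
      "an Effect is only meaningful with a non-empty Therapeutic Context",
      "the effect free text is used exactly when the effect term is 'other'",
      "a CanDL level label must be one of Tier 1..Tier 4",
      "somatic classification outside the controlled vocabulary",
      "variant type outside the controlled vocabulary",
      "variant consequence outside the controlled vocabulary",
      "biomarker class outside the controlled vocabulary",
      "effect term outside the controlled vocabulary",
      "DNA HGVS description violates the grammar",
      "protein HGVS description violates the grammar",
      "both DNA and protein HGVS are strongly suggested for coding variants",
      "supporting PubMed IDs are strongly suggested",
      "gene symbol not found in the packaged HUGO symbol subset",
      "declared variant type disagrees with the type inferred from the DNA HGVS",
      "a 'Frame shift' consequence is inconsistent with an SNV",
      "an 'Intronic' consequence is inconsistent with a protein change",
      "trial/study evidence (categories 1-2) requires an NCT id or a PMID",
      "expert opinion (category 3) requires the expert's name, date and affiliation",
      "case reports and preclinical data (categories 4-5) require at least one PMID",
      "inferential/in-silico evidence (category 6) requires a PMID or a program name",
      "unknown input column preserved into record extensions",
      "row could not be structurally constructed and was skipped"
    ),
    stringsAsFactors = FALSE
  )
  rbind(req, oth)
}

.empty_findings <- function() {
  data.frame(severity = character(), rule_id = character(),
             field_path = character(), message = character(),
             record = integer(), stringsAsFactors = FALSE)
}

.finding <- function(severity, rule_id, field_path, message,
                     record = NA_integer_) {
  data.frame(severity = severity, rule_id = rule_id,
             field_path = field_path, message = message,
             record = as.integer(record), stringsAsFactors = FALSE)
}

#' Bundle findings into a validation report
#'
#' @param findings A data.frame of findings as produced by
#'   [validate_record()] helpers, with columns `severity`, `rule_id`,
#'   `field_path`, `message`, `record`.
#' @return An object of class `mvld_validation_report` with the ordered
#'   findings and their tallies (`error_count`, `warning_count`). A report
#'   with zero findings means the input is conformant.
#' @export
validation_report <- function(findings = .empty_findings()) {
  rownames(findings) <- NULL
  structure(
    list(
      findings = findings,
      error_count = sum(findings$severity == "error"),
      warning_count = sum(findings$severity == "warning")
    ),
    class = "mvld_validation_report"
  )
}

#' @export
print.mvld_validation_report <- function(x, ...) {
  cat("<mvld validation report> ", x$error_count, " error(s), ",
      x$warning_count, " warning(s)\n", sep = "")
  if (nrow(x$findings)) {
    f <- x$findings
    where <- ifelse(is.na(f$record), f$field_path,
                    paste0("record ", f$record, ": ", f$field_path))
    cat(paste0("  [", f$severity, "] ", f$rule_id, " at ", where, " - ",
               f$message, collapse = "\n"), "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.mvld_validation_report <- function(x, ...) x$findings

#' Serialize a validation report as JSON
#'
#' Deterministic: identical reports serialize to byte-identical JSON.
#'
#' @param report An `mvld_validation_report`.
#' @return A JSON string with the findings array and the two counts.
#' @export
report_to_json <- function(report) {
  stopifnot(inherits(report, "mvld_validation_report"))
  f <- report$findings
  items <- lapply(seq_len(nrow(f)), function(i) {
    it <- list(severity = f$severity[[i]], rule_id = f$rule_id[[i]],
               field_path = f$field_path[[i]], message = f$message[[i]])
    if (!is.na(f$record[[i]])) it$record <- f$record[[i]]
    it
  })
  as.character(jsonlite::toJSON(
    list(error_count = report$error_count,
         warning_count = report$warning_count,
         findings = items),
    auto_unbox = TRUE, digits = NA
  ))
}

.hugo_symbols <- function() {
  if (is.null(.mvld_env$hugo)) {
    path <- system.file("extdata", "hugo_symbols.tsv", package = "mvldr",
                        mustWork = TRUE)
    .mvld_env$hugo <- utils::read.delim(path, stringsAsFactors = FALSE,
                                        colClasses = "character")
  }
  .mvld_env$hugo
}

# Noncoding variants are exempt from the both-HGVS suggestion: a genomic or
# noncoding-transcript description, or a consequence outside the coding
# sequence.
.noncoding_consequences <- c("3UTR", "5UTR", "Splice", "Splice-region",
                             "Intronic", "Upstream", "Downstream")

.is_noncoding <- function(record) {
  cons <- record$interpretation$variant_consequence
  if (!.is_absent(cons) && cons %in% .noncoding_consequences) return(TRUE)
  dna <- record$interpretation$dna_hgvs
  if (!.is_absent(dna)) {
    p <- check_dna_hgvs(dna)
    if (!is_hgvs_error(p) && p$molecule %in% c("g", "n")) return(TRUE)
  }
  FALSE
}

.get_field <- function(record, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  record[[parts[[1L]]]][[parts[[2L]]]]
}

#' Validate one MVLD record against the standard's field logic
#'
#' Applies, in order: the required-field rules (all allele descriptive
#' fields; somatic classification; variant type; variant consequence; cancer
#' type; biomarker class; level of evidence), the conditional rules (at
#' least one of the DNA/protein HGVS descriptions; RefSeq transcripts may be
#' empty only for genomic descriptions; an effect requires a therapeutic
#' context; an `"other"` effect requires its free text), the
#' controlled-vocabulary rules, the HGVS grammar rules, the
#' strongly-suggested items, the cross-field consistency checks
#' ([check_consistency()]) and the evidence-citation rules
#' ([check_evidence_citations()]) for every sub-level assertion.
#'
#' Under the `submission` profile the strongly-suggested items (both HGVS
#' forms for coding variants; supporting PMIDs) are warnings; the `strict`
#' profile upgrades them to errors. Noncoding variants may carry the DNA
#' description only without any finding. All problems are findings; this
#' function never throws on a structurally constructed record.
#'
#' @param record An [mvld_record()].
#' @param profile `"submission"` (default) or `"strict"`.
#' @return An `mvld_validation_report`; zero findings means conformant.
#' @examples
#' r <- mvld_record(
#'   allele_descriptor("GRCh37", "BRAF", "7", 140453136, "NM_004333.4"),
#'   allele_interpretation("Confirmed somatic", "c.1799T>A", "p.V600E",
#'                         "SNV", "Missense", pmids = 12068308),
#'   cancer_interpretation(ontology_term("Oncotree", "MEL", "Melanoma"),
#'                         "Predictive", "vemurafenib",
#'                         effect = list(term = "sensitive", free_text = ""),
#'                         level_of_evidence = list(schema_name = "CanDL",
#'                                                  level_label = "Tier 1"))
#' )
#' validate_record(r, "strict")
#' @export
validate_record <- function(record, profile = c("submission", "strict")) {
  stopifnot(inherits(record, "mvld_record"))
  profile <- match.arg(profile)
  out <- list()
  add <- function(severity, rule_id, field_path, message) {
    out[[length(out) + 1L]] <<- .finding(severity, rule_id, field_path, message)
  }
  d <- record$descriptor; i <- record$interpretation; k <- record$cancer

  # required fields -------------------------------------------------------
  dna_parse <- if (!.is_absent(i$dna_hgvs)) check_dna_hgvs(i$dna_hgvs) else NULL
  dna_is_genomic <- !is.null(dna_parse) && !is_hgvs_error(dna_parse) &&
    dna_parse$molecule == "g"
  for (r in seq_len(nrow(.required_fields))) {
    rule <- .required_fields$rule_id[[r]]
    path <- .required_fields$field_path[[r]]
    if (rule == "REQ.TRANSCRIPT" && dna_is_genomic) next
    val <- .get_field(record, path)
    if (.is_absent(val)) {
      add("error", rule, path,
          paste0("required field ", .required_fields$label[[r]], " is missing"))
    }
  }

  # conditional rules -----------------------------------------------------
  if (.is_absent(i$dna_hgvs) && .is_absent(i$protein_hgvs)) {
    add("error", "COND.HGVS_PRESENT", "interpretation.dna_hgvs",
        "at least one of the DNA and protein HGVS descriptions is required")
  }
  if (!is.null(k$effect) && length(k$therapeutic_context) == 0L) {
    add("error", "COND.EFFECT_CONTEXT", "cancer.therapeutic_context",
        "an Effect is given but the Therapeutic Context it depends on is empty")
  }
  if (!is.null(k$effect)) {
    term <- k$effect$term; ft <- k$effect$free_text
    has_text <- !.is_absent(ft)
    if (identical(term, "other") && !has_text) {
      add("error", "COND.EFFECT_OTHER_TEXT", "cancer.effect.free_text",
          "effect term 'other' requires a free-text description")
    } else if (!identical(term, "other") && has_text) {
      add("error", "COND.EFFECT_OTHER_TEXT", "cancer.effect.free_text",
          "effect free text is only used with the term 'other'")
    }
  }
  if (!is.null(k$level_of_evidence) &&
      identical(k$level_of_evidence$schema_name, "CanDL") &&
      !k$level_of_evidence$level_label %in% paste("Tier", 1:4)) {
    add("error", "COND.CANDL_LABEL", "cancer.level_of_evidence.level_label",
        paste0("'", k$level_of_evidence$level_label,
               "' is not a CanDL tier (Tier 1..Tier 4)"))
  }

  # controlled vocabularies ------------------------------------------------
  voc <- list(
    c("VOC.SOMATIC_CLASS", "interpretation.somatic_classification",
      "somatic_classification"),
    c("VOC.VARIANT_TYPE", "interpretation.variant_type", "variant_type"),
    c("VOC.CONSEQUENCE", "interpretation.variant_consequence",
      "variant_consequence"),
    c("VOC.BIOMARKER_CLASS", "cancer.biomarker_class", "biomarker_class")
  )
  for (v in voc) {
    val <- .get_field(record, v[[2L]])
    if (!.is_absent(val) && !val %in% vocabulary(v[[3L]])) {
      add("error", v[[1L]], v[[2L]],
          paste0("'", val, "' is not in the ", v[[3L]], " vocabulary"))
    }
  }
  if (!is.null(k$effect) && !k$effect$term %in% vocabulary("effect")) {
    add("error", "VOC.EFFECT", "cancer.effect.term",
        paste0("'", k$effect$term, "' is not in the effect vocabulary"))
  }

  # HGVS grammar ------------------------------------------------------------
  if (!is.null(dna_parse) && is_hgvs_error(dna_parse)) {
    add("error", "HGVS.DNA", "interpretation.dna_hgvs",
        paste0("'", i$dna_hgvs, "': ", dna_parse$message))
  }
  if (!.is_absent(i$protein_hgvs)) {
    pp <- check_protein_hgvs(i$protein_hgvs)
    if (is_hgvs_error(pp)) {
      add("error", "HGVS.PROTEIN", "interpretation.protein_hgvs",
          paste0("'", i$protein_hgvs, "': ", pp$message))
    }
  }

  # strongly suggested items ------------------------------------------------
  sug_sev <- if (profile == "strict") "error" else "warning"
  n_hgvs <- (!.is_absent(i$dna_hgvs)) + (!.is_absent(i$protein_hgvs))
  if (n_hgvs == 1L && !.is_noncoding(record)) {
    add(sug_sev, "SUG.BOTH_HGVS", "interpretation.protein_hgvs",
        "both DNA and protein HGVS are strongly suggested for coding variants")
  }
  if (length(i$pmids) == 0L) {
    add(sug_sev, "SUG.PMIDS", "interpretation.pmids",
        "supporting PubMed IDs are strongly suggested")
  }

  # packaged HUGO symbol subset (advisory) -----------------------------------
  if (!.is_absent(d$gene_symbol) &&
      !d$gene_symbol %in% .hugo_symbols()$symbol) {
    add("warning", "WARN.GENE_SYMBOL", "descriptor.gene_symbol",
        paste0("'", d$gene_symbol,
               "' is not in the packaged HUGO symbol subset"))
  }

  # cross-field consistency + evidence citations ----------------------------
  cons <- check_consistency(record)
  evid <- .empty_findings()
  if (length(k$sub_level)) {
    evid <- do.call(rbind, c(
      lapply(seq_along(k$sub_level), function(j) {
        f <- check_evidence_citations(k$sub_level[[j]])
        if (nrow(f)) f$field_path <- sub("^assertion",
                                         sprintf("cancer.sub_level[%d]", j),
                                         f$field_path)
        f
      }),
      list(.empty_findings())
    ))
  }

  findings <- do.call(rbind, c(out, list(cons, evid, .empty_findings())))
  validation_report(findings)
}

#' Cross-field consistency checks
#'
#' Sanity checks beyond the letter of the standard, always emitted as
#' warnings (curated legacy data may legitimately disagree): the declared
#' variant type versus the type inferred from the DNA HGVS description; a
#' `"Frame shift"` consequence on an SNV; an `"Intronic"` consequence
#' alongside a protein change.
#'
#' @param record An [mvld_record()].
#' @return A data.frame of warning findings (possibly empty).
#' @export
check_consistency <- function(record) {
  stopifnot(inherits(record, "mvld_record"))
  i <- record$interpretation
  out <- list(.empty_findings())
  if (!.is_absent(i$dna_hgvs) && !.is_absent(i$variant_type) &&
      i$variant_type %in% vocabulary("variant_type")) {
    p <- check_dna_hgvs(i$dna_hgvs)
    if (!is_hgvs_error(p)) {
      inferred <- infer_variant_type(p)
      if (inferred != i$variant_type) {
        out[[length(out) + 1L]] <- .finding(
          "warning", "CONS.TYPE_MISMATCH", "interpretation.variant_type",
          paste0("declared ", i$variant_type, " but '", i$dna_hgvs,
                 "' implies ", inferred))
      }
    }
  }
  if (identical(i$variant_consequence, "Frame shift") &&
      identical(i$variant_type, "SNV")) {
    out[[length(out) + 1L]] <- .finding(
      "warning", "CONS.FRAMESHIFT_SNV", "interpretation.variant_consequence",
      "a frame shift cannot arise from an equal-length single-base change")
  }
  if (identical(i$variant_consequence, "Intronic") &&
      !.is_absent(i$protein_hgvs)) {
    out[[length(out) + 1L]] <- .finding(
      "warning", "CONS.INTRONIC_PROTEIN",
      "interpretation.variant_consequence",
      "an intronic variant should not carry a protein change")
  }
  do.call(rbind, out)
}

#' Citation requirements for one sub-level evidence assertion
#'
#' Each evidence category mandates its citations: prospective and
#' retrospective trials/studies (categories 1-2) need a clinical-trial
#' number or a PMID; expert opinion (category 3) needs the expert's name,
#' date and affiliation; case reports and published preclinical data
#' (categories 4-5) always need at least the PMID; inferential data or in
#' silico predictions (category 6) need a PMID or the names of the programs
#' used.
#'
#' @param assertion An [evidence_assertion()].
#' @return A data.frame of error findings (possibly empty); never throws.
#' @examples
#' nrow(check_evidence_citations(evidence_assertion(4)))        # missing PMID
#' nrow(check_evidence_citations(evidence_assertion(4, pmids = 123)))
#' @export
check_evidence_citations <- function(assertion) {
  stopifnot(inherits(assertion, "mvld_evidence_assertion"))
  cat <- assertion$category
  path <- function(f) paste0("assertion.", f)
  if (cat %in% c(1L, 2L)) {
    if (length(assertion$trial_ids) == 0L && length(assertion$pmids) == 0L) {
      return(.finding("error", "EVID.TRIAL_OR_PMID_REQUIRED",
                      path("trial_ids"),
                      paste0("category ", cat,
                             " (trials/studies) requires an NCT id or a PMID")))
    }
  } else if (cat == 3L) {
    ok <- !is.null(assertion$expert) &&
      all(!vapply(assertion$expert[c("name", "date", "affiliation")],
                  .is_absent, logical(1)))
    if (!ok) {
      return(.finding("error", "EVID.EXPERT_REQUIRED", path("expert"),
                      "expert opinion requires the expert's name, date and affiliation"))
    }
  } else if (cat %in% c(4L, 5L)) {
    if (length(assertion$pmids) == 0L) {
      return(.finding("error", "EVID.PMID_REQUIRED", path("pmids"),
                      paste0("category ", cat,
                             " (case reports/preclinical data) requires at least one PMID")))
    }
  } else if (cat == 6L) {
    if (length(assertion$pmids) == 0L && length(assertion$tools) == 0L) {
      return(.finding("error", "EVID.PMID_OR_TOOL_REQUIRED", path("pmids"),
                      "inferential/in-silico evidence requires a PMID or a program name"))
    }
  }
  .empty_findings()
}

#' Validate a corpus of records
#'
#' Runs [validate_record()] on every record and aggregates the findings,
#' tagging each with its 1-based record index.
#'
#' @param records List of [mvld_record()] objects.
#' @inheritParams validate_record
#' @return An `mvld_validation_report` whose findings carry a `record`
#'   column.
#' @export
validate_records <- function(records, profile = c("submission", "strict")) {
  profile <- match.arg(profile)
  parts <- lapply(seq_along(records), function(n) {
    f <- validate_record(records[[n]], profile)$findings
    if (nrow(f)) f$record <- n
    f
  })
  validation_report(do.call(rbind, c(parts, list(.empty_findings()))))
}
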