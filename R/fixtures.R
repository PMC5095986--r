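# Seeded generator of conformant and deliberately violating MVLD records.
#
# Record i is generated from a sub-stream keyed by (seed, i), so a corpus is
# stable under changes of n: the first 10 records of generate_records(200, s)
# equal generate_records(10, s). Violations are injected after clean
# generation, one per selected record, and logged in a manifest of
# (record index, rule id, field path) triples so that validator output can
# be compared against ground truth exactly.

.fixture_drugs <- c(
  "vemurafenib", "dabrafenib", "trametinib", "erlotinib", "gefitinib",
  "osimertinib", "imatinib", "crizotinib", "alectinib", "trastuzumab",
  "cetuximab", "panitumumab", "olaparib", "ruxolitinib", "sunitinib"
)

.fixture_tools <- c("PolyPhen-2", "SIFT", "MutationTaster", "CADD")

.fixture_experts <- c("A. Reviewer", "B. Oncologist", "C. Pathologist",
                      "D. Geneticist")

.fixture_affiliations <- c(
  "Example Cancer Center", "University Hospital Tumor Board",
  "Institute of Molecular Pathology"
)

.rand_bases <- function(len, exclude = NULL) {
  pool <- c("A", "C", "G", "T")
  out <- paste(sample(pool, len, replace = TRUE), collapse = "")
  while (!is.null(exclude) && identical(out, exclude)) {
    out <- paste(sample(pool, len, replace = TRUE), collapse = "")
  }
  out
}

.rand_assertion <- function(category) {
  switch(as.character(category),
    "1" = , "2" = evidence_assertion(
      category, trial_ids = sprintf("NCT%08d", sample.int(99999999L, 1L))),
    "3" = evidence_assertion(
      category,
      expert = list(name = sample(.fixture_experts, 1L),
                    date = sprintf("2016-%02d-%02d", sample.int(12L, 1L),
                                   sample.int(28L, 1L)),
                    affiliation = sample(.fixture_affiliations, 1L))),
    "4" = , "5" = evidence_assertion(
      category, pmids = sample.int(99999999L, sample(1:2, 1L))),
    "6" = evidence_assertion(category, tools = sample(.fixture_tools, 1L))
  )
}

.gen_clean_record <- function(seed, i) {
  set.seed(as.integer((as.numeric(seed) + 7919 * i) %% 2147483647))
  genes <- .hugo_symbols()
  grow <- genes[sample.int(nrow(genes), 1L), ]
  cons <- sample(vocabulary("variant_consequence"), 1L)
  noncoding <- cons %in% .noncoding_consequences
  start <- sample.int(5000L, 1L)

  if (cons %in% c("Intronic", "Splice", "Splice-region")) {
    # intron-adjacent position with an offset; a single-base change
    vt <- "SNV"
    ref <- .rand_bases(1L)
    alt <- .rand_bases(1L, exclude = ref)
    sign <- sample(c("+", "-"), 1L)
    dna <- paste0("c.", start, sign, sample.int(20L, 1L), ref, ">", alt)
  } else {
    vt <- switch(cons,
      "Nonsense" = , "Missense" = , "Silent" = sample(c("SNV", "SNV", "MNV"), 1L),
      "Frame shift" = sample(c("INS", "DEL"), 1L),
      "In-frame" = sample(c("INS", "DEL", "MNV"), 1L),
      sample(vocabulary("variant_type"), 1L)
    )
    alleles <- switch(vt,
      SNV = {
        r <- .rand_bases(1L)
        list(r, .rand_bases(1L, exclude = r))
      },
      MNV = list(.rand_bases(sample(2:3, 1L)), .rand_bases(sample(1:3, 1L))),
      INS = list("", .rand_bases(sample(1:3, 1L))),
      DEL = list(.rand_bases(sample(1:3, 1L)), "")
    )
    dna <- hgvs_from_alleles(alleles[[1L]], alleles[[2L]], start)
  }

  aa <- names(.aa3_to_1)[1:20]
  prot <- if (noncoding) NA_character_ else {
    pos <- sample.int(900L, 1L)
    if (cons == "Frame shift") {
      paste0("p.", .aa3_to_1[[sample(aa, 1L)]], pos, "fs")
    } else if (cons == "Nonsense") {
      paste0("p.", .aa3_to_1[[sample(aa, 1L)]], pos, "*")
    } else {
      a1 <- .aa3_to_1[[sample(aa, 1L)]]
      a2 <- .aa3_to_1[[sample(aa, 1L)]]
      paste0("p.", a1, pos, a2)
    }
  }

  descriptor <- allele_descriptor(
    genome_build = sample(c("GRCh37", "GRCh38"), 1L),
    gene_symbol = grow$symbol,
    chromosome = grow$chromosome,
    genomic_position = sample.int(200000000L, 1L),
    transcripts = grow$transcript,
    protein_id = if (noncoding) NA else grow$protein
  )
  interpretation <- allele_interpretation(
    somatic_classification = sample(vocabulary("somatic_classification"), 1L),
    dna_hgvs = dna, protein_hgvs = prot,
    variant_type = vt, variant_consequence = cons,
    pmids = sample.int(99999999L, sample(1:2, 1L))
  )

  terms <- .cancer_table()
  trow <- terms[sample.int(nrow(terms), 1L), ]
  biomarker <- sample(vocabulary("biomarker_class"), 1L)
  context <- character()
  effect <- NULL
  if (biomarker == "Predictive") {
    context <- sample(.fixture_drugs, sample(1:2, 1L))
    term <- sample(vocabulary("effect"), 1L)
    effect <- list(
      term = term,
      free_text = if (term == "other") "direction not covered by the five standard descriptors" else ""
    )
  }
  sub_level <- lapply(
    if (sample(c(TRUE, FALSE), 1L)) sample.int(6L, sample(1:2, 1L)) else integer(),
    .rand_assertion
  )
  cancer <- cancer_interpretation(
    cancer_type = ontology_term("Oncotree", trow$oncotree_code, trow$label),
    biomarker_class = biomarker,
    therapeutic_context = context,
    effect = effect,
    level_of_evidence = list(schema_name = "CanDL",
                             level_label = paste("Tier", sample.int(4L, 1L))),
    sub_level = sub_level
  )
  mvld_record(descriptor, interpretation, cancer)
}

# Fixed catalogue of malformed HGVS strings for deterministic error text.
.bad_dna_hgvs <- c("76A>T", "c.76A>", "c._78del", "c.12_10del",
                   "g.100+2A>G", "c.76insA")
.bad_protein_hgvs <- c("V600E", "p.600E", "p.Vxl600Glu", "p.V600")

.injectors <- list(
  REQ.GENOME_BUILD = function(r) {
    r$descriptor$genome_build <- NA_character_
    list(record = r, field_path = "descriptor.genome_build")
  },
  REQ.GENE_NAME = function(r) {
    r$descriptor$gene_symbol <- NA_character_
    list(record = r, field_path = "descriptor.gene_symbol")
  },
  REQ.CHROMOSOME = function(r) {
    r$descriptor$chromosome <- NA_character_
    list(record = r, field_path = "descriptor.chromosome")
  },
  REQ.DNA_POSITION = function(r) {
    r$descriptor$genomic_position <- NA_integer_
    list(record = r, field_path = "descriptor.genomic_position")
  },
  REQ.TRANSCRIPT = function(r) {
    r$descriptor$transcripts <- character()
    list(record = r, field_path = "descriptor.transcripts")
  },
  REQ.SOMATIC_CLASS = function(r) {
    r$interpretation$somatic_classification <- NA_character_
    list(record = r, field_path = "interpretation.somatic_classification")
  },
  REQ.VARIANT_TYPE = function(r) {
    r$interpretation$variant_type <- NA_character_
    list(record = r, field_path = "interpretation.variant_type")
  },
  REQ.CONSEQUENCE = function(r) {
    r$interpretation$variant_consequence <- NA_character_
    list(record = r, field_path = "interpretation.variant_consequence")
  },
  REQ.CANCER_TYPE = function(r) {
    r$cancer$cancer_type <- NULL
    list(record = r, field_path = "cancer.cancer_type")
  },
  REQ.BIOMARKER_CLASS = function(r) {
    r$cancer$biomarker_class <- NA_character_
    list(record = r, field_path = "cancer.biomarker_class")
  },
  REQ.EVIDENCE_LEVEL = function(r) {
    r$cancer$level_of_evidence <- NULL
    list(record = r, field_path = "cancer.level_of_evidence")
  },
  COND.HGVS_PRESENT = function(r) {
    r$interpretation$dna_hgvs <- NA_character_
    r$interpretation$protein_hgvs <- NA_character_
    list(record = r, field_path = "interpretation.dna_hgvs")
  },
  COND.EFFECT_CONTEXT = function(r) {
    r$cancer$effect <- list(term = "sensitive", free_text = "")
    r$cancer$therapeutic_context <- character()
    list(record = r, field_path = "cancer.therapeutic_context")
  },
  COND.EFFECT_OTHER_TEXT = function(r) {
    r$cancer$effect <- list(term = "other", free_text = "")
    if (length(r$cancer$therapeutic_context) == 0L) {
      r$cancer$therapeutic_context <- "imatinib"
    }
    list(record = r, field_path = "cancer.effect.free_text")
  },
  COND.CANDL_LABEL = function(r) {
    r$cancer$level_of_evidence <- list(schema_name = "CanDL",
                                       level_label = "Tier 7")
    list(record = r, field_path = "cancer.level_of_evidence.level_label")
  },
  VOC.SOMATIC_CLASS = function(r) {
    r$interpretation$somatic_classification <- "likely somatic"
    list(record = r, field_path = "interpretation.somatic_classification")
  },
  VOC.VARIANT_TYPE = function(r) {
    r$interpretation$variant_type <- "INDEL"
    list(record = r, field_path = "interpretation.variant_type")
  },
  VOC.CONSEQUENCE = function(r) {
    r$interpretation$variant_consequence <- "stop_lost"
    list(record = r, field_path = "interpretation.variant_consequence")
  },
  VOC.BIOMARKER_CLASS = function(r) {
    r$cancer$biomarker_class <- "Theranostic"
    list(record = r, field_path = "cancer.biomarker_class")
  },
  VOC.EFFECT = function(r) {
    r$cancer$effect <- list(term = "refractory", free_text = "")
    if (length(r$cancer$therapeutic_context) == 0L) {
      r$cancer$therapeutic_context <- "imatinib"
    }
    list(record = r, field_path = "cancer.effect.term")
  },
  HGVS.DNA = function(r) {
    r$interpretation$dna_hgvs <- sample(.bad_dna_hgvs, 1L)
    list(record = r, field_path = "interpretation.dna_hgvs")
  },
  HGVS.PROTEIN = function(r) {
    r$interpretation$protein_hgvs <- sample(.bad_protein_hgvs, 1L)
    # the record may have been noncoding (no protein form, and exempt from
    # the both-HGVS suggestion); the malformed string is a grammar error
    # regardless of the consequence
    list(record = r, field_path = "interpretation.protein_hgvs")
  },
  EVID.TRIAL_OR_PMID_REQUIRED = function(r) {
    r$cancer$sub_level <- list(new_evidence_assertion(1L))
    list(record = r, field_path = "cancer.sub_level[1].trial_ids")
  },
  EVID.EXPERT_REQUIRED = function(r) {
    r$cancer$sub_level <- list(new_evidence_assertion(
      3L, note = "expert panel, unattributed"))
    list(record = r, field_path = "cancer.sub_level[1].expert")
  },
  EVID.PMID_REQUIRED = function(r) {
    r$cancer$sub_level <- list(new_evidence_assertion(
      sample(c(4L, 5L), 1L)))
    list(record = r, field_path = "cancer.sub_level[1].pmids")
  },
  EVID.PMID_OR_TOOL_REQUIRED = function(r) {
    r$cancer$sub_level <- list(new_evidence_assertion(6L))
    list(record = r, field_path = "cancer.sub_level[1].pmids")
  }
)

#' Generate a seeded MVLD fixture corpus with optional injected violations
#'
#' Clean records draw gene symbols (from the packaged HUGO subset), HGVS
#' edits covering all four variant types, consequences, cancer terms (from
#' the packaged ontology subset), biomarker classes, effects and evidence
#' assertions of all six categories from their valid spaces; a clean corpus
#' passes strict-profile validation with zero errors. Violations are
#' injected exactly as requested — one rule per selected record, records
#' chosen without replacement — and logged in the manifest, so that
#' [validate_records()] under the submission profile recovers the manifest's
#' (index, rule id) set exactly.
#'
#' Record `i` is generated from a sub-stream keyed by `(seed, i)`, so
#' corpora are stable under changes of `n`.
#'
#' @param n Number of records (>= 1).
#' @param seed Integer seed.
#' @param error_spec Named list or vector mapping an injectable rule id (see
#'   [mvld_rules()]) to the number of records to violate; the total must not
#'   exceed `n`.
#' @return A list with `records` and `manifest`; the manifest holds `seed`,
#'   `n` and `injected`, a data.frame of (index, rule_id, field_path).
#' @examples
#' gen <- generate_records(5, seed = 1)
#' validate_records(gen$records, "strict")$error_count   # 0
#' @export
generate_records <- function(n, seed, error_spec = list()) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  counts <- vapply(error_spec, function(v) as.integer(v), integer(1))
  if (length(counts)) {
    unknown <- setdiff(names(counts),
                       mvld_rules()$rule_id[mvld_rules()$injectable])
    if (length(unknown)) {
      stop("unknown or non-injectable rule id(s) in error_spec: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (any(counts < 0L)) stop("requested counts must be >= 0", call. = FALSE)
    if (sum(counts) > n) {
      stop("requested ", sum(counts), " injections for ", n, " records; ",
           "at most one violation is injected per record", call. = FALSE)
    }
  }
  records <- lapply(seq_len(n), function(i) .gen_clean_record(seed, i))

  injected <- data.frame(index = integer(), rule_id = character(),
                         field_path = character(), stringsAsFactors = FALSE)
  if (length(counts) && sum(counts) > 0L) {
    set.seed(as.integer((as.numeric(seed) + 104729) %% 2147483647))
    idx <- sample.int(n, sum(counts))
    k <- 0L
    for (rule in names(counts)) {
      for (j in seq_len(counts[[rule]])) {
        k <- k + 1L
        i <- idx[[k]]
        res <- .injectors[[rule]](records[[i]])
        records[[i]] <- res$record
        injected <- rbind(injected, data.frame(
          index = i, rule_id = rule, field_path = res$field_path,
          stringsAsFactors = FALSE
        ))
      }
    }
    injected <- injected[order(injected$index), , drop = FALSE]
    rownames(injected) <- NULL
  }
  list(records = records,
       manifest = list(seed = as.integer(seed), n = n, injected = injected))
}
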