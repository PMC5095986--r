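# Typed in-memory model for MVLD records.
#
# One MVLD record is one variant-level assertion: one variant in one cancer
# type with one biomarker class and one therapeutic context. The record is
# composed of the three MVLD field blocks (allele descriptive, allele
# interpretive, cancer interpretive) plus a free-text extension map that is
# round-tripped but never validated.
#
# Exported constructors reject hard domain violations (a chromosome outside
# 1-22/X/Y/MT, a genomic position below 1, a malformed genome build or
# RefSeq/NCT identifier, an evidence category outside 1-6) at construction
# time. Presence of required fields, vocabulary membership of free-typed
# inputs and cross-field conditional logic are the validator's job, so that
# nonconforming records read from files or produced by the fixture generator
# can be represented and reported on rather than crashing the pipeline.

.is_absent <- function(x) {
  is.null(x) || length(x) == 0L ||
    (length(x) == 1L && is.na(x)) ||
    (is.character(x) && length(x) == 1L && !nzchar(trimws(x)))
}

.chr_scalar <- function(x, what) {
  if (.is_absent(x)) return(NA_character_)
  if (!is.character(x) && !is.numeric(x)) {
    stop(what, " must be a character scalar", call. = FALSE)
  }
  as.character(x)[[1L]]
}

.int_scalar <- function(x, what) {
  if (.is_absent(x)) return(NA_integer_)
  xi <- suppressWarnings(as.numeric(x)[[1L]])
  if (is.na(xi) || xi != floor(xi)) {
    stop(what, " must be an integer", call. = FALSE)
  }
  as.integer(xi)
}

# internal, unchecked builders -------------------------------------------

new_allele_descriptor <- function(genome_build = NA_character_,
                                  gene_symbol = NA_character_,
                                  chromosome = NA_character_,
                                  genomic_position = NA_integer_,
                                  transcripts = character(),
                                  protein_id = NA_character_) {
  structure(
    list(
      genome_build = genome_build, gene_symbol = gene_symbol,
      chromosome = chromosome, genomic_position = genomic_position,
      transcripts = transcripts, protein_id = protein_id
    ),
    class = "mvld_allele_descriptor"
  )
}

new_allele_interpretation <- function(somatic_classification = NA_character_,
                                      dna_hgvs = NA_character_,
                                      protein_hgvs = NA_character_,
                                      variant_type = NA_character_,
                                      variant_consequence = NA_character_,
                                      pmids = integer()) {
  structure(
    list(
      somatic_classification = somatic_classification,
      dna_hgvs = dna_hgvs, protein_hgvs = protein_hgvs,
      variant_type = variant_type,
      variant_consequence = variant_consequence,
      pmids = pmids
    ),
    class = "mvld_allele_interpretation"
  )
}

new_cancer_interpretation <- function(cancer_type = NULL,
                                      biomarker_class = NA_character_,
                                      therapeutic_context = character(),
                                      effect = NULL,
                                      level_of_evidence = NULL,
                                      sub_level = list()) {
  structure(
    list(
      cancer_type = cancer_type, biomarker_class = biomarker_class,
      therapeutic_context = therapeutic_context, effect = effect,
      level_of_evidence = level_of_evidence, sub_level = sub_level
    ),
    class = "mvld_cancer_interpretation"
  )
}

new_evidence_assertion <- function(category = NA_integer_,
                                   trial_ids = character(),
                                   pmids = integer(),
                                   expert = NULL,
                                   tools = character(),
                                   note = NA_character_) {
  structure(
    list(
      category = category, trial_ids = trial_ids, pmids = pmids,
      expert = expert, tools = tools, note = note
    ),
    class = "mvld_evidence_assertion"
  )
}

new_mvld_record <- function(descriptor, interpretation, cancer,
                            extensions = list()) {
  structure(
    list(
      descriptor = descriptor, interpretation = interpretation,
      cancer = cancer, extensions = extensions
    ),
    class = "mvld_record"
  )
}

# exported constructors ---------------------------------------------------

#' Allele descriptive fields of an MVLD record
#'
#' The descriptive block locates the variant: reference genome build, the
#' HUGO-approved gene symbol, chromosome, 1-based genomic position (HGVS
#' convention), the applicable RefSeq transcripts and, optionally, the
#' RefSeq protein identifier.
#'
#' Hard domain violations are rejected at construction: the genome build must
#' be GRCh37 or GRCh38 with an optional patch suffix (e.g. `"GRCh38.p7"`),
#' the chromosome must be one of 1-22, X, Y, MT (a `"chr"` prefix is stripped
#' and stored without it), the position must be a positive integer, and
#' RefSeq identifiers must carry their NM_/NR_/NP_ prefixes. Absent fields
#' (`NA`) are allowed here and reported by [validate_record()].
#'
#' @param genome_build Assembly label, e.g. `"GRCh37"` or `"GRCh38.p13"`.
#' @param gene_symbol HUGO-approved gene symbol, e.g. `"BRAF"`.
#' @param chromosome Chromosome name; `"chr7"` is normalized to `"7"`.
#' @param genomic_position 1-based genomic coordinate.
#' @param transcripts Character vector of RefSeq transcript identifiers
#'   (`NM_`/`NR_` prefix, optional version suffix). May be empty only for
#'   variants whose DNA description is genomic (`g.`); enforced by the
#'   validator.
#' @param protein_id RefSeq protein identifier (`NP_` prefix) or `NA`.
#' @return An object of class `mvld_allele_descriptor`.
#' @examples
#' allele_descriptor("GRCh37", "BRAF", "chr7", 140453136,
#'                   transcripts = "NM_004333.4", protein_id = "NP_004324.2")
#' @export
allele_descriptor <- function(genome_build = NA, gene_symbol = NA,
                              chromosome = NA, genomic_position = NA,
                              transcripts = character(), protein_id = NA) {
  genome_build <- .chr_scalar(genome_build, "genome_build")
  if (!is.na(genome_build)) {
    m <- regexec("^grch3([78])(\\.p([0-9]+))?$", tolower(trimws(genome_build)))
    hit <- regmatches(tolower(trimws(genome_build)), m)[[1L]]
    if (length(hit) == 0L) {
      stop("genome_build must be GRCh37 or GRCh38, optionally with a patch ",
           "suffix (e.g. GRCh38.p7); got '", genome_build, "'", call. = FALSE)
    }
    genome_build <- paste0("GRCh3", hit[[2L]],
                           if (nzchar(hit[[3L]])) paste0(".p", hit[[4L]]) else "")
  }
  gene_symbol <- .chr_scalar(gene_symbol, "gene_symbol")
  if (!is.na(gene_symbol)) gene_symbol <- trimws(gene_symbol)
  chromosome <- .chr_scalar(chromosome, "chromosome")
  if (!is.na(chromosome)) {
    chromosome <- sub("^chr", "", trimws(chromosome), ignore.case = TRUE)
    chromosome <- normalize_term("chromosome", chromosome)
  }
  genomic_position <- .int_scalar(genomic_position, "genomic_position")
  if (!is.na(genomic_position) && genomic_position < 1L) {
    stop("genomic_position must be >= 1 (1-based, HGVS convention)",
         call. = FALSE)
  }
  transcripts <- as.character(transcripts[!is.na(transcripts)])
  transcripts <- trimws(transcripts[nzchar(trimws(transcripts))])
  bad <- transcripts[!grepl("^N[MR]_[0-9]+(\\.[0-9]+)?$", transcripts)]
  if (length(bad)) {
    stop("not RefSeq transcript identifiers (NM_/NR_ prefix): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  protein_id <- .chr_scalar(protein_id, "protein_id")
  if (!is.na(protein_id)) {
    protein_id <- trimws(protein_id)
    if (!grepl("^NP_[0-9]+(\\.[0-9]+)?$", protein_id)) {
      stop("protein_id must be a RefSeq protein identifier (NP_ prefix); ",
           "got '", protein_id, "'", call. = FALSE)
    }
  }
  new_allele_descriptor(genome_build, gene_symbol, chromosome,
                        genomic_position, transcripts, protein_id)
}

#' Allele interpretive fields of an MVLD record
#'
#' The interpretive block carries the somatic classification, the HGVS DNA
#' and protein descriptions (at least one is required; enforced by the
#' validator), the variant type (SNV/MNV/INS/DEL), the molecular consequence
#' and optional supporting PubMed IDs.
#'
#' Enumerated inputs are normalized to their canonical vocabulary spelling
#' via [normalize_term()]; an unknown term is rejected at construction. HGVS
#' strings are stored verbatim; their grammar is checked by
#' [validate_record()] through [check_dna_hgvs()] / [check_protein_hgvs()].
#'
#' @param somatic_classification One of `"Confirmed somatic"`,
#'   `"Confirmed germline"`, `"Unknown"`.
#' @param dna_hgvs HGVS DNA description (`g.`/`c.`/`n.`) or `NA`.
#' @param protein_hgvs HGVS protein description (`p.`) or `NA`.
#' @param variant_type One of `"SNV"`, `"MNV"`, `"INS"`, `"DEL"`.
#' @param variant_consequence One of the twelve canonical consequence terms
#'   (see `vocabulary("variant_consequence")`).
#' @param pmids Vector of positive-integer PubMed IDs (optional).
#' @return An object of class `mvld_allele_interpretation`.
#' @examples
#' allele_interpretation("Confirmed somatic", dna_hgvs = "c.1799T>A",
#'                       protein_hgvs = "p.V600E", variant_type = "SNV",
#'                       variant_consequence = "Missense", pmids = 12068308)
#' @export
allele_interpretation <- function(somatic_classification = NA,
                                  dna_hgvs = NA, protein_hgvs = NA,
                                  variant_type = NA,
                                  variant_consequence = NA,
                                  pmids = integer()) {
  somatic_classification <- .chr_scalar(somatic_classification,
                                        "somatic_classification")
  if (!is.na(somatic_classification)) {
    somatic_classification <- normalize_term("somatic_classification",
                                             somatic_classification)
  }
  variant_type <- .chr_scalar(variant_type, "variant_type")
  if (!is.na(variant_type)) {
    variant_type <- normalize_term("variant_type", variant_type)
  }
  variant_consequence <- .chr_scalar(variant_consequence,
                                     "variant_consequence")
  if (!is.na(variant_consequence)) {
    variant_consequence <- normalize_term("variant_consequence",
                                          variant_consequence)
  }
  pmids <- pmids[!is.na(pmids)]
  pmids <- vapply(pmids, .int_scalar, integer(1), what = "pmid")
  if (any(pmids < 1L)) stop("pmids must be positive integers", call. = FALSE)
  new_allele_interpretation(
    somatic_classification,
    .chr_scalar(dna_hgvs, "dna_hgvs"),
    .chr_scalar(protein_hgvs, "protein_hgvs"),
    variant_type, variant_consequence, as.integer(pmids)
  )
}

#' Cancer-type ontology term
#'
#' A cancer type drawn from the NCI Thesaurus, Oncotree, or a local
#' vocabulary. Oncotree codes are the short initialisms (e.g. `"RGNT"` for
#' rosette-forming glioneuronal tumor). Use [lookup_cancer_term()] to
#' resolve codes or labels against the packaged ontology subset.
#'
#' @param source One of `"NCIt"`, `"Oncotree"`, `"local"`.
#' @param code Non-empty term code.
#' @param label Human-readable label (optional but recommended).
#' @return An object of class `mvld_ontology_term`.
#' @examples
#' ontology_term("Oncotree", "RGNT", "rosette-forming glioneuronal tumor")
#' @export
ontology_term <- function(source, code, label = NA) {
  source <- normalize_term("ontology_source", .chr_scalar(source, "source"))
  code <- .chr_scalar(code, "code")
  if (is.na(code)) stop("ontology term code must be non-empty", call. = FALSE)
  structure(
    list(source = source, code = trimws(code),
         label = .chr_scalar(label, "label")),
    class = "mvld_ontology_term"
  )
}

#' One sub-level evidence assertion
#'
#' A single supporting evidence item for a variant-level assertion, carrying
#' its sub-level category (1 = prospective trials/studies, 2 = retrospective
#' trials/studies and metadata analysis, 3 = expert opinion, 4 = case
#' reports, 5 = published preclinical data, 6 = inferential data or in
#' silico predictions) and its citations. Each category has mandated
#' citations, checked by [check_evidence_citations()]: clinical-trial
#' numbers (NCT) for trials, PMIDs for case reports/preclinical/inferential
#' publications, the expert's name, date and affiliation for expert opinion,
#' and program names for in silico predictions.
#'
#' @param category Integer 1-6.
#' @param trial_ids Clinical-trial identifiers matching `NCT` + 8 digits.
#' @param pmids Positive-integer PubMed IDs.
#' @param expert `NULL`, or a list/character vector giving `name`, `date`
#'   and `affiliation`.
#' @param tools Names of in silico prediction programs.
#' @param note Free-text note.
#' @return An object of class `mvld_evidence_assertion`.
#' @examples
#' evidence_assertion(1, trial_ids = "NCT01234567")
#' evidence_assertion(3, expert = c(name = "A. Curator", date = "2016-05-01",
#'                                  affiliation = "Example Cancer Center"))
#' @export
evidence_assertion <- function(category, trial_ids = character(),
                               pmids = integer(), expert = NULL,
                               tools = character(), note = NA) {
  category <- .int_scalar(category, "category")
  if (is.na(category) || category < 1L || category > 6L) {
    stop("evidence category must be an integer in 1..6", call. = FALSE)
  }
  trial_ids <- toupper(trimws(as.character(trial_ids)))
  trial_ids <- trial_ids[nzchar(trial_ids)]
  bad <- trial_ids[!grepl("^NCT[0-9]{8}$", trial_ids)]
  if (length(bad)) {
    stop("trial_ids must match NCT + 8 digits: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  pmids <- pmids[!is.na(pmids)]
  pmids <- vapply(pmids, .int_scalar, integer(1), what = "pmid")
  if (any(pmids < 1L)) stop("pmids must be positive integers", call. = FALSE)
  if (!is.null(expert)) {
    expert <- as.list(expert)
    want <- c("name", "date", "affiliation")
    if (is.null(names(expert)) || !all(want %in% names(expert))) {
      if (length(expert) == 3L) names(expert) <- want
      else stop("expert must give name, date and affiliation", call. = FALSE)
    }
    expert <- lapply(expert[want], function(v) .chr_scalar(v, "expert field"))
    if (any(vapply(expert, is.na, logical(1)))) {
      stop("expert name, date and affiliation must all be non-empty",
           call. = FALSE)
    }
  }
  new_evidence_assertion(category, trial_ids, as.integer(pmids), expert,
                         as.character(tools[nzchar(as.character(tools))]),
                         .chr_scalar(note, "note"))
}

#' Cancer interpretive fields of an MVLD record
#'
#' The cancer-interpretive block is the cancer-specific part of MVLD: the
#' cancer type as an ontology term, the biomarker class (Diagnostic,
#' Prognostic or Predictive), the optional therapeutic context (drug names)
#' and effect (direction of the variant-drug relationship), the level of
#' evidence under a named scoring schema (`"CanDL"` built in; any
#' well-described framework may substitute), and optional sub-level
#' evidence assertions.
#'
#' The effect is a pair of a term from the effect vocabulary and a free-text
#' description that must be used exactly when the term is `"other"`; that
#' rule, and the rule that an effect requires a non-empty therapeutic
#' context, are reported by [validate_record()].
#'
#' @param cancer_type An [ontology_term()] or `NULL`.
#' @param biomarker_class One of `"Diagnostic"`, `"Prognostic"`,
#'   `"Predictive"`.
#' @param therapeutic_context Character vector of drug names (free text).
#' @param effect `NULL`, or a list with elements `term` (one of the effect
#'   vocabulary terms) and `free_text`.
#' @param level_of_evidence `NULL`, or a list with elements `schema_name`
#'   and `level_label`; for schema `"CanDL"` the label must be one of
#'   `"Tier 1"`..`"Tier 4"` (checked by the validator).
#' @param sub_level List of [evidence_assertion()] objects.
#' @return An object of class `mvld_cancer_interpretation`.
#' @examples
#' cancer_interpretation(
#'   cancer_type = ontology_term("Oncotree", "MEL", "Melanoma"),
#'   biomarker_class = "Predictive",
#'   therapeutic_context = "vemurafenib",
#'   effect = list(term = "sensitive", free_text = ""),
#'   level_of_evidence = list(schema_name = "CanDL", level_label = "Tier 1")
#' )
#' @export
cancer_interpretation <- function(cancer_type = NULL, biomarker_class = NA,
                                  therapeutic_context = character(),
                                  effect = NULL, level_of_evidence = NULL,
                                  sub_level = list()) {
  if (!is.null(cancer_type) && !inherits(cancer_type, "mvld_ontology_term")) {
    stop("cancer_type must be an ontology_term() or NULL", call. = FALSE)
  }
  biomarker_class <- .chr_scalar(biomarker_class, "biomarker_class")
  if (!is.na(biomarker_class)) {
    biomarker_class <- normalize_term("biomarker_class", biomarker_class)
  }
  therapeutic_context <- as.character(therapeutic_context)
  therapeutic_context <- trimws(therapeutic_context[nzchar(trimws(therapeutic_context))])
  if (!is.null(effect)) {
    effect <- as.list(effect)
    if (is.null(names(effect)) && length(effect) >= 1L) {
      names(effect) <- c("term", "free_text")[seq_along(effect)]
    }
    term <- .chr_scalar(effect$term, "effect term")
    if (is.na(term)) stop("effect$term must be given", call. = FALSE)
    term <- normalize_term("effect", term)
    ft <- .chr_scalar(effect$free_text, "effect free_text")
    effect <- list(term = term, free_text = if (is.na(ft)) "" else ft)
  }
  if (!is.null(level_of_evidence)) {
    level_of_evidence <- as.list(level_of_evidence)
    if (is.null(names(level_of_evidence)) && length(level_of_evidence) == 2L) {
      names(level_of_evidence) <- c("schema_name", "level_label")
    }
    sn <- .chr_scalar(level_of_evidence$schema_name, "schema_name")
    ll <- .chr_scalar(level_of_evidence$level_label, "level_label")
    if (is.na(sn) || is.na(ll)) {
      stop("level_of_evidence needs schema_name and level_label",
           call. = FALSE)
    }
    level_of_evidence <- list(schema_name = sn, level_label = ll)
  }
  if (!is.list(sub_level) ||
      !all(vapply(sub_level, inherits, logical(1), "mvld_evidence_assertion"))) {
    stop("sub_level must be a list of evidence_assertion() objects",
         call. = FALSE)
  }
  new_cancer_interpretation(cancer_type, biomarker_class,
                            therapeutic_context, effect, level_of_evidence,
                            unname(sub_level))
}

#' One MVLD record: a single variant-level assertion
#'
#' Composes the three MVLD blocks into one record. A record represents
#' exactly one assertion — one variant in one cancer type, with one
#' biomarker class and one therapeutic context; a variant asserted in two
#' therapeutic contexts is two records. Unknown input columns are carried in
#' `extensions`, a free key-to-text map that is round-tripped through all
#' serializations but never validated.
#'
#' @param descriptor An [allele_descriptor()].
#' @param interpretation An [allele_interpretation()].
#' @param cancer A [cancer_interpretation()].
#' @param extensions Named list of character scalars.
#' @return An object of class `mvld_record`.
#' @seealso [validate_record()], [write_mvld_table()], [to_clinvar_row()]
#' @export
mvld_record <- function(descriptor = allele_descriptor(),
                        interpretation = allele_interpretation(),
                        cancer = cancer_interpretation(),
                        extensions = list()) {
  stopifnot(inherits(descriptor, "mvld_allele_descriptor"),
            inherits(interpretation, "mvld_allele_interpretation"),
            inherits(cancer, "mvld_cancer_interpretation"))
  if (length(extensions)) {
    if (is.null(names(extensions)) || any(!nzchar(names(extensions)))) {
      stop("extensions must be a named list", call. = FALSE)
    }
    extensions <- lapply(extensions, function(v) as.character(v)[[1L]])
  } else {
    extensions <- stats::setNames(list(), character())
  }
  new_mvld_record(descriptor, interpretation, cancer, extensions)
}

#' @export
print.mvld_record <- function(x, ...) {
  d <- x$descriptor; i <- x$interpretation; k <- x$cancer
  ct <- if (is.null(k$cancer_type)) "<no cancer type>" else
    paste0(k$cancer_type$source, ":", k$cancer_type$code,
           if (!is.na(k$cancer_type$label)) paste0(" (", k$cancer_type$label, ")") else "")
  loe <- if (is.null(k$level_of_evidence)) "<no level of evidence>" else
    paste0(k$level_of_evidence$schema_name, " ", k$level_of_evidence$level_label)
  cat("<mvld_record>\n",
      "  ", ifelse(is.na(d$gene_symbol), "<gene?>", d$gene_symbol), " ",
      ifelse(is.na(i$dna_hgvs), "", i$dna_hgvs),
      ifelse(is.na(i$protein_hgvs), "", paste0(" / ", i$protein_hgvs)), "\n",
      "  ", ifelse(is.na(d$genome_build), "<build?>", d$genome_build),
      " chr", ifelse(is.na(d$chromosome), "?", d$chromosome), ":",
      ifelse(is.na(d$genomic_position), "?", d$genomic_position), "\n",
      "  ", ifelse(is.na(i$variant_type), "<type?>", i$variant_type), " / ",
      ifelse(is.na(i$variant_consequence), "<consequence?>", i$variant_consequence),
      " / ", ifelse(is.na(i$somatic_classification), "<class?>",
                    i$somatic_classification), "\n",
      "  ", ct, " | ",
      ifelse(is.na(k$biomarker_class), "<class?>", k$biomarker_class),
      " | ", loe, "\n", sep = "")
  invisible(x)
}

#' @export
format.mvld_ontology_term <- function(x, ...) {
  paste0(x$source, ":", x$code,
         if (!is.na(x$label)) paste0(" (", x$label, ")") else "")
}

#' @export
print.mvld_ontology_term <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
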