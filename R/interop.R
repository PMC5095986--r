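# Serialization: MVLD TSV and JSON, ClinVar-style export, ontology lookup.
#
# Table dialect: UTF-8, tab-separated, one header row with the exact
# canonical column names in the standard's field order, ";" as the list
# delimiter inside a cell, empty cell for an absent optional. Sub-level
# evidence assertions are structured objects and are carried inside their
# cell as minified JSON. Unknown columns are preserved into record
# extensions and written back after the canonical columns, in first-seen
# order. Output is deterministic: identical records give byte-identical
# files.

.mvld_cols <- c(
  "genome_build", "gene_name", "chromosome", "dna_position",
  "refseq_transcript", "refseq_protein",
  "somatic_classification", "dna_hgvs", "protein_hgvs", "variant_type",
  "variant_consequence", "pmids",
  "cancer_type_source", "cancer_type_code", "cancer_type_label",
  "biomarker_class", "therapeutic_context", "effect", "effect_description",
  "level_of_evidence_schema", "level_of_evidence_label",
  "sub_level_of_evidence"
)

#' Canonical MVLD table columns
#'
#' The header of an MVLD TSV file: the canonical column names in the
#' standard's field order (allele descriptive, allele interpretive, cancer
#' interpretive).
#'
#' @return Character vector of column names.
#' @export
mvld_columns <- function() .mvld_cols

.cell <- function(x) {
  if (.is_absent(x)) return("")
  as.character(x)
}

.join_list <- function(x) {
  x <- as.character(x)
  if (length(x) == 0L) return("")
  if (any(grepl("[;\t\n]", x))) {
    stop("list values may not contain ';', tabs or newlines", call. = FALSE)
  }
  paste(x, collapse = ";")
}

.split_list <- function(cell) {
  if (!nzchar(cell)) return(character())
  strsplit(cell, ";", fixed = TRUE)[[1L]]
}

.assertion_to_list <- function(a) {
  x <- list(category = a$category)
  if (length(a$trial_ids)) x$trial_ids <- as.list(a$trial_ids)
  if (length(a$pmids)) x$pmids <- as.list(a$pmids)
  if (!is.null(a$expert)) x$expert <- a$expert
  if (length(a$tools)) x$tools <- as.list(a$tools)
  if (!is.na(a$note)) x$note <- a$note
  x
}

.list_to_assertion <- function(x) {
  new_evidence_assertion(
    category = as.integer(x$category),
    trial_ids = as.character(unlist(x$trial_ids)),
    pmids = as.integer(unlist(x$pmids)),
    expert = if (!is.null(x$expert)) {
      lapply(x$expert[c("name", "date", "affiliation")], as.character)
    },
    tools = as.character(unlist(x$tools)),
    note = if (!is.null(x$note)) as.character(x$note) else NA_character_
  )
}

.sublevel_to_cell <- function(sub_level) {
  if (length(sub_level) == 0L) return("")
  as.character(jsonlite::toJSON(lapply(sub_level, .assertion_to_list),
                                auto_unbox = TRUE, digits = NA))
}

.cell_to_sublevel <- function(cell) {
  if (!nzchar(cell)) return(list())
  lapply(jsonlite::fromJSON(cell, simplifyVector = FALSE),
         .list_to_assertion)
}

.record_to_cells <- function(r) {
  d <- r$descriptor; i <- r$interpretation; k <- r$cancer
  ct <- k$cancer_type
  ef <- k$effect
  loe <- k$level_of_evidence
  c(
    genome_build = .cell(d$genome_build),
    gene_name = .cell(d$gene_symbol),
    chromosome = .cell(d$chromosome),
    dna_position = .cell(d$genomic_position),
    refseq_transcript = .join_list(d$transcripts),
    refseq_protein = .cell(d$protein_id),
    somatic_classification = .cell(i$somatic_classification),
    dna_hgvs = .cell(i$dna_hgvs),
    protein_hgvs = .cell(i$protein_hgvs),
    variant_type = .cell(i$variant_type),
    variant_consequence = .cell(i$variant_consequence),
    pmids = .join_list(i$pmids),
    cancer_type_source = if (is.null(ct)) "" else .cell(ct$source),
    cancer_type_code = if (is.null(ct)) "" else .cell(ct$code),
    cancer_type_label = if (is.null(ct)) "" else .cell(ct$label),
    biomarker_class = .cell(k$biomarker_class),
    therapeutic_context = .join_list(k$therapeutic_context),
    effect = if (is.null(ef)) "" else .cell(ef$term),
    effect_description = if (is.null(ef)) "" else .cell(ef$free_text),
    level_of_evidence_schema = if (is.null(loe)) "" else .cell(loe$schema_name),
    level_of_evidence_label = if (is.null(loe)) "" else .cell(loe$level_label),
    sub_level_of_evidence = .sublevel_to_cell(k$sub_level)
  )
}

#' Write records as an MVLD TSV table
#'
#' Writes one row per record in the canonical column order, ";"-joined
#' lists, empty cells for absent optionals, and sub-level evidence as
#' minified JSON inside its cell. Extension keys become extra columns after
#' the canonical ones, in first-seen order. Byte output is stable for
#' identical input; an empty record list yields a header-only file.
#'
#' @param records List of [mvld_record()] objects.
#' @param path Output file path, or `NULL` to return the lines.
#' @return Invisibly, the character vector of file lines.
#' @seealso [read_mvld_table()]
#' @export
write_mvld_table <- function(records, path = NULL) {
  stopifnot(is.list(records),
            all(vapply(records, inherits, logical(1), "mvld_record")))
  ext_cols <- character()
  for (r in records) {
    ext_cols <- union(ext_cols, names(r$extensions))
  }
  header <- c(.mvld_cols, ext_cols)
  rows <- vapply(records, function(r) {
    cells <- .record_to_cells(r)
    ext <- vapply(ext_cols, function(cn) {
      v <- r$extensions[[cn]]
      if (is.null(v)) "" else .cell(v)
    }, character(1))
    all_cells <- c(cells, ext)
    if (any(grepl("[\t\n]", all_cells))) {
      stop("cell values may not contain tabs or newlines", call. = FALSE)
    }
    paste(all_cells, collapse = "\t")
  }, character(1))
  lines <- c(paste(header, collapse = "\t"), rows)
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, useBytes = TRUE)
  }
  invisible(lines)
}

.parse_cells <- function(cells, header, row_no) {
  findings <- .empty_findings()
  note <- function(severity, rule_id, field_path, message) {
    findings <<- rbind(findings,
                       .finding(severity, rule_id, field_path, message,
                                record = row_no))
  }
  skip <- function(message) {
    list(record = NULL,
         findings = .finding("error", "IO.ROW_SKIPPED",
                             paste0("row[", row_no, "]"), message,
                             record = row_no))
  }
  g <- function(col) {
    v <- cells[[match(col, header)]]
    if (is.na(v)) "" else trimws(v)
  }
  norm <- function(field, raw, rule_id, path) {
    if (!nzchar(raw)) return(NA_character_)
    tryCatch(normalize_term(field, raw), error = function(e) {
      note("error", rule_id, path,
           paste0("'", raw, "' is not in the ", field, " vocabulary"))
      raw
    })
  }

  # descriptor ------------------------------------------------------------
  gb <- g("genome_build")
  if (nzchar(gb)) {
    d <- tryCatch(allele_descriptor(genome_build = gb),
                  error = function(e) NULL)
    if (is.null(d)) return(skip(paste0("malformed genome build '", gb, "'")))
    gb <- d$genome_build
  } else gb <- NA_character_
  chrom <- g("chromosome")
  if (nzchar(chrom)) {
    chrom <- sub("^chr", "", chrom, ignore.case = TRUE)
    if (!chrom %in% vocabulary("chromosome")) {
      return(skip(paste0("chromosome '", g("chromosome"),
                         "' outside 1-22/X/Y/MT")))
    }
  } else chrom <- NA_character_
  pos_raw <- g("dna_position")
  pos <- NA_integer_
  if (nzchar(pos_raw)) {
    pos <- suppressWarnings(as.integer(pos_raw))
    if (is.na(pos) || pos < 1L) {
      return(skip(paste0("DNA position '", pos_raw,
                         "' is not a positive integer")))
    }
  }
  transcripts <- .split_list(g("refseq_transcript"))
  if (length(transcripts) &&
      any(!grepl("^N[MR]_[0-9]+(\\.[0-9]+)?$", transcripts))) {
    return(skip("malformed RefSeq transcript identifier"))
  }
  protein_id <- g("refseq_protein")
  if (nzchar(protein_id)) {
    if (!grepl("^NP_[0-9]+(\\.[0-9]+)?$", protein_id)) {
      return(skip(paste0("malformed RefSeq protein identifier '",
                         protein_id, "'")))
    }
  } else protein_id <- NA_character_
  descriptor <- new_allele_descriptor(
    gb, if (nzchar(g("gene_name"))) g("gene_name") else NA_character_,
    chrom, pos, transcripts, protein_id
  )

  # interpretation --------------------------------------------------------
  pm_raw <- .split_list(g("pmids"))
  if (length(pm_raw) && any(!grepl("^[0-9]+$", pm_raw))) {
    return(skip("PubMed IDs must be positive integers"))
  }
  interpretation <- new_allele_interpretation(
    norm("somatic_classification", g("somatic_classification"),
         "VOC.SOMATIC_CLASS", "interpretation.somatic_classification"),
    if (nzchar(g("dna_hgvs"))) g("dna_hgvs") else NA_character_,
    if (nzchar(g("protein_hgvs"))) g("protein_hgvs") else NA_character_,
    norm("variant_type", g("variant_type"),
         "VOC.VARIANT_TYPE", "interpretation.variant_type"),
    norm("variant_consequence", g("variant_consequence"),
         "VOC.CONSEQUENCE", "interpretation.variant_consequence"),
    as.integer(pm_raw)
  )

  # cancer ----------------------------------------------------------------
  ct <- NULL
  if (nzchar(g("cancer_type_code"))) {
    src_raw <- g("cancer_type_source")
    src <- tryCatch(normalize_term("ontology_source",
                                   if (nzchar(src_raw)) src_raw else "local"),
                    error = function(e) NULL)
    if (is.null(src)) {
      return(skip(paste0("unknown ontology source '", src_raw, "'")))
    }
    ct <- structure(
      list(source = src, code = g("cancer_type_code"),
           label = if (nzchar(g("cancer_type_label"))) g("cancer_type_label")
                   else NA_character_),
      class = "mvld_ontology_term"
    )
  }
  ef <- NULL
  if (nzchar(g("effect"))) {
    ef <- list(term = norm("effect", g("effect"), "VOC.EFFECT",
                           "cancer.effect.term"),
               free_text = g("effect_description"))
  }
  loe <- NULL
  if (nzchar(g("level_of_evidence_schema")) ||
      nzchar(g("level_of_evidence_label"))) {
    loe <- list(schema_name = g("level_of_evidence_schema"),
                level_label = g("level_of_evidence_label"))
  }
  sub_level <- tryCatch(.cell_to_sublevel(g("sub_level_of_evidence")),
                        error = function(e) NULL)
  if (is.null(sub_level)) {
    return(skip("malformed sub-level evidence JSON"))
  }
  cancer <- new_cancer_interpretation(
    ct, norm("biomarker_class", g("biomarker_class"),
             "VOC.BIOMARKER_CLASS", "cancer.biomarker_class"),
    .split_list(g("therapeutic_context")), ef, loe, sub_level
  )

  # extensions ------------------------------------------------------------
  ext_cols <- setdiff(header, .mvld_cols)
  extensions <- stats::setNames(list(), character())
  for (cn in ext_cols) {
    v <- cells[[match(cn, header)]]
    if (!is.na(v) && nzchar(v)) extensions[[cn]] <- v
  }

  list(record = new_mvld_record(descriptor, interpretation, cancer,
                                extensions),
       findings = findings)
}

#' Read an MVLD TSV table
#'
#' Parses each data row into an [mvld_record()] via [normalize_term()];
#' vocabulary terms that cannot be normalized are kept verbatim and reported
#' as `VOC.*` findings, unknown columns are preserved into record extensions
#' with an `IO.UNKNOWN_COLUMN` warning, and rows that cannot be structurally
#' constructed (e.g. a non-integer position) are skipped with an
#' `IO.ROW_SKIPPED` error finding carrying the row number. A missing header
#' or duplicated canonical columns is a hard read error.
#'
#' @param path Path to a UTF-8 tab-separated file with a header row of
#'   canonical column names (see [mvld_columns()]).
#' @return A list with `records` (list of `mvld_record`) and `report`
#'   (an `mvld_validation_report` of read findings; row numbers are 1-based
#'   over data rows).
#' @export
read_mvld_table <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("unreadable input: no such file", call. = FALSE)
  }
  lines <- tryCatch(suppressWarnings(readLines(path, encoding = "UTF-8",
                                               warn = FALSE)),
                    error = function(e) NULL)
  if (is.null(lines) || length(lines) == 0L ||
      any(grepl("[\x01-\x08\x0e-\x1f]", lines[seq_len(min(5L, length(lines)))]))) {
    stop("unreadable input: not a UTF-8 MVLD table", call. = FALSE)
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  canon <- intersect(header, .mvld_cols)
  if (length(canon) < length(.mvld_cols)) {
    missing <- setdiff(.mvld_cols, header)
    if (length(missing) == length(.mvld_cols)) {
      stop("missing header: no canonical MVLD columns found", call. = FALSE)
    }
    stop("missing canonical column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(header[header %in% .mvld_cols])) {
    stop("duplicate canonical column(s) in header", call. = FALSE)
  }
  findings <- .empty_findings()
  for (cn in setdiff(header, .mvld_cols)) {
    findings <- rbind(findings,
                      .finding("warning", "IO.UNKNOWN_COLUMN", cn,
                               paste0("unknown column '", cn,
                                      "' preserved into extensions")))
  }
  records <- list()
  data_lines <- lines[-1L]
  data_lines <- data_lines[nzchar(data_lines)]
  for (rn in seq_along(data_lines)) {
    cells <- strsplit(data_lines[[rn]], "\t", fixed = TRUE)[[1L]]
    length(cells) <- length(header)    # pad trailing empties with NA
    parsed <- .parse_cells(cells, header, rn)
    findings <- rbind(findings, parsed$findings)
    if (!is.null(parsed$record)) records[[length(records) + 1L]] <- parsed$record
  }
  list(records = records, report = validation_report(findings))
}

# JSON corpus I/O ----------------------------------------------------------

.record_to_list <- function(r) {
  d <- r$descriptor; i <- r$interpretation; k <- r$cancer
  list(
    descriptor = list(
      genome_build = d$genome_build, gene_symbol = d$gene_symbol,
      chromosome = d$chromosome, genomic_position = d$genomic_position,
      transcripts = as.list(d$transcripts), protein_id = d$protein_id
    ),
    interpretation = list(
      somatic_classification = i$somatic_classification,
      dna_hgvs = i$dna_hgvs, protein_hgvs = i$protein_hgvs,
      variant_type = i$variant_type,
      variant_consequence = i$variant_consequence,
      pmids = as.list(i$pmids)
    ),
    cancer = list(
      cancer_type = if (!is.null(k$cancer_type)) {
        list(source = k$cancer_type$source, code = k$cancer_type$code,
             label = k$cancer_type$label)
      },
      biomarker_class = k$biomarker_class,
      therapeutic_context = as.list(k$therapeutic_context),
      effect = k$effect,
      level_of_evidence = k$level_of_evidence,
      sub_level = lapply(k$sub_level, .assertion_to_list)
    ),
    extensions = r$extensions
  )
}

.list_to_record <- function(x) {
  chr1 <- function(v) if (is.null(v)) NA_character_ else as.character(v)
  d <- x$descriptor
  descriptor <- new_allele_descriptor(
    chr1(d$genome_build), chr1(d$gene_symbol), chr1(d$chromosome),
    if (is.null(d$genomic_position)) NA_integer_ else as.integer(d$genomic_position),
    as.character(unlist(d$transcripts)), chr1(d$protein_id)
  )
  i <- x$interpretation
  interpretation <- new_allele_interpretation(
    chr1(i$somatic_classification), chr1(i$dna_hgvs), chr1(i$protein_hgvs),
    chr1(i$variant_type), chr1(i$variant_consequence),
    as.integer(unlist(i$pmids))
  )
  k <- x$cancer
  ct <- if (!is.null(k$cancer_type)) {
    structure(list(source = chr1(k$cancer_type$source),
                   code = chr1(k$cancer_type$code),
                   label = chr1(k$cancer_type$label)),
              class = "mvld_ontology_term")
  }
  ef <- if (!is.null(k$effect)) {
    list(term = chr1(k$effect$term),
         free_text = if (is.null(k$effect$free_text)) "" else
           as.character(k$effect$free_text))
  }
  loe <- if (!is.null(k$level_of_evidence)) {
    list(schema_name = chr1(k$level_of_evidence$schema_name),
         level_label = chr1(k$level_of_evidence$level_label))
  }
  cancer <- new_cancer_interpretation(
    ct, chr1(k$biomarker_class),
    as.character(unlist(k$therapeutic_context)), ef, loe,
    lapply(k$sub_level, .list_to_assertion)
  )
  ext <- x$extensions
  extensions <- if (is.null(ext) || length(ext) == 0L) {
    stats::setNames(list(), character())
  } else {
    lapply(ext, as.character)
  }
  new_mvld_record(descriptor, interpretation, cancer, extensions)
}

#' Write records as an MVLD JSON document
#'
#' One document holds the list of records under `"records"` plus a
#' top-level `"mvld_version"` string. The JSON schema mirrors the type model
#' one-to-one; absent fields are `null`.
#'
#' @inheritParams write_mvld_table
#' @return Invisibly, the JSON string.
#' @export
write_mvld_json <- function(records, path = NULL) {
  stopifnot(is.list(records),
            all(vapply(records, inherits, logical(1), "mvld_record")))
  doc <- list(mvld_version = "1.0",
              records = lapply(records, .record_to_list))
  js <- as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                                      na = "null", digits = NA))
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(js, con, useBytes = TRUE)
  }
  invisible(js)
}

#' Read an MVLD JSON document
#'
#' @param path Path to a JSON file produced by [write_mvld_json()] (or any
#'   document following the same schema).
#' @return A list with `records` and an (empty unless problems arise)
#'   `report`, mirroring [read_mvld_table()].
#' @export
read_mvld_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) NULL)
  if (is.null(doc) || is.null(doc$records)) {
    stop("unreadable input: not an MVLD JSON document", call. = FALSE)
  }
  list(records = lapply(doc$records, .list_to_record),
       report = validation_report())
}

# ClinVar-style export ------------------------------------------------------

.clinvar_cols <- c(
  "gene_symbol", "genome_build", "chromosome", "start",
  "refseq_transcripts", "refseq_protein", "hgvs_dna", "hgvs_protein",
  "somatic_classification", "variant_type", "variant_consequence",
  "condition", "clinical_significance", "assertion_method", "citations"
)

#' Export one record as a ClinVar-submission-style row
#'
#' Renders a conformant record into a flat mapping of the kind a ClinVar
#' submission table uses: HGVS expressions, gene symbol, the condition as
#' `"source:code (label)"`, a clinical-significance analog assembled from
#' the biomarker class, effect and therapeutic context, the level of
#' evidence rendered into the assertion-method field (for CanDL, with the
#' verbatim tier sentence), and citations (the record's PMIDs plus any NCT
#' ids from sub-level evidence). The layout is a documented generic mapping,
#' not a bit-exact copy of a dated ClinVar template.
#'
#' A record with validation errors under the submission profile is refused;
#' the error message lists the blocking findings.
#'
#' @param record An [mvld_record()] with zero submission-profile errors.
#' @return Named character vector (one flat row).
#' @seealso [write_clinvar_table()], [clinvar_row_to_record()]
#' @export
to_clinvar_row <- function(record) {
  rep <- validate_record(record, "submission")
  if (rep$error_count > 0L) {
    f <- rep$findings[rep$findings$severity == "error", ]
    stop("record has validation errors and cannot be exported:\n",
         paste0("  ", f$rule_id, " at ", f$field_path, collapse = "\n"),
         call. = FALSE)
  }
  d <- record$descriptor; i <- record$interpretation; k <- record$cancer
  ct <- k$cancer_type
  condition <- paste0(ct$source, ":", ct$code,
                      if (!is.na(ct$label)) paste0(" (", ct$label, ")") else "")
  sig <- k$biomarker_class
  if (!is.null(k$effect)) {
    eff <- k$effect$term
    if (identical(eff, "other")) eff <- paste0("other (", k$effect$free_text, ")")
    sig <- paste0(sig, "; ", eff,
                  if (length(k$therapeutic_context)) {
                    paste0(" to ", paste(k$therapeutic_context, collapse = " + "))
                  } else "")
  }
  loe <- k$level_of_evidence
  am <- paste0(loe$schema_name, ": ", loe$level_label)
  if (identical(loe$schema_name, "CanDL") &&
      loe$level_label %in% paste("Tier", 1:4)) {
    tier <- as.integer(sub("Tier ", "", loe$level_label))
    am <- paste0(am, " - ", .candl_sentences[[tier]])
  }
  ncts <- unique(unlist(lapply(k$sub_level, function(a) a$trial_ids)))
  citations <- paste(c(paste0("PMID:", i$pmids), ncts), collapse = ";")
  c(
    gene_symbol = d$gene_symbol,
    genome_build = d$genome_build,
    chromosome = d$chromosome,
    start = as.character(d$genomic_position),
    refseq_transcripts = .join_list(d$transcripts),
    refseq_protein = .cell(d$protein_id),
    hgvs_dna = .cell(i$dna_hgvs),
    hgvs_protein = .cell(i$protein_hgvs),
    somatic_classification = i$somatic_classification,
    variant_type = i$variant_type,
    variant_consequence = i$variant_consequence,
    condition = condition,
    clinical_significance = sig,
    assertion_method = am,
    citations = citations
  )
}

#' Reconstruct the required MVLD fields from a ClinVar-style row
#'
#' The export is lossless for the required fields: this inverse rebuilds the
#' allele descriptor, the allele interpretation, the cancer type, the
#' biomarker class and the level of evidence from a row written by
#' [to_clinvar_row()]. Optional cancer-interpretive detail (therapeutic
#' context, effect, sub-level assertions) is not reconstructed.
#'
#' @param row Named character vector as returned by [to_clinvar_row()].
#' @return An [mvld_record()].
#' @export
clinvar_row_to_record <- function(row) {
  stopifnot(all(.clinvar_cols %in% names(row)))
  gv <- function(col) {
    v <- unname(row[[col]])
    if (is.na(v) || !nzchar(v)) NA_character_ else v
  }
  pm <- regmatches(row[["citations"]],
                   gregexpr("PMID:([0-9]+)", row[["citations"]]))[[1L]]
  pmids <- as.integer(sub("PMID:", "", pm))
  cm <- regmatches(row[["condition"]],
                   regexec("^([A-Za-z]+):([^ ]+)( \\((.*)\\))?$",
                           row[["condition"]]))[[1L]]
  ct <- if (length(cm)) {
    structure(list(source = cm[[2L]], code = cm[[3L]],
                   label = if (nzchar(cm[[5L]])) cm[[5L]] else NA_character_),
              class = "mvld_ontology_term")
  }
  sig <- row[["clinical_significance"]]
  biomarker <- trimws(strsplit(sig, ";", fixed = TRUE)[[1L]][[1L]])
  am <- row[["assertion_method"]]
  schema <- trimws(sub(":.*$", "", am))
  label <- trimws(sub("^[^:]*:", "", am))
  label <- trimws(sub(" - .*$", "", label))
  new_mvld_record(
    new_allele_descriptor(
      gv("genome_build"), gv("gene_symbol"), gv("chromosome"),
      as.integer(gv("start")),
      .split_list(unname(row[["refseq_transcripts"]])),
      gv("refseq_protein")
    ),
    new_allele_interpretation(
      gv("somatic_classification"), gv("hgvs_dna"), gv("hgvs_protein"),
      gv("variant_type"), gv("variant_consequence"), pmids
    ),
    new_cancer_interpretation(
      ct, biomarker, character(), NULL,
      list(schema_name = schema, level_label = label), list()
    ),
    stats::setNames(list(), character())
  )
}

#' Write a ClinVar-submission-style table
#'
#' Validates every record under the submission profile first and refuses to
#' write anything if any record has errors (no partial output); otherwise
#' writes one flat tab-separated row per record.
#'
#' @inheritParams write_mvld_table
#' @return Invisibly, the character vector of file lines.
#' @export
write_clinvar_table <- function(records, path = NULL) {
  reps <- lapply(records, validate_record, profile = "submission")
  bad <- which(vapply(reps, function(r) r$error_count > 0L, logical(1)))
  if (length(bad)) {
    stop("records with validation errors cannot be exported: record(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rows <- vapply(records, function(r) {
    paste(to_clinvar_row(r), collapse = "\t")
  }, character(1))
  lines <- c(paste(.clinvar_cols, collapse = "\t"), rows)
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, useBytes = TRUE)
  }
  invisible(lines)
}

# Ontology lookup -----------------------------------------------------------

.cancer_table <- function() {
  if (is.null(.mvld_env$cancer)) {
    path <- system.file("extdata", "cancer_terms.tsv", package = "mvldr",
                        mustWork = TRUE)
    .mvld_env$cancer <- utils::read.delim(path, stringsAsFactors = FALSE,
                                          colClasses = "character")
  }
  .mvld_env$cancer
}

#' The packaged cancer-term subset
#'
#' A small curated subset of cancer types with their Oncotree-style short
#' code, label, and the paired NCI Thesaurus code, shipped as a static file
#' for desk-scale, offline term resolution. It is a fixture, not a live
#' ontology export.
#'
#' @return A data.frame with columns `oncotree_code`, `label`, `ncit_code`.
#' @export
cancer_terms <- function() .cancer_table()

#' Resolve a cancer type against the packaged ontology subset
#'
#' Exact (case-insensitive) code match or case-insensitive label match.
#' Oncotree entries carry their paired NCI Thesaurus code as the
#' `"ncit_code"` attribute of the returned term. An unmatched query is an
#' error with the nearest label suggestions.
#'
#' @param query Code (e.g. `"RGNT"`) or label (e.g. `"melanoma"`).
#' @param source `"Oncotree"` (default) or `"NCIt"`.
#' @return An [ontology_term()].
#' @examples
#' lookup_cancer_term("RGNT", "Oncotree")
#' lookup_cancer_term("melanoma", "Oncotree")
#' @export
lookup_cancer_term <- function(query, source = c("Oncotree", "NCIt")) {
  source <- match.arg(source)
  tab <- .cancer_table()
  q <- trimws(as.character(query)[[1L]])
  code_col <- if (source == "Oncotree") tab$oncotree_code else tab$ncit_code
  hit <- which(toupper(code_col) == toupper(q))
  if (length(hit) == 0L) hit <- which(tolower(tab$label) == tolower(q))
  if (length(hit) >= 1L) {
    hit <- hit[[1L]]
    term <- ontology_term(source, code_col[[hit]], tab$label[[hit]])
    attr(term, "ncit_code") <- tab$ncit_code[[hit]]
    return(term)
  }
  d <- utils::adist(tolower(q), tolower(tab$label), partial = TRUE)
  near <- tab$label[order(d)][1:3]
  stop("unknown cancer term '", query, "'; nearest labels: ",
       paste(near, collapse = ", "), call. = FALSE)
}
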