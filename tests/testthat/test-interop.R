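test_that("TSV round-trip reproduces the records exactly", {
  gen <- generate_records(40, seed = 21)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_mvld_table(gen$records, tf)
  back <- read_mvld_table(tf)
  expect_identical(back$records, gen$records)
  expect_identical(back$report$error_count, 0L)
  # stable byte output across two runs
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_mvld_table(gen$records, tf2)
  expect_identical(readLines(tf), readLines(tf2))
})

test_that("JSON round-trip reproduces the records exactly", {
  gen <- generate_records(40, seed = 22)
  jf <- withr::local_tempfile(fileext = ".json")
  write_mvld_json(gen$records, jf)
  back <- read_mvld_json(jf)
  expect_identical(back$records, gen$records)
})

test_that("the table dialect joins lists with semicolons and keeps column order", {
  r <- make_record(interpretation = make_interpretation(
    pmids = c(12345678L, 23456789L)))
  lines <- write_mvld_table(list(r))
  header <- strsplit(lines[[1]], "\t")[[1]]
  expect_identical(header[seq_along(mvld_columns())], mvld_columns())
  cells <- strsplit(lines[[2]], "\t")[[1]]
  expect_identical(cells[[match("pmids", header)]], "12345678;23456789")
  # empty record list: header-only output
  expect_identical(write_mvld_table(list()),
                   paste(mvld_columns(), collapse = "\t"))
})

test_that("unknown columns are preserved into extensions and survive a cycle", {
  gen <- generate_records(3, seed = 4)
  lines <- write_mvld_table(gen$records)
  lines[[1]] <- paste0(lines[[1]], "\tmy_note")
  lines[-1] <- paste0(lines[-1], "\t", c("keep me", "", "and me"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  back <- read_mvld_table(tf)
  expect_true("IO.UNKNOWN_COLUMN" %in% back$report$findings$rule_id)
  expect_identical(back$records[[1]]$extensions$my_note, "keep me")
  expect_identical(length(back$records[[2]]$extensions), 0L)
  # unknown column content is byte-identical after a full read -> write cycle
  out1 <- write_mvld_table(back$records)
  out2 <- write_mvld_table(read_mvld_table({
    tf2 <- withr::local_tempfile(fileext = ".tsv")
    writeLines(out1, tf2); tf2
  })$records)
  expect_identical(out1, out2)
})

test_that("header problems are hard read errors", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("not\ta\tmvld\tfile", "x\ty\tz\tw"), tf)
  expect_error(read_mvld_table(tf), "missing header")
  lines <- write_mvld_table(generate_records(1, seed = 1)$records)
  writeLines(c(paste0(lines[[1]], "\tgene_name"), paste0(lines[[2]], "\tX")),
             tf)
  expect_error(read_mvld_table(tf), "duplicate")
  partial <- sub("^genome_build\t", "assembly\t", lines[[1]])
  writeLines(c(partial, lines[[2]]), tf)
  expect_error(read_mvld_table(tf), "missing canonical")
})

test_that("unconstructable rows are skipped with a numbered finding", {
  gen <- generate_records(3, seed = 9)
  lines <- write_mvld_table(gen$records)
  cells <- strsplit(lines[[3]], "\t")[[1]]
  cells[[match("dna_position", strsplit(lines[[1]], "\t")[[1]])]] <- "not-a-number"
  lines[[3]] <- paste(cells, collapse = "\t")
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  back <- read_mvld_table(tf)
  expect_length(back$records, 2L)
  skipped <- back$report$findings[back$report$findings$rule_id == "IO.ROW_SKIPPED", ]
  expect_identical(skipped$record, 2L)
  expect_identical(back$records, gen$records[c(1, 3)])
})

test_that("vocabulary violations in a table are findings, the raw term is kept", {
  gen <- generate_records(1, seed = 9)
  lines <- write_mvld_table(gen$records)
  header <- strsplit(lines[[1]], "\t")[[1]]
  cells <- strsplit(lines[[2]], "\t")[[1]]
  cells[[match("biomarker_class", header)]] <- "Theranostic"
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(lines[[1]], paste(cells, collapse = "\t")), tf)
  back <- read_mvld_table(tf)
  expect_length(back$records, 1L)
  expect_identical(back$records[[1]]$cancer$biomarker_class, "Theranostic")
  expect_true("VOC.BIOMARKER_CLASS" %in% back$report$findings$rule_id)
})

test_that("ClinVar export renders condition, significance and assertion method", {
  r <- make_record()
  row <- to_clinvar_row(r)
  expect_identical(unname(row[["condition"]]), "Oncotree:MEL (Melanoma)")
  expect_match(row[["assertion_method"]], "^CanDL: Tier 1 - ")
  expect_match(row[["assertion_method"]],
               "Alteration has matching FDA approved or NCCN recommended therapy",
               fixed = TRUE)
  expect_match(row[["clinical_significance"]],
               "Predictive; sensitive to vemurafenib", fixed = TRUE)
  expect_match(row[["citations"]], "PMID:12068308", fixed = TRUE)
  expect_match(row[["citations"]], "NCT01006980", fixed = TRUE)
  rgnt <- make_record(cancer = make_cancer(cancer_type = ontology_term(
    "Oncotree", "RGNT", "rosette-forming glioneuronal tumor")))
  expect_identical(unname(to_clinvar_row(rgnt)[["condition"]]),
                   "Oncotree:RGNT (rosette-forming glioneuronal tumor)")
})

test_that("records failing validation are refused from ClinVar export", {
  r <- make_record()
  r$descriptor$gene_symbol <- NA_character_
  expect_error(to_clinvar_row(r), "REQ.GENE_NAME")
  # no partial output: the whole corpus is refused before any row is written
  tf <- withr::local_tempfile(fileext = ".tsv")
  expect_error(write_clinvar_table(list(make_record(), r), tf),
               "record\\(s\\) 2")
  expect_false(file.exists(tf))
})

test_that("ClinVar export is lossless for the required MVLD fields", {
  gen <- generate_records(30, seed = 23)
  for (r in gen$records) {
    back <- clinvar_row_to_record(to_clinvar_row(r))
    expect_identical(back$descriptor, r$descriptor)
    expect_identical(back$interpretation, r$interpretation)
    expect_identical(back$cancer$cancer_type, r$cancer$cancer_type)
    expect_identical(back$cancer$biomarker_class, r$cancer$biomarker_class)
    expect_identical(back$cancer$level_of_evidence, r$cancer$level_of_evidence)
  }
})

test_that("cancer terms resolve by code or label against the packaged subset", {
  t1 <- lookup_cancer_term("RGNT", "Oncotree")
  expect_identical(t1$source, "Oncotree")
  expect_identical(t1$code, "RGNT")
  expect_identical(tolower(t1$label), "rosette-forming glioneuronal tumor")
  expect_match(attr(t1, "ncit_code"), "^C[0-9]+$")
  t2 <- lookup_cancer_term("melanoma", "Oncotree")
  expect_identical(t2$code, "MEL")
  t3 <- lookup_cancer_term("C3224", "NCIt")
  expect_identical(t3$source, "NCIt")
  expect_identical(t3$label, "Melanoma")
  err <- tryCatch(lookup_cancer_term("XYZQ", "Oncotree"),
                  error = function(e) conditionMessage(e))
  expect_match(err, "unknown cancer term")
  expect_match(err, "nearest labels")
})
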