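# Independent length-rule oracle: the variant class is determined by the
# ref/alt allele lengths alone.
oracle_variant_type <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == 1L && na == 1L) return("SNV")
  if (nr == 0L) return("INS")
  if (na == 0L) return("DEL")
  "MNV"
}

all_alleles_upto <- function(max_len) {
  pool <- c("A", "C", "G", "T")
  out <- ""
  for (len in seq_len(max_len)) {
    out <- c(out, apply(expand.grid(rep(list(pool), len)), 1L, paste,
                        collapse = ""))
  }
  out
}

test_that("DNA grammar accepts the core edit forms with correct fields", {
  p <- check_dna_hgvs("c.76A>T")
  expect_identical(p$molecule, "c")
  expect_identical(p$kind, "substitution")
  expect_identical(p$start$base, 76L)
  expect_identical(p$ref, "A")
  expect_identical(p$alt, "T")

  p <- check_dna_hgvs("c.76_78delinsTT")
  expect_identical(p$kind, "delins")
  expect_identical(p$start$base, 76L)
  expect_identical(p$end$base, 78L)
  expect_identical(p$alt, "TT")

  p <- check_dna_hgvs("c.88+2T>G")
  expect_identical(p$start$base, 88L)
  expect_identical(p$start$offset, 2L)

  expect_identical(check_dna_hgvs("c.76_77insG")$kind, "insertion")
  expect_identical(check_dna_hgvs("c.76del")$kind, "deletion")
  expect_identical(check_dna_hgvs("c.76_78dup")$kind, "duplication")
  expect_identical(check_dna_hgvs("g.140453136A>T")$molecule, "g")
  expect_identical(check_dna_hgvs("n.76A>T")$molecule, "n")
  expect_identical(check_dna_hgvs("c.*12A>T")$start$anchor, "*")
  expect_identical(check_dna_hgvs("c.-14G>C")$start$anchor, "-")
})

test_that("DNA grammar violations return structured errors, never crashes", {
  expect_true(is_hgvs_error(check_dna_hgvs("76A>T")))          # no prefix
  expect_identical(check_dna_hgvs("76A>T")$code, "no_prefix")
  expect_true(is_hgvs_error(check_dna_hgvs("c.76A>")))         # malformed edit
  expect_true(is_hgvs_error(check_dna_hgvs("c._78del")))       # bad position
  expect_true(is_hgvs_error(check_dna_hgvs("c.12_10del")))     # end < start
  expect_true(is_hgvs_error(check_dna_hgvs("g.100+2A>G")))     # offset on g.
  expect_true(is_hgvs_error(check_dna_hgvs("c.76insA")))       # ins needs range
  expect_true(is_hgvs_error(check_dna_hgvs("c.76_79insA")))    # non-adjacent
  expect_true(is_hgvs_error(check_dna_hgvs("p.V600E")))        # wrong checker
  # exotic constructs get the distinct unsupported error
  expect_identical(check_dna_hgvs("c.[76A>T;88G>C]")$code, "unsupported")
  expect_identical(check_dna_hgvs("c.76_78inv")$code, "unsupported")
  expect_identical(check_dna_hgvs("c.76A=")$code, "unsupported")
})

test_that("protein grammar handles one/three-letter code, fs and predicted forms", {
  p <- check_protein_hgvs("p.V600E")
  expect_identical(p$molecule, "p")
  expect_identical(p$kind, "substitution")
  expect_identical(p$start$base, 600L)
  expect_identical(p$ref, "V")
  expect_identical(p$alt, "E")
  # three-letter input yields the identical parse
  expect_identical(check_protein_hgvs("p.Val600Glu"), p)
  expect_identical(check_protein_hgvs("p.Arg130Ter")$alt, "*")
  expect_true(check_protein_hgvs("p.(V600E)")$predicted)
  fs <- check_protein_hgvs("p.Val600GlufsTer12")
  expect_identical(fs$kind, "frameshift")
  expect_identical(fs$alt, "E")
  expect_identical(fs$term_offset, 12L)
  expect_identical(check_protein_hgvs("p.V600fs")$kind, "frameshift")
  ext <- check_protein_hgvs("p.*110Glnext*17")
  expect_identical(ext$kind, "extension")
  expect_identical(ext$ref, "*")
  expect_identical(ext$term_offset, 17L)

  expect_true(is_hgvs_error(check_protein_hgvs("V600E")))
  expect_true(is_hgvs_error(check_protein_hgvs("p.600E")))
  expect_true(is_hgvs_error(check_protein_hgvs("p.V600")))
  expect_true(is_hgvs_error(check_protein_hgvs("p.Vxl600Glu")))
})

test_that("parsing is total on arbitrary text (fuzz)", {
  set.seed(42)
  pool <- c(letters, LETTERS, 0:9, ".", ">", "_", "+", "-", "*", "(", ")",
            "[", "]", ";", "=")
  for (i in 1:300) {
    s <- paste(sample(pool, sample(1:15, 1), replace = TRUE), collapse = "")
    rd <- check_dna_hgvs(s)
    rp <- check_protein_hgvs(s)
    expect_true(inherits(rd, "mvld_hgvs_parse") || is_hgvs_error(rd))
    expect_true(inherits(rp, "mvld_hgvs_parse") || is_hgvs_error(rp))
  }
  expect_true(is_hgvs_error(check_dna_hgvs(NA_character_)))
  expect_true(is_hgvs_error(check_dna_hgvs("")))
  expect_true(is_hgvs_error(check_protein_hgvs(character())))
})

test_that("serialize/parse round-trips over the grammar-conforming corpus", {
  corpus <- c(
    "c.76A>T", "g.140453136A>T", "n.52G>C", "c.88+2T>G", "c.89-1G>A",
    "c.*12A>T", "c.-14G>C", "c.76del", "c.76delA", "c.76_78del",
    "c.76_78delACT", "c.76dup", "c.76_78dupACT", "c.76_77insG",
    "c.76_77insGATC", "c.76delAinsTT", "c.76_78delinsTT",
    "c.76_78delACTinsG", "p.V600E", "p.R130*", "p.V600fs", "p.V600Efs*12",
    "p.(V600E)", "p.M1ext-5", "p.*110Qext*17"
  )
  for (s in corpus) {
    p <- if (startsWith(s, "p.")) check_protein_hgvs(s) else check_dna_hgvs(s)
    expect_false(is_hgvs_error(p), info = s)
    expect_identical(format_hgvs(p), s, info = s)            # already canonical
    p2 <- if (startsWith(s, "p.")) check_protein_hgvs(format_hgvs(p)) else
      check_dna_hgvs(format_hgvs(p))
    expect_identical(p2, p, info = s)                        # parse o serialize = id
  }
  # non-canonical spellings serialize to the canonical form
  expect_identical(format_hgvs(check_protein_hgvs("p.Val600Glu")), "p.V600E")
  expect_identical(format_hgvs(check_dna_hgvs("c.0076A>T")), "c.76A>T")
})

test_that("infer_variant_type agrees with the length-rule oracle exhaustively", {
  alleles <- all_alleles_upto(3L)   # "", all 1-3-mers over ACGT
  for (ref in alleles) {
    for (alt in alleles) {
      if (ref == "" && alt == "") next
      s <- hgvs_from_alleles(ref, alt, start = 100L)
      p <- check_dna_hgvs(s)
      expect_false(is_hgvs_error(p), info = s)
      expect_identical(infer_variant_type(p), oracle_variant_type(ref, alt),
                       info = s)
    }
  }
})

test_that("variant type maps the edit kinds onto the four-way vocabulary", {
  expect_identical(infer_variant_type(check_dna_hgvs("c.76A>T")), "SNV")
  expect_identical(infer_variant_type(check_dna_hgvs("c.76_78delinsTT")), "MNV")
  expect_identical(infer_variant_type(check_dna_hgvs("c.76_77insG")), "INS")
  expect_identical(infer_variant_type(check_dna_hgvs("c.76del")), "DEL")
  expect_identical(infer_variant_type(check_dna_hgvs("c.76_78dup")), "INS")
  expect_error(infer_variant_type(check_protein_hgvs("p.V600E")),
               "DNA descriptions")
  expect_error(infer_variant_type(check_dna_hgvs("76A>T")), "parse error")
})
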