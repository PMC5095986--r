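# Syntax-level validation of HGVS variant descriptions.
#
# This is a grammar checker, not a normalizer: no transcript or genome
# sequence is ever consulted, so a description can be grammatically valid yet
# biologically wrong. The grammar covers the substitution / del / dup / ins /
# delins core shared by all HGVS versions, intronic-offset and UTR-anchored
# positions on c./n. molecules, and protein substitutions, frameshifts and
# extensions in one- or three-letter code. Exotic constructs (inversions,
# alleles in cis, repeats, mosaicism, predicted-only "=") are rejected with a
# distinct "unsupported HGVS construct" error rather than a generic parse
# failure.
#
# Parsing is total: both checkers return either an `mvld_hgvs_parse` or an
# `mvld_hgvs_error` object and never signal a condition, whatever the input.

.aa3_to_1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Ter = "*"
)

hgvs_error <- function(code, message, span = NA_character_) {
  structure(list(code = code, message = message, span = span),
            class = "mvld_hgvs_error")
}

#' Test for an HGVS parse error
#'
#' [check_dna_hgvs()] and [check_protein_hgvs()] never throw; a
#' grammar-violating input comes back as an error object. This predicate
#' distinguishes the two outcomes.
#'
#' @param x Result of [check_dna_hgvs()] or [check_protein_hgvs()].
#' @return `TRUE` for an `mvld_hgvs_error`.
#' @export
is_hgvs_error <- function(x) inherits(x, "mvld_hgvs_error")

#' @export
print.mvld_hgvs_error <- function(x, ...) {
  cat("<hgvs parse error [", x$code, "]> ", x$message,
      if (!is.na(x$span)) paste0(" (at '", x$span, "')") else "", "\n",
      sep = "")
  invisible(x)
}

new_hgvs_pos <- function(base, offset = 0L, anchor = "") {
  list(anchor = anchor, base = as.integer(base), offset = as.integer(offset))
}

new_hgvs_parse <- function(molecule, kind, start, end = NULL,
                           ref = NA_character_, alt = NA_character_,
                           predicted = FALSE, term_offset = NA_integer_) {
  structure(
    list(molecule = molecule, kind = kind, start = start, end = end,
         ref = ref, alt = alt, predicted = predicted,
         term_offset = as.integer(term_offset)),
    class = "mvld_hgvs_parse"
  )
}

#' @export
print.mvld_hgvs_parse <- function(x, ...) {
  cat("<hgvs parse> ", format_hgvs(x), "  [", x$molecule, ". ", x$kind, "]\n",
      sep = "")
  invisible(x)
}

.unsupported_rx <- "(\\[|\\]|;|=|\\?|inv|con|\\^|\\{)"

.parse_pos <- function(txt) {
  m <- regexec("^([*-]?)([0-9]+)([+-][0-9]+)?$", txt)
  hit <- regmatches(txt, m)[[1L]]
  if (length(hit) == 0L) return(NULL)
  off <- if (nzchar(hit[[4L]])) as.integer(hit[[4L]]) else 0L
  new_hgvs_pos(as.integer(hit[[3L]]), off, hit[[2L]])
}

.fmt_pos <- function(p) {
  paste0(p$anchor, p$base,
         if (p$offset > 0L) paste0("+", p$offset)
         else if (p$offset < 0L) p$offset
         else "")
}

#' Syntax-check a DNA HGVS description
#'
#' Parses a `g.`/`c.`/`n.` HGVS DNA description covering substitutions
#' (`c.76A>T`), deletions (`c.76del`, `c.76_78delACT`), duplications,
#' insertions (`c.76_77insG`) and deletion-insertions (`c.76_78delinsTT`),
#' with intronic-offset (`c.88+2T>G`) and UTR-anchored (`c.*12`, `c.-14`)
#' positions on transcript molecules. Validation is purely syntactic; no
#' reference sequence is consulted.
#'
#' @param x A single string.
#' @return An `mvld_hgvs_parse` on success, otherwise an `mvld_hgvs_error`
#'   naming the offending span (see [is_hgvs_error()]). Never throws.
#' @examples
#' check_dna_hgvs("c.76A>T")
#' check_dna_hgvs("c.76_78delinsTT")
#' is_hgvs_error(check_dna_hgvs("76A>T"))
#' @export
check_dna_hgvs <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    return(hgvs_error("bad_input", "input is not a single string"))
  }
  s <- trimws(x)
  if (!nzchar(s)) return(hgvs_error("bad_input", "empty HGVS description"))
  m <- regexec("^([a-z])\\.(.*)$", s)
  hit <- regmatches(s, m)[[1L]]
  if (length(hit) == 0L) {
    return(hgvs_error("no_prefix",
                      "missing molecule prefix (expected g., c. or n.)", s))
  }
  mol <- hit[[2L]]
  if (mol == "p") {
    return(hgvs_error("wrong_molecule",
                      "p. is a protein description; use check_protein_hgvs()",
                      s))
  }
  if (!mol %in% c("g", "c", "n")) {
    return(hgvs_error("no_prefix",
                      paste0("unknown molecule prefix '", mol, ".'"), mol))
  }
  body <- hit[[3L]]
  if (grepl(.unsupported_rx, body) || grepl("fs", body, fixed = TRUE)) {
    return(hgvs_error("unsupported", "unsupported HGVS construct", body))
  }
  pm <- regexec("^([*-]?[0-9]+(?:[+-][0-9]+)?)(?:_([*-]?[0-9]+(?:[+-][0-9]+)?))?(.*)$",
                body)
  ph <- regmatches(body, pm)[[1L]]
  if (length(ph) == 0L || !nzchar(ph[[2L]])) {
    return(hgvs_error("bad_position", "malformed position", body))
  }
  start <- .parse_pos(ph[[2L]])
  if (is.null(start)) return(hgvs_error("bad_position", "malformed position", ph[[2L]]))
  end <- NULL
  if (nzchar(ph[[3L]])) {
    end <- .parse_pos(ph[[3L]])
    if (is.null(end)) return(hgvs_error("bad_position", "malformed position", ph[[3L]]))
  }
  if (mol == "g") {
    offs <- c(start$offset, if (!is.null(end)) end$offset else 0L)
    anch <- c(start$anchor, if (!is.null(end)) end$anchor else "")
    if (any(offs != 0L) || any(nzchar(anch))) {
      return(hgvs_error("bad_position",
                        "intronic offsets and UTR anchors are only permitted on c./n. molecules",
                        body))
    }
  }
  if (!is.null(end) && start$anchor == "" && end$anchor == "" &&
      start$offset == 0L && end$offset == 0L && end$base < start$base) {
    return(hgvs_error("bad_position",
                      paste0("range end ", end$base, " precedes start ", start$base),
                      body))
  }
  edit <- ph[[4L]]
  if (!nzchar(edit)) return(hgvs_error("bad_edit", "missing edit", body))

  if (grepl("^[ACGT]>[ACGT]$", edit)) {
    if (!is.null(end)) {
      return(hgvs_error("bad_edit",
                        "a substitution describes a single position, not a range",
                        body))
    }
    return(new_hgvs_parse(mol, "substitution", start,
                          ref = substr(edit, 1L, 1L),
                          alt = substr(edit, 3L, 3L)))
  }
  dm <- regmatches(edit, regexec("^del([ACGT]*)ins([ACGT]+)$", edit))[[1L]]
  if (length(dm)) {
    return(new_hgvs_parse(mol, "delins", start, end,
                          ref = if (nzchar(dm[[2L]])) dm[[2L]] else NA_character_,
                          alt = dm[[3L]]))
  }
  dm <- regmatches(edit, regexec("^del([ACGT]*)$", edit))[[1L]]
  if (length(dm)) {
    return(new_hgvs_parse(mol, "deletion", start, end,
                          ref = if (nzchar(dm[[2L]])) dm[[2L]] else NA_character_))
  }
  dm <- regmatches(edit, regexec("^dup([ACGT]*)$", edit))[[1L]]
  if (length(dm)) {
    return(new_hgvs_parse(mol, "duplication", start, end,
                          ref = if (nzchar(dm[[2L]])) dm[[2L]] else NA_character_))
  }
  dm <- regmatches(edit, regexec("^ins([ACGT]+)$", edit))[[1L]]
  if (length(dm)) {
    if (is.null(end)) {
      return(hgvs_error("bad_edit",
                        "an insertion requires the two flanking positions (start_end)",
                        body))
    }
    if (start$anchor == "" && end$anchor == "" &&
        start$offset == 0L && end$offset == 0L &&
        end$base != start$base + 1L) {
      return(hgvs_error("bad_edit",
                        "insertion positions must be adjacent (end = start + 1)",
                        body))
    }
    return(new_hgvs_parse(mol, "insertion", start, end, alt = dm[[2L]]))
  }
  hgvs_error("bad_edit", "malformed edit", edit)
}

.parse_aa <- function(txt) {
  # one leading amino acid, three-letter first; returns c(one_letter, rest)
  m3 <- regmatches(txt, regexec(
    "^(Ala|Arg|Asn|Asp|Cys|Gln|Glu|Gly|His|Ile|Leu|Lys|Met|Phe|Pro|Ser|Thr|Trp|Tyr|Val|Ter)(.*)$",
    txt))[[1L]]
  if (length(m3)) return(c(unname(.aa3_to_1[[m3[[2L]]]]), m3[[3L]]))
  m1 <- regmatches(txt, regexec("^([ACDEFGHIKLMNPQRSTVWY*])(.*)$", txt))[[1L]]
  if (length(m1)) return(c(m1[[2L]], m1[[3L]]))
  NULL
}

#' Syntax-check a protein HGVS description
#'
#' Parses a `p.`-prefixed protein description: substitutions in one- or
#' three-letter amino-acid code (`p.V600E`, `p.Val600Glu`, nonsense
#' `p.R130*` / `p.Arg130Ter`), frameshifts (`p.V600fs`,
#' `p.Val600GlufsTer12`), extensions (`p.*110Glnext*17`) and parenthesized
#' predicted forms (`p.(V600E)`). Amino acids are normalized to one-letter
#' code internally, so `p.Val600Glu` and `p.V600E` yield the same parse.
#'
#' @param x A single string.
#' @return An `mvld_hgvs_parse` on success, otherwise an `mvld_hgvs_error`.
#'   Never throws.
#' @examples
#' check_protein_hgvs("p.V600E")
#' identical(check_protein_hgvs("p.Val600Glu"), check_protein_hgvs("p.V600E"))
#' @export
check_protein_hgvs <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    return(hgvs_error("bad_input", "input is not a single string"))
  }
  s <- trimws(x)
  if (!nzchar(s)) return(hgvs_error("bad_input", "empty HGVS description"))
  if (!startsWith(s, "p.")) {
    return(hgvs_error("no_prefix", "missing molecule prefix (expected p.)", s))
  }
  body <- substr(s, 3L, nchar(s))
  predicted <- FALSE
  if (startsWith(body, "(")) {
    if (!endsWith(body, ")")) {
      return(hgvs_error("bad_edit", "unbalanced parentheses", body))
    }
    predicted <- TRUE
    body <- substr(body, 2L, nchar(body) - 1L)
  }
  if (grepl(.unsupported_rx, body)) {
    return(hgvs_error("unsupported", "unsupported HGVS construct", body))
  }
  aa <- .parse_aa(body)
  if (is.null(aa)) {
    return(hgvs_error("bad_aa", "unknown amino-acid code", body))
  }
  ref <- aa[[1L]]; rest <- aa[[2L]]
  pm <- regmatches(rest, regexec("^([0-9]+)(.*)$", rest))[[1L]]
  if (length(pm) == 0L) {
    return(hgvs_error("bad_position", "malformed position", rest))
  }
  start <- new_hgvs_pos(as.integer(pm[[2L]]))
  tail <- pm[[3L]]
  if (!nzchar(tail)) {
    return(hgvs_error("bad_edit", "missing edit after position", body))
  }

  # frameshift / extension: optional new amino acid, then fs/ext keyword
  alt <- NA_character_
  kw <- tail
  aa2 <- .parse_aa(tail)
  if (!is.null(aa2) && (startsWith(aa2[[2L]], "fs") || startsWith(aa2[[2L]], "ext"))) {
    alt <- aa2[[1L]]
    kw <- aa2[[2L]]
  }
  if (startsWith(kw, "fs")) {
    suff <- substr(kw, 3L, nchar(kw))
    to <- NA_integer_
    if (nzchar(suff)) {
      tm <- regmatches(suff, regexec("^(?:\\*|Ter)([0-9]+)$", suff))[[1L]]
      if (length(tm) == 0L) {
        return(hgvs_error("bad_edit", "malformed frameshift suffix", kw))
      }
      to <- as.integer(tm[[2L]])
    }
    return(new_hgvs_parse("p", "frameshift", start, ref = ref, alt = alt,
                          predicted = predicted, term_offset = to))
  }
  if (startsWith(kw, "ext")) {
    suff <- substr(kw, 4L, nchar(kw))
    to <- NA_integer_
    if (nzchar(suff)) {
      tm <- regmatches(suff, regexec("^(\\*|-)([0-9]+)$", suff))[[1L]]
      if (length(tm) == 0L) {
        return(hgvs_error("bad_edit", "malformed extension suffix", kw))
      }
      to <- as.integer(tm[[3L]])
      if (tm[[2L]] == "-") to <- -to
    }
    return(new_hgvs_parse("p", "extension", start, ref = ref, alt = alt,
                          predicted = predicted, term_offset = to))
  }
  # plain substitution: tail must be exactly one amino acid
  aa3 <- .parse_aa(tail)
  if (is.null(aa3)) {
    return(hgvs_error("bad_aa", "unknown amino-acid code", tail))
  }
  if (nzchar(aa3[[2L]])) {
    return(hgvs_error("bad_edit", "trailing text after substitution", aa3[[2L]]))
  }
  new_hgvs_parse("p", "substitution", start, ref = ref, alt = aa3[[1L]],
                 predicted = predicted)
}

#' Serialize an HGVS parse back to its canonical string
#'
#' The canonical form uses one-letter amino-acid codes, no leading zeros and
#' the `del<seq>ins<seq>` spelling for deletion-insertions. For every
#' grammar-conforming string `s`, `format_hgvs(check_dna_hgvs(s))` is the
#' canonical form of `s`, and re-parsing the canonical form reproduces the
#' parse exactly.
#'
#' @param parse An `mvld_hgvs_parse`.
#' @return A single string.
#' @export
format_hgvs <- function(parse) {
  stopifnot(inherits(parse, "mvld_hgvs_parse"))
  if (parse$molecule == "p") {
    core <- paste0(
      parse$ref, parse$start$base,
      switch(parse$kind,
        substitution = parse$alt,
        frameshift = paste0(
          if (!is.na(parse$alt)) parse$alt else "", "fs",
          if (!is.na(parse$term_offset)) paste0("*", parse$term_offset) else ""
        ),
        extension = paste0(
          if (!is.na(parse$alt)) parse$alt else "", "ext",
          if (!is.na(parse$term_offset)) {
            if (parse$term_offset < 0L) parse$term_offset
            else paste0("*", parse$term_offset)
          } else ""
        ),
        stop("unsupported protein edit kind: ", parse$kind)
      )
    )
    if (parse$predicted) core <- paste0("(", core, ")")
    return(paste0("p.", core))
  }
  pos <- .fmt_pos(parse$start)
  if (!is.null(parse$end)) pos <- paste0(pos, "_", .fmt_pos(parse$end))
  edit <- switch(parse$kind,
    substitution = paste0(parse$ref, ">", parse$alt),
    deletion = paste0("del", if (!is.na(parse$ref)) parse$ref else ""),
    duplication = paste0("dup", if (!is.na(parse$ref)) parse$ref else ""),
    insertion = paste0("ins", parse$alt),
    delins = paste0("del", if (!is.na(parse$ref)) parse$ref else "",
                    "ins", parse$alt),
    stop("unsupported DNA edit kind: ", parse$kind)
  )
  paste0(parse$molecule, ".", pos, edit)
}

#' Infer the MVLD variant type from a DNA HGVS parse
#'
#' Maps a parsed DNA edit onto the four-way MVLD variant-type vocabulary:
#' a one-base substitution is an SNV; a multi-base substitution or any
#' deletion-insertion (the "deletion plus substitution" complex case) is an
#' MNV; a pure insertion or duplication is an INS; a pure deletion is a DEL.
#'
#' @param parse An `mvld_hgvs_parse` for a DNA molecule (`g.`/`c.`/`n.`).
#' @return One of `"SNV"`, `"MNV"`, `"INS"`, `"DEL"`.
#' @examples
#' infer_variant_type(check_dna_hgvs("c.76A>T"))
#' infer_variant_type(check_dna_hgvs("c.76_78delinsTT"))
#' @export
infer_variant_type <- function(parse) {
  if (is_hgvs_error(parse)) {
    stop("cannot infer a variant type from a parse error: ", parse$message,
         call. = FALSE)
  }
  stopifnot(inherits(parse, "mvld_hgvs_parse"))
  if (parse$molecule == "p") {
    stop("variant type is defined on DNA descriptions, not protein",
         call. = FALSE)
  }
  switch(parse$kind,
    substitution = {
      if (!is.na(parse$ref) && !is.na(parse$alt) &&
          nchar(parse$ref) == 1L && nchar(parse$alt) == 1L) "SNV" else "MNV"
    },
    delins = "MNV",
    insertion = "INS",
    duplication = "INS",
    deletion = "DEL",
    stop("no variant type for edit kind: ", parse$kind)
  )
}

#' Compose a canonical DNA HGVS string from explicit alleles
#'
#' Builds the canonical HGVS description of the edit replacing `ref` with
#' `alt` at `start`: a one-for-one base change becomes a substitution, an
#' empty `ref` an insertion (between `start` and `start + 1`), an empty
#' `alt` a deletion, and anything else a deletion-insertion. Useful for
#' generating grammatically valid test corpora.
#'
#' @param ref Reference allele (string over ACGT, possibly `""`).
#' @param alt Alternate allele (string over ACGT, possibly `""`).
#' @param start 1-based start position.
#' @param molecule `"c"`, `"g"` or `"n"`.
#' @return A single HGVS string accepted by [check_dna_hgvs()].
#' @examples
#' hgvs_from_alleles("A", "T", 76)      # "c.76A>T"
#' hgvs_from_alleles("", "G", 76)       # "c.76_77insG"
#' hgvs_from_alleles("ACT", "TT", 76)   # "c.76_78delACTinsTT"
#' @export
hgvs_from_alleles <- function(ref, alt, start = 100L, molecule = "c") {
  stopifnot(molecule %in% c("g", "c", "n"))
  ref <- toupper(ref); alt <- toupper(alt)
  if (!grepl("^[ACGT]*$", ref) || !grepl("^[ACGT]*$", alt)) {
    stop("alleles must be strings over ACGT", call. = FALSE)
  }
  start <- as.integer(start)
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == 0L && na == 0L) stop("ref and alt cannot both be empty", call. = FALSE)
  pre <- paste0(molecule, ".")
  if (nr == 1L && na == 1L) return(paste0(pre, start, ref, ">", alt))
  if (nr == 0L) return(paste0(pre, start, "_", start + 1L, "ins", alt))
  span <- if (nr == 1L) as.character(start) else paste0(start, "_", start + nr - 1L)
  if (na == 0L) return(paste0(pre, span, "del", ref))
  paste0(pre, span, "del", ref, "ins", alt)
}
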