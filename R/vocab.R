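# Controlled vocabularies for every enumerated MVLD field.
#
# Term lists are stored in their canonical order and capitalization; matching
# is case-insensitive with a small declared synonym table, and the canonical
# spelling is always what gets stored and written.

.mvld_vocab <- list(
  somatic_classification = c("Confirmed somatic", "Confirmed germline", "Unknown"),
  variant_type = c("SNV", "MNV", "INS", "DEL"),
  variant_consequence = c(
    "Nonsense", "Missense", "Silent", "Frame shift", "In-frame",
    "3UTR", "5UTR", "Splice", "Splice-region", "Intronic",
    "Upstream", "Downstream"
  ),
  biomarker_class = c("Diagnostic", "Prognostic", "Predictive"),
  effect = c(
    "resistant", "responsive", "not-responsive", "sensitive",
    "reduced sensitivity", "other"
  ),
  chromosome = c(as.character(1:22), "X", "Y", "MT"),
  ontology_source = c("NCIt", "Oncotree", "local")
)

# Declared synonyms, keyed by folded form (see .fold_term). Sequence Ontology
# spellings and common free-text variants map onto the canonical terms.
.mvld_synonyms <- list(
  variant_consequence = c(
    "3'utr" = "3UTR", "three prime utr" = "3UTR", "3 prime utr" = "3UTR",
    "5'utr" = "5UTR", "five prime utr" = "5UTR", "5 prime utr" = "5UTR",
    "frameshift" = "Frame shift", "frameshift variant" = "Frame shift",
    "inframe" = "In-frame",
    "splice region" = "Splice-region",
    "stop gained" = "Nonsense",
    "synonymous" = "Silent"
  ),
  effect = c(
    "not responsive" = "not-responsive",
    "reduced-sensitivity" = "reduced sensitivity"
  ),
  chromosome = c("m" = "MT", "mt" = "MT"),
  ontology_source = c(
    "nci thesaurus" = "NCIt", "ncit" = "NCIt", "nci" = "NCIt",
    "oncotree" = "Oncotree", "local" = "local"
  )
)

# Case/whitespace/underscore fold used for matching only; canonical
# capitalization is recovered from the vocabulary itself.
.fold_term <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("_+", " ", x)
  gsub("[ \t]+", " ", x)
}

#' Canonical term list for an enumerated MVLD field
#'
#' Returns the controlled vocabulary for one of the enumerated MVLD fields,
#' in canonical order and capitalization. The somatic classification,
#' variant type, variant consequence, biomarker class and effect
#' vocabularies are the standard's published term sets; `chromosome` and
#' `ontology_source` are the allowed value sets of the corresponding
#' descriptor fields.
#'
#' @param field_name Name of an enumerated MVLD field, one of
#'   `"somatic_classification"`, `"variant_type"`, `"variant_consequence"`,
#'   `"biomarker_class"`, `"effect"`, `"chromosome"`, `"ontology_source"`.
#' @return Character vector of canonical terms, stable across calls.
#' @examples
#' vocabulary("biomarker_class")
#' vocabulary("variant_type")
#' @export
vocabulary <- function(field_name) {
  stopifnot(is.character(field_name), length(field_name) == 1L)
  if (!field_name %in% names(.mvld_vocab)) {
    stop("no such enumerated field: '", field_name, "' (known fields: ",
         paste(names(.mvld_vocab), collapse = ", "), ")", call. = FALSE)
  }
  .mvld_vocab[[field_name]]
}

#' Normalize a raw term to its canonical vocabulary spelling
#'
#' Matches `raw` against the controlled vocabulary of `field_name`,
#' case-insensitively and after trimming whitespace and folding underscores,
#' and returns the canonical spelling. Declared synonyms (for example
#' `"3'UTR"` for `"3UTR"`, `"not responsive"` for `"not-responsive"`) are
#' accepted. An unmatched term is an error carrying the nearest candidate
#' terms.
#'
#' @param field_name Name of an enumerated MVLD field (see [vocabulary()]).
#' @param raw Raw input term.
#' @return The canonical term, a length-one character vector.
#' @examples
#' normalize_term("biomarker_class", "predictive")
#' normalize_term("effect", " Reduced Sensitivity ")
#' @export
normalize_term <- function(field_name, raw) {
  terms <- vocabulary(field_name)
  stopifnot(is.character(raw), length(raw) == 1L)
  key <- .fold_term(raw)
  hit <- match(key, .fold_term(terms))
  if (!is.na(hit)) return(terms[[hit]])
  syn <- .mvld_synonyms[[field_name]]
  if (!is.null(syn) && key %in% names(syn)) return(unname(syn[[key]]))
  d <- utils::adist(key, .fold_term(terms))
  near <- terms[order(d)][seq_len(min(3L, length(terms)))]
  stop("unknown term '", raw, "' for field '", field_name,
       "'; nearest candidates: ", paste(near, collapse = ", "),
       call. = FALSE)
}

# Inert annotation table relating consequence terms to Sequence Ontology
# accessions. Provided for convenience only; never consulted by validation.
#' Sequence Ontology annotations for the consequence vocabulary
#'
#' An inert lookup table pairing each canonical variant-consequence term with
#' the closest Sequence Ontology term and accession. Informational only: no
#' validation rule consults it.
#'
#' @return A data.frame with columns `consequence`, `so_id`, `so_label`.
#' @export
consequence_so_annotations <- function() {
  data.frame(
    consequence = .mvld_vocab$variant_consequence,
    so_id = c(
      "SO:0001587", "SO:0001583", "SO:0001819", "SO:0001589", "SO:0001650",
      "SO:0001624", "SO:0001623", "SO:0001629", "SO:0001630", "SO:0001627",
      "SO:0001631", "SO:0001632"
    ),
    so_label = c(
      "stop_gained", "missense_variant", "synonymous_variant",
      "frameshift_variant", "inframe_variant",
      "3_prime_UTR_variant", "5_prime_UTR_variant",
      "splice_site_variant", "splice_region_variant", "intron_variant",
      "upstream_gene_variant", "downstream_gene_variant"
    ),
    stringsAsFactors = FALSE
  )
}
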