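# CanDL four-tier level-of-evidence assignment.
#
# The tier sentences are verbatim from the CanDL scheme and live in one
# table; assign_tier() returns the strongest (numerically smallest)
# applicable tier, so adding evidence can only strengthen the result.

.candl_sentences <- c(
  "Alteration has matching FDA approved or NCCN recommended therapy",
  "Alteration has matching therapy based on evidence from clinical trials, case reports, or exceptional responders",
  "Alteration predicts for response or resistance to therapy based on evidence from pre-clinical data (in vitro or in vivo models)",
  "Alteration is a putative oncogenic driver based on functional activation of a pathway"
)

#' The CanDL tier table
#'
#' The four-tier CanDL somatic interpretation scheme, each tier with its
#' short structured sentence describing the clinical utility of the variant.
#'
#' @return A data.frame with columns `tier` (1-4), `label` (`"Tier 1"`..)
#'   and `sentence` (the verbatim structured sentence).
#' @export
candl_tiers <- function() {
  data.frame(tier = 1:4, label = paste("Tier", 1:4),
             sentence = .candl_sentences, stringsAsFactors = FALSE)
}

#' Assign a CanDL tier from evidence assertions and therapy flags
#'
#' Returns the strongest applicable tier: a matching FDA-approved or
#' NCCN-recommended therapy is Tier 1; clinical-trial, retrospective-study
#' or case-report/exceptional-responder evidence (sub-level categories 1, 2
#' and 4) is Tier 2; preclinical evidence (category 5) is Tier 3; a putative
#' pathway driver or inferential/in-silico evidence (category 6) is Tier 4.
#' Expert opinion (category 3) carries no tier of its own. The `supporting`
#' element lists every assertion and flag matching the returned tier.
#'
#' @param evidence List of [evidence_assertion()] objects.
#' @param fda_approved,nccn_recommended Does the alteration have a matching
#'   FDA-approved / NCCN-recommended therapy? Caller-supplied flags; no drug
#'   registry is consulted.
#' @param pathway_driver Is the alteration a putative oncogenic driver based
#'   on functional activation of a pathway?
#' @return An object of class `mvld_tier` with elements `schema_name`
#'   (`"CanDL"`), `tier`, `level_label`, `sentence` (the verbatim tier
#'   sentence) and `supporting`.
#' @examples
#' assign_tier(fda_approved = TRUE)
#' assign_tier(list(evidence_assertion(5, pmids = 123)))   # Tier 3
#' @export
assign_tier <- function(evidence = list(), fda_approved = FALSE,
                        nccn_recommended = FALSE, pathway_driver = FALSE) {
  if (inherits(evidence, "mvld_evidence_assertion")) evidence <- list(evidence)
  stopifnot(is.list(evidence),
            all(vapply(evidence, inherits, logical(1),
                       "mvld_evidence_assertion")))
  cats <- vapply(evidence, function(a) a$category, integer(1))
  flags <- character()
  if (isTRUE(fda_approved)) flags <- c(flags, "fda_approved")
  if (isTRUE(nccn_recommended)) flags <- c(flags, "nccn_recommended")

  tier <- NA_integer_
  supporting <- list()
  if (length(flags)) {
    tier <- 1L
    supporting <- as.list(flags)
  } else if (any(cats %in% c(1L, 2L, 4L))) {
    tier <- 2L
    supporting <- evidence[cats %in% c(1L, 2L, 4L)]
  } else if (any(cats == 5L)) {
    tier <- 3L
    supporting <- evidence[cats == 5L]
  } else if (isTRUE(pathway_driver) || any(cats == 6L)) {
    tier <- 4L
    supporting <- c(if (isTRUE(pathway_driver)) list("pathway_driver"),
                    evidence[cats == 6L])
  }
  if (is.na(tier)) {
    stop("no tierable evidence: supply a therapy flag, trial/case-report, ",
         "preclinical or inferential evidence", call. = FALSE)
  }
  structure(
    list(schema_name = "CanDL", tier = tier,
         level_label = paste("Tier", tier),
         sentence = .candl_sentences[[tier]],
         supporting = supporting),
    class = "mvld_tier"
  )
}

#' @export
print.mvld_tier <- function(x, ...) {
  cat("<CanDL ", x$level_label, "> ", x$sentence, "\n  (",
      length(x$supporting), " supporting item(s))\n", sep = "")
  invisible(x)
}

#' Categorize an evidence assertion into its sub-level (1-6)
#'
#' Applies the sub-level scheme: a populated expert triple is expert opinion
#' (3); populated in silico program names are inferential (6); a populated
#' clinical-trial id is a prospective (1) or retrospective (2) trial/study
#' depending on the `prospective` flag; otherwise the category follows the
#' declared hint keyword (case report 4, preclinical 5, inferential 6).
#'
#' @param assertion An [evidence_assertion()] with at least one of
#'   trial ids, PMIDs, expert or tools populated.
#' @param prospective,retrospective Is the cited trial/study prospective or
#'   retrospective? Used only when trial ids are present; a trial that is
#'   not flagged prospective is categorized retrospective.
#' @param hint For PMID-only assertions, one of `"case report"`,
#'   `"preclinical"`, `"inferential"`.
#' @return An integer in 1..6.
#' @examples
#' categorize_sublevel(evidence_assertion(1, trial_ids = "NCT00000001"),
#'                     prospective = TRUE)
#' categorize_sublevel(evidence_assertion(6, tools = "PolyPhen"))
#' @export
categorize_sublevel <- function(assertion, prospective = FALSE,
                                retrospective = FALSE, hint = NULL) {
  stopifnot(inherits(assertion, "mvld_evidence_assertion"))
  if (!is.null(assertion$expert)) return(3L)
  if (length(assertion$tools)) return(6L)
  if (length(assertion$trial_ids)) return(if (isTRUE(prospective)) 1L else 2L)
  if (length(assertion$pmids) && !is.null(hint)) {
    hit <- match(.fold_term(hint),
                 c("case report", "case reports", "preclinical",
                   "published preclinical data", "inferential"))
    if (!is.na(hit)) return(c(4L, 4L, 5L, 5L, 6L)[[hit]])
  }
  stop("uncategorizable evidence item: no expert/tools/trial ids, and no ",
       "usable hint for a PMID-only assertion", call. = FALSE)
}
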