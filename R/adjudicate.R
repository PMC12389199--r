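RESPONSE_LEVELS <- c("none", "adr", "inefficacy", "adr_and_inefficacy",
                     "unknown")

#' Split a medication trial into its ADR/inefficacy events
#'
#' A trial whose response is the combined category (both an ADR and an
#' inefficacy during a single medication course) contributes one event of
#' each type; `none` and `unknown` responses contribute no events.
#'
#' @param trial A list or one-row data frame with at least `participant_id`,
#'   `medication` and `response`.
#' @return A data frame with one row per event: `participant_id`,
#'   `medication`, `event_type` (`"adr"` or `"inefficacy"`).
#' @examples
#' explode_events(list(participant_id = "P1", medication = "sertraline",
#'                     response = "adr_and_inefficacy"))
#' @export
explode_events <- function(trial) {
  response <- as.character(trial$response)
  if (!response %in% RESPONSE_LEVELS) {
    stop("unknown response category '", response, "'", call. = FALSE)
  }
  types <- switch(response,
                  adr = "adr",
                  inefficacy = "inefficacy",
                  adr_and_inefficacy = c("adr", "inefficacy"),
                  character())
  data.frame(participant_id = rep(as.character(trial$participant_id),
                                  length(types)),
             medication = rep(as.character(trial$medication), length(types)),
             event_type = types,
             stringsAsFactors = FALSE)
}

#' Adjudicate one ADR or inefficacy event against the guidelines
#'
#' An ADR event is consistent with the metabolizer phenotype when, for any
#' gene mapped to the medication, the guideline rule for the participant's
#' phenotype carries an explicit increased-ADR-risk flag; an inefficacy
#' event is consistent when the corresponding therapeutic-failure flag is
#' set. Medications without a guideline and Indeterminate phenotypes yield a
#' `not_evaluable` verdict, which can never be counted as consistent.
#'
#' @param event A list or one-row data frame with `participant_id`,
#'   `medication`, `event_type`.
#' @param phenotype_calls Named list of phenotype calls (or strings) for
#'   both genes.
#' @param kb A `pgx_kb`.
#' @return A one-row data frame: `participant_id`, `medication`,
#'   `event_type`, `verdict` (`consistent`/`inconsistent`/`not_evaluable`),
#'   `gene_basis` (gene + phenotype supporting a consistent verdict, else
#'   `NA`), and `rationale` naming the rule applied.
#' @examples
#' kb <- load_knowledge_base()
#' adjudicate_event(list(participant_id = "P1", medication = "sertraline",
#'                       event_type = "adr"),
#'                  list(CYP2C19 = "PM", CYP2D6 = "NM"), kb)
#' @export
adjudicate_event <- function(event, phenotype_calls, kb) {
  stopifnot(event$event_type %in% c("adr", "inefficacy"))
  med <- normalize_medication(event$medication, kb)
  rules <- kb_lookup(kb, med, phenotype_calls)
  verdict_row <- function(verdict, gene_basis, rationale) {
    data.frame(participant_id = as.character(event$participant_id),
               medication = med,
               event_type = as.character(event$event_type),
               verdict = verdict, gene_basis = gene_basis,
               rationale = rationale, stringsAsFactors = FALSE)
  }
  if (inherits(rules, "pgx_no_guideline")) {
    return(verdict_row("not_evaluable", NA_character_,
                       "no clinical PGx guideline for this medication"))
  }
  if (all(vapply(rules, function(r) r$recommendation == "not_evaluable",
                 TRUE))) {
    return(verdict_row("not_evaluable", NA_character_,
                       "indeterminate metabolizer phenotype"))
  }
  flag <- if (event$event_type == "adr") "adr_risk" else "inefficacy_risk"
  risky <- Filter(function(r) isTRUE(r[[flag]]), rules)
  if (length(risky) > 0) {
    r <- risky[[1]]
    verdict_row("consistent", paste(r$gene, r$phenotype),
                paste0(r$source, " rule for ", med, " flags ", r$gene, " ",
                       r$phenotype, " with increased ",
                       if (flag == "adr_risk") "ADR risk"
                       else "risk of therapeutic failure"))
  } else {
    phenos <- vapply(rules, function(r) paste(r$gene, r$phenotype), "")
    verdict_row("inconsistent", NA_character_,
                paste0("no guideline risk flag for ",
                       paste(phenos, collapse = " or "), " and ", med))
  }
}

#' Adjudicate every event in a cohort
#'
#' Translates each participant, explodes trials into events, and adjudicates
#' each event (vectorized per medication, equivalent to applying
#' [adjudicate_event()] to every event). Every reported event appears in the
#' output, including `not_evaluable` events for medications without
#' guidelines, so that denominators reflect all reported outcomes while only
#' explicit guideline-flagged phenotypes can be numerators.
#'
#' @param cohort A `pgx_cohort`.
#' @param kb A `pgx_kb`.
#' @param translated Optional pre-computed [translate_cohort()] output.
#' @return A data frame of consistency verdicts, one row per event.
#' @export
adjudicate_cohort <- function(cohort, kb, translated = NULL) {
  stopifnot(inherits(cohort, "pgx_cohort"))
  if (is.null(translated)) translated <- translate_cohort(cohort)
  trials <- cohort$trials
  empty <- data.frame(participant_id = character(), medication = character(),
                      event_type = character(), verdict = character(),
                      gene_basis = character(), rationale = character(),
                      stringsAsFactors = FALSE)
  if (nrow(trials) == 0) return(empty)
  is_adr <- trials$response %in% c("adr", "adr_and_inefficacy")
  is_ineff <- trials$response %in% c("inefficacy", "adr_and_inefficacy")
  events <- data.frame(
    participant_id = c(trials$participant_id[is_adr],
                       trials$participant_id[is_ineff]),
    medication = c(trials$medication[is_adr], trials$medication[is_ineff]),
    event_type = rep(c("adr", "inefficacy"), c(sum(is_adr), sum(is_ineff))),
    stringsAsFactors = FALSE)
  if (nrow(events) == 0) return(empty)
  events$medication <- vapply(events$medication, normalize_medication, "",
                              kb = kb)
  idx <- match(events$participant_id, translated$participant_id)
  pheno <- list(CYP2C19 = translated$cyp2c19_phenotype[idx],
                CYP2D6 = translated$cyp2d6_phenotype[idx])
  n <- nrow(events)
  verdict <- character(n)
  gene_basis <- rep(NA_character_, n)
  rationale <- character(n)
  gm <- guideline_medications(kb)
  for (med in unique(events$medication)) {
    msel <- events$medication == med
    if (!med %in% gm) {
      verdict[msel] <- "not_evaluable"
      rationale[msel] <- "no clinical PGx guideline for this medication"
      next
    }
    genes <- kb$gene_map[[med]]$gene
    for (type in c("adr", "inefficacy")) {
      sel <- which(msel & events$event_type == type)
      if (length(sel) == 0) next
      flag <- if (type == "adr") "adr_risk" else "inefficacy_risk"
      consistent <- rep(FALSE, length(sel))
      basis <- rep(NA_character_, length(sel))
      all_indeterminate <- rep(TRUE, length(sel))
      other <- rep("", length(sel))
      for (gene in genes) {
        ph <- pheno[[gene]][sel]
        all_indeterminate <- all_indeterminate & ph == "Indeterminate"
        flagged <- risk_phenotypes(kb, med, gene, flag)
        hit <- ph %in% flagged & !consistent
        basis[hit] <- paste(gene, ph[hit])
        consistent <- consistent | ph %in% flagged
        other <- paste0(other, ifelse(nzchar(other), " or ", ""), gene, " ",
                        ph)
      }
      verdict[sel] <- ifelse(all_indeterminate, "not_evaluable",
                             ifelse(consistent, "consistent", "inconsistent"))
      gene_basis[sel] <- ifelse(verdict[sel] == "consistent", basis,
                                NA_character_)
      risk_text <- if (flag == "adr_risk") "ADR risk"
                   else "risk of therapeutic failure"
      rationale[sel] <- ifelse(
        verdict[sel] == "not_evaluable",
        "indeterminate metabolizer phenotype",
        ifelse(verdict[sel] == "consistent",
               paste0(rule_source(kb, med, basis), " rule for ", med,
                      " flags ", basis, " with increased ", risk_text),
               paste0("no guideline risk flag for ", other, " and ", med)))
    }
  }
  data.frame(participant_id = events$participant_id,
             medication = events$medication,
             event_type = events$event_type, verdict = verdict,
             gene_basis = gene_basis, rationale = rationale,
             stringsAsFactors = FALSE)
}

# source guideline for a "GENE PHENOTYPE" basis string (vectorized)
rule_source <- function(kb, med, basis) {
  vapply(basis, function(b) {
    if (is.na(b)) return(NA_character_)
    parts <- strsplit(b, " ", fixed = TRUE)[[1]]
    hit <- Filter(function(r) r$medication == med && r$gene == parts[1] &&
                    r$phenotype == parts[2], kb$rules)
    if (length(hit) > 0) hit[[1]]$source else "default"
  }, "", USE.NAMES = FALSE)
}

#' Write consistency verdicts as TSV
#'
#' @param verdicts Data frame from [adjudicate_cohort()].
#' @param path Output file path.
#' @export
write_verdicts <- function(verdicts, path) {
  utils::write.table(verdicts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
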