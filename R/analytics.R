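#' Round half away from zero
#'
#' Report percentages are rounded half-up (5 rounds away from zero) to match
#' conventional clinical-report rounding, rather than R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(11.55, 1)  # 11.6
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# percent, rounded half-up to one decimal; NA when the denominator is zero
pct1 <- function(num, den) {
  if (den == 0) return(NA_real_)
  round_half_up(100 * num / den, 1)
}

#' Phenotype frequency distribution of a cohort
#'
#' Per-gene metabolizer phenotype counts plus the joint
#' CYP2C19 x CYP2D6 combination counts (the quantities behind a phenotype
#' UpSet plot). Combination counts partition the cohort; their marginals
#' equal the per-gene counts.
#'
#' @param cohort A `pgx_cohort`, or a translated cohort data frame from
#'   [translate_cohort()].
#' @return A list with `per_gene` (named list of count tables),
#'   `combinations` (data frame of all CYP2C19 x CYP2D6 cells with counts),
#'   `n` (cohort size) and `n_altered_any`.
#' @export
phenotype_distribution <- function(cohort) {
  translated <- if (inherits(cohort, "pgx_cohort")) translate_cohort(cohort)
                else cohort
  lev19 <- c(PHENOTYPE_LEVELS$CYP2C19, "Indeterminate")
  lev6 <- c(PHENOTYPE_LEVELS$CYP2D6, "Indeterminate")
  f19 <- factor(translated$cyp2c19_phenotype, levels = lev19)
  f6 <- factor(translated$cyp2d6_phenotype, levels = lev6)
  combo <- as.data.frame(table(cyp2c19 = f19, cyp2d6 = f6),
                         stringsAsFactors = FALSE)
  names(combo)[3] <- "count"
  list(per_gene = list(CYP2C19 = table(f19), CYP2D6 = table(f6)),
       combinations = combo,
       n = nrow(translated),
       n_altered_any = sum(altered(translated$cyp2c19_phenotype) |
                             altered(translated$cyp2d6_phenotype)))
}

#' Actionability of test results across a cohort
#'
#' The denominator is the set of participants with at least one trial of a
#' guideline medication (any response, including event-free use); the
#' numerator is those for whom at least one such trial carries a
#' non-standard recommendation given their phenotypes. Also returns a
#' per-medication breakdown of recommendation categories among users.
#'
#' @param cohort A `pgx_cohort`.
#' @param kb A `pgx_kb`.
#' @param translated Optional pre-computed [translate_cohort()] output.
#' @return A list with `n_pgx_med_users`, `n_actionable_participants`,
#'   `percent_actionable`, and `per_medication` (data frame: medication,
#'   n_users, n_actionable, recommendation-category counts).
#' @export
actionability_summary <- function(cohort, kb, translated = NULL) {
  stopifnot(inherits(cohort, "pgx_cohort"), inherits(kb, "pgx_kb"))
  if (is.null(translated)) translated <- translate_cohort(cohort)
  trials <- cohort$trials
  trials$medication <- vapply(trials$medication, normalize_medication, "",
                              kb = kb)
  guided <- trials[trials$medication %in% guideline_medications(kb), ,
                   drop = FALSE]
  users <- unique(guided$participant_id)
  rec_levels <- c(RECOMMENDATION_LEVELS, "not_evaluable")
  idx <- match(guided$participant_id, translated$participant_id)
  per_trial_rec <- character(nrow(guided))
  for (i in seq_len(nrow(guided))) {
    act <- kb_actionable(kb, guided$medication[i],
                         phenotype_calls_from_row(translated[idx[i], ]))
    per_trial_rec[i] <- act$recommendation
  }
  guided$recommendation <- per_trial_rec
  guided$actionable <- !per_trial_rec %in% c("standard", "not_evaluable",
                                             "no_guideline")
  actionable_ids <- unique(guided$participant_id[guided$actionable])
  per_med <- do.call(rbind, lapply(split(guided, guided$medication),
    function(g) {
      counts <- table(factor(g$recommendation, levels = rec_levels))
      cbind(data.frame(medication = g$medication[1],
                       n_users = length(unique(g$participant_id)),
                       n_actionable = sum(g$actionable),
                       stringsAsFactors = FALSE),
            as.data.frame.matrix(t(as.matrix(counts))))
    }))
  if (is.null(per_med)) {
    per_med <- data.frame(medication = character(), n_users = integer(),
                          n_actionable = integer(), stringsAsFactors = FALSE)
  }
  rownames(per_med) <- NULL
  list(n_pgx_med_users = length(users),
       n_actionable_participants = length(actionable_ids),
       percent_actionable = pct1(length(actionable_ids), length(users)),
       per_medication = per_med)
}

#' Medication-centered concordance summary
#'
#' For each event type, the fraction of events adjudicated consistent with
#' the metabolizer phenotype, overall and per medication. `not_evaluable`
#' events on guideline medications stay in the denominators; events on
#' medications without guidelines are excluded (they belong to the
#' participant-centered, all-medication view).
#'
#' @param verdicts Data frame from [adjudicate_cohort()].
#' @param kb A `pgx_kb`; used to restrict denominators to guideline
#'   medications.
#' @return A list with `overall` (data frame: event_type, n_events,
#'   n_consistent, percent_consistent) and `per_medication`. Fractions are
#'   `NA`, not 0, when an event type has no events.
#' @export
medication_centered_summary <- function(verdicts, kb) {
  guided <- verdicts[verdicts$medication %in% guideline_medications(kb), ,
                     drop = FALSE]
  summarize <- function(v) {
    do.call(rbind, lapply(c("adr", "inefficacy"), function(type) {
      ev <- v[v$event_type == type, , drop = FALSE]
      n <- nrow(ev)
      k <- sum(ev$verdict == "consistent")
      data.frame(event_type = type, n_events = n, n_consistent = k,
                 percent_consistent = if (n == 0) NA_real_ else pct1(k, n),
                 stringsAsFactors = FALSE)
    }))
  }
  per_med <- do.call(rbind, lapply(split(guided, guided$medication),
    function(v) cbind(medication = v$medication[1], summarize(v))))
  if (is.null(per_med)) {
    per_med <- data.frame(medication = character(), event_type = character(),
                          n_events = integer(), n_consistent = integer(),
                          percent_consistent = numeric(),
                          stringsAsFactors = FALSE)
  }
  rownames(per_med) <- NULL
  list(overall = summarize(guided), per_medication = per_med)
}

#' Participant-centered explained-response summary
#'
#' Counts, over participants who reported at least one ADR or inefficacy on
#' a guideline medication, how many had (a) at least one event consistent
#' with their metabolizer phenotypes, (b) all guideline-medication events
#' consistent, and (c) all events consistent including responses to
#' psychotropics without guidelines (which can never be explained by the
#' test, so any such event keeps a participant out of this strictest tally).
#'
#' @param verdicts Data frame from [adjudicate_cohort()]; must include the
#'   not_evaluable events for non-guideline medications.
#' @param kb A `pgx_kb`.
#' @return A list with the three tallies, the eligible-participant
#'   denominator, percentages, and a `per_participant` data frame.
#' @export
participant_centered_summary <- function(verdicts, kb) {
  guided_meds <- guideline_medications(kb)
  verdicts$guideline <- verdicts$medication %in% guided_meds
  ids <- unique(verdicts$participant_id[verdicts$guideline])
  per <- do.call(rbind, lapply(ids, function(id) {
    v <- verdicts[verdicts$participant_id == id, , drop = FALSE]
    g <- v[v$guideline, , drop = FALSE]
    data.frame(participant_id = id,
               n_events_guideline = nrow(g),
               n_consistent = sum(g$verdict == "consistent"),
               n_events_all = nrow(v),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per)) {
    per <- data.frame(participant_id = character(),
                      n_events_guideline = integer(),
                      n_consistent = integer(), n_events_all = integer(),
                      stringsAsFactors = FALSE)
  }
  n <- nrow(per)
  n_any <- sum(per$n_consistent >= 1)
  n_full_guideline <- sum(per$n_consistent == per$n_events_guideline &
                            per$n_events_guideline > 0)
  n_full_all <- sum(per$n_consistent == per$n_events_all &
                      per$n_events_all > 0)
  list(n_participants_with_events = n,
       n_any_consistent = n_any,
       n_fully_explained_guideline = n_full_guideline,
       n_fully_explained_all_medications = n_full_all,
       percent_any_consistent = if (n == 0) NA_real_ else pct1(n_any, n),
       per_participant = per)
}

#' Full machine-readable cohort summary
#'
#' Composes the phenotype distribution, actionability, medication-centered
#' and participant-centered summaries into one list suitable for JSON
#' serialization (the machine-readable twin of the study's figures).
#'
#' @param cohort A `pgx_cohort`.
#' @param kb A `pgx_kb`.
#' @return A named list of summaries.
#' @export
cohort_summary <- function(cohort, kb) {
  translated <- translate_cohort(cohort)
  verdicts <- adjudicate_cohort(cohort, kb, translated)
  dist <- phenotype_distribution(translated)
  list(
    n_participants = dist$n,
    phenotype_distribution = list(
      CYP2C19 = as.list(dist$per_gene$CYP2C19),
      CYP2D6 = as.list(dist$per_gene$CYP2D6),
      combinations = dist$combinations[dist$combinations$count > 0, ],
      n_altered_any = dist$n_altered_any),
    actionability = actionability_summary(cohort, kb, translated),
    medication_centered = medication_centered_summary(verdicts, kb),
    participant_centered = participant_centered_summary(verdicts, kb))
}
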