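#' Construct a cohort object
#'
#' Bundles the participant table (one row per participant with demographics
#' and the two diplotype strings) and the long-format trials table (one row
#' per participant-medication course with the response category) after
#' validating the schema: unique participant ids, no orphan trial rows,
#' response values from the recognized vocabulary, and parseable diplotypes.
#'
#' @param participants Data frame with columns `participant_id`,
#'   `cyp2c19_diplotype`, `cyp2d6_diplotype` (plus optional `age_years`,
#'   `sex`, `diagnoses`).
#' @param trials Data frame with columns `participant_id`, `medication`,
#'   `response` (plus optional `adr_description`, `dose_info`).
#' @return An object of class `pgx_cohort`.
#' @export
new_cohort <- function(participants, trials) {
  req_p <- c("participant_id", "cyp2c19_diplotype", "cyp2d6_diplotype")
  missing <- setdiff(req_p, names(participants))
  if (length(missing) > 0) {
    stop("participant table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  req_t <- c("participant_id", "medication", "response")
  missing <- setdiff(req_t, names(trials))
  if (length(missing) > 0) {
    stop("trials table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  participants$participant_id <- as.character(participants$participant_id)
  trials$participant_id <- as.character(trials$participant_id)
  dup <- participants$participant_id[duplicated(participants$participant_id)]
  if (length(dup) > 0) {
    stop("duplicate participant_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  orphans <- setdiff(trials$participant_id, participants$participant_id)
  if (length(orphans) > 0) {
    stop("trial rows reference unknown participant_id: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  bad_resp <- setdiff(unique(trials$response), RESPONSE_LEVELS)
  if (length(bad_resp) > 0) {
    stop("unknown response value(s): ", paste(bad_resp, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(participants))) {
    for (col in c("cyp2c19_diplotype", "cyp2d6_diplotype")) {
      gene <- if (col == "cyp2c19_diplotype") "CYP2C19" else "CYP2D6"
      tryCatch(parse_diplotype(participants[[col]][i], gene),
               error = function(e) {
                 stop("participant ", participants$participant_id[i], ": ",
                      conditionMessage(e), call. = FALSE)
               })
    }
  }
  if (is.null(trials$adr_description)) {
    trials$adr_description <- rep("", nrow(trials))
  }
  if (is.null(trials$dose_info)) trials$dose_info <- rep("", nrow(trials))
  structure(list(participants = participants, trials = trials),
            class = "pgx_cohort")
}

#' Read a cohort from CSV files
#'
#' @param participants_path CSV with the participant table (UTF-8, header
#'   row).
#' @param trials_path CSV with the long-format trials table.
#' @return A validated `pgx_cohort`.
#' @export
read_cohort <- function(participants_path, trials_path) {
  # read as text to avoid lossy type inference (e.g. sex "F" as logical);
  # age is restored to integer below
  participants <- utils::read.csv(participants_path,
                                  stringsAsFactors = FALSE,
                                  colClasses = "character")
  trials <- utils::read.csv(trials_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  if (!is.null(participants$age_years)) {
    participants$age_years <- as.integer(participants$age_years)
  }
  new_cohort(participants, trials)
}

#' Write a cohort to CSV files
#'
#' Diplotype strings are written in canonical form, so reading the files
#' back yields a semantically identical cohort.
#'
#' @param cohort A `pgx_cohort`.
#' @param participants_path,trials_path Output CSV paths.
#' @export
write_cohort <- function(cohort, participants_path, trials_path) {
  stopifnot(inherits(cohort, "pgx_cohort"))
  pp <- cohort$participants
  pp$cyp2c19_diplotype <- vapply(pp$cyp2c19_diplotype, function(x)
    format_diplotype(parse_diplotype(x, "CYP2C19")), "")
  pp$cyp2d6_diplotype <- vapply(pp$cyp2d6_diplotype, function(x)
    format_diplotype(parse_diplotype(x, "CYP2D6")), "")
  utils::write.csv(pp, participants_path, row.names = FALSE, quote = TRUE)
  utils::write.csv(cohort$trials, trials_path, row.names = FALSE,
                   quote = TRUE)
  invisible(cohort)
}

#' @export
print.pgx_cohort <- function(x, ...) {
  cat("PGx cohort:", nrow(x$participants), "participants,",
      nrow(x$trials), "medication trials\n")
  invisible(x)
}

#' Run the full interpretation pipeline
#'
#' Translates diplotypes to phenotypes, adjudicates every reported ADR and
#' inefficacy against the knowledge base, computes the cohort summaries, and
#' (optionally) writes the verdicts TSV, the phenotype table TSV and the
#' summary JSON to an output directory. Partial outputs are removed when a
#' stage fails.
#'
#' @param cohort A `pgx_cohort`.
#' @param kb A `pgx_kb` (defaults to the shipped knowledge base).
#' @param out_dir Optional output directory; created if needed.
#' @return Invisibly, a list with `translated`, `verdicts` and `summary`.
#' @export
run_pipeline <- function(cohort, kb = load_knowledge_base(),
                         out_dir = NULL) {
  stopifnot(inherits(cohort, "pgx_cohort"), inherits(kb, "pgx_kb"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  translated <- stage("translate", translate_cohort(cohort))
  verdicts <- stage("adjudicate", adjudicate_cohort(cohort, kb, translated))
  summary <- stage("summarize", cohort_summary(cohort, kb))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    written <- character()
    tryCatch({
      p1 <- file.path(out_dir, "phenotypes.tsv")
      utils::write.table(translated, p1, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <- c(written, p1)
      p2 <- file.path(out_dir, "verdicts.tsv")
      write_verdicts(verdicts, p2)
      written <- c(written, p2)
      p3 <- file.path(out_dir, "summary.json")
      jsonlite::write_json(
        summary_for_json(summary), p3, auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    }, error = function(e) {
      unlink(written)
      stop("pipeline stage 'write' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  invisible(list(translated = translated, verdicts = verdicts,
                 summary = summary))
}

# strip data-frame attributes jsonlite cannot serialize deterministically
summary_for_json <- function(summary) {
  summary$phenotype_distribution$CYP2C19 <-
    lapply(summary$phenotype_distribution$CYP2C19, as.integer)
  summary$phenotype_distribution$CYP2D6 <-
    lapply(summary$phenotype_distribution$CYP2D6, as.integer)
  summary
}
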