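RECOMMENDATION_LEVELS <- c("standard", "dose_adjust",
                           "dose_adjust_or_alternative", "alternative")

#' Load the guideline knowledge base
#'
#' Reads a YAML knowledge base encoding, for each pharmacogenetically guided
#' medication, the gene(s) whose metabolizer phenotype drives dosing, and
#' per-phenotype rules: a recommendation category, an optional dose
#' adjustment (percent reduction of standard dose; ranges allowed; negative
#' values indicate an increase), and flags marking whether the source
#' guideline explicitly associates the phenotype with increased ADR risk or
#' therapeutic-failure risk. Phenotypes without an explicit rule fall back to
#' standard dosing for medications listed under `default_standard`.
#'
#' The file is schema-validated on load; any (medication, gene, phenotype)
#' combination that resolves to neither an explicit rule nor a default is a
#' coverage gap and raises an error naming the missing triples.
#'
#' @param path Path to the YAML file; defaults to the curated CPIC/DPWG
#'   knowledge base shipped with the package.
#' @return An object of class `pgx_kb`.
#' @examples
#' kb <- load_knowledge_base()
#' guideline_medications(kb)
#' @export
load_knowledge_base <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "guideline_kb.yaml",
                        package = "pgxconcord", mustWork = TRUE)
  }
  if (!file.exists(path)) {
    stop("knowledge base file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  kb <- build_kb(raw)
  report <- validate_knowledge_base(kb)
  if (length(report$errors) > 0) {
    stop("knowledge base validation failed:\n  ",
         paste(report$errors, collapse = "\n  "), call. = FALSE)
  }
  for (w in report$warnings) warning(w, call. = FALSE)
  kb
}

build_kb <- function(raw) {
  for (field in c("version", "medication_gene_map", "rules")) {
    if (is.null(raw[[field]])) {
      stop("knowledge base schema error at /", field, ": field is required",
           call. = FALSE)
    }
  }
  gene_map <- lapply(raw$medication_gene_map, function(entries) {
    data.frame(gene = vapply(entries, function(e) e$gene %||% NA_character_, ""),
               role = vapply(entries, function(e) e$role %||% "primary", ""),
               stringsAsFactors = FALSE)
  })
  names(gene_map) <- tolower(names(raw$medication_gene_map))
  rules <- lapply(seq_along(raw$rules), function(i) {
    r <- raw$rules[[i]]
    ptr <- paste0("/rules/", i - 1)
    for (field in c("medication", "gene", "phenotype", "recommendation")) {
      if (is.null(r[[field]])) {
        stop("knowledge base schema error at ", ptr, "/", field,
             ": field is required", call. = FALSE)
      }
    }
    dose <- r$dose_adjust_percent
    if (!is.null(dose) && !length(dose) %in% c(1, 2)) {
      stop("knowledge base schema error at ", ptr,
           "/dose_adjust_percent: expected a scalar or [low, high] range",
           call. = FALSE)
    }
    list(medication = tolower(r$medication), gene = r$gene,
         phenotype = r$phenotype, recommendation = r$recommendation,
         dose_adjust_percent = if (is.null(dose)) NULL else as.numeric(dose),
         adr_risk = isTRUE(r$adr_risk),
         inefficacy_risk = isTRUE(r$inefficacy_risk),
         source = r$source %||% NA_character_,
         note = r$note %||% "")
  })
  structure(
    list(version = raw$version,
         sources = raw$sources %||% character(),
         gene_map = gene_map,
         default_standard = tolower(unlist(raw$default_standard) %||% character()),
         synonyms = raw$synonyms %||% list(),
         rules = rules),
    class = "pgx_kb")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a knowledge base
#'
#' Checks the schema (enum values, gene-specific phenotype vocabularies,
#' dose fields), rule uniqueness, and phenotype coverage of every medication
#' x mapped-gene combination. Risk flags asserted on a standard
#' recommendation without an explanatory note are reported as warnings, not
#' errors.
#'
#' @param kb A `pgx_kb`.
#' @return A list with `errors` and `warnings` (character vectors); an empty
#'   `errors` element means the knowledge base is usable.
#' @export
validate_knowledge_base <- function(kb) {
  stopifnot(inherits(kb, "pgx_kb"))
  errors <- character()
  warnings <- character()
  seen <- character()
  for (i in seq_along(kb$rules)) {
    r <- kb$rules[[i]]
    ptr <- paste0("/rules/", i - 1)
    if (!r$gene %in% PGX_GENES) {
      errors <- c(errors, paste0(ptr, "/gene: unknown gene '", r$gene, "'"))
      next
    }
    if (!r$phenotype %in% PHENOTYPE_LEVELS[[r$gene]]) {
      errors <- c(errors, paste0(
        ptr, "/phenotype: '", r$phenotype, "' is not a valid ", r$gene,
        " phenotype"))
    }
    if (!r$recommendation %in% RECOMMENDATION_LEVELS) {
      errors <- c(errors, paste0(
        ptr, "/recommendation: unknown category '", r$recommendation, "'"))
    }
    if (r$recommendation == "standard" && !is.null(r$dose_adjust_percent)) {
      errors <- c(errors, paste0(
        ptr, "/dose_adjust_percent: must be absent for standard dosing"))
    }
    if (!r$medication %in% names(kb$gene_map)) {
      errors <- c(errors, paste0(
        ptr, "/medication: '", r$medication,
        "' is not in the medication_gene_map"))
    } else if (!r$gene %in% kb$gene_map[[r$medication]]$gene) {
      errors <- c(errors, paste0(
        ptr, "/gene: ", r$gene, " is not mapped for ", r$medication))
    }
    key <- paste(r$medication, r$gene, r$phenotype)
    if (key %in% seen) {
      errors <- c(errors, paste0(ptr, ": duplicate rule for (", key, ")"))
    }
    seen <- c(seen, key)
    if (r$recommendation == "standard" &&
        (r$adr_risk || r$inefficacy_risk) && !nzchar(r$note)) {
      warnings <- c(warnings, paste0(
        ptr, ": risk flag asserted with standard dosing and no",
        " explanatory note (", key, ")"))
    }
  }
  # coverage: every medication x mapped gene x determinate phenotype resolves
  gaps <- character()
  for (med in names(kb$gene_map)) {
    if (med %in% kb$default_standard) next
    for (gene in kb$gene_map[[med]]$gene) {
      for (ph in PHENOTYPE_LEVELS[[gene]]) {
        if (!paste(med, gene, ph) %in% seen) {
          gaps <- c(gaps, paste0("(", med, ", ", gene, ", ", ph, ")"))
        }
      }
    }
  }
  if (length(gaps) > 0) {
    errors <- c(errors, paste0("coverage gap: no rule and no default for ",
                               paste(gaps, collapse = ", ")))
  }
  list(errors = errors, warnings = warnings)
}

#' Medications covered by the knowledge base
#'
#' @param kb A `pgx_kb`.
#' @return Character vector of normalized medication names.
#' @export
guideline_medications <- function(kb) names(kb$gene_map)

#' Normalize a medication name
#'
#' Lower-cases, trims, and resolves brand-name synonyms against the
#' knowledge base's synonym table.
#'
#' @param medication Medication name as recorded.
#' @param kb A `pgx_kb`.
#' @return Normalized generic name (still possibly outside the knowledge
#'   base, e.g. `"methylphenidate"`).
#' @export
normalize_medication <- function(medication, kb) {
  name <- tolower(trimws(medication))
  syn <- kb$synonyms[[name]]
  if (!is.null(syn)) tolower(syn) else name
}

standard_rule <- function(medication, gene, phenotype) {
  list(medication = medication, gene = gene, phenotype = phenotype,
       recommendation = "standard", dose_adjust_percent = NULL,
       adr_risk = FALSE, inefficacy_risk = FALSE, source = "default",
       note = "default standard dosing (no explicit guideline rule)")
}

not_evaluable_rule <- function(medication, gene) {
  list(medication = medication, gene = gene, phenotype = "Indeterminate",
       recommendation = "not_evaluable", dose_adjust_percent = NULL,
       adr_risk = FALSE, inefficacy_risk = FALSE, source = NA_character_,
       note = "indeterminate phenotype: rule not evaluable")
}

#' Look up guideline rules for a medication and phenotype set
#'
#' Returns one rule per gene mapped to the medication. An Indeterminate
#' phenotype yields a `not_evaluable` sentinel rule for that gene; a
#' medication without any guideline yields a `pgx_no_guideline` object
#' (not an error) so downstream stages can treat it as not evaluable.
#'
#' @param kb A `pgx_kb`.
#' @param medication Medication name (brand names resolved via synonyms).
#' @param phenotype_calls Named list of `pgx_phenotype_call`s (or phenotype
#'   strings) covering at least the mapped gene(s), names being gene symbols.
#' @return A list of rule records, or a `pgx_no_guideline` object.
#' @examples
#' kb <- load_knowledge_base()
#' kb_lookup(kb, "risperidone", list(CYP2D6 = "PM"))[[1]]$dose_adjust_percent
#' @export
kb_lookup <- function(kb, medication, phenotype_calls) {
  stopifnot(inherits(kb, "pgx_kb"))
  med <- normalize_medication(medication, kb)
  if (!med %in% names(kb$gene_map)) {
    return(structure(list(medication = med), class = "pgx_no_guideline"))
  }
  phenos <- lapply(phenotype_calls, function(p) {
    if (inherits(p, "pgx_phenotype_call")) p$phenotype else p
  })
  out <- list()
  for (gene in kb$gene_map[[med]]$gene) {
    if (is.null(phenos[[gene]])) {
      stop("phenotype call for mapped gene ", gene,
           " is required to evaluate ", med, call. = FALSE)
    }
    ph <- phenos[[gene]]
    if (ph == "Indeterminate") {
      out[[gene]] <- not_evaluable_rule(med, gene)
      next
    }
    hit <- Filter(function(r) r$medication == med && r$gene == gene &&
                    r$phenotype == ph, kb$rules)
    out[[gene]] <- if (length(hit) > 0) hit[[1]]
                   else standard_rule(med, gene, ph)
  }
  out
}

#' Is a test result actionable for a medication?
#'
#' A result is actionable when any mapped gene's rule recommends something
#' other than standard dosing (for dual-gene medications, either gene
#' suffices). Medications without a guideline and Indeterminate phenotypes
#' are never actionable.
#'
#' @inheritParams kb_lookup
#' @return A list with `actionable` (logical) and `recommendation` (the
#'   non-standard recommendation category, or `"standard"`,
#'   `"no_guideline"`, `"not_evaluable"`), plus the underlying `rules`.
#' @examples
#' kb <- load_knowledge_base()
#' kb_actionable(kb, "aripiprazole", list(CYP2D6 = "PM"))
#' @export
kb_actionable <- function(kb, medication, phenotype_calls) {
  rules <- kb_lookup(kb, medication, phenotype_calls)
  if (inherits(rules, "pgx_no_guideline")) {
    return(list(actionable = FALSE, recommendation = "no_guideline",
                rules = rules))
  }
  recs <- vapply(rules, function(r) r$recommendation, "")
  nonstd <- recs[!recs %in% c("standard", "not_evaluable")]
  if (length(nonstd) > 0) {
    list(actionable = TRUE, recommendation = nonstd[[1]], rules = rules)
  } else if (all(recs == "not_evaluable")) {
    list(actionable = FALSE, recommendation = "not_evaluable", rules = rules)
  } else {
    list(actionable = FALSE, recommendation = "standard", rules = rules)
  }
}

#' @export
print.pgx_kb <- function(x, ...) {
  cat("Guideline knowledge base v", x$version, ": ",
      length(x$gene_map), " medications, ", length(x$rules),
      " explicit rules\n", sep = "")
  invisible(x)
}
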