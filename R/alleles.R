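#' Supported pharmacogenes
#'
#' The pipeline interprets star-allele diplotypes for the two cytochrome P450
#' genes with the strongest evidence base for psychotropic dosing guidance.
#' @export
PGX_GENES <- c("CYP2C19", "CYP2D6")

#' Metabolizer phenotype levels
#'
#' Valid metabolizer categories per gene. The rapid metabolizer (RM) category
#' exists only for CYP2C19; CYP2D6 phenotypes are assigned from the activity
#' score, which has no rapid bin.
#' @export
PHENOTYPE_LEVELS <- list(
  CYP2C19 = c("PM", "IM", "NM", "RM", "UM"),
  CYP2D6  = c("PM", "IM", "NM", "UM")
)

ALLELE_FUNCTION_CLASSES <- c("normal", "decreased", "no_function",
                             "increased", "uncertain")

#' Load a star-allele function-definition table
#'
#' Reads a tab-separated allele-definition table with columns `gene`,
#' `allele`, `function_class` and `activity_value`. Activity values are the
#' per-copy contributions to the CYP2D6 activity score (1 for normal
#' function, 0.25 or 0.5 for decreased function, 0 for no function) and are
#' `NA` for CYP2C19, whose phenotype assignment is categorical. Hybrid tandem
#' alleles (e.g. `*36+*10`) appear as dedicated rows and are scored as a
#' unit.
#'
#' @param path Path to the TSV file. Defaults to the curated table shipped
#'   with the package.
#' @return A data frame with one row per allele, validated against the
#'   allele-definition invariants.
#' @examples
#' defs <- load_allele_definitions()
#' subset(defs, gene == "CYP2D6" & allele == "*41")
#' @export
load_allele_definitions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "allele_definitions.tsv",
                        package = "pgxconcord", mustWork = TRUE)
  }
  defs <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c("character", "character",
                                           "character", "character"))
  required <- c("gene", "allele", "function_class", "activity_value")
  missing <- setdiff(required, names(defs))
  if (length(missing) > 0) {
    stop("allele definition table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  defs$activity_value <- suppressWarnings(as.numeric(defs$activity_value))
  validate_allele_definitions(defs)
  defs
}

validate_allele_definitions <- function(defs) {
  bad_gene <- setdiff(unique(defs$gene), PGX_GENES)
  if (length(bad_gene) > 0) {
    stop("unknown gene(s) in allele definitions: ",
         paste(bad_gene, collapse = ", "), call. = FALSE)
  }
  bad_fn <- setdiff(unique(defs$function_class), ALLELE_FUNCTION_CLASSES)
  if (length(bad_fn) > 0) {
    stop("unknown function_class value(s): ",
         paste(bad_fn, collapse = ", "), call. = FALSE)
  }
  dup <- defs[duplicated(defs[c("gene", "allele")]), , drop = FALSE]
  if (nrow(dup) > 0) {
    stop("duplicated allele definition(s): ",
         paste(paste0(dup$gene, " ", dup$allele), collapse = ", "),
         call. = FALSE)
  }
  d6 <- defs[defs$gene == "CYP2D6" & defs$function_class != "uncertain", ]
  if (any(is.na(d6$activity_value))) {
    stop("CYP2D6 alleles with determinate function require an activity_value",
         call. = FALSE)
  }
  if (any(d6$activity_value < 0)) {
    stop("activity_value must be non-negative", call. = FALSE)
  }
  # zero activity and no-function status must coincide for CYP2D6
  mismatch <- xor(d6$activity_value == 0, d6$function_class == "no_function")
  if (any(mismatch)) {
    stop("activity_value 0 must coincide with function_class no_function: ",
         paste(d6$allele[mismatch], collapse = ", "), call. = FALSE)
  }
  inc <- defs[defs$function_class == "increased" & defs$gene != "CYP2C19", ]
  if (nrow(inc) > 0) {
    stop("increased function is only defined for CYP2C19 (*17); offending: ",
         paste(paste0(inc$gene, " ", inc$allele), collapse = ", "),
         call. = FALSE)
  }
  invisible(defs)
}

allele_lookup <- function(gene, allele, defs) {
  hit <- defs[defs$gene == gene & defs$allele == allele, , drop = FALSE]
  if (nrow(hit) == 0) return(NULL)
  hit[1, , drop = FALSE]
}
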