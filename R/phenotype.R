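#' CYP2D6 activity-score phenotype bins
#'
#' The CYP2D6 metabolizer phenotype is assigned by binning the activity
#' score: 0 is a poor metabolizer, scores in (0, 1] intermediate, (1, 2.25]
#' normal, and above 2.25 ultrarapid. Bin edges follow the current CPIC
#' translation and are exposed here so they can be overridden (edges are
#' upper-inclusive).
#'
#' @param pm_max Upper edge of the PM bin (default 0).
#' @param im_max Upper edge of the IM bin (default 1).
#' @param nm_max Upper edge of the NM bin (default 2.25); everything above is
#'   UM.
#' @return A named list of bin edges used by [call_phenotype()].
#' @export
phenotype_bins <- function(pm_max = 0, im_max = 1, nm_max = 2.25) {
  stopifnot(pm_max < im_max, im_max < nm_max)
  list(pm_max = pm_max, im_max = im_max, nm_max = nm_max)
}

bin_activity_score <- function(score, bins = phenotype_bins()) {
  if (is.na(score)) return(NA_character_)
  if (score <= bins$pm_max) "PM"
  else if (score <= bins$im_max) "IM"
  else if (score <= bins$nm_max) "NM"
  else "UM"
}

#' CYP2D6 activity score of a diplotype
#'
#' Sums per-copy activity values over both alleles:
#' \eqn{AS = v(a_1) c_1 + v(a_2) c_2}, where \eqn{v} is the allele's activity
#' value and \eqn{c} its copy number. Hybrid tandems contribute the activity
#' value of their dedicated table entry.
#'
#' @param d A CYP2D6 `pgx_diplotype`.
#' @param defs Allele-definition table from [load_allele_definitions()].
#' @return The activity score, or `NA` when either allele is unknown or of
#'   uncertain function (the caller maps this to an Indeterminate phenotype).
#' @examples
#' defs <- load_allele_definitions()
#' activity_score(parse_diplotype("*1/*41", "CYP2D6"), defs)
#' @export
activity_score <- function(d, defs = load_allele_definitions()) {
  stopifnot(inherits(d, "pgx_diplotype"))
  if (d$gene != "CYP2D6") {
    stop("activity scores are defined for CYP2D6 only", call. = FALSE)
  }
  contrib <- function(allele, copy) {
    def <- allele_lookup("CYP2D6", allele, defs)
    if (is.null(def) || def$function_class == "uncertain") return(NA_real_)
    def$activity_value * copy
  }
  contrib(d$allele1, d$copy1) + contrib(d$allele2, d$copy2)
}

cyp2c19_function_pair <- function(fn1, fn2) {
  fns <- c(fn1, fn2)
  if (any(is.na(fns)) || any(fns == "uncertain")) return("Indeterminate")
  n_no <- sum(fns == "no_function")
  n_inc <- sum(fns == "increased")
  n_dec <- sum(fns == "decreased")
  if (n_no == 2) "PM"
  else if (n_no == 1) "IM"       # includes no_function/increased
  else if (n_dec >= 1) "IM"      # decreased-function allele present
  else if (n_inc == 2) "UM"
  else if (n_inc == 1) "RM"
  else "NM"
}

#' Translate a diplotype to a metabolizer phenotype
#'
#' CYP2C19 phenotypes are assigned from the pair of allele function classes
#' (two no-function alleles give a poor metabolizer, one gives an
#' intermediate metabolizer, one or two increased-function alleles give
#' rapid/ultrarapid metabolizers); CYP2D6 phenotypes are assigned by binning
#' the activity score. A diplotype containing an allele that is absent from
#' the definitions or has uncertain function yields an Indeterminate call.
#'
#' @param d A `pgx_diplotype`.
#' @param defs Allele-definition table.
#' @param bins CYP2D6 activity-score bins from [phenotype_bins()].
#' @return An object of class `pgx_phenotype_call` with fields `gene`,
#'   `phenotype`, `activity_score` (CYP2D6 only, `NA` when Indeterminate)
#'   and `diplotype`.
#' @examples
#' defs <- load_allele_definitions()
#' call_phenotype(parse_diplotype("*2/*2", "CYP2C19"), defs)
#' call_phenotype(parse_diplotype("*1/*1x2", "CYP2D6"), defs)
#' @export
call_phenotype <- function(d, defs = load_allele_definitions(),
                           bins = phenotype_bins()) {
  stopifnot(inherits(d, "pgx_diplotype"))
  if (d$gene == "CYP2D6") {
    score <- activity_score(d, defs)
    phenotype <- if (is.na(score)) "Indeterminate"
                 else bin_activity_score(score, bins)
    as_val <- if (is.na(score)) NA_real_ else score
  } else {
    fn_of <- function(allele) {
      def <- allele_lookup("CYP2C19", allele, defs)
      if (is.null(def)) NA_character_ else def$function_class
    }
    phenotype <- cyp2c19_function_pair(fn_of(d$allele1), fn_of(d$allele2))
    as_val <- NA_real_
  }
  structure(
    list(gene = d$gene, phenotype = phenotype, activity_score = as_val,
         diplotype = d),
    class = "pgx_phenotype_call")
}

#' @export
print.pgx_phenotype_call <- function(x, ...) {
  score <- if (!is.na(x$activity_score))
    sprintf(" (activity score %.2f)", x$activity_score) else ""
  cat(x$gene, format_diplotype(x$diplotype), "->", x$phenotype, score, "\n")
  invisible(x)
}

#' Is a phenotype altered (non-normal)?
#'
#' A call is altered when its phenotype is neither normal metabolizer nor
#' Indeterminate; Indeterminate calls are deliberately never counted as
#' altered so they cannot enter actionability or consistency numerators.
#'
#' @param p A `pgx_phenotype_call` or a phenotype string.
#' @return Logical.
#' @export
altered <- function(p) {
  pheno <- if (inherits(p, "pgx_phenotype_call")) p$phenotype else p
  !(pheno %in% c("NM", "Indeterminate"))
}

#' Translate every participant in a cohort
#'
#' @param cohort A `pgx_cohort` from [read_cohort()], [simulate_cohort()] or
#'   [build_reference_cohort()].
#' @param defs Allele-definition table.
#' @param bins CYP2D6 activity-score bins.
#' @return A data frame with one row per participant: `participant_id`, the
#'   canonical diplotype strings, phenotypes for both genes, the CYP2D6
#'   activity score, and `altered_any` (non-normal phenotype in at least one
#'   gene).
#' @export
translate_cohort <- function(cohort, defs = load_allele_definitions(),
                             bins = phenotype_bins()) {
  stopifnot(inherits(cohort, "pgx_cohort"))
  pp <- cohort$participants
  one <- function(text, gene) {
    call_phenotype(parse_diplotype(text, gene), defs, bins)
  }
  c19 <- lapply(pp$cyp2c19_diplotype, one, gene = "CYP2C19")
  d6 <- lapply(pp$cyp2d6_diplotype, one, gene = "CYP2D6")
  out <- data.frame(
    participant_id = pp$participant_id,
    cyp2c19_diplotype = vapply(c19, function(x) format_diplotype(x$diplotype), ""),
    cyp2c19_phenotype = vapply(c19, function(x) x$phenotype, ""),
    cyp2d6_diplotype = vapply(d6, function(x) format_diplotype(x$diplotype), ""),
    cyp2d6_phenotype = vapply(d6, function(x) x$phenotype, ""),
    cyp2d6_activity_score = vapply(d6, function(x) x$activity_score, 0.0),
    stringsAsFactors = FALSE)
  out$altered_any <- altered(out$cyp2c19_phenotype) | altered(out$cyp2d6_phenotype)
  out
}

# Internal: named list of pgx_phenotype_call objects for one participant row
# of a translated cohort table.
phenotype_calls_from_row <- function(row) {
  list(
    CYP2C19 = structure(list(gene = "CYP2C19",
                             phenotype = row$cyp2c19_phenotype,
                             activity_score = NA_real_,
                             diplotype = NULL),
                        class = "pgx_phenotype_call"),
    CYP2D6 = structure(list(gene = "CYP2D6",
                            phenotype = row$cyp2d6_phenotype,
                            activity_score = row$cyp2d6_activity_score,
                            diplotype = NULL),
                       class = "pgx_phenotype_call"))
}
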