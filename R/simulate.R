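#' Simulation configuration
#'
#' Parameters of the synthetic-cohort generator. Defaults emulate the study
#' setting: a cohort of 100 children and adolescents, medication-use
#' probabilities taken from the reported cohort medication frequencies
#' (sertraline 46%, aripiprazole 29%, risperidone 27%, atomoxetine 25%,
#' escitalopram 18%, ... ) plus common non-guideline psychotropics
#' (methylphenidate 55%), so that participants accumulate a median of about
#' four psychotropic and one guideline medication. Allele frequencies are an
#' illustrative preset loosely modeled on global population frequencies (the
#' study cohort's own diplotype frequencies are not published) and are fully
#' overridable. Event generation is per-trial: an ADR occurs with
#' `baseline_adr_prob`, multiplied by `risk_multiplier_adr` when the
#' participant's phenotype is guideline-flagged for that medication (capped
#' at 1), and analogously for inefficacy; the two draws are independent and
#' a trial where both fire is recorded as the combined response category.
#'
#' @param n_participants Cohort size.
#' @param allele_freqs Per-gene named list of allele frequencies (must sum
#'   to 1 within 1e-9); allele names may carry copy-number suffixes (e.g.
#'   `"*1x2"`).
#' @param med_use_probs Named vector of per-participant use probabilities;
#'   names outside the knowledge base are simulated as non-guideline
#'   psychotropics.
#' @param baseline_adr_prob,baseline_ineff_prob Per-trial event
#'   probabilities in a non-risk phenotype.
#' @param risk_multiplier_adr,risk_multiplier_ineff Relative risk applied
#'   when the guideline flags the phenotype (>= 0).
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   cohort exactly.
#' @return A list of class `pgx_sim_config`.
#' @export
simulation_config <- function(
    n_participants = 100,
    allele_freqs = list(
      CYP2C19 = c("*1" = 0.62, "*2" = 0.15, "*3" = 0.01, "*17" = 0.22),
      CYP2D6 = c("*1" = 0.40, "*2" = 0.25, "*4" = 0.15, "*5" = 0.03,
                 "*9" = 0.02, "*10" = 0.05, "*41" = 0.08, "*1x2" = 0.02)),
    med_use_probs = c(
      sertraline = 0.46, escitalopram = 0.18, fluvoxamine = 0.07,
      vortioxetine = 0.04, citalopram = 0.02, atomoxetine = 0.25,
      venlafaxine = 0.03, risperidone = 0.27, aripiprazole = 0.29,
      brexpiprazole = 0.02, amitriptyline = 0.01, clomipramine = 0.01,
      methylphenidate = 0.55, quetiapine = 0.35, fluoxetine = 0.30,
      guanfacine = 0.30, clonidine = 0.25, lisdexamfetamine = 0.30),
    baseline_adr_prob = 0.25,
    baseline_ineff_prob = 0.20,
    risk_multiplier_adr = 2,
    risk_multiplier_ineff = 2,
    seed = 1L) {
  for (gene in names(allele_freqs)) {
    s <- sum(allele_freqs[[gene]])
    if (abs(s - 1) > 1e-9) {
      stop("allele frequencies for ", gene, " sum to ", s, ", not 1",
           call. = FALSE)
    }
    if (any(allele_freqs[[gene]] < 0)) {
      stop("allele frequencies must be non-negative", call. = FALSE)
    }
  }
  stopifnot(n_participants >= 1,
            all(med_use_probs >= 0 & med_use_probs <= 1),
            baseline_adr_prob >= 0, baseline_adr_prob <= 1,
            baseline_ineff_prob >= 0, baseline_ineff_prob <= 1,
            risk_multiplier_adr >= 0, risk_multiplier_ineff >= 0)
  structure(list(n_participants = as.integer(n_participants),
                 allele_freqs = allele_freqs,
                 med_use_probs = med_use_probs,
                 baseline_adr_prob = baseline_adr_prob,
                 baseline_ineff_prob = baseline_ineff_prob,
                 risk_multiplier_adr = risk_multiplier_adr,
                 risk_multiplier_ineff = risk_multiplier_ineff,
                 seed = as.integer(seed)),
            class = "pgx_sim_config")
}

#' Sample diplotypes under Hardy-Weinberg equilibrium
#'
#' Draws the two alleles of each gene independently from the configured
#' allele frequencies (random mating, no linkage), yielding genotype
#' frequencies p^2 / 2pq / q^2.
#'
#' @param config A `pgx_sim_config`. The caller controls the RNG state;
#'   [simulate_cohort()] seeds it from `config$seed`.
#' @return A data frame with `participant_id` and one diplotype string
#'   column per gene.
#' @export
sample_diplotypes <- function(config) {
  stopifnot(inherits(config, "pgx_sim_config"))
  n <- config$n_participants
  out <- data.frame(participant_id = sprintf("S%04d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (gene in PGX_GENES) {
    freqs <- config$allele_freqs[[gene]]
    a1 <- sample(names(freqs), n, replace = TRUE, prob = freqs)
    a2 <- sample(names(freqs), n, replace = TRUE, prob = freqs)
    col <- paste0(tolower(gene), "_diplotype")
    out[[col]] <- vapply(seq_len(n), function(i) {
      format_diplotype(parse_diplotype(paste0(a1[i], "/", a2[i]), gene))
    }, "")
  }
  out
}

# phenotypes the KB flags for a medication/gene/event type
risk_phenotypes <- function(kb, med, gene, flag) {
  hits <- Filter(function(r) r$medication == med && r$gene == gene &&
                   isTRUE(r[[flag]]), kb$rules)
  vapply(hits, function(r) r$phenotype, "")
}

trial_risk_flag <- function(kb, med, calls, event_type) {
  rules <- kb_lookup(kb, med, calls)
  if (inherits(rules, "pgx_no_guideline")) return(FALSE)
  flag <- if (event_type == "adr") "adr_risk" else "inefficacy_risk"
  any(vapply(rules, function(r) isTRUE(r[[flag]]), TRUE))
}

#' Sample medication trials and treatment-response events
#'
#' @param config A `pgx_sim_config`.
#' @param translated Translated participant table ([translate_cohort()]
#'   output for the sampled diplotypes).
#' @param kb A `pgx_kb`.
#' @return A trials data frame (participant_id, medication, response).
#' @export
sample_trials <- function(config, translated, kb) {
  stopifnot(inherits(config, "pgx_sim_config"), inherits(kb, "pgx_kb"))
  n <- nrow(translated)
  pheno <- list(CYP2C19 = translated$cyp2c19_phenotype,
                CYP2D6 = translated$cyp2d6_phenotype)
  gm <- guideline_medications(kb)
  out <- vector("list", length(config$med_use_probs))
  for (m in seq_along(config$med_use_probs)) {
    med <- names(config$med_use_probs)[m]
    used <- stats::runif(n) < config$med_use_probs[[m]]
    adr_flagged <- ineff_flagged <- rep(FALSE, n)
    if (med %in% gm) {
      for (gene in kb$gene_map[[med]]$gene) {
        adr_flagged <- adr_flagged |
          pheno[[gene]] %in% risk_phenotypes(kb, med, gene, "adr_risk")
        ineff_flagged <- ineff_flagged |
          pheno[[gene]] %in% risk_phenotypes(kb, med, gene,
                                             "inefficacy_risk")
      }
    }
    p_adr <- pmin(1, config$baseline_adr_prob *
                    ifelse(adr_flagged, config$risk_multiplier_adr, 1))
    p_ineff <- pmin(1, config$baseline_ineff_prob *
                      ifelse(ineff_flagged, config$risk_multiplier_ineff, 1))
    has_adr <- stats::runif(n) < p_adr
    has_ineff <- stats::runif(n) < p_ineff
    response <- ifelse(has_adr & has_ineff, "adr_and_inefficacy",
                       ifelse(has_adr, "adr",
                              ifelse(has_ineff, "inefficacy", "none")))
    out[[m]] <- data.frame(
      participant_id = translated$participant_id[used],
      medication = rep(med, sum(used)), response = response[used],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out[order(out$participant_id, out$medication), , drop = FALSE]
}

#' Simulate a synthetic cohort
#'
#' Seeds the RNG from the configuration, samples Hardy-Weinberg diplotypes
#' and phenotype-dependent treatment responses, and returns a validated
#' cohort whose ground-truth phenotype table is attached as the
#' `"truth"` attribute.
#'
#' @param config A `pgx_sim_config`.
#' @param kb A `pgx_kb`.
#' @return A `pgx_cohort` with attribute `truth` (the generator's phenotype
#'   bookkeeping, identical in structure to [translate_cohort()] output).
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_participants = 20, seed = 7))
#' cohort
#' @export
simulate_cohort <- function(config = simulation_config(),
                            kb = load_knowledge_base()) {
  set.seed(config$seed)
  participants <- sample_diplotypes(config)
  participants$age_years <- sample(6:17, config$n_participants,
                                   replace = TRUE)
  participants$sex <- sample(c("F", "M"), config$n_participants,
                             replace = TRUE, prob = c(0.41, 0.59))
  truth <- translate_cohort(
    structure(list(participants = participants,
                   trials = data.frame(participant_id = character(),
                                       medication = character(),
                                       response = character())),
              class = "pgx_cohort"))
  trials <- sample_trials(config, truth, kb)
  cohort <- new_cohort(participants, trials)
  attr(cohort, "truth") <- truth
  cohort
}

#' Expected consistent-event fraction under the null
#'
#' Closed-form marginal probability that a randomly chosen event of the
#' given type on a guideline medication falls on a participant whose
#' phenotype the guideline flags, under the null generative model where
#' event risk does not depend on phenotype (risk multiplier 1). Computed by
#' enumerating diplotype probabilities from the configured allele
#' frequencies, weighting medications by their use probabilities.
#'
#' @param config A `pgx_sim_config`.
#' @param kb A `pgx_kb`.
#' @param event_type `"adr"` or `"inefficacy"`.
#' @param defs,bins Allele definitions and CYP2D6 bins used to call
#'   phenotypes on the enumerated diplotypes.
#' @return Expected fraction in [0, 1].
#' @export
expected_risk_fraction <- function(config, kb, event_type = "adr",
                                   defs = load_allele_definitions(),
                                   bins = phenotype_bins()) {
  flag <- if (event_type == "adr") "adr_risk" else "inefficacy_risk"
  pheno_prob <- function(gene) {
    freqs <- config$allele_freqs[[gene]]
    alleles <- names(freqs)
    probs <- new.env()
    for (i in seq_along(alleles)) {
      for (j in seq_along(alleles)) {
        d <- parse_diplotype(paste0(alleles[i], "/", alleles[j]), gene)
        ph <- call_phenotype(d, defs, bins)$phenotype
        prev <- mget(ph, probs, ifnotfound = 0)[[1]]
        assign(ph, prev + freqs[[i]] * freqs[[j]], probs)
      }
    }
    as.list(probs)
  }
  dist <- lapply(PGX_GENES, pheno_prob)
  names(dist) <- PGX_GENES
  meds <- intersect(names(config$med_use_probs), guideline_medications(kb))
  num <- 0
  den <- 0
  for (med in meds) {
    w <- config$med_use_probs[[med]]
    p_clear <- 1
    for (gene in kb$gene_map[[med]]$gene) {
      flagged <- risk_phenotypes(kb, med, gene, flag)
      p_gene <- sum(unlist(dist[[gene]][intersect(names(dist[[gene]]),
                                                  flagged)]))
      p_clear <- p_clear * (1 - p_gene)
    }
    num <- num + w * (1 - p_clear)
    den <- den + w
  }
  num / den
}
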