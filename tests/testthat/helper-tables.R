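# Shared fixtures: the shipped tables are loaded once, and a small in-code
# allele table is available for property tests that need full control over
# activity values.

shipped_defs <- load_allele_definitions()
shipped_kb <- load_knowledge_base()

# minimal CYP2D6 allele table with one allele per function class
tiny_d6_defs <- data.frame(
  gene = "CYP2D6",
  allele = c("*1", "*2", "*9", "*10", "*4", "*22"),
  function_class = c("normal", "normal", "decreased", "decreased",
                     "no_function", "uncertain"),
  activity_value = c(1, 1, 0.5, 0.25, 0, NA),
  stringsAsFactors = FALSE)

# build a one-participant cohort with given diplotypes and trials
make_cohort <- function(c19 = "*1/*1", d6 = "*1/*1",
                        trials = data.frame(participant_id = character(),
                                            medication = character(),
                                            response = character())) {
  ids <- sprintf("P%d", seq_along(c19))
  new_cohort(
    data.frame(participant_id = ids, cyp2c19_diplotype = c19,
               cyp2d6_diplotype = d6, stringsAsFactors = FALSE),
    trials)
}

phenos <- function(c19, d6) list(CYP2C19 = c19, CYP2D6 = d6)
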