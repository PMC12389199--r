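# pgxconcord

Pharmacogenetic (PGx) testing of the drug-metabolism genes *CYP2C19* and
*CYP2D6* is increasingly used in child and adolescent psychiatry, often
*reactively* — after a patient has already experienced adverse drug
reactions (ADRs) or treatment inefficacy on psychotropic medication.
`pgxconcord` is an R package for evaluating what such testing can and
cannot explain. It implements the full interpretation pipeline:

1. **Star-allele diplotype parsing** — the clinical-report grammar
   `allele[xN](+allele)*/allele[xN](+allele)*`, including *CYP2D6*
   copy-number duplications (`*1x2`) and hybrid tandem alleles
   (`*36+*10`), with canonical ordering so `*2/*1` equals `*1/*2`.
2. **Metabolizer phenotype translation** — *CYP2D6* via the activity score
   `AS = v(a₁)·c₁ + v(a₂)·c₂` (per-allele activity values times copy
   numbers) binned as AS = 0 → PM, 0 < AS ≤ 1 → IM, 1 < AS ≤ 2.25 → NM,
   AS > 2.25 → UM; *CYP2C19* via categorical function-pair rules
   (PM/IM/NM/RM/UM). Unknown or uncertain-function alleles yield
   Indeterminate calls that never enter numerators.
3. **A curated CPIC/DPWG knowledge base** (versioned YAML, not code) for
   the twelve guideline-covered psychotropics — sertraline, escitalopram,
   citalopram, fluvoxamine, vortioxetine, venlafaxine, atomoxetine,
   risperidone, aripiprazole, brexpiprazole, and the dual-gene tricyclics
   amitriptyline and clomipramine — encoding per-phenotype recommendations,
   dose adjustments (e.g. risperidone/CYP2D6 PM: 67% reduction), and
   explicit ADR-risk and inefficacy-risk flags, including the guideline
   exceptions (aripiprazole IM is *not* ADR-flagged; sertraline RM/UM are
   *not* inefficacy-flagged).
4. **Consistency adjudication** — each reported ADR or inefficacy event is
   classified `consistent` / `inconsistent` / `not_evaluable` against the
   patient's phenotypes: consistent only when the guideline explicitly
   flags the phenotype for that event type and medication.
5. **Cohort analytics** — phenotype frequencies and joint combinations,
   dosing actionability among guideline-medication users,
   medication-centered concordance fractions, and participant-centered
   "how much of this patient's history is explained" tallies.
6. **A Hardy–Weinberg cohort simulator** with phenotype-dependent event
   rates, plus a deterministic reference cohort for end-to-end validation.

## Worked example

```r
library(pgxconcord)

defs <- load_allele_definitions()
kb <- load_knowledge_base()

# a CYP2D6 gene duplication -> ultrarapid metabolizer
call_phenotype(parse_diplotype("*1/*1x2", "CYP2D6"), defs)
#> CYP2D6 *1/*1x2 -> UM  (activity score 3.00)

# what would the guideline have recommended?
kb_actionable(kb, "risperidone", list(CYP2C19 = "NM", CYP2D6 = "PM"))$recommendation
#> [1] "dose_adjust"      # 67% dose reduction per DPWG

# is a sertraline ADR consistent with a CYP2C19 poor metabolizer?
adjudicate_event(
  list(participant_id = "P1", medication = "sertraline", event_type = "adr"),
  list(CYP2C19 = "PM", CYP2D6 = "NM"), kb)[, c("verdict", "gene_basis")]
#>     verdict gene_basis
#> 1 consistent CYP2C19 PM
```

Running the pipeline on the bundled reference cohort (86 participants, 69
of whom reported events on guideline medications):

```r
res <- run_pipeline(build_reference_cohort(), kb)
res$summary$medication_centered$overall
#>   event_type n_events n_consistent percent_consistent
#> 1        adr       76            6                7.9
#> 2 inefficacy       61            2                3.3
res$summary$participant_centered$n_any_consistent
#> [1] 8   # 11.6% of 69 participants had >=1 explained event
```

Only 7.9% of ADRs and 3.3% of inefficacies are phenotype-consistent, and
no participant's results explain their entire psychotropic history —
illustrating why metabolism-gene testing is better suited to preemptive
dosing guidance than to retrospective explanation.

## Analysis workflow

The numbered drivers under `analysis/` run the steps end to end and write
tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R       # synthetic cohort (n = 100)
Rscript analysis/02_phenotype_frequencies.R # per-gene + joint phenotype counts
Rscript analysis/03_reference_concordance.R # concordance on the reference cohort
Rscript analysis/04_participant_utility.R   # participant-centered tallies
```

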