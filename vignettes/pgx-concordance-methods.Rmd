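---
title: "Methods: phenotype translation, guideline rules, and treatment-response concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype translation, guideline rules, and treatment-response concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxconcord)
```

## The problem

Reactive pharmacogenetic testing asks, after the fact, whether a patient's
adverse drug reactions (ADRs) or treatment failures on psychotropic
medication can be attributed to their drug-metabolism genotype.
`pgxconcord` formalizes that question as a pipeline with four stages:
star-allele diplotypes are translated to *CYP2C19*/*CYP2D6* metabolizer
phenotypes; a curated guideline knowledge base determines what dosing
advice those phenotypes would have triggered; each reported event is
adjudicated for consistency with the phenotypes; and results are
aggregated per medication and per participant. Every stage is data-driven
and testable without patient data, via a simulator and a deterministic
reference cohort.

## Phenotype translation

**Diplotype grammar.** Each gene's genotype is a pair of star alleles
separated by `/`. A side may carry a copy-number suffix (`*1x2`, a gene
duplication) or be a hybrid tandem joined by `+` (`*36+*10`). Tandems are
kept as a single unit and resolved against a dedicated entry in the
allele-definition table; where no dedicated value is curated the
convention is to use the functional component's value (the shipped table
assigns `*36+*10` the decreased value of `*10`, and `*68+*4` the
no-function value of `*4`). Copy-number suffixes inside a tandem are
rejected as malformed. Parsed diplotypes are put in canonical order (lower
numeric star value first) so allele order never affects equality, lookups
or output.

**CYP2D6.** The phenotype comes from the activity score
$AS = v(a_1)\,c_1 + v(a_2)\,c_2$, the sum of per-copy activity values
($v = 1$ normal, $0.5$ or $0.25$ decreased, $0$ no function). The bins are
upper-inclusive: $AS = 0$ poor (PM), $0 < AS \le 1$ intermediate (IM),
$1 < AS \le 2.25$ normal (NM), $AS > 2.25$ ultrarapid (UM). These edges
follow the current consensus translation used by clinical guidelines; they
live in `phenotype_bins()` rather than in code so alternative binnings
(e.g. an older convention where $AS = 1$ was NM) can be evaluated without
touching the translator. The bins provably partition $[0, \infty)$ — the
test suite checks totality and monotonicity over a dense score grid.

**CYP2C19.** There is no activity score; the phenotype is a categorical
function of the two allele classes: two no-function alleles give PM,
exactly one gives IM (including no-function with increased-function, a
deliberately conservative call), one increased-function allele with a
normal allele gives RM, two give UM, and normal/normal gives NM. The
rapid metabolizer (RM) category exists only for CYP2C19. Decreased-function
alleles (e.g. `*9`) are not covered by that enumeration; the package
assigns IM whenever a decreased allele is present without a no-function
partner, including decreased/increased pairs — a conservative choice made
once and documented here, since published translations label several of
those diplotypes "likely intermediate".

**Indeterminate calls.** An allele that is absent from the definition
table or curated as uncertain-function makes the whole call Indeterminate.
Indeterminate is deliberately *not* altered: it can never make a result
actionable nor an event consistent, and in the consistency analysis such
events are retained in denominators as `not_evaluable`. The alternative —
dropping them from denominators — would silently shrink the evidence base;
keeping them biases all explained-fractions downward, which is the honest
direction for a method whose point is to bound explanatory power.

## The guideline knowledge base

Rules are data (versioned YAML), not code, because guideline content
drifts faster than software. Each rule keys (medication, gene, phenotype)
to a recommendation category (`standard`, `dose_adjust`,
`dose_adjust_or_alternative`, `alternative`), an optional dose adjustment
stored as percent reduction of standard dose (positive = reduce, ranges
allowed, e.g. aripiprazole PM 25–32%), and two boolean risk flags: does
the source guideline *explicitly* associate this phenotype with increased
ADR risk, or with therapeutic-failure risk? Phenotypes without an explicit
rule fall back to standard dosing for medications listed under
`default_standard`; the loader verifies that every medication × mapped
gene × phenotype combination resolves one way or the other and fails with
the missing triples otherwise.

The flags encode the guideline exceptions that make naive
"any altered phenotype explains any event" counting wrong:
aripiprazole's intermediate metabolizers are *not* ADR-flagged;
sertraline's rapid/ultrarapid metabolizers are *not* inefficacy-flagged;
risperidone's ultrarapid metabolizers carry an inefficacy, not an ADR,
association. Flags for medications whose guideline summaries are not
reproduced verbatim in accessible sources (atomoxetine, venlafaxine,
vortioxetine, fluvoxamine, brexpiprazole, the tricyclics) are curated from
the public CPIC/DPWG guidance and marked `Curated:` in their note fields
so they can be re-reviewed independently of the code.

Dual-gene medications (amitriptyline, clomipramine, metabolized by both
enzymes) use either-gene logic throughout: a result is actionable, and an
event consistent, if *either* mapped gene's rule fires. This is the
package's own decision where practice is not prescriptive; it matches the
fact that the relevant guidelines key dosing on both enzymes.

## Consistency adjudication

A trial's response is one of `none`, `adr`, `inefficacy`,
`adr_and_inefficacy`, `unknown`. The combined category contributes one
event of each type — so a cohort's ADR and inefficacy denominators count
events, not trials. Whether a combined response should instead count once
is not externally specified; counting one-per-type is the package default
and is isolated in `explode_events()` so it can be overridden.

An ADR event is `consistent` iff some mapped gene's rule for the
participant's phenotype has the ADR-risk flag; likewise inefficacy with
the failure-risk flag. Events on medications without any guideline, and
events whose relevant phenotypes are all Indeterminate, are
`not_evaluable`: kept in denominators, never numerators. Adjudication is
deterministic and order-independent; the vectorized cohort path is tested
against the per-event reference implementation.

Percentages are rounded half away from zero to one decimal
(`round_half_up()`), matching clinical-report conventions rather than R's
banker's rounding; this is what makes reported fractions like 6/76 → 7.9
and 8/69 → 11.6 bit-reproducible.

## The reference cohort

`build_reference_cohort()` reconstructs, deterministically and entirely in
code, a cohort with the event structure of a published retrospective
pediatric study: 69 participants with events on guideline medications
carrying 76 ADR and 61 inefficacy events, with the candidate phenotypes on
distinct participants — six ADR carriers and two inefficacy carriers whose
phenotypes the guidelines flag, plus three *decoys* (aripiprazole IM,
risperidone UM, sertraline UM) whose phenotypes are altered but not
flagged for their event type. The decoys ensure the pinned concordance
fractions (7.9% of ADRs, 3.3% of inefficacies, 11.6% of participants) are
reproduced only by correct rule logic. The split of the unattributed
events across medications is not published; the fixture's fixed arbitrary
split cannot affect the pinned totals because all those carriers are
normal metabolizers. Six consistent-event carriers are given one extra
unexplained guideline event and two a methylphenidate ADR, so the
participant-centered tallies (8 with ≥1 explained, 2 fully explained over
guideline medications, 0 over all psychotropics) also reproduce, along
with the usage-level counts (46 sertraline users, 28 with an ADR).

## The simulator

`simulate_cohort()` draws each gene's two alleles independently from
configured frequencies (Hardy–Weinberg: genotype probabilities
$p^2, 2pq, q^2$), assigns medications independently per participant with
the configured use probabilities, and draws ADR and inefficacy events
independently per trial with probability baseline × multiplier (capped at
1), the multiplier applying when the participant's phenotype is
guideline-flagged for that medication and event type.

Defaults are fixed once to emulate the study conditions: n = 100;
medication-use probabilities equal to the reported cohort frequencies
(sertraline 0.46, aripiprazole 0.29, risperidone 0.27, atomoxetine 0.25,
escitalopram 0.18, …) plus common non-guideline psychotropics
(methylphenidate 0.55, quetiapine 0.35, …), which yields a median of four
psychotropic and about one guideline medication per participant; baseline
per-trial probabilities of 0.25 (ADR) and 0.20 (inefficacy), in the range
reported for pediatric psychotropic discontinuation; risk multipliers of 2
as a moderate pharmacokinetic effect. The default allele-frequency preset
is an illustrative, roughly European-weighted set — the study cohort's own
frequencies are unpublished — and is config-overridable.

What the generator does *not* emulate: phenoconversion by inhibiting
co-medications, correlations between medications or between the two event
types, dose titration, age/sex effects, and population structure. Passing
simulation tests therefore validate the pipeline's *logic and
calibration*, not clinical effect sizes: under null multipliers the
consistent-event fraction must equal the closed-form marginal
risk-phenotype frequency (`expected_risk_fraction()`, computed by
enumerating diplotype probabilities) within three Monte-Carlo standard
errors, and injected relative risks must be recoverable from phenotype
strata.

## Problem sizes and numerical choices

The test suite runs the calibration checks at n = 10,000 (null
concordance, Hardy–Weinberg) and n = 6,000–8,000 (relative-risk
recovery), sizes at which three standard errors are a few percentage
points; the analysis drivers use the study-scale n = 100. All stochastic
tests fix seeds; the fixture and knowledge base are fully deterministic.
Degenerate inputs are defined, not errors: empty cohorts summarize to
zeros, event types with zero events report `NA` rather than 0%, and a
zero-probability allele simply never appears.

## Known limitations

- The knowledge base snapshot reflects the curated guidelines at packaging
  time; guidelines are living documents, and the YAML should be re-curated
  against current CPIC/DPWG releases before clinical-adjacent use.
- No variant-level genotyping: the pipeline starts from called star-allele
  diplotypes, as produced by commercial panels.
- Genes beyond *CYP2C19*/*CYP2D6* (e.g. *CYP2B6* for sertraline, *CYP3A4*
  for quetiapine) are out of scope, though the knowledge-base schema
  permits adding them.
- No phenoconversion adjustment and no causality scoring of ADRs; the
  pipeline trusts the upstream response classification.
- No inferential statistics: the analytics are deliberately descriptive,
  mirroring the design they evaluate.
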