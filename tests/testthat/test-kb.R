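test_that("shipped knowledge base loads with full phenotype coverage", {
  expect_s3_class(shipped_kb, "pgx_kb")
  report <- validate_knowledge_base(shipped_kb)
  expect_length(report$errors, 0)
  expect_length(report$warnings, 0)
  expect_setequal(
    guideline_medications(shipped_kb),
    c("sertraline", "escitalopram", "citalopram", "fluvoxamine",
      "vortioxetine", "venlafaxine", "atomoxetine", "risperidone",
      "aripiprazole", "brexpiprazole", "amitriptyline", "clomipramine"))
  # dual-gene tricyclics, single-gene everything else
  expect_setequal(shipped_kb$gene_map$amitriptyline$gene,
                  c("CYP2C19", "CYP2D6"))
  expect_identical(shipped_kb$gene_map$sertraline$gene, "CYP2C19")
  expect_identical(shipped_kb$gene_map$risperidone$gene, "CYP2D6")
})

test_that("coverage gaps and invalid phenotypes are reported with paths", {
  raw <- list(
    version = "t",
    medication_gene_map = list(
      sertraline = list(list(gene = "CYP2C19", role = "primary"))),
    rules = list(
      list(medication = "sertraline", gene = "CYP2C19", phenotype = "IM",
           recommendation = "dose_adjust")))
  kb <- pgxconcord:::build_kb(raw)
  report <- validate_knowledge_base(kb)
  expect_true(any(grepl("coverage gap", report$errors)))
  expect_true(any(grepl("sertraline, CYP2C19, PM", report$errors)))

  # RM is a CYP2C19-only phenotype: a CYP2D6 rule using it is a schema error
  raw$medication_gene_map$risperidone <-
    list(list(gene = "CYP2D6", role = "primary"))
  raw$rules[[2]] <- list(medication = "risperidone", gene = "CYP2D6",
                         phenotype = "RM", recommendation = "dose_adjust")
  report <- validate_knowledge_base(pgxconcord:::build_kb(raw))
  expect_true(any(grepl("/rules/1/phenotype.*RM", report$errors)))
})

test_that("dose on a standard rule and flagged-standard rules are caught", {
  raw <- list(
    version = "t",
    medication_gene_map = list(
      sertraline = list(list(gene = "CYP2C19", role = "primary"))),
    default_standard = list("sertraline"),
    rules = list(
      list(medication = "sertraline", gene = "CYP2C19", phenotype = "NM",
           recommendation = "standard", dose_adjust_percent = 50),
      list(medication = "sertraline", gene = "CYP2C19", phenotype = "RM",
           recommendation = "standard", adr_risk = TRUE)))
  report <- validate_knowledge_base(pgxconcord:::build_kb(raw))
  expect_true(any(grepl("dose_adjust_percent: must be absent",
                        report$errors)))
  expect_true(any(grepl("risk flag asserted with standard dosing",
                        report$warnings)))
})

test_that("lookup returns the printed guideline dose adjustments", {
  r <- kb_lookup(shipped_kb, "risperidone", phenos("NM", "PM"))
  expect_equal(r$CYP2D6$dose_adjust_percent, 67)
  expect_true(r$CYP2D6$adr_risk)

  r <- kb_lookup(shipped_kb, "sertraline", phenos("PM", "NM"))
  expect_equal(r$CYP2C19$dose_adjust_percent, 50)
  expect_identical(r$CYP2C19$recommendation, "dose_adjust_or_alternative")

  r <- kb_lookup(shipped_kb, "aripiprazole", phenos("NM", "PM"))
  expect_equal(r$CYP2D6$dose_adjust_percent, c(25, 32))
})

test_that("medications without guidelines give a no_guideline signal", {
  r <- kb_lookup(shipped_kb, "methylphenidate", phenos("PM", "PM"))
  expect_s3_class(r, "pgx_no_guideline")
  act <- kb_actionable(shipped_kb, "methylphenidate", phenos("PM", "PM"))
  expect_false(act$actionable)
  expect_identical(act$recommendation, "no_guideline")
})

test_that("actionability follows non-standard recommendations", {
  act <- kb_actionable(shipped_kb, "aripiprazole", phenos("NM", "PM"))
  expect_true(act$actionable)
  expect_identical(act$recommendation, "dose_adjust")

  act <- kb_actionable(shipped_kb, "fluvoxamine", phenos("NM", "NM"))
  expect_false(act$actionable)
  expect_identical(act$recommendation, "standard")

  act <- kb_actionable(shipped_kb, "amitriptyline", phenos("NM", "NM"))
  expect_false(act$actionable)
  # dual-gene: either gene's non-standard rule makes the result actionable
  act <- kb_actionable(shipped_kb, "amitriptyline", phenos("NM", "IM"))
  expect_true(act$actionable)
  act <- kb_actionable(shipped_kb, "amitriptyline", phenos("UM", "NM"))
  expect_true(act$actionable)
})

test_that("indeterminate phenotypes are never actionable", {
  act <- kb_actionable(shipped_kb, "sertraline",
                       phenos("Indeterminate", "NM"))
  expect_false(act$actionable)
  expect_identical(act$recommendation, "not_evaluable")
  expect_identical(act$rules$CYP2C19$recommendation, "not_evaluable")
})

test_that("lookup never raises over the full medication x phenotype grid", {
  for (med in guideline_medications(shipped_kb)) {
    genes <- shipped_kb$gene_map[[med]]$gene
    grids <- lapply(genes, function(g) PHENOTYPE_LEVELS[[g]])
    combos <- expand.grid(grids, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(combos))) {
      calls <- as.list(combos[i, , drop = TRUE])
      names(calls) <- genes
      if (!"CYP2C19" %in% genes) calls$CYP2C19 <- "NM"
      if (!"CYP2D6" %in% genes) calls$CYP2D6 <- "NM"
      expect_no_error(kb_lookup(shipped_kb, med, calls))
    }
  }
})

test_that("normal metabolizers get standard dosing with no risk flags", {
  for (med in guideline_medications(shipped_kb)) {
    rules <- kb_lookup(shipped_kb, med, phenos("NM", "NM"))
    for (r in rules) {
      expect_identical(r$recommendation, "standard")
      expect_false(r$adr_risk)
      expect_false(r$inefficacy_risk)
    }
  }
})

test_that("every risk-flagged rule is non-standard unless it carries a note", {
  for (r in shipped_kb$rules) {
    if ((r$adr_risk || r$inefficacy_risk) && r$recommendation == "standard") {
      expect_true(nzchar(r$note))
    }
  }
  # the guideline-stated exceptions are encoded: flags off despite altered pheno
  r <- kb_lookup(shipped_kb, "aripiprazole", phenos("NM", "IM"))
  expect_false(r$CYP2D6$adr_risk)
  r <- kb_lookup(shipped_kb, "sertraline", phenos("UM", "NM"))
  expect_false(r$CYP2C19$inefficacy_risk)
  r <- kb_lookup(shipped_kb, "risperidone", phenos("NM", "UM"))
  expect_false(r$CYP2D6$adr_risk)
})

test_that("brand names resolve through the synonym table", {
  expect_identical(normalize_medication("Zoloft", shipped_kb), "sertraline")
  expect_identical(normalize_medication("  SERTRALINE ", shipped_kb),
                   "sertraline")
  r <- kb_lookup(shipped_kb, "Abilify", phenos("NM", "PM"))
  expect_equal(r$CYP2D6$dose_adjust_percent, c(25, 32))
})
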