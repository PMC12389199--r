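# Brute-force activity-score oracle: expand each allele into per-copy
# contributions and sum, independently of the production formula.
oracle_score <- function(d, defs) {
  per_copy <- function(allele, copy) {
    row <- defs[defs$gene == "CYP2D6" & defs$allele == allele, ]
    if (nrow(row) == 0 || row$function_class == "uncertain") return(NA_real_)
    sum(rep(row$activity_value, copy))
  }
  per_copy(d$allele1, d$copy1) + per_copy(d$allele2, d$copy2)
}

test_that("activity score equals the brute-force additivity oracle", {
  expect_equal(activity_score(parse_diplotype("*4/*4", "CYP2D6"),
                              shipped_defs), 0)
  expect_equal(activity_score(parse_diplotype("*1/*1x2", "CYP2D6"),
                              shipped_defs), 3.0)
  expect_equal(activity_score(parse_diplotype("*1/*41", "CYP2D6"),
                              shipped_defs), 1.25)
  set.seed(7)
  alleles <- tiny_d6_defs$allele[tiny_d6_defs$function_class != "uncertain"]
  for (i in 1:100) {
    text <- paste0(sample(alleles, 1), sample(c("", "x2", "x3"), 1), "/",
                   sample(alleles, 1), sample(c("", "x2"), 1))
    d <- parse_diplotype(text, "CYP2D6")
    expect_equal(activity_score(d, tiny_d6_defs), oracle_score(d, tiny_d6_defs),
                 info = text)
  }
})

test_that("CYP2D6 translation matches the published diplotype-phenotype table", {
  # frozen cross-check against the CPIC CYP2D6 translation on a small grid
  expected <- data.frame(
    diplotype = c("*1/*1", "*1/*4", "*4/*4", "*1/*41", "*1/*10", "*10/*41",
                  "*4/*41", "*1/*1x2", "*1x2/*4", "*2/*2", "*5/*5", "*1/*9",
                  "*9/*41"),
    score = c(2, 1, 0, 1.25, 1.25, 0.5, 0.25, 3, 2, 2, 0, 1.5, 0.75),
    phenotype = c("NM", "IM", "PM", "NM", "NM", "IM", "IM", "UM", "NM",
                  "NM", "PM", "NM", "IM"),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(expected))) {
    d <- parse_diplotype(expected$diplotype[i], "CYP2D6")
    call <- call_phenotype(d, shipped_defs)
    expect_equal(call$activity_score, expected$score[i],
                 info = expected$diplotype[i])
    expect_identical(call$phenotype, expected$phenotype[i],
                     info = expected$diplotype[i])
  }
  # hybrid tandem scored via its dedicated table entry
  expect_identical(
    call_phenotype(parse_diplotype("*36+*10/*4", "CYP2D6"),
                   shipped_defs)$phenotype, "IM")
})

test_that("CYP2C19 translation matches the published diplotype-phenotype table", {
  expected <- list(
    c("*1/*1", "NM"), c("*1/*2", "IM"), c("*2/*2", "PM"), c("*2/*3", "PM"),
    c("*1/*17", "RM"), c("*17/*17", "UM"), c("*2/*17", "IM"),
    c("*1/*3", "IM"), c("*3/*17", "IM"))
  for (e in expected) {
    call <- call_phenotype(parse_diplotype(e[1], "CYP2C19"), shipped_defs)
    expect_identical(call$phenotype, e[2], info = e[1])
    expect_true(is.na(call$activity_score))
  }
})

test_that("phenotype bins partition the score axis with no gaps or overlaps", {
  bins <- phenotype_bins()
  grid <- seq(0, 6, by = 0.01)
  assigned <- vapply(grid, pgxconcord:::bin_activity_score, "", bins = bins)
  expect_false(any(is.na(assigned)))
  expect_true(all(assigned %in% c("PM", "IM", "NM", "UM")))
  # boundaries are upper-inclusive
  expect_identical(vapply(c(0, 1, 1.0001, 2.25, 2.2501),
                          pgxconcord:::bin_activity_score, "", bins = bins),
                   c("PM", "IM", "NM", "NM", "UM"))
  # each score maps to exactly one bin, in non-decreasing severity order
  ord <- c(PM = 1, IM = 2, NM = 3, UM = 4)
  expect_true(all(diff(ord[assigned]) >= 0))
})

test_that("lower-activity substitution never raises score or phenotype", {
  ord <- c(PM = 1, IM = 2, NM = 3, UM = 4)
  alleles <- tiny_d6_defs[tiny_d6_defs$function_class != "uncertain", ]
  alleles <- alleles[order(-alleles$activity_value), ]
  for (i in seq_len(nrow(alleles))) {
    for (j in seq_len(nrow(alleles))) {
      for (k in seq_len(nrow(alleles))) {
        if (alleles$activity_value[k] > alleles$activity_value[j]) next
        base <- parse_diplotype(
          paste0(alleles$allele[i], "/", alleles$allele[j]), "CYP2D6")
        swapped <- parse_diplotype(
          paste0(alleles$allele[i], "/", alleles$allele[k]), "CYP2D6")
        expect_lte(activity_score(swapped, tiny_d6_defs),
                   activity_score(base, tiny_d6_defs))
        expect_lte(ord[call_phenotype(swapped, tiny_d6_defs)$phenotype],
                   ord[call_phenotype(base, tiny_d6_defs)$phenotype])
      }
    }
  }
})

test_that("translation is symmetric in allele order", {
  pairs <- list(c("*1", "*4"), c("*17", "*2"), c("*1", "*17"))
  for (p in pairs) {
    a <- call_phenotype(parse_diplotype(paste0(p[1], "/", p[2]), "CYP2C19"),
                        shipped_defs)
    b <- call_phenotype(parse_diplotype(paste0(p[2], "/", p[1]), "CYP2C19"),
                        shipped_defs)
    expect_identical(a$phenotype, b$phenotype)
  }
})

test_that("unknown or uncertain alleles give Indeterminate, never altered", {
  unknown <- call_phenotype(parse_diplotype("*1/*999", "CYP2D6"),
                            shipped_defs)
  expect_identical(unknown$phenotype, "Indeterminate")
  expect_true(is.na(unknown$activity_score))
  uncertain <- call_phenotype(parse_diplotype("*1/*22", "CYP2D6"),
                              shipped_defs)
  expect_identical(uncertain$phenotype, "Indeterminate")
  expect_false(altered(unknown))
  expect_false(altered("Indeterminate"))
  expect_false(altered("NM"))
  expect_true(altered("PM"))
  expect_true(altered("RM"))
})

test_that("activity scores are refused outside CYP2D6", {
  expect_error(activity_score(parse_diplotype("*1/*2", "CYP2C19")),
               "CYP2D6")
})
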