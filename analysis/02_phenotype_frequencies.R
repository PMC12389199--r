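#!/usr/bin/env Rscript
# Translate the simulated cohort's diplotypes and summarize metabolizer
# phenotype frequencies per gene and jointly (the counts behind a phenotype
# UpSet plot), including the fraction with any altered (non-normal)
# phenotype.

suppressPackageStartupMessages(library(pgxconcord))

cohort <- read_cohort("results/synthetic/participants.csv",
                      "results/synthetic/trials.csv")
translated <- translate_cohort(cohort)
dist <- phenotype_distribution(translated)

out_dir <- "results/synthetic"
write.table(translated, file.path(out_dir, "phenotypes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
combos <- dist$combinations[dist$combinations$count > 0, ]
combos <- combos[order(-combos$count), ]
write.table(combos, file.path(out_dir, "phenotype_combinations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("CYP2C19 phenotype counts:")
print(dist$per_gene$CYP2C19)
message("CYP2D6 phenotype counts:")
print(dist$per_gene$CYP2D6)
message(sprintf("Altered (non-normal) phenotype in >=1 gene: %d/%d (%.1f%%)",
                dist$n_altered_any, dist$n,
                round_half_up(100 * dist$n_altered_any / dist$n)))
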