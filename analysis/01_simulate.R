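#!/usr/bin/env Rscript

# Stage 1: simulate the study cohort.
#
# Generates a synthetic peripheral-blood microarray cohort with the same
# shape as the study this pipeline emulates: 22,078 log2-intensity features
# on 89 IPF cases and 26 healthy controls, 2% of genes differentially
# expressed at 2 gene-sds, severity strata mixed 23:44:14:8 among cases.
# Writes the expression matrix (TSV), annotations (CSV) and the list of
# truly differential genes (the simulation truth) under data/.

suppressMessages(library(bprsig))

SEED <- 20141016
dir.create("data", showWarnings = FALSE)

cfg <- synthetic_config(effect_size_sd = 2.0, de_fraction = 0.02, seed = SEED)
cohort <- generate_cohort(cfg)

write_expression(cohort$expression, "data/expression.tsv", digits = 6)
write_annotations(cohort$annotations, "data/annotations.csv")
writeLines(cohort$de_features, "data/de_truth.txt")

cat("Simulated cohort:", nrow(cohort$expression), "features x",
    ncol(cohort$expression), "samples\n")
print(table(cohort$annotations$phenotype))
cat(length(cohort$de_features), "genes carry a true class shift\n")
cat("Wrote data/expression.tsv, data/annotations.csv, data/de_truth.txt\n")
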