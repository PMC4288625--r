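#!/usr/bin/env Rscript

# Stage 3: choose the signature size by nested leave-one-out cross-validation.
#
# Consecutive candidate signatures over k = 50..120 genes are each scored on
# the training cohort by nested LOOCV (feature selection redone inside every
# fold): ROC AUC first, sum of deviance as the tie-breaker, smallest k last.
# The range is capped at 120 (rather than the method's traditional 250) to
# keep a desk-scale run in minutes; widen k_max for a full sweep.

suppressMessages(library(bprsig))

SEED <- 20141016
x <- read_expression("data/expression.tsv")
ann <- read_annotations("results/annotations_split.csv")
tr <- ann$sample_id[ann$cohort == "TRAINING"]
y_tr <- ann$phenotype[match(tr, ann$sample_id)]

tuning <- suppressWarnings(
  tune_k(x[, tr], y_tr, k_min = 50, k_max = 120,
         iterations = 2000, burn_in = 500, seed = SEED))
print(tuning)

write.table(tuning$curve, "results/curve.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(as.character(tuning$chosen_k), "results/chosen_k.txt")
cat("Wrote results/curve.tsv and results/chosen_k.txt\n")
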