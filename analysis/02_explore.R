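#!/usr/bin/env Rscript

# Stage 2: unsupervised exploration and the cohort split.
#
# Classifies disease severity from pulmonary function, performs the
# stratified systematic training/validation split (every third sample per
# stratum), filters to the top decile by coefficient of variation, and runs
# PCA and average-linkage clustering on the filtered data. On a well-behaved
# cohort the PCA should NOT separate batches or severity strata - this stage
# is the sanity check that justifies pooling all severities downstream.

suppressMessages(library(bprsig))

x <- read_expression("data/expression.tsv")
ann <- annotate_severity(read_annotations("data/annotations.csv"))
dir.create("results", showWarnings = FALSE)

sp <- split_cohorts(ann)
ann <- apply_split(ann, sp)
write_annotations(ann, "results/annotations_split.csv")
print(sp)

filtered <- cov_filter(x, 0.10)
cat("CoV filter:", nrow(x), "->", nrow(filtered), "features\n")

pca <- run_pca(filtered, 2)
cat(sprintf("PC1 %.0f%% + PC2 %.0f%% = %.0f%% of variation\n",
            100 * pca$variance_fractions[1], 100 * pca$variance_fractions[2],
            100 * sum(pca$variance_fractions)))
write.table(data.frame(sample_id = rownames(pca$sample_scores),
                       pc1 = pca$sample_scores[, 1],
                       pc2 = pca$sample_scores[, 2],
                       phenotype = ann$phenotype[match(rownames(pca$sample_scores),
                                                       ann$sample_id)],
                       severity = ann$severity[match(rownames(pca$sample_scores),
                                                     ann$sample_id)],
                       cohort = ann$cohort[match(rownames(pca$sample_scores),
                                                 ann$sample_id)]),
            "results/pca_scores.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

hc <- hcluster(filtered[, sp$training_ids], "samples")
write(ape::write.tree(ape::as.phylo(hc)), "results/training_dendrogram.nwk")
cat("Wrote results/pca_scores.tsv and results/training_dendrogram.nwk\n")
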