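# bprsig — blood gene-expression diagnostic signatures via Bayesian probit regression

`bprsig` builds and validates *functional gene signatures*: portable
classifiers that call a disease phenotype (here idiopathic pulmonary
fibrosis, IPF, versus healthy) from a peripheral-blood expression profile.
A functional gene signature is more than a gene list — it bundles the
selected features, the training-set factorization that summarizes them, a
fitted Bayesian regression with uncertainty, and a decision threshold, so it
can be applied to any new sample.

It is aimed at transcriptomics analysts who have a normalized log2
expression matrix with case/control labels and want an honestly
cross-validated signature plus an independent-validation report.

## The method

For a training matrix `X` (features × samples) and labels `y`:

1. **Feature ranking** — pooled-variance two-sample *t* statistic per gene;
   the top *k* genes by |t| enter the signature.
2. **Metagene summarization** — center each selected gene and take the SVD
   `Xc = U D Vᵀ`; the first two left singular vectors define two *metagenes*
   and any sample is summarized as `f = U₂ᵀ (x − μ)`.
3. **Bayesian probit regression** — `P(y = 1 | f) = Φ(β₀ + β₁f₁ + β₂f₂)`
   with a diffuse `N(0, 10⁶ I)` prior, sampled by the Albert–Chib
   data-augmentation Gibbs sampler (C++ core, bit-reproducible given a
   seed). Predictions are posterior-mean probabilities with 95% credible
   intervals.
4. **Size selection** — every *k* in a range (classically 50–250) is scored
   by *fully nested* leave-one-out cross-validation: selection,
   factorization and fitting are redone inside each fold. Best ROC AUC
   wins; sum of deviance `SOD = Σ|yᵢ − pᵢ|` breaks ties, then the smaller *k*.
5. **Validation** — the final model predicts a held-out cohort (assigned by
   a stratified every-third-sample rule); the Youden index picks the
   threshold, and the report carries AUC, sensitivity, specificity, PPV,
   NPV, accuracy and a Wilcoxon rank-sum p-value.

A synthetic-cohort generator (`generate_cohort()`) emulates the kind of
dataset the method was designed for — 22,078 heteroscedastic log2-intensity
features on 89 cases and 26 controls, a minority of shifted genes, severity
strata derived from simulated pulmonary function — so the whole pipeline
runs with no external data.

## Worked example

```r
library(bprsig)

# a modest cohort: 2,000 genes, 62 cases vs 18 controls, 3% of genes
# shifted by 0.75 gene-sds
cohort <- generate_cohort(synthetic_config(
  n_features = 2000, n_ipf = 62, n_normal = 18,
  de_fraction = 0.03, effect_size_sd = 0.75, seed = 7))
ann <- annotate_severity(cohort$annotations)
split <- split_cohorts(ann)

x_train <- cohort$expression[, split$training_ids]
y_train <- ann$phenotype[match(split$training_ids, ann$sample_id)]

tuning <- tune_k(x_train, y_train, k_min = 30, k_max = 60,
                 iterations = 2000, burn_in = 500, seed = 7)
print(tuning)
#> Nested LOOCV tuning over k = 30 .. 60
#>   chosen k = 44 (AUC 0.833, SOD 9.361)

model <- train_signature(x_train, y_train, k = tuning$chosen_k, seed = 7)
preds <- predict(model, cohort$expression[, split$validation_ids])
y_val <- ann$phenotype[match(split$validation_ids, ann$sample_id)]
report <- evaluate_performance(preds$probability, y_val)
print(report)
#> Validation performance (19 IPF vs 6 normal)
#>   AUC         0.772
#>   threshold   1.000 (youden)
#>   sensitivity  68%
#>   specificity  83%
#>   PPV          93%
#>   NPV          45%
#>   accuracy     72%
#>   Wilcoxon p  0.043

head(preds, 3)
#>   sample_id probability      ci_lo ci_hi call
#> 1    IPF008   0.7617421 0.01246285     1  IPF
#> 2    IPF010   1.0000000 1.00000000     1  IPF
#> 3    IPF012   0.9904210 0.84806824     1  IPF
```

Reading the output: nested LOOCV judged a 44-gene signature best on the
training cohort (internal AUC 0.833); applied to the 25 held-out samples it
ranks cases above controls with AUC 0.772 and, at the Youden-optimal
threshold, calls 68% of cases and 83% of controls correctly. Each prediction
carries a posterior credible interval — wide for the uncertain `IPF008`,
collapsed for confident calls. At this weak effect size the probabilities
saturate near 1 (a property of t-selected signatures overfitting small
cohorts), which is why the threshold lands near 1; stronger signals or more
samples spread the scale out. Fit warnings about the Geweke diagnostic flag
chains that drift under class separation — see the vignette.

## The analysis workflow

`analysis/` holds the same pipeline as numbered narrative scripts over a
simulated study-sized cohort (22,078 × 115, effect 2 sd):

```sh
Rscript analysis/01_simulate.R   # cohort + planted-truth list -> data/
Rscript analysis/02_explore.R    # severity, split, CoV filter, PCA -> results/
Rscript analysis/03_tune.R       # nested-LOOCV tuning curve -> results/curve.tsv
Rscript analysis/04_validate.R   # final model, predictions, report -> results/
```

`run_full_pipeline(pipeline_config(...))` does the same from file paths in
one call, writing `curve.tsv`, `model.json`, `preds.tsv`, `report.json` and
a seed-stamped log.

## Documentation

The methods vignette (`vignettes/blood-signature-methods.Rmd`) explains the
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, the
numerical conventions, and known limitations.
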