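# somnia

Ensemble prediction of self-disclosed insomnia from microblog text.

## The problem

Users who repeatedly post about their own sleeplessness form a
self-disclosed insomniac population whose *other* language — word-category
usage, sentence semantics, personality traits — may carry predictive signal.
`somnia` implements that study design end to end for a binary
insomniac/control label:

1. **Cohort**: a synthetic generator calibrated to the published summary
   statistics of a 1574-user microblog cohort (820 insomniacs, 754
   controls): tweet volumes, disclosure-post frequency (mean 28.60, SD
   24.57, range 8–363), Big 5 trait means (insomniac neuroticism 0.83),
   gender and country composition, and a pregnancy/postpartum subgroup.
   Token streams carry planted class-conditional category effects, so every
   downstream stage is testable against known truth.
2. **Preprocessing**: mention and URL removal, hashtag-to-text, emoji-to-word,
   emoticon removal, contractions and stop words kept — and, crucially,
   whole-token stripping of the label-defining seed phrases ("insomnia",
   "sleepless") so no model can read the answer key.
3. **Three feature families**: LIWC-convention percent-of-token category
   scores against an open JSON lexicon; deterministic 768-dimensional
   feature-hashing sentence embeddings mean-pooled per user (a pluggable
   stand-in shaped like a transformer encoder); Big 5 trait vectors.
4. **Selection**: two-class Fisher criterion `J = (μ₁−μ₂)²/(s₁²+s₂²)` with
   the conventional `J > 1` admission rule, plus greedy collinearity pruning
   (|r| ≥ 0.7 drops the lower-J member of a pair).
5. **Models**: naive Bayes, random forest, SVM, AdaBoost, Gaussian process,
   and a two-hidden-layer dense network (leaky-ReLU → tanh + dropout →
   softmax, Adam, binary cross-entropy) for the embeddings, evaluated by
   repeated stratified cross-validation inside a 70/30 model-building split.
6. **Double-weighted ensemble**: on a shared 60/40 weighting split, each
   family's best model contributes `W = 1 − RMSE` per split side; the sides
   merge by a convex coefficient λ and the final score is

   I_final = Σₘ Wₘ·Yₘ / Σₘ Wₘ,

   a probability in the convex hull of the component predictions,
   thresholded at 0.5.
7. **Reporting**: midrank ROC/AUC, per-class TPR/FPR, 2×2 Pearson
   chi-square, five-bin trait distributions, and seeded collapsed-Gibbs LDA
   topic models for subgroup corpora.

The methods vignette (`vignettes/insomnia-ensemble.Rmd`) documents the
model, every calibration decision, and the limits of what synthetic cohorts
can show.

## Worked example

A balanced cohort in which each family carries its own moderate signal
(`complementary_config()`), run through the whole pipeline:

```r
library(somnia)
pl <- run_insomnia_pipeline(complementary_config(seed = 101),
                            cv = cv_config(folds = 5, repeats = 2, seed = 101),
                            net = net_config(epochs = 60, hidden = c(32, 16)),
                            fisher_threshold = 0.2)
pl
#> <somnia_pipeline> 300 users
#>   lexicon features: negate, swear, health, sad, death
#>   trait features: conscientiousness, neuroticism
#>   ensemble AUC: train 1, test 0.916
#>   component test AUC: lexicon=0.851, embedding=0.741, traits=0.836
pl$ensemble
#> <somnia_ensemble> lambda 0.5
#>   approach   model_train    model_test rmse_train rmse_test   w_train    w_test w_combined
#>    lexicon random-forest   naive-bayes 0.15456390 0.3996159 0.8454361 0.6003841  0.7229101
#>  embedding embedding-net embedding-net 0.01507655 0.4706593 0.9849234 0.5293407  0.7571321
#>     traits random-forest   naive-bayes 0.16712686 0.4057080 0.8328731 0.5942920  0.7135826
```

The fused test AUC (0.916) exceeds each single family (0.851 / 0.741 /
0.836): the three channels are moderate and partly independent, the regime
in which error-diverse fusion pays. Each row shows the family's best model
per split side, its RMSE there, and the resulting weights `W = 1 − RMSE`
merged at λ = 0.5.

The descriptive analyses recompute directly:

```r
compare_groups(pl$features, "anx")
#> anxiety-word usage: Yes 2.16 vs No 1.89 (+14%)
#> (the generator plants a +10% anxiety-word excess; this cohort drew +14%)

chi_square_2x2(cohort_reference()$gender_table)
#> X2 = 17.57, df = 1, p = 2.77e-05   # gender-insomnia association
```

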