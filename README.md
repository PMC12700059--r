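# placebotalk

Predicting placebo response in chronic pain from the language of
patient interviews.

In placebo trials for chronic low-back pain, some patients report
statistically significant pain relief after an inert treatment and
others do not. `placebotalk` implements a complete, testable analysis
chain for asking whether that split is visible in how patients talk:

* **Responder labelling** — each participant's twice-daily 0–10 pain
  ratings (28 baseline, 28 per treatment phase) are compared by a
  one-sided permutation test (Welch t statistic, exact enumeration when
  feasible); a participant is a *responder* if either treatment phase is
  significantly below baseline, and their *analgesia magnitude* is the
  percent drop of the last treatment week relative to baseline.
* **Document embeddings** — topic-tagged interview transcripts are
  cleaned (annotations, URLs and user tags become `[UNK]`; HTML,
  markdown and emoji are stripped; capitalization is preserved),
  structured sequentially or by topic, encoded token-by-token
  (D = 768), pooled (elementwise mean or max) into one vector per
  participant, with over-long documents split into two overlapping
  encoder windows so nothing is truncated.
* **Classification** — robust (median/IQR) scaling, top-k ANOVA-F
  feature selection, and a linear SVC minimizing
  `||w||₁ + C Σ max(0, 1 − y(w·x + b))²`, tuned over
  k ∈ {1,2,5,10,20,50} × C ∈ {0.01,0.1,1,10} in a stratified 10-fold
  inner loop and evaluated by leave-one-out outer cross-validation,
  with label-permutation significance and a bootstrap CI.
* **Interpretation** — any string can be projected into the model's
  space and scored by its signed Euclidean distance to the decision
  hyperplane, `(w·x + b)/‖w‖₂` (> 0 = responder side); interview
  sentences are clustered by a built-in HDBSCAN (mutual reachability,
  condensed tree, stability selection; unclusterable sentences are
  noise) and each cluster is placed by its centroid's distance.
* **Transfer validation** — a fitted model is applied as-is to an
  independent cohort, or refit on the subset of interview topics the
  two studies share; plus no-treatment specificity checks and
  cross-model feature correlations.

Because clinical interview corpora of this kind are not public, the
package includes a fully seeded synthetic-cohort generator (diaries,
transcripts, ground truth) with the statistical structure the analysis
assumes — planted semantic signal in a small number of embedding
dimensions, class-specific cue rates, recurrent template sentences —
so the entire pipeline is reproducible and testable offline. See the
methods vignette (`vignettes/placebotalk-methods.Rmd`) for the model,
all defaults, and the generator's scope.

## Worked example

```r
library(placebotalk)

cfg <- synthetic_config(seed = 2024)      # 60 participants, 16 topics
cohort <- generate_cohort(cfg)

outcomes <- label_cohort(cohort$diaries, n_perm = 2000, seed = 1)
table(outcomes$responder)
#> FALSE  TRUE
#>    30    30

encoder <- toy_encoder_for(cfg)
X <- embed_transcripts(encoder, cohort$transcripts,
                       mode = "sequential", pooling = "mean")
y <- outcomes$responder[match(rownames(X), outcomes$participant_id)]

cv <- nested_cv(X, y, seed = 1)
cv
#> nested CV over 60 samples: outer accuracy 0.950 (95% CI 0.88-1.00)
#>   mean inner-CV accuracy of selected models: 0.974

pipe <- final_fit(X, y, seed = 1)
probe_concepts(pipe, encoder, concept_tokens(cfg)$token)
#>         label signed_distance         side
#> 1    respcue2        8.683906    responder
#> 2    respcue1        1.585841    responder
#> 3 nonrespcue1      -16.196526 nonresponder
#> 4 nonrespcue2      -17.713895 nonresponder

analgesia <- outcomes$analgesia_pct[match(rownames(X),
                                          outcomes$participant_id)]
ct <- group_contrast(analgesia, factor(predict(pipe, X),
                     c("nonresponder", "responder")))
round(c(ct$group_means, d = ct$cohens_d), 3)
#> [1] -0.875 23.526  d = 3.351
```

Reading the output: 30 of 60 synthetic participants were labelled
responders by the permutation test on their diaries; leave-one-out
accuracy of the language classifier was 0.950 against those labels; the
planted responder cue words project onto the responder side of the
fitted boundary and the non-responder cues onto the other side; and
participants the model predicts to be responders show ~24% pain relief
versus ~0% for predicted non-responders (Cohen's d 3.4) — the planted
effect, recovered end to end. On real data the same calls apply with
`read_ratings()` / `read_transcripts()` and a transformer encoder
behind the `toy_encoder()` contract.

A full run — simulate, label, embed, fit, interpret, validate, with all
artifacts and a stage log written to an output directory — is

```r
run_pipeline(list(seed = 1, out_dir = "run1", validate_cohort = TRUE))
```

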