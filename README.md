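# epiwatch

Two-stage surveillance of online epidemic information, for infodemiology
researchers and public-health opinion monitors. During an outbreak,
online platforms carry a flood of epidemic messages of which a sizeable
fraction is false; acting on the stream requires (1) filtering the false
items out and (2) watching the surviving "effective" stream for public
opinion shifts that warrant early warning. `epiwatch` implements both
stages as composable R functions around a from-scratch second-order
gradient-boosted tree classifier.

## The method

**Stage 1 — identification of false epidemic information.**

- *Reliable sources.* A link graph over N web pages is summarized by a
  column-stochastic transfer matrix M with M[i, j] = 1/outdegree(j) when
  page j links to page i. Damped power iteration (damping 0.85) over M
  yields a reliability score per page; pages at or above the uniform
  baseline 1/N (or a top fraction) are kept as reliable sources.
- *Nine features per message*, spanning four levels plus one regulatory
  feature:
  | | feature | level |
  |---|---|---|
  | F1 | subject relevance: mean over (noun, feature word) pairs of max(PMI, 0), with PMI(a, b) = log p(a,b) / (p(a) p(b)) estimated from document frequencies | coarse granularity |
  | F2 | count W of nouns, verbs, adjectives, adverbs | fine granularity |
  | F3 | clause count S | fine granularity |
  | F4 | effective length E/T (characters after removing invalid ones over total) | fine granularity |
  | F5 | emotional intensity P/(P+R), the positive share of polarized clauses | emotional orientation |
  | F6 | real-name indicator | publisher behaviour |
  | F7 | platform tier in {1, 2, 3} | publisher behaviour |
  | F8 | historical message count H | publisher behaviour |
  | F9 | regulatory: running probability the publisher released false information, 0 at start | regulatory |
- *Classifier.* An additive tree ensemble trained by second-order
  boosting of the logistic loss: round t fits a regression tree to the
  per-sample gradients g = p − y and hessians h = p(1 − p) at the
  previous margin, minimizing

      Obj_t = Σ_j [ G_j w_j + ½ (H_j + λ) w_j² ] + γT,

  so each leaf takes the closed-form weight w_j\* = −G_j/(H_j + λ) and
  splits maximize the structure-score gain
  ½[G_L²/(H_L+λ) + G_R²/(H_R+λ) − G²/(H+λ)] − γ (exact greedy search,
  midpoint thresholds). Messages classified false are filtered out,
  each publisher's F9 becomes its classified-false fraction, and every
  publisher with F9 ≥ θ (default 0.5) is eliminated with all of its
  messages.
- The learner is implemented in this package (`epiboost()`); the
  xgboost library appears only in the test suite as an independent
  cross-check of margins and structure scores.

**Stage 2 — five-indicator early warning** over daily windows of the
effective messages:

| | indicator | definition |
|---|---|---|
| I1 | quantity change rate | Qr = (l₂ − l₁)/l₁ between adjacent days |
| I2 | regional coverage | Ac = p_l/P, distinct provinces mentioned over P (default 34) |
| I3 | emotional tendency | Et = mean of per-message F5 over the window |
| I4 | subject concentration | Tc = n/c with c clusters from adaptive PMI clustering of per-message noun lists |
| I5 | new subjects | Nt = current clusters whose PMI relevance to every previous-day cluster is below a threshold |

Because no deposited corpus exists for this problem, a seeded
synthetic-corpus module (`generate_corpus()`, `generate_link_graph()`,
`generate_timeline()`) plants the distributional structure the feature
system assumes — topical co-occurrence, polarity ratios, publisher
profiles, topic drift — so the whole pipeline is testable offline.

## Worked example

```r
library(epiwatch)

gen <- generate_corpus(generator_config(n_messages = 300, seed = 42))
report <- run_identification(
  gen$corpus, gen$feature_words,
  pages  = generate_link_graph(generator_config(n_pages = 100, seed = 42)),
  config = pipeline_config(seed = 42))
print(report)
#> <identification_report> test accuracy 1.000, 187 effective message(s)
#>   reliable source pages: 11
summary(report$model)
#> <epiboost> 50 tree(s), depth <= 3, eta = 0.3, lambda = 1, gamma = 0
#>   trained on 240 samples, 8 features; final objective 2.44032
#> Feature importance (total split gain):
#>                 feature        gain
#>    f1_subject_relevance 278.5855173
#>     f4_effective_length   8.0921320
#>   f2_feature_word_count   1.8924032
#>  f5_emotional_intensity   1.5913902
#>       f8_history_amount   0.4837724
#>   ...
```

The report says: of 300 labeled synthetic messages, the model trained
on an 80% stratified split classified the held-out 20% perfectly, and
after filtering classified-false messages and eliminating publishers
whose false-history probability reached θ = 0.5, 187 effective messages
remain. Subject relevance (F1) dominates the importance ranking — the
planted false messages are mostly off-topic. Early warning on the
filtered stream:

```r
ind <- run_warning(report$filtered_corpus, gen$gazetteer)
head(ind[, 1:6], 4)
#>         date n_messages i1_change_rate i2_region_coverage i3_emotional_tendency i4_concentration
#> 1 2020-02-04         20             NA          0.6176471             0.4306548         2.500000
#> 2 2020-02-05         25           0.25          0.7352941             0.3971429         2.777778
#> 3 2020-02-06         24          -0.04          0.5882353             0.4666171         3.000000
#> 4 2020-02-07         18          -0.25          0.5588235             0.5879630         3.600000
```

Day one's change rate is undefined (no preceding day); on 5 February
the message count rose 25%, the messages touched 25 of 34 provinces
(Ac = 0.74), average sentiment stayed slightly negative (Et < 0.5), and
attention concentrated at ~2.8 messages per subject cluster.

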