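# tcmrec

Multi-task meta-attention recommendation of Traditional Chinese Medicine
(TCM) evidence elements.

In TCM syndrome differentiation, a consultation record — tokenized symptom
findings, demographics, consulting department and season, disease name —
is mapped to a set of *evidence elements* (atomic diagnostic units such as
"xu" = deficiency), grouped into five categories: a = disease site,
b = essential substance, c = disease evil, d = pathological state,
e = connecting word. `tcmrec` ranks all candidate elements per case so the
true ones surface at the top, for builders of clinical decision-support
tools and for methods researchers who need a fully testable reference
implementation.

The package implements the whole pipeline:

* **Corpus I/O** — delimited/JSON-lines case readers with strict
  validation, deterministic vocabularies, reproducible train/test splits,
  and a schema-versioned feature store.
* **Knowledge-guided features** — symptom–element association statistics
  (co-occurrence probability `count(a,b)/count(a,B)`, rule confidence
  `count(A∩B)/count(A)`, support `count(A∩B)/count(T)`, TF–IDF with
  `IDF = log N/(n_i+1)`), sexagenary-calendar features of the birth year,
  female-seven/male-eight age-stage codes, diagnosis labels, and
  per-symptom common-element priors.
* **The model** — embeddings → multi-head self-attention + feed-forward
  over the symptom sequence → squeeze-and-excitation fusion with dense
  statistical features → S shared + K task-unique experts gated by
  scene-conditioned **meta-attention** (`α_i = Vᵀ Meta(E_i)`, where the
  Meta unit's weights are generated from the scene embedding,
  `W_meta = Reshape(W·e_scene + b)`) → per-task meta towers → five
  category score vectors. MLP and MMoE baselines share the input pipeline.
  Forward and backward passes run on a small reverse-mode autodiff tape
  verified by finite differences.
* **Training** — minibatch Adam with seed-reproducible shuffling, held-out
  evaluation, best-checkpoint retention, early stopping, and a five-run
  mean ± sd harness.
* **Evaluation** — AUC, Hits@10, mean rank, MRR, and the positional
  **unit hit rate** (fraction of cases whose k-th ranked prediction is a
  true element), with `hits_avg` = mean of positions 1–3. All metrics are
  cross-checked against brute-force oracles.
* **Synthetic corpora** — a generator with planted per-scene
  `P(element | symptom)` tables plus a Bayes-optimal ranking oracle, so
  that feature statistics, learnability and metric behavior are testable
  without private clinical data.

## Worked example

```r
library(tcmrec)

cases <- example_cases()                   # packaged 6-case corpus
stats <- build_association_stats(cases)

rule_confidence(stats, "white moss", "xu") # 0.5
rule_support(stats, "stringy pulse", "xu") # 0.3333333
term_frequency(stats, "zu", "c002")        # 0.25
inverse_doc_frequency(stats, "zu")         # 1.098612  (= ln 3)
```

`"white moss"` appears in two cases and co-occurs with `"xu"` in one of
them, hence confidence 0.5; `"stringy pulse"` and `"xu"` share two of the
six cases, hence support 1/3; `"zu"` is one of four element tokens in its
case (TF 0.25) and occurs in a single case of six (IDF ln(6/2)).

Training on a planted corpus and comparing against the Bayes ceiling:

```r
spec  <- synthetic_spec(n_symptoms = 50, n_elements = 30, n_scenes = 5,
                        n_diseases = 10, seed = 101)
corp  <- generate_corpus(spec, 6000, seed = 102)
split <- split_dataset(corp$cases, 1/6, seed = 103)

vocabs <- build_vocabularies(split$train)
bundle <- dense_feature_bundle(vocabs, split$train)
model  <- build_model(vocabs,
                      model_config(expert_dim = 64, tower_dim = 64,
                                   scene_field = "department", seed = 104),
                      kind = "meta", prior = bundle)

fit <- train_model(model, split,
                   train_config(batch_size = 256, epochs = 40,
                                learning_rate = 3e-3, seed = 105))
report <- evaluate_ranking(fit$model, split$test)
report
#> <metric_report> n = 1000
#>   AUC      0.68951
#>   Hits@10  0.56417
#>   MeanRank 10.93742
#>   MRR      0.23698
#>   unit hit rate 1..3: 0.5600 0.4150 0.3830 (hits_avg 0.45267)

oracle <- oracle_predictions(spec, split$test, vocabs)
hits_at_k_mean(oracle, 10)                  # 0.6797464 — the Bayes ceiling
```

The Hits@10 of 0.564 means that on average 56% of a test case's true
elements appear in the model's top 10 (of 30 candidates); the unit hit
rate says the model's first-ranked element is correct for 56% of cases.
This run recovers 0.83 of the oracle's Hits@10 and 0.88 of its Hits@1; the
remainder is estimation error that no learner can close at this sample
size (see the methods vignette).

A thin command-line front end over the same functions lives at
`inst/cli/tcmrec.R` (`simulate`, `featurize`, `train`, `evaluate`,
`score`).

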