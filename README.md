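# gdrex — gene–disease relation extraction by joint ensemble learning

Biomedical abstracts assert (or deny) associations between genes and
diseases one sentence at a time: *"the LOXL1 gene polymorphism is associated
with exfoliation glaucoma"* asserts one; *"HIF-1alpha is **not** involved in
progression of colorectal carcinoma"* denies one. `gdrex` is an R toolkit
for the supervised extraction of these sentence-level associations, aimed at
text-mining practitioners who work with the public gene–disease gold corpora
(EU-ADR, GAD, CoMAGC, PolySearch) or need a fully reproducible testbed for
relation-classification pipelines.

## The method

Each candidate pair (one gene mention, one disease mention, same sentence)
is classified by a **joint** model:

* a **sparse handcrafted block** — word windows around the blinded entities
  (GW/GWR, DW/DWR), the leftmost relational keyword between them (RELW),
  mention bag-of-words and POS, mention order and bucketed token distance,
  POS|lemma|chunk local context, between-entity trigrams, pattern-template
  flags from trigger/action-verb/genetic-phenomenon lexicons, and a
  negation flag (a cue like "not"/"unlikely" within 4 tokens before a
  trigger);
* a **dense block** — the L2-normalised mean of skip-gram word embeddings
  (negative sampling, unigram^0.75 noise, subsampling, trained in-package
  with a bit-reproducible single-threaded implementation) over the
  between-entity and window tokens.

The concatenated vector X_i feeds a bagged ensemble of m instance-weighted
soft-margin RBF-kernel SVMs,

    min 1/2 wᵀw + C Σ c_i ξ_i   s.t.   Y_i (wᵀφ(X_i) + b) ≥ 1 − ξ_i,  ξ_i ≥ 0,

each trained on a stratified bootstrap subsample and aggregated by majority
vote (ties → negative); the vote fraction is the score. Evaluation is
stratified 10-fold cross-validated precision / recall / F (micro over pooled
confusion counts, macro alongside) plus ROC/AUC.

## Worked example

```r
library(gdrex)

# a labeled synthetic corpus with the generator's study conditions
pairs <- generate_corpus(generator_config(n_pos = 150, n_neg = 150,
                                          label_noise = 0.05, seed = 42))
corpus_stats(pairs)
#> corpus: 300 sentences, 300 pairs (151 positive / 149 negative),
#>         40 unique genes, 40 unique diseases

pairs[[1]]
#> <candidate_pair +1> MMP2 | gastric carcinoma
#>   These results suggest that MMP2 is linked to gastric carcinoma in a large population .

b <- extract_all(pairs[[1]], corpus_index = build_pair_index(pairs))
b[c("WINDOW:GW-1", "PATTERN:action_verb", "NEGATION:flag", "CONCEPT:order")]
#> $`WINDOW:GW-1`         "that"
#> $`PATTERN:action_verb` TRUE        # "linked to" matched between entities
#> $`NEGATION:flag`       FALSE
#> $`CONCEPT:order`       "GENE_DISEASE"

report <- cross_validate(pairs, pipeline_config(svm = svm_config(cost = 10)),
                         k = 5, seed = 42)
report
#> 5-fold cross-validation over 300 pairs
#>   micro: P = 95.33  R = 94.70  F = 95.02
#>   macro: P = 95.42  R = 94.69  F = 94.99
#>   AUC (pooled scores): 0.953
```

With 5% of labels flipped, the pipeline recovers the relation structure at
F ≈ 95 — the noise ceiling for this corpus — because positives carry a
trigger phrase between the entities while negatives either negate it or
co-mention without one.

Corpus files in the four gold-corpus dialects are normalised with
`read_corpus(path, dialect)` and written back with `write_interchange()`;
`benchmark_scores()` and `corpus_characteristics()` tabulate the published
reference scores and corpus sizes for orientation. A command-line wrapper
(`inst/cli/gdrex`) exposes `convert`, `embed`, `train`, `evaluate`,
`predict` and `simulate` subcommands over YAML run configurations.

## Layout

* `R/` — corpus I/O, preprocessing, feature extraction, embeddings
  (R wrapper), joint vectorizer, ensemble, evaluation, generator, CLI
* `src/skipgram.cpp` — the skip-gram negative-sampling trainer
* `inst/extdata/lexicons/` — editable seed lexicons (triggers, action
  verbs, genetic phenomena, context phrases, negation cues, stop words)
* `vignettes/joint-ensemble-extraction.Rmd` — the methods vignette: model,
  parameters, design decisions, limitations
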