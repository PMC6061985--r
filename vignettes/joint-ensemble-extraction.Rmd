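---
title: "Joint ensemble learning for gene-disease relation extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint ensemble learning for gene-disease relation extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The task and the model

`gdrex` classifies *candidate pairs* — one gene mention and one disease
mention co-occurring in a sentence — as asserted associations (+1) or false
associations (-1). The classifier is a bagged ensemble of soft-margin
RBF-kernel SVMs over a *joint* representation: a sparse block of handcrafted
linguistic features concatenated with a dense block pooled from skip-gram
word embeddings. The intuition is complementary coverage: handcrafted
windows, trigger lexicons and negation cues capture precise local evidence
(including for words an embedding has never seen), while the embedding block
supplies distributional semantics at the global level.

Formally, given training vectors $X_i$ with labels $Y_i \in \{+1,-1\}$, each
base model solves

$$\min_{w,b,\xi} \tfrac12 w^\top w + C\sum_i c_i\,\xi_i
\quad\text{s.t.}\quad Y_i\,(w^\top\varphi(X_i)+b) \ge 1-\xi_i,\ \xi_i \ge 0,$$

with $\varphi$ realised through the RBF kernel
$K(u,v)=\exp(-\gamma\|u-v\|^2)$ and optional per-instance weights $c_i$. $m$
base models are trained on stratified bootstrap subsamples (per-class size
$\mathrm{round}(f \cdot n_{\text{class}})$, drawn with replacement) and
aggregated by majority vote; the vote fraction is the prediction score.

## Corpus interchange

Four reader dialects (GAD-style label-per-sentence TSV, EU-ADR-style offset
TSV, CoMAGC-style XML units, PolySearch-style relevance lists) normalise to
one JSON-lines interchange format with 0-based half-open offsets. Two
dialect-level decisions deserve note:

* GAD- and PolySearch-style records label a sentence, not offsets; mentions
  are completed at read time by the longest-match-first dictionary tagger,
  and the first gene plus first disease mention form the candidate pair.
* CoMAGC has no native positive/negative split. Expression-change and
  causality annotation classes map to +1, everything else to -1, through an
  overridable configuration — it is an interpretation, not a corpus fact.

## Linguistic preprocessing

Tokenization is deterministic: whitespace split, edge punctuation peeled
into its own tokens, hyphenated biomedical terms kept whole, and forced
splits at mention boundaries so mentions never cross tokens. POS/lemma/chunk
layers come from a deterministic rule annotator (closed-class lexicons,
verb-base lexicon with inflection stripping, suffix heuristics, NP/VP chunk
runs); any statistical tagger can be plugged in through the annotator
adapter (`tokens -> equal-length pos/lemma/chunk`). A rule fallback, rather
than a model download, keeps every test reproducible offline. Entity
blinding replaces each mention with `GENE_ENTITY` / `DISEASE_ENTITY` so
features generalise across entity names.

## Feature families and their parameters

* **Windows** (`WINDOW:`): `GW-i`/`GWR-i` and `DW-i`/`DWR-i` are the i-th
  non-punctuation tokens left/right of the blinded entities; `RELW` is the
  *leftmost* between-entity token in the relational-keyword lexicon (a
  deterministic tie-break; the scan depth is `between_max`). Default sizes
  are (3, 1, 4, 3); a compact (2, 2, 3, 3) layout is also in circulation
  for this feature family and is one `window_config()` call away. Stop
  words are *retained* in windows — the reference window layout keeps
  "the"/"that" — while stop-word removal applies only to the global n-gram
  features. `boundary_slot` reproduces a quirk of windows computed over
  entity-tagged text, where the closing boundary of the rightmost entity
  consumes the first right-hand slot (emitted as the empty marker); it is
  on by default because the package's golden test reproduces the reference
  layout verbatim, and can be switched off.
* **Lexical** (`LEXICAL:`): lowercased unigrams of each mention surface and
  the POS tag sequence of the mention tokens.
* **Concept** (`CONCEPT:`): mention order (gene-first vs disease-first), the
  bucketed token gap — 0 adjacent, 1 near, 2 far, with the near threshold
  defaulting to 5 tokens (the bucket labels are standard, the numeric
  threshold is this package's choice and is configurable) — and the
  corpus-wide occurrence count of the normalized pair. "Corpus-wide" (not
  within-sentence) is an interpretation; during cross-validation the index
  is built from training folds only.
* **Context** (`CONTEXT_LOCAL:`/`CONTEXT_GLOBAL:`): POS|lemma|chunk triples
  for k = 2 tokens each side of each entity (no padding at sentence edges);
  between-entity trigrams (n = 3, stop words and punctuation removed
  first); a topic-sentence flag (sentence index 0); the bucketed corpus
  frequency of the pair; and the relationship-mention code (`I`/`FI`/`IA`)
  *passed through* when EU-ADR-style annotation supplies it — the codes are
  never computed, since no definition is available to compute them from.
* **Patterns** (`PATTERN:`): one flag per lexicon family (trigger words,
  action verbs, genetic phenomena, context-specific phrases) over the
  between-entity span plus a two-token margin, case-insensitive,
  longest-first; the leftmost matched phrase is also emitted.
* **Negation** (`NEGATION:`): flagged when a negation cue starts within 4
  tokens (configurable) before a trigger/action match in the between-entity
  span; the cue itself becomes a feature. This captures the asymmetry that
  "not involved in", "unlikely to be associated with" flip an otherwise
  relational context.

All lexicons ship as editable one-phrase-per-line text files, seeded from
the phrases this feature scheme is defined over; the shipped lists are
deliberately small and meant to be extended for real corpora.

## Skip-gram embeddings

`train_skipgram()` implements skip-gram with negative sampling from
scratch: noise distribution $\propto$ unigram$^{0.75}$, per-position window
radius uniform on $[1, c]$, frequent-word subsampling with discard
probability $\max(0, 1-\sqrt{t/f})$, linear learning-rate decay to
$10^{-4}\alpha_0$ (a tiny logged final alpha is a decay artifact, not a
setting), input vectors initialised uniformly on $(-0.5/D, 0.5/D)$ and
output vectors at zero. Defaults follow the regime the method was designed
around: window 8, 25 negatives, subsample threshold $10^{-5}$; the
dimensionality is a free choice, default $D = 100$. Training is
single-threaded with a self-contained xorshift generator, so a fixed seed
is bit-reproducible; the `threads` field is accepted for configuration
compatibility but one thread is always used.

Two practical notes. Tokens are lowercased and edge punctuation is stripped
before vocabulary construction, so "cancer," does not enter the vocabulary
as a new word. And the subsampling threshold is a *corpus-scale* parameter:
$t = 10^{-5}$ is calibrated for multi-million-word corpora, while on a
thousand-token test corpus it would discard nearly every token
($1-\sqrt{t/f} \approx 0.99$ at $f \approx 1/6$); desk-scale tests therefore
disable it (`subsample = 1`) and use more epochs.

`skipgram_objective()` computes the exact full-softmax average log
probability as a training diagnostic; negative sampling optimises a
surrogate of it, and on clustered corpora the objective after training
exceeds its value at initialisation.

## Joint vectorization

`fit_space()` freezes a sorted name-to-column map over the training
bundles; categorical features expand to `name=value` indicators; unseen
names at transform time are dropped, never grown. The dense block is the
L2-normalised mean embedding of the between-entity tokens plus the window
tokens (whole-sentence pooling is available) — normalisation keeps the
dense block on the same unit scale as the one-hot block so neither
dominates RBF distances. How the two representations are "jointly learned"
admits two readings, and both are implemented: `CONCAT` (one vector per
instance, the default for simplicity and reproducibility) and `MULTIVIEW`
(separate base SVMs per representation, votes pooled in the ensemble).
Concatenating the two MULTIVIEW views reproduces the CONCAT vector exactly.

## Ensemble defaults and numerics

`m = 10` base models at bootstrap fraction `frac = 0.5` are desk-scale
defaults in the spirit of subsample-ensemble SVM practice; both are
configurable, as the method itself fixes neither. `C = 1` and
$\gamma = 1/\text{dim}$ are the conventional defaults when no values are
published; small corpora benefit from larger `C` (the package's own tests
use `C` of 10-50 at n of a few hundred). Tie votes resolve to the negative
class — in doubt, no asserted association — which favours precision.
Uniform-weight base problems are delegated to libsvm (e1071); non-uniform
instance weights (the hook for up-weighting negation/trigger-bearing
instances) use a direct dual QP with per-instance box constraints solved by
kernlab's interior-point optimiser, with a $10^{-6}$ ridge on the kernel
matrix so bootstrap duplicates keep the dual well-conditioned. The
degenerate all-identical-vectors case falls back to a constant
majority-class model (ties negative). The ensemble logic itself — sampling,
weighting, voting — is implemented in this package, not delegated.

## Evaluation

Precision, recall and F (harmonic mean) are reported as percentages;
zero-denominator cases are 0 by convention; display rounding is two
decimals, round-half-even, with unrounded values kept internally. Published
per-corpus tables in this literature do not always state whether they are
micro or macro averaged (and occasionally print an F inconsistent with the
harmonic mean of the printed P/R, suggesting fold-averaging), so
`cross_validate()` always reports both: pooled-count micro scores are the
headline, per-fold and macro means sit alongside. Within each fold the
embedding, the pair-occurrence index, the feature space and the ensemble
are all fitted on the training portion only. ROC points sweep the distinct
vote-fraction thresholds in descending order, anchored at (0,0) and (1,1);
the trapezoid AUC equals the normalised Mann-Whitney statistic, which the
test suite asserts against a pairwise-comparison oracle.

## The synthetic generator: what it does and does not show

`generate_corpus()` emulates the statistical structure the method assumes:
one gene and one disease mention per sentence with exact offsets; positives
built from templates placing a trigger/action phrase between the entities;
negatives split between *negated* templates (a cue such as "not" or
"unlikely to be" immediately before the trigger) and *neutral* co-mention
templates, mirroring the fact that real corpora contain both
negation-marked and merely non-associative negatives; independent label
flips with probability $\varepsilon$; gene-shaped names (uppercase +
digits) and multiword lowercase disease names so dictionary tagging is
exercised. With $\varepsilon = 0$ and disjoint trigger/negation lexicons,
the pattern and negation features alone separate the corpus — the
generator's separability guarantee — and raising $\varepsilon$ lowers
achievable cross-validated F.

The generator makes no attempt to mimic real PubMed token distributions,
sentence lengths, multi-pair sentences, anaphora or cross-sentence
relations. Passing tests on synthetic corpora therefore demonstrate that
the pipeline's machinery is correct and leak-free, not that the shipped
lexicons or defaults reach any particular score on the real gold corpora,
which require external downloads and corpus-scale lexicons.

## Problem sizes and reproducibility

The package's own evaluation runs use: the study-condition corpus of 500
positive + 500 negative sentences with $\varepsilon = 0.05$ under 10-fold
cross-validation for the end-to-end recovery check; a 400-sentence
noiseless corpus for the exact-separability check; and the 200-sentence
two-cluster corpus (D = 16) for the embedding check. Every stochastic step
— generation, fold assignment, bootstrap, embedding training — is driven by
an explicit seed, and single-threaded embedding training makes reruns
bit-identical. `scripts/acceptance.R` re-derives the headline quantities
from scratch for any seed.

The command-line interface (`inst/cli/gdrex`) wires the same functions into
`convert`, `embed`, `train`, `evaluate`, `predict` and `simulate`
subcommands driven by a declarative YAML run configuration (YAML being the
standard configuration dialect in the R ecosystem); unknown configuration
keys are rejected rather than ignored.

## Known limitations

* The rule-based annotator is a deliberately simple fallback; real corpora
  deserve a statistical tagger behind the adapter interface.
* Shipped lexicons are seed lists, not the unpublished full lists the
  method was originally tuned with.
* Long, multi-clause sentences ("not only ... but also", multiple
  co-referent mentions) defeat window- and span-based features by design;
  dependency structure is out of scope.
* The dual-QP path for instance-weighted training is $O(n^3)$ and intended
  for base-model-sized subsamples, not full corpora.
* Vote fractions are uncalibrated scores, not probabilities.
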