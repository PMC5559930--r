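---
title: "Interpretable classification of health-forum sentences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable classification of health-forum sentences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`lspforest` classifies sentences from online health forums into three
classes — background (0), medication (1), symptom (2) — and explains its
predictions. This vignette documents the model, the tunable parameters,
the synthetic study corpus, and the design decisions taken where the
problem left genuine freedom.

## 1. The model

### Labeled sequences

A sentence is first rewritten as a *labeled sequence*: an ordered list
of tags paired with the class label. The tag alphabet is the
Penn-Treebank POS tags plus three special tags filled from lexicons:
`DRUG` (drug terms), `SYMP` (symptom terms) and `FREQ` (frequency
phrases described by regular expressions). Lexicon matches take
precedence over POS tags, are case-insensitive, proceed left-to-right
preferring the longest phrase at each position, and collapse a matched
multi-word span to a single tag — so the token count is an upper bound
on the sequence length. When spans tie in length, `FREQ` beats `DRUG`
beats `SYMP`: frequency phrases are the most structured of the three
and a tie usually means a frequency expression was also listed as a
term. Frequency regexes are matched on the raw sentence and mapped back
to token ranges, because phrases like "three times a day" cross token
boundaries.

POS tagging is an injected dependency with a pure contract (token
vector in, equal-length tag vector out). The bundled
`default_tagger()` is a deterministic dictionary tagger covering
closed-class English words and the synthetic generator's vocabulary,
with numerals tagged `CD`, punctuation tagged literally (the comma is
spelled `comma` so patterns serialize cleanly) and unknown words
defaulting to `NN`. Determinism keeps every mapping example exact; any
stronger tagger can be swapped in without touching the rest of the
pipeline.

### Frequent labeled sequential patterns

A *sequential pattern* is a tag subsequence matched at strictly
increasing positions whose consecutive index differences are at most a
gap threshold $g$ (default 5; $g = 1$ means adjacent). Support is the
fraction of database sequences containing the pattern; confidence for
class $l$ is the fraction of containing sequences labeled $l$. Patterns
with support $\ge \mu$ (default 0.05) and confidence $\ge$ 0.85 for
medication or symptom become *FLSPs* and enter the feature space as 0/1
containment indicators. Background is never a target class: background
sentences are, by definition, the residual class and are not
interpreted.

Mining is exact depth-first prefix growth with support pruning,
implemented in C++: a pattern is extended one tag at a time while every
feasible match end-position is retained per sequence, which makes the
extension step complete under the gap constraint, and support is
anti-monotone under prefix extension, which makes pruning sound. The
test suite checks the miner against exhaustive enumeration of gap-valid
embeddings on hundreds of random databases. Output order (descending
support, then lexicographic tags) is a pure function of the input.

Parameter notes: $\mu = 0.05$ keeps patterns that occur in at least ~5%
of sentences — low enough to admit class-specific constructions, high
enough to exclude singletons. Confidence 0.85 deliberately admits
somewhat impure patterns; the classifier, not the miner, makes the
final decision. `max_pattern_length` defaults to 6 tags, one more than
the longest pattern we ever found informative, purely as a cost guard.
Whether the gap threshold counts intervening items or index differences
is ambiguous in common usage; we fix *index difference* $\le g$ and
expose it as configuration.

### Feature space

Blocks are assembled in a fixed order (FLSP, semantic types, words,
morphological, heuristic) so column indices are reproducible:

* **Semantic types** — 0/1 per UMLS-style code (`sosy`, `phsu`,
  `patf`, ...). The upstream concept tagger is replaced by a pluggable
  phrase-table interface (`semantic_tagger()`): the framework only
  needs the 0/1 indicators, not the full UMLS machinery, and an
  external tagger can be adapted to the same interface.
* **Words** — case-folded unigram/bigram indicators, vocabulary built
  on the training fold only; terms in fewer than 2 training sentences
  are pruned before any selection.
* **Morphological** — has a capitalized non-initial word (the pronoun
  "I" is excluded: its capitalization is orthography, not morphology);
  has an abbreviation, defined as $\ge 2$ uppercase letters or internal
  periods. Both definitions are declared conventions.
* **Heuristic** — thread-creator flag, post position, word count.
  Position and word count are kept *numeric*, not binarized: the tree
  models learn their own thresholds (such as "position < v"), which is
  strictly more expressive than fixing a cutoff up front.

Entropy-based feature selection fits a single `rpart` tree with the
information criterion (surrogates disabled so importance reflects
primary splits only) and keeps the top-k features by impurity decrease;
zero-importance features are never kept.

All fold-dependent state — FLSPs, vocabulary, selection — is refit
inside each training fold of `cross_validate()`; nothing leaks from
test to train.

### Forest, decomposition, discriminative patterns

The forest is grown by `ranger` (bootstrap size N, best-of-mtry Gini
splits, unpruned); defaults T = 500 trees and mtry = ceiling(sqrt(D)).
The package then reconstructs, for every node, the class-proportion
vector of the in-bag samples reaching it (the node's *criterion score
vector*). These vectors are the substance of everything interpretable:

* prediction = average of leaf vectors over trees, argmax with ties
  broken in class order (background < medication < symptom);
* per-feature contribution = summed child-minus-parent proportion
  changes across the splits on that feature along the instance's paths,
  averaged over trees;
* conservation, `bias + sum_k FC_k(x) = F(x)`, holds *exactly* (to
  floating-point) because prediction and decomposition read the same
  node tables — it is a telescoping sum, not an approximation.

The criterion score must be the class-proportion vector (not a scalar
impurity): conservation and the per-class columns of the contribution
tables are only defined for vectors that sum to the prediction.
Contributions of one instance sum to zero across classes, and a feature
never split on along the instance's paths contributes exactly zero.
Class-averaged contributions over all instances of one class, ranked by
the target-class column, give the per-class discriminative-feature
table; the implementation aggregates per occupied leaf (contributions
depend only on the leaf reached), which is algebraically identical to
per-instance averaging.

Discriminative patterns are complete root-to-leaf paths with leaf Gini
$\le$ 0.2 and $\ge$ 5 in-bag samples (both configurable; the defaults
encode "low impurity" and "not anecdotal"). Rules are canonicalized —
sorted by feature, redundant same-feature bounds merged — and
deduplicated across trees. Forward selection then adds, per iteration,
the candidate whose pattern-indicator set gives the best validation
accuracy of a linear-kernel SVM, accepting only strict improvements
(so the accepted-accuracy trajectory is strictly increasing) and
stopping early when nothing improves. Accuracy is measured on a
stratified 20% validation split with a fixed seed; the baseline before
any pattern is the majority-class rate. Ties between equally improving
candidates go to the lower candidate index. The selection's ill-posed
aspects (what data the accuracy is computed on; whether the final
pattern-space classifier replaces the forest) are resolved as: a
held-out split, and no — `dp_transform()` exposes the binary pattern
space and composition is left to the user.

### Baselines and evaluation

The SVM baseline is two one-vs-rest RBF-kernel machines (medication,
symptom) with Platt-scaled probabilities and gamma fixed to 1/D; a
sentence is background when both probabilities are below 0.5, otherwise
the larger one wins (exactly 0.5 is *not* "less than 0.5"). The lasso
baseline is one-vs-rest L1-penalized logistic regression at a fixed
penalty of 0.001, fitted without standardization so weights of 0/1
indicators are directly comparable and sign-interpretable.

Evaluation reports one-vs-rest precision/recall/F1/accuracy per class
and their class-size-weighted averages; weighted recall equals overall
multiclass accuracy identically (one-vs-rest recall is within-class
accuracy), which the tests assert on random label vectors. Empty
denominators yield 0 with a warning. Cross-validation is stratified
with a seeded fold assignment (stratification is our choice; with a 10%
background class, unstratified 5-fold splits can starve a fold).

## 2. The synthetic study corpus

Real labeled forum corpora of this kind are not public, so the
generator is a first-class module, not a test fixture. It emulates:

* **class balance**: default mixture (0.10, 0.54, 0.36) over
  (background, medication, symptom) at n = 2099, matching the setting
  the framework targets — a medication-heavy, background-light corpus;
* **planted patterns**: medication sentences realize a dosage template
  ("I am taking 90 units Lantus twice a day") containing the tag run
  `(CD, NNS, DRUG, FREQ)`; symptom sentences a coordinated symptom run
  ("I have nausea, bloating and fatigue") containing
  `(SYMP, SYMP, SYMP)`. Each full template occurs with probability 0.9
  (the occurrence probability); otherwise a degraded template without
  the planted run is used. The designed support is therefore
  class share x 0.9 (0.486 for medication) and designed confidence is
  1.0, because the special tags each pattern needs are class-exclusive
  by construction;
* **noise**: with probability 0.1 a filler adverb is inserted at a
  template boundary. Fillers never split a multi-word phrase and the
  induced gaps stay within g = 5, so noise dilutes nothing by design —
  it exercises the gap constraint rather than the thresholds;
* **thread structure**: symptom sentences come from thread creators
  with probability 0.8 (others 0.3) and from first posts with
  probability 0.7, reproducing the "creators describe their own
  condition early" heuristic;
* **lexicon closure**: the returned lexicons cover exactly the
  generated drug/symptom/frequency vocabulary, and the generator's word
  templates are chosen so the bundled dictionary tagger reproduces the
  intended tags exactly — generation is deterministic given the seed.

What the generator does *not* emulate: lexical diversity (a handful of
templates), misspellings, lexicon gaps (real drug lexicons miss terms),
annotation noise, and topic drift. Consequently, passing recovery and
end-to-end tests shows the machinery is correct and that the pipeline
recovers known structure under realistic class imbalance — it does not
certify real-world accuracy, where feature noise and lexicon coverage
dominate. On the synthetic corpus the forest with FLSP + semantic
features reaches ~0.99 cross-validated accuracy against a 0.55 majority
baseline; on real forum text the same pipeline would be expected to land
far lower, and the published setting this emulates reports accuracies
near 0.81.

## 3. Numerical choices and degenerate inputs

* Support thresholding uses the integer count `ceil(mu * N - 1e-9)` so
  floating-point representation of mu never excludes a boundary
  pattern.
* Argmax ties anywhere (forest, lasso, FLSP class assignment) break in
  fixed class order; miner output ties break lexicographically — all
  outputs are pure functions of inputs and seeds.
* Zero-support patterns have undefined confidence and are rejected, as
  are empty patterns and empty rule sets.
* Empty corpora, empty candidate sets and single-class training data
  raise informative errors rather than degenerate fits.
* Forward selection guards against degenerate SVM fits (constant
  indicator columns) by treating a failed fit as no improvement.
* Problem sizes in the tests: the miner-oracle equivalence runs on 200
  random databases small enough for exhaustive enumeration (≤ 8
  sequences of length ≤ 6); conservation is checked on 50 random
  forests x 100 probes at 1e-9; recovery tests use 20 generator seeds
  at n = 2099 (FLSP recovery) and n = 300 (contribution-ranking
  recovery, 50-tree forests); the end-to-end cross-validation uses the
  full default corpus with 200 trees. These sizes were chosen to make
  the probabilistic recovery criteria sharp (≥ 19/20 and ≥ 18/20
  successes) while keeping the suite brisk.

## 4. Known limitations

* The dictionary tagger is deliberately minimal; on open-domain text
  most content words fall back to `NN`, which flattens POS-level
  patterns. Real use should inject a trained tagger.
* Sentence splitting is a regex splitter with an abbreviation list, not
  a trained model; unusual markup or emoticon-heavy text will produce
  imperfect splits.
* The phrase-table semantic tagger matches exact (case-folded) token
  runs; no normalization, no concept disambiguation.
* `mine_fsps` enumerates *all* frequent patterns; on corpora with long
  sentences and permissive thresholds the pattern set grows
  combinatorially. The max-pattern-length cap is the safety valve.
* Forward selection retrains an SVM per candidate per iteration;
  with thousands of candidates it is the slowest interpretable step.
  Filtering candidates by leaf impurity/support first (the defaults)
  is assumed.
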