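---
title: "Methods: CRF chemical tagging and conditional-precision ensembles"
author: "chemner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CRF chemical tagging and conditional-precision ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemner)
```

# The problem

Chemical named-entity recognition locates every mention of a chemical
name or formula in free text, scored by exact character offsets within
a document section (title or abstract).  Two complementary strategies
are implemented here:

1. a **standalone tagger** — a first-order linear-chain conditional
   random field (CRF) over a feature battery designed for chemical
   nomenclature; and
2. an **ensemble combiner** — a probabilistic framework that fuses the
   span predictions of several black-box extractors into calibrated
   per-entity confidences, without requiring any individual extractor
   to emit a probability.

# The ensemble model

Let $E_1, \dots, E_n$ be indicator variables, one per extractor, with
$E_i = 1$ when extractor $i$ predicted a candidate span $t$ (a span is
identified by document, section, start and end offset only; overlapping
but unequal spans are distinct candidates).  The combiner estimates

$$P(t = \mathrm{Entity} \mid E_1, \dots, E_n)$$

for every non-zero outcome of the indicator vector — $2^n - 1$
parameters, since the all-zero outcome never produces a candidate.
Each parameter is estimated on an annotated corpus as the **precision
of a derived extractor**: for signature $s$, take the intersection of
the span sets of the extractors with $s_i = 1$, subtract the union of
the others, and compute the fraction of the remaining spans that are
gold.  With three extractors there are exactly 7 cells.

The estimate is the maximum-likelihood binomial proportion per cell, so
when the same corpus is scored with its own table, every retained set
at threshold $\tau$ is a union of cells whose precision is at least
$\tau$ — retained-set precision can therefore never fall below the
threshold.  This self-consistency property is the basis of the
threshold-tuning workflow: low $\tau$ favors recall, high $\tau$
precision, and the precision–recall curve (`pr_curve()`) is evaluated
at every realized confidence value.

Numerical choices:

* Cells never realized during estimation have a *missing* probability.
  When a later corpus produces such a signature, the default fallback
  scores it with the unweighted mean of the single-extractor
  probabilities of the firing extractors (policies `zero` and `error`
  are selectable).  The original three-extractor study realized all 7
  cells, so it never needed a fallback; the default is this package's
  own choice.
* No smoothing is applied by default (raw precisions are reported); an
  add-one option exists for very small estimation corpora.
* Estimation and scoring corpora are distinct inputs, reflecting the
  estimate-on-development / apply-on-test workflow.

# The CRF tagger

The tagger is a first-order linear-chain CRF over BIO labels (`B`
begins an entity, `I` continues it, `O` is outside).  Sentences are the
unit of inference: a rule-based splitter ends a sentence at `.`, `!` or
`?` followed by whitespace and an uppercase letter (or end of text),
and a chemistry-aware tokenizer ("chem", the default of a pluggable
registry) splits on whitespace and peels edge punctuation while keeping
internal hyphens, digit commas and balanced brackets attached — so
`1,2-dichloroethane` and `Ca(2+)` each stay one token, and a sentence
period is always split off.  The peeling is edge-only by design:
fragment-internal punctuation never splits a token, which is the
reading that keeps chemical names whole.

Feature families, per token:

* **word / lower** — the surface and its lowercase form;
* **shape predicates** — contains digit, initial capital, all capitals,
  all lowercase, mixed case, ends in a sign, ends in a digit, contains
  a dash, starts with a digit;
* **character n-grams** of length 2, 3 and 4;
* **formula heuristic** — set when no two consecutive characters are
  lowercase letters (`CO2`, `C2H5OH` fire; `Methanol` does not);
* **sentence-start marker** — distinguishes positional capitalization
  from intentional capitalization;
* **word class** — uppercase→`A`, lowercase→`a`, digit→`0`, other→`x`,
  plus the run-collapsed brief form (`Ca(2+)` → `Aax0xx` / `Aax0x`);
* **Soundex** — the census phonetic code generalized to a configurable
  digit count (default 7; the ablation grid is 3/5/7/100).  Codes are
  *not* zero-padded: padding would break the defining property that
  *carbon*, *carbonate*, *carbonic* and *carbonyl* all share `C615` at
  the census length of 3, and variable-length codes remain comparable
  across length settings.  Tokens with no ASCII letters share the
  sentinel code `#` rather than erroring.
* **embedding cluster id** — a hash-map lookup of the term (exact form,
  then lowercased — embedding corpora are conventionally lowercased and
  the choice is recorded here as this package's own default) returning
  `cluster=<id>`; absent terms yield *no* feature rather than a default
  id, so the model never confuses "unknown" with a real cluster;
* **gazetteer lookups** — token membership (`in_<name>`), whole-entry
  run membership (`in_<name>_full`), surface prefix/suffix matches, and
  a boost-term list emitting a bare `boost` feature.  Multi-word
  dictionary entries are pre-tokenized with the active tokenizer so
  lookups operate on the same token units as the CRF.

Neighboring tokens contribute their features re-keyed with the relative
offset (`word[-1]=...`).  The window width is per family: the source
design says only "1 or 2 based on the feature", so the defaults here
are the package's own choice — ±2 for word/lower, ±1 for shape, word
class, cluster, gazetteer and lemma families, 0 for Soundex and
n-grams.  The rationale is parameter growth: high-cardinality families
at wide windows multiply the feature space fastest, and Soundex/n-grams
already generalize across positions.

Training minimizes the L2-penalized negative log-likelihood with
L-BFGS (`stats::optim`), with penalty $\tfrac{\lambda}{2}\lVert\theta\rVert^2$,
$\lambda = 1$ by default (the classic CRF-toolkit default scale; the
source is silent).  Optimization starts from zero weights and is
deterministic given the data.  Gold mentions that do not coincide with
token boundaries are *skipped* (with a count in the training log)
rather than extended to token boundaries — extending would teach the
model systematically wrong offsets.

At tagging time the best label sequence is decoded by Viterbi and each
decoded entity's confidence is the product of the per-token marginal
probabilities of its labels, clipped to $[0,1]$ — the source defines no
confidence for the single tagger, and this choice is available from any
linear-chain CRF and monotone in model certainty.  An `I` emitted
without a preceding `B` is decoded as if it were `B`.  No
post-processing and no abbreviation matching are performed; a
surface-form blacklist filter exists but is off by default (the
revised tagger design dropped it).

# The tokenizer benchmark

Tokenization quality upper-bounds recall: an extractor cannot emit a
span its tokenizer never delimits.  `evaluate_tokenizer()` classifies
each gold mention as *correct* (a single token matches the span
exactly), *split correct* (the mention contains spaces — space being
the only admitted word separator — and every space-separated word is
matched exactly by one token), or *incorrect*; accuracy is the
percentage of the first two.  Two readings were possible for space-free
mentions (single token vs. a contiguous token run); the strict
single-token reading is used and asserted in tests.

# The synthetic world

`gen_corpus()` emulates what the real benchmark corpus provides, at
desk scale and fully seeded:

* chemical-like surface forms from a fragment grammar (stems
  *meth/eth/prop/but/pent/hex/hept/oct* × suffixes
  *-ane/-anol/-ylene/-oate/-anal/-anoic*), formula tokens satisfying
  the no-two-consecutive-lowercase heuristic (`CO2`, `C2H5OH`, …), and
  multi-word names (`... acid`, `... chloride`);
* defaults: 40 distinct chemical terms (25 % formulas, 20 % multi-word),
  a Poisson mean of 1.2 mentions per sentence, titles of one sentence
  and abstracts of 2–4; a gazetteer covering 70 % of the vocabulary and
  a cluster map that places chemical tokens in dedicated clusters.
  These are this package's definitions of a realistic small world —
  mention density and dictionary coverage of the same order as the
  real corpus — and they are fixed, not tuned.

Mentions are always whitespace-delimited by construction, so every gold
span is token-aligned under the default tokenizer and the corpus
separates logic errors from alignment noise.  What a green end-to-end
test establishes is therefore deliberately limited: the synthetic world
plants strongly separable lexical/cluster/gazetteer signal, so held-out
F1 near 1 shows the pipeline (offsets, labeling, features, optimization,
decoding) is correct — it says nothing about F1 on real abstracts,
which depends on an external corpus and is out of scope here.

`simulate_extractors()` is the generative inverse of table estimation:
it fabricates distinct spans per signature cell and marks them gold at
the cell's true fraction, either deterministically (*exact* mode —
estimation must recover the planted fraction to the integer) or by
independent coin flips (*stochastic* mode — estimation error is
binomial, standard error $\sqrt{q(1-q)/n}$ per cell).  Tests run the
stochastic recovery check at 20,000 candidates per cell, where the
worst-case deviation over 7 cells × 20 seeds sits well inside the 0.03
acceptance band; at the 1,000-candidate minimum the same band would be
at the mercy of a ~2.8σ tail event.

All generators draw from one explicitly seeded RNG and restore the
caller's RNG state, so fixtures are bit-reproducible and tests never
leak state.

# Known limitations

* Candidate identity in the ensemble is the exact span key; near-miss
  boundaries from different extractors are never merged.
* The default tokenizer approximates a chemistry-aware tokenizer but
  does not reproduce any third-party tokenizer byte for byte, and the
  published benchmark counts are not reproducible without the external
  corpus and tools.
* Lemmatization is a pluggable hook defaulting to off; word-class
  conversion is native.
* Training word embeddings at corpus scale is out of scope;
  `train_cluster_map()` (PPMI + SVD + K-means) exists for small-corpus
  integration testing of the cluster-feature pipeline only.
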