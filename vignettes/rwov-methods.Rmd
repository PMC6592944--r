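---
title: "Positional vectorization of clinical free text: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional vectorization of clinical free text: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwov)
```

## The problem

Pathology reports state biomarker results as free text, in a small but
variable set of phrasings: "estrogen receptor positive", "ER+", "positive
for ER", "positive staining for ER", "ER: 30%", or grouped lists such as
"positive for CK7 and MOC31, negative for CK5/6, TTF-1, CK20, ER and PR".
A bag-of-words representation records *which* words occur but not *where*
they sit relative to the marker being asked about, and it is exactly that
relative position that distinguishes "positive for ER, negative for PR"
from its converse. This package vectorizes a report by the signed
reciprocal positional distance between a **term of interest** (TOI — e.g.
the ER mention) and the words that co-occur with it most frequently across
the corpus, and ships the evaluation harness (per-class F1 and AUC,
stratified cross-validation on shared splits, percentile bootstrap
intervals, DeLong comparison of correlated AUCs) plus a synthetic report
generator so the whole pipeline is testable without access to protected
clinical text.

## The vectorization

For observation $i$ and relevant word $j$, the feature is

$$T(i,j) = \begin{cases} 0 & \text{word } j \text{ does not occur in block } i,\\
\pm\dfrac{1}{d+1} & d = \text{number of relevant-word occurrences strictly
between } j \text{ and the TOI,} \end{cases}$$

negative when the chosen occurrence of $j$ precedes the TOI anchor and
positive when it follows. Values therefore fall away nonlinearly from
$\lvert 1\rvert$ (adjacent in relevant-word terms) to $0$ (absent), and a
block without the TOI is an all-zero row. Distance is counted in
*relevant-word occurrences*, not raw tokens, which makes the feature
insensitive to interleaved non-relevant filler.

Conventions the formula itself does not fix, resolved here once and
deterministically:

* **Sign**: before the anchor is negative, after is positive.
* **Multiple occurrences of $j$**: the occurrence minimizing $d$ is used
  (proximity dominates); an exact tie between a before- and an
  after-occurrence resolves to after.
* **Multiple TOI occurrences**: the anchor is the first occurrence in the
  block. Blocks are one token stream; sentence boundaries do not reset
  positions.
* **Strict betweenness**: neither endpoint counts toward $d$; duplicate
  relevant words between are counted per occurrence, not per type.
* An empty relevant-word index is rejected at construction.

## Normalization

Blocks are sentence-split by a terminal-punctuation rule (period/`!`/`?`
followed by whitespace and a capital or digit — no statistical model),
tokenized into alphanumeric runs and single symbols (internal hyphens are
kept, so `Ki-67` and `her-2` survive intact), case-folded, filtered against
the fixed nine-word stop list (`the, are, of, as, is, and, or, report,
pathology`), symbol-substituted (`,` → `comm`, `/` → `slash`, `+` → `plu`),
and stemmed.

The stemmer is the package's own iterated suffix stripper: one plural strip
followed by up to three rounds of longest-suffix removal, never leaving
fewer than three characters, never touching tokens containing digits.
It reduces clinical vocabulary to short roots (`received` → `receiv`,
`prognostic` → `prognost`, `necrosis` → `necros`) but its exact surface
forms are a package convention, not a reproduction target; any fixed
stemmer yields an equivalent feature space as long as it is applied
corpus-wide.

Percentages qualified by a polarity word within the three preceding tokens
of the same sentence collapse to the identifiers `pospct`/`negpct`
("Positive (85%)" → `pospct`); unqualified percentages stay as a number
plus `%`. A stem that happens to land on a stop word is dropped, so no
output token ever equals a stop word.

## Relevant vocabulary

The top-$k$ words for a TOI are those occurring most often inside blocks
that contain at least one TOI match (canonical token or alias; multi-word
aliases are matched longest-first on normalized tokens, and `her/` matches
its tokenized form `her`+`slash`). Alias spans are consumed by the match,
but occurrences of the canonical token itself do count — repeated mentions
of the marker are evidence of relevance, and the marker routinely ranks
among its own top words. Mean frequencies divide by the total number of
observations, and ties at the cut rank break lexicographically, so the
vocabulary is a deterministic function of the corpus. The default is
$k = 30$.

## Baselines

Two comparison vectorizations consume the same normalized sequences:
n-gram count matrices over the ranges $(1,2), (2,2), (1,3), (2,3), (3,3)$
with smoothed IDF weighting $\log\{(1+N)/(1+\mathrm{df})\} + 1$ (ubiquitous
terms receive the floor weight 1), and skip-gram embeddings (dimension 100,
window 6, 5 negative samples drawn from the unigram distribution to the
3/4 power) pooled per document as the unweighted mean of token vectors —
the pooling rule is a stated convention, since no canonical choice exists.
Both exist for harness parity; their absolute scores on synthetic text are
not meaningful beyond comparison.

## Classifiers and evaluation

Each class of each receptor gets its own binary model (positive-vs-rest),
trained on the feature matrix by either a multilayer perceptron — three
ReLU hidden layers of 50, 50 and 100 units, sigmoid output, binary
cross-entropy with L2 weight decay, minibatch Adam — or an RBF-kernel SVM
with inverse-class-frequency weights, scored by its oriented decision
values. Evaluation is stratified 3-fold cross-validation; fold assignment
depends only on the labels and the seed, so different feature sets are
compared on identical splits, which is what makes the paired (correlated-
curve) DeLong test on pooled out-of-fold scores valid. AUC is the exact
Mann–Whitney probability with ties at one half; F1 thresholds network
probabilities at 0.5 and SVM decision values at 0 (a documented convention
— the threshold is not part of the F1 definition). Bootstrap intervals are
percentile intervals over class-stratified resamples (default $B = 2000$),
so every resample retains both classes.

Network training details the evaluation depends on, fixed here: He
initialization, Adam at learning rate 0.01, 300 epochs of minibatches of
32, seeded per fold. For positional features the recommended configuration
disables per-column standardization: the features are already bounded in
$[-1, 1]$ on a common scale, and z-scoring distorts the cross-column
magnitude comparisons (is `posit` closer than `negat`?) that carry the
signal. Count features (n-grams) are standardized. The L2 strength
($10^{-3}$), epoch budget and batch size were selected on tuning corpora
generated with seeds disjoint from every corpus used in the package's
tests — mirroring the protocol of tuning hyperparameters on an independent
dataset — and then frozen.

## The synthetic generator

`generate_corpus()` emulates the phrasing diversity of hormone-receptor
pathology reports: per-receptor statuses drawn independently at prevalences
ER+ 78.1%, PR+ 66.1%, HER2+ 18.3%; 3–10 biomarkers per report (the
labelled receptors plus distractors CK7, MOC31, CK5/6, TTF-1, CK20,
Ki-67); standalone phrasings sampled over the inventory above; shared list
clauses that interleave several biomarkers between one polarity word and a
receptor mention (`interleave`, default 0.35, controls how often a receptor
is expressed this way); and an equivocal HER2 immunostain resolved by a
FISH follow-up sentence (`equivocal_her2_rate`, default 0.15) rendered as a
contiguous fragment at the head of the report, the order in which reflex
testing is dictated. Every receptor is mentioned exactly once, so text
never contradicts labels, and a rule-based reference extractor that inverts
the template inventory certifies label-text fidelity on every generated
corpus.

What the generator does *not* emulate: correlated receptor statuses (real
ER/PR/HER2 are correlated; independence gives simpler nulls), typos and
OCR noise, section headers and administrative boilerplate, longitudinal
report structure, and any phrasing outside the template inventory. Passing
tests on this corpus therefore demonstrate that the pipeline recovers
labels whose textual encoding matches the stated phrasing inventory — not
performance on arbitrary clinical text.

Percent-style negatives are worded ("ER: Negative.") rather than written
as "0%": an unqualified zero percentage encodes the label solely in a
numeral token that would have to compete into the top-30 vocabulary, which
is a property of the vocabulary-selection bottleneck rather than of the
phrasing the inventory is meant to exercise.

## Problem sizes and degenerate inputs

The shipped tests run the full pipeline at $n = 600$ reports (3-fold
cross-validation over six receptor-class tasks), the mechanism comparison
at $n = 300$ over ten generator seeds, oracle equivalence on all blocks of
length ≤ 6 over a six-token vocabulary plus 10,000 random longer blocks,
and calibration/coverage studies with 500–1,000 simulations at $n = 200$ —
sizes chosen so the whole suite completes in minutes on one core while
keeping Monte-Carlo error well inside the asserted tolerances.

Degenerate inputs are defined, not errors: empty text yields an empty
token sequence and an all-zero feature row; a corpus in which no block
contains the TOI is a configuration error; AUC and the DeLong test refuse
single-class inputs; identical score vectors have degenerate placement
variance and return p = 1 with a warning.

## Known limitations

* The vectorization keeps only the minimum-distance occurrence per word;
  repeated distant mentions are invisible beyond it.
* One anchor per block: a report discussing the same marker twice with
  different meanings (e.g. prior history) is outside the model.
* Feature values are tied to the corpus-specific relevant vocabulary; a
  vocabulary learned on one corpus transfers to new text only insofar as
  the vocabulary does (`predict()` freezes it deliberately).
* The aggressive stemmer can conflate distinct clinical terms with shared
  roots; it trades precision for vocabulary compactness.
* `commabef`-style artifacts of other preprocessing pipelines are not
  reproduced; no negation-scope parsing or concept normalization is
  attempted.

## A compact worked example

```{r example}
corp <- generate_corpus(synthetic_config(n = 120, seed = 42))
fit <- rwov(corp, "er", k = 20)
summary(fit)

ev <- cross_validate(as.matrix(fit), as.integer(corp$er == "POS"),
                     classifier_config("nn", l2_lambda = 1e-3,
                                       epochs = 300, batch_size = 32,
                                       class_weighting = FALSE,
                                       standardize = FALSE, seed = 5),
                     seed = 11, bootstrap = TRUE, B = 500)
ev
```
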