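---
title: "Clinical named-entity recognition with structural SVMs, CRFs and unsupervised word representations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clinical named-entity recognition with structural SVMs, CRFs and unsupervised word representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical notes bury most patient information in free text. Concept
extraction — finding typed spans for medical *problems*, *treatments* and
*tests* in discharge summaries — is the canonical first step for downstream
clinical NLP, and the community standardized it as a shared task with
annotated spans in `line:token` coordinates (lines 1-based, tokens 0-based,
inclusive on both ends). clinner implements a complete system for this task:
corpus I/O in the challenge dialect, span/label-sequence conversion, sparse
feature extraction including two unsupervised word-representation families,
two trainers for the same first-order linear-chain model, span-level
evaluation, and paired-system significance testing. Because the original
challenge corpus requires a data use agreement, the package also ships a
synthetic clinical-note generator so every claim made here is reproducible
from code alone.

## The model

Both trainers share one discriminant over label sequences $y = y_1 \dots y_N$
for a token sequence $x$:

$$ h_w(x, y) = \sum_{i=1}^{N} w^\top \big( f(x_i, y_i),\, f(y_{i-1} y_i) \big), $$

an emission block (one weight vector per label over a sparse binary feature
index) plus a label-pair transition matrix with a begin-of-sequence row.
Transitions are observation-independent indicators; all observation
dependence lives in the emission features. Decoding is exact Viterbi; ties
break toward the lowest label index so runs are reproducible.

**Structural SVM.** Training solves the margin-rescaling program

$$ \min_{w,\,\xi}\; \tfrac12 \lVert w \rVert^2 + \tfrac{C}{m} \sum_{x \in S} \xi_x
\quad \text{s.t.} \quad
w^\top F(x,y) \ge w^\top F(x,y') + \ell(y,y') - \xi_x \;\; \forall y' \ne y, $$

with $\ell$ fixed to per-token Hamming loss, which decomposes per position so
the most violated constraint is found exactly by loss-augmented Viterbi. The
cutting-plane loop adds each example's most violated constraint and re-solves
the restricted quadratic program in the dual by SMO-style coordinate ascent:
single-coordinate steps within the box $\alpha \ge 0$,
$\sum_{y'} \alpha_{x,y'} \le C/m$, plus pairwise mass-transfer steps inside an
example once its budget is tight (without these the ascent provably stalls —
a full-constraint QP oracle test in the suite pins this down). Training stops
when no constraint is violated by more than `epsilon`. The n-slack
formulation (one slack per example, as the program is written) is the
default; a 1-slack variant over averaged constraints reaches the same
optimum with many cheap iterations and is available via
`ssvm_control(formulation = "1-slack")`. The recorded objective is the
restricted-QP optimum, which is **non-decreasing** across re-solves (each
re-solve only adds constraints; the suite asserts this direction).

**CRF.** The same representation trained by penalized maximum conditional
likelihood: minimize $\sum_x [\log Z_w(x) - h_w(x, y)] + \tfrac{\lambda}{2}\lVert w \rVert^2$
with exact gradients (empirical minus expected feature counts) from
forward–backward in log space, optimized by L-BFGS-B. The analytic gradient
is checked against central finite differences in the suite.

The multiclass chain here is a single joint model over the full label
inventory. A pairwise one-against-one decomposition is sometimes used for
flat multiclass SVMs, but it has no standard interaction with sequence
decoding, so it is not implemented.

## Tag schemes

`tag_scheme("BIO")` uses Begin/Inside/Outside (7 labels over three types);
`tag_scheme("BIESO")` adds End and Single-token labels (13). Label order is
fixed (per type: B, I[, E, S]; "O" last) so weight indices are stable.
Decoding of model output is lenient in the usual CoNLL style: an I or E with
no compatible open entity starts one; a type change closes the previous
entity; an unterminated B/I run closes at its last token. Repairs are
counted and exposed for logging; gold data must encode with zero repairs
(the generator's output is property-tested for this).

## Features

`feature_config()` controls the templates, all namespaced by template and
relative offset (`w[-1]=pain`, `ortho[0]=ALLCAPS`, `brown[0]=1111`,
`th[0]=quelene@top5`):

* **word** — token identity in a ±2 window by default (window in tokens;
  boundary positions emit `<BOS>`/`<EOS>` placeholders).
* **orthographic** — initial-cap, all-caps, all-digits, contains-digit,
  -hyphen, -slash, punctuation-only, plus a character-class word shape
  (`12/09/03` → `dd/dd/dd`). The field has no single canonical inventory;
  this is the common clinical-NER set.
* **affix** — prefixes and suffixes of lengths 2–4.
* **pos** — part-of-speech tags in the window. POS is consumed as an input
  column, never computed; with no POS column the template is skipped with a
  warning.
* **combined** — five fixed conjunctions: `w|p[0]`, `w[-1]w[0]`, `p[-1]p[0]`,
  `w[0]p[-1]`, `w[0]p[+1]`. Bigram conjunctions are skipped at sentence
  boundaries rather than padded.
* **section** — a discourse label carried forward from the most recent
  header line (a line whose final token matches `:` by default), standing in
  for the section structure of discharge summaries.
* **lexicon** — a pluggable gazetteer (`term → tag`). This is the
  architectural slot that licensed terminology resources (UMLS concept IDs
  and semantic types) would occupy; those resources cannot be redistributed,
  so the slot is generic.
* **brown** — all prefixes of the word's Brown bit path (below), optionally
  capped to fixed lengths.
* **thesaurus** — the word's nearest semantic neighbours (below), bucketed by
  rank (top1/top5/top10/top20) so the feature space stays small.

The indexer grows during training, is frozen with the model, and silently
drops unseen feature strings at prediction time. Enabling an extra template
can only add features (a monotonicity property the suite tests).

## Word representations

**Brown clustering** (`brown_clusters()`) greedily merges word classes to
maximize the average mutual information (AMI) of adjacent class bigrams,
producing a binary tree whose root-to-leaf bit paths encode distributional
similarity at every granularity; all path prefixes become features. The
implementation is the classic windowed variant: the `num_clusters` most
frequent words start as singletons, remaining words are inserted by
frequency and each insertion is followed by the AMI-optimal merge, then the
final clusters are merged to one to complete the tree. Each chosen merge is
verified against exhaustive pair enumeration on small vocabularies in the
suite. Two conventions are ours because any choice is arbitrary: ties break
toward the smallest pair of cluster creation ids, and the child containing
the earlier-created cluster takes bit 0. AMI is provably non-increasing
across merges only when no insertions intervene (inserting a word adds
information), so that invariant is asserted in the pure agglomerative regime
(`num_clusters ≥` vocabulary). Words under `min_count` share one
out-of-vocabulary class, whose path also serves unknown words at test time.

**Random indexing** (`build_semantic_index()`) assigns each word a sparse
ternary index vector (dimension 1500, 8 nonzeros — half +1, half −1 —
drawn from a seeded generator) and accumulates, for every token occurrence,
the index vectors of tokens within 4 positions on each side
(sentence-bounded, unweighted). Cosine similarity over the accumulated
context vectors yields a k = 20 nearest-neighbour thesaurus
(`semantic_thesaurus()`). The source work defers its parameter values to an
earlier study without printing them; 1500/8/window-4/k-20 are standard
random-indexing settings, and all are exposed. Ties in cosine break
lexicographically. The suite checks near-orthogonality of index vectors in
expectation, agreement of the accumulation with an explicit co-occurrence
matrix product, and agreement of top-k retrieval with brute-force ranking.

## Evaluation and system comparison

`evaluate_spans()` scores span predictions micro-averaged over all documents,
in two modes: **exact** (start, end and type all identical) and **inexact**
(any overlap with a gold span). Matching is greedy, one-to-one, in document
order — each gold and each predicted span is used at most once, so
TP ≤ min(|gold|, |predicted|), and exact TP ≤ inexact TP always. Inexact
matching requires type agreement by default (the challenge's class-level
criterion); `require_type = FALSE` switches to pure-overlap since the
one-line description in the source leaves this ambiguous.

`bootstrap_compare()` draws 2000 sentences with replacement 200 times (the
same draw applied to both systems), computes each system's exact-mode
overall F per replicate, and applies a Wilcoxon signed-rank test to the 200
paired F values. The signed-rank test drops zero differences, averages tied
ranks, uses the exact null distribution up to n = 25 nonzero pairs (computed
by convolution, identical to enumerating all $2^n$ sign patterns) and the
tie-corrected normal approximation (no continuity correction) above. All
differences zero is degenerate: statistic 0, p = 1 by convention — "no
evidence of difference" is the only safe report there. Because exact
matching never crosses sentence boundaries, replicate F values pool
precomputed per-sentence counts, which keeps 200 × 2000 resampling cheap.

## The synthetic stated world

`generate_corpus()` emulates the *structure* of the restricted challenge
data, not its language: multi-document corpora with three section headers
(history of present illness / medications / laboratory data) that bias the
entity-type mixture; three entity types realized as 1–4-token phrases
(lengths with probabilities 0.45/0.30/0.15/0.10) built from shared modifiers
plus a type-assigned head word; type-specific context words flanking
entities with probability 0.7; and background text mixing function words
with the same modifiers, so a modifier is not in itself an entity cue.
Head words are syllable combinations assigned to types round-robin —
deliberately *suffix-neutral*, because a vocabulary whose morphology
identifies the type lets character affixes solve the unseen-entity problem
and leaves word representations nothing to contribute; an early iteration of
the generator had exactly this flaw. Co-occurrence classes (heads with their
context words) are the planted structure that Brown clustering and random
indexing should recover.

Defaults are the desk-scale stated world used by the tests: 200k unlabeled
tokens, 400 training and 400 test sentences, and an out-of-vocabulary
entity fraction of 0.3 — per type, exactly `round(0.3 × 20)` of the 20
distinct test surface forms are built on reserved heads that never occur in
the labeled training text but do occur in the unlabeled corpus. Everything
is reproducible byte-for-byte from the seed.

What a green test on this world does establish: the trainers optimize their
objectives correctly; the representations recover planted distributional
structure; word-representation features raise recall and F exactly in the
out-of-vocabulary regime they target. What it does not establish: absolute
performance on real clinical text, robustness to annotation noise,
sentence-splitting or tokenization errors (inputs are pre-tokenized by
contract), or the relative ranking of algorithms at real-corpus scale.

## Experiment settings and numerical choices

* SSVM: `C = 1`, `epsilon = 0.01` are the trainer defaults (the program's
  penalty is `C/m` per example, as written). For the desk-scale experiments
  the package uses `C = 100, epsilon = 0.05`: with m ≈ 350–400 sentences the
  default per-example penalty `1/m` underfits badly, and the reference
  procedure for this choice — grid search by 10-fold cross-validation
  (`cv_tune()`) — is what a user should run on their own data. The inner QP
  is solved to KKT tolerance `epsilon/20`.
* CRF: `l2 = 1`, L-BFGS-B with projected-gradient tolerance `1e-6`,
  iteration cap 200.
* Degenerate inputs: empty documents featurize to empty sequences and
  predict to empty span sets; empty label sequences score 0; a zero context
  vector has no neighbours; all-zero paired differences give p = 1.
* Determinism: every stochastic step (index vectors, generator, bootstrap,
  fold assignment) takes an explicit seed; Viterbi/merge/cosine ties have
  fixed break rules.

## A finding the desk-scale world reverses

On the synthetic stated world the BIESO scheme scores *below* BIO with both
trainers (mean exact F over five seeds ≈ 0.80 vs 0.82), the opposite of the
finding reported on the real corpus. Two forces act here. BIESO splits the
same ~370 training entities across 13 labels instead of 7, a label-sparsity
cost; and in this generator the boundary information BIESO encodes is
largely recoverable by BIO from the type-specific context words, so the
scheme pays the cost without collecting the benefit. Quadrupling the
training size erases the gap on some seeds but not others, so scale alone
does not restore the direction: the missing ingredient is the messier
boundary ambiguity of real clinical language (where the reported advantage
came mainly from single-word-entity precision), which this generator does
not attempt to model. The acceptance suite keeps the directional assertion
as stated and it fails honestly on this world; the word-representation
direction (higher recall and F at OOV fraction ≥ 0.3) reproduces robustly
on every seed.

## Known limitations

First-order chains only; no semi-Markov segment models, no kernels, no
higher-order transitions. Tokenization is whitespace splitting by contract.
Nested or discontinuous entities are out of scope (the tag encodings cannot
represent them, and overlapping gold spans are rejected on input). The
Brown implementation recomputes cluster bigram statistics per insertion,
which is comfortable for vocabularies in the thousands but not for
million-word vocabularies.
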