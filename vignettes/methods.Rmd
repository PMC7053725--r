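---
title: "Methods: kernels, classifiers, and evaluation design in cpirex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kernels, classifiers, and evaluation design in cpirex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpirex)
```

## The classification problem

A sentence that mentions both a chemical compound and a protein may or may
not assert a functional relationship between them (direct interaction,
regulation, part-of, cofactor). `cpirex` treats every compound x protein
co-occurrence within one sentence as a candidate instance and classifies
it with kernel methods over two complementary sentence representations.
The unit of generalization is the *document*: all evaluation is
document-wise, because sentences from one abstract share vocabulary and
annotation context, and instance-wise splitting leaks that context from
training into test folds, inflating every metric.

Entities arrive pre-annotated (character spans, types, optional database
identifiers); named-entity recognition is explicitly out of scope. Before
feature extraction the candidate entities are *blinded* — collapsed to
single placeholder tokens `COMPOUND_C` / `PROTEIN_C` — so the classifier
cannot memorize entity names; other annotated entities become
`COMPOUND_O` / `PROTEIN_O` by default (`blind_others = TRUE`), which is
the standard practice in kernel-based relation extraction and
distinguishes "the candidate" from "some other entity nearby" without
leaking identity.

## Shallow linguistic kernel

The SL kernel is the sum of five cosine-normalized sub-kernels.

* **Global context.** Three token patterns around the candidate pair —
  fore-between (tokens before the first placeholder plus those between),
  between, and between-after — are each mapped to a bag of contiguous
  k-grams, k = 1..n, of lowercased surfaces. The bag is unordered but
  token order *within* a gram is preserved; a pure word-set reading would
  make n > 1 meaningless. Candidate placeholders are excluded from the
  patterns; other-entity placeholders participate as ordinary tokens.
* **Local context.** For each candidate placeholder and each window
  offset −w..−1, +1..+w inside the sentence, indicator features record
  the neighbor's lowercased surface, POS tag, and three orthographic
  flags (capitalized / punctuation / numeral), keyed by (entity, offset,
  kind, value). Left-side and right-side features form two separately
  normalized sub-kernels. Punctuation tokens count as window positions:
  tokens are tokens.

Each sub-kernel is normalized per pattern (cosine), with an empty pattern
contributing 0; unnormalized sums would let long sentences dominate and
would break score comparability across cross-validation folds. The
diagonal of the Gram matrix is therefore 5 when all patterns are
non-empty. Surfaces are lowercased in the global patterns because the
local features carry capitalization separately — counting case twice
would double-weight it.

Defaults n = 3, w = 1: the 3 x 3 grid is the evaluated parameter space,
and (3, 1) is the configuration with the best area under the curve on the
annotated benchmark; larger values are permitted with a warning.

## All-paths graph kernel

Each blinded instance becomes a weighted graph over its tokens. Edges
come from a dependency parse and are inserted in both orientations —
dependency direction would otherwise disconnect entity pairs in trees —
with weight `w_sp` = 0.9 on edges lying on *any* shortest (unit-length,
undirected) path between the candidate placeholders and `w_other` = 0.3
elsewhere. The published description of the kernel fixes only the
ordering ("highest emphasis" on shortest-path edges); the default values
follow the kernel's original publication lineage and are configurable.

Vertex labels are the lowercased surface (or placeholder), `pos:TAG`,
and `dep:TYPE` of the token's incoming dependency. The feature matrix is
defined over vertex labels only, so dependency types are housed as vertex
labels on the dependent token (configurable off) rather than inventing an
edge-label algebra.

Summing all positive-length adjacency powers gives total path weights. If
the spectral radius of `W` is below `1 − 1e-6` the closed form
`(I − W)⁻¹ − I` is used; otherwise the series is truncated at `d_max`
(default `2 |V|`) and flagged — never silently rescaled — so results are
deterministic and testable. Note that with the default weights an
undirected chain already has spectral radius `w_sp·2cos(π/(m+1)) > 1`
for longer sentences, so the truncated branch is the common case on real
parses; the closed form matters for the convergent regime and for
verification against the truncated series. The label-pair matrix
`G = Lᵀ M L` is compared across instances by the Frobenius inner
product, cosine-normalized to unit diagonal for cross-sentence
comparability.

The linear-order (surface-sequence) secondary subgraph of some APG
formulations is deliberately not implemented: the dependency graph is the
representation here.

## Classifiers on precomputed kernels

* **Support-vector classifier** (used with SL): the soft-margin dual is
  solved by sequential minimal optimization with maximal-violating-pair
  selection, stopping when the KKT violation gap falls below `1e-8`
  (cap 500,000 iterations, warned). The bias averages `y_i − f(x_i)`
  over free support vectors. Cost `C = 1` by default; the benchmark's
  original cost is unpublished, so it is configuration-exposed.
* **Regularized least squares** (used with APG): `a = (K + λI)⁻¹ y`.
  The mapping `λ = 1/c` makes a larger `c` mean weaker regularization,
  matching the direction of the evaluated grid `c ∈ {0.25, 0.5, 1, 2}`.
  The convention in parts of the literature ("larger c, lower risk of
  overfitting") conflicts with this; the mapping is documented and
  configuration-exposed rather than guessed both ways.

Decision thresholds use strict `>`; a score exactly at the threshold is
negative. This makes "the largest prediction count with precision at
least the target" well-defined in the matched-precision scan, which
prefers `−Inf` (all-positive) when the target is already met there and
returns `+Inf` with a warning when the target is unreachable.

## Evaluation design

* Folds are assigned by shuffling documents with a seeded permutation and
  dealing them round-robin, so fold sizes differ by at most one. The
  benchmark's own randomization is unpublished; this choice is
  deterministic and reproducible.
* The Gram matrix is computed once over all instances and sliced per
  fold — the kernel does not depend on the split.
* AUC is the Mann–Whitney statistic on the *pooled* cross-fold scores
  (one AUC per configuration, the convention of the benchmark lineage);
  per-fold averaging can be done downstream from the returned per-fold
  scores. Pooling is meaningful because unit-diagonal normalization keeps
  decision scores on a comparable scale across folds; no per-fold
  rescaling is applied.
* Undefined ratios (e.g. precision with no positive predictions) are
  reported absent (`NA`), never 0 by convention. Percentages are kept at
  full precision internally and rounded half-up to one decimal only at
  presentation (`round1()`).
* The chi-squared test of label x verb dependence is Pearson's without
  continuity correction, df = 1, matching the analytic closed form
  `n(ad−bc)² / ((a+b)(c+d)(a+c)(b+d))`.
* "Majority voting" of two kernels is conjunction — positive only if both
  kernels are positive — which provably cannot raise recall above either
  input or lower specificity below either input; both bounds are asserted
  in the test suite.

## Linguistic preprocessing and its limits

The tokenizer keeps word-internal hyphens/periods ("COX-2",
"7-ketocholesterol", "0.5" are single tokens) and splits other
punctuation off. POS tags come from a deliberately small rule set
(punctuation, numerals, known interaction verbs → verbal tag, capitalized
→ proper noun, default noun). Lemma matching for interaction verbs
lowercases and tries rudimentary suffix strips (`s`/`es`/`ed`/`ing`, plus
an `-e` restoration). Verb detection requires both a lemma hit *and* a
verbal tag, so nominal homographs ("an increase in...") are not counted
when no verb lexicon marks them. Enclosure is defined on surface token
order — at least one qualifying token strictly between the two candidate
spans — not on the dependency structure, and is symmetric in entity
order.

Dependency parses enter through a backend contract. The built-in
`"fixture"` backend returns the deterministic linear chain (`i → i+1`,
type `next`); real parsers can be registered with
`register_parser_backend()`. All shipped results therefore measure the
discriminative machinery over a *known* graph structure, not parser
quality — which is also why the prediction command refuses the fixture
backend unless explicitly allowed. Performance on real corpora will
depend on the parser and tagger plugged in; no specific external parser
is assumed or bundled.

## The synthetic corpus: what it does and does not emulate

`generate_corpus()` produces sentences of the shape
`filler* COMPOUND [assoc] mid PROTEIN filler* .` where `mid` is an
inflected interaction verb with class-conditional probability and a
neutral preposition otherwise, and `assoc` is a planted lexical marker.
Defaults mirror the annotated benchmark where its published statistics
pin them down: positive fraction 2931/5562, and enclosed-verb rates
1598/2931 (functional) and 1269/2631 (non-functional), the rates
derivable from the published strata sizes. The marker appears in
positives with probability 0.8 and never in negatives by default; making
all class-conditional probabilities equal yields a null corpus with no
learnable signal, which is how the no-signal calibration below is
constructed. The signal is planted lexically (marker + verb placement)
rather than syntactically so that both kernels can learn it through the
fixture chain parse.

Emulated: sentence/document structure, pair labels, entity spans,
class-conditional verb enclosure, learnable signal, multi-entity
sentences (a `multi` mode with 2 x 2 entities exercises candidate
enumeration and other-entity blinding). Not emulated: real biomedical
syntax and vocabulary distributions, annotation noise, entity-boundary
ambiguity, nested or overlapping mentions, class imbalance drift across
documents. Passing the recovery checks therefore demonstrates that the
pipeline's machinery is correct and signal-sensitive; it does not
certify performance on real literature.

## Problem sizes and numerical tolerances

The shipped verification suite uses: 200 documents x 5 sentences (1,000
pairs) for signal-recovery and null runs under 10-fold document-wise CV —
large enough for stable AUC estimates and label-verb chi-squared
dependence (p far below 0.01 at the 0.9/0.1 verb-placement
configuration), small enough to run in seconds; 6–10 instance sets for
oracle-equivalence checks (explicit feature vectors, brute-force walk
enumeration, exhaustive AUC pair counts, direct numerical minimization of
the RLS objective); and random graphs of at most 8 vertices for the
Neumann-series comparisons. Key tolerances: kernel-vs-oracle `1e-12`,
series-vs-closed-form `1e-9`, PSD eigenvalue floor `−1e-8`, SVC KKT gap
`1e-8` (verified to `1e-6`), RLS residual `1e-8`.

## Known limitations

* The rule-based tagger and suffix lemmatizer are fixture-grade; a real
  deployment should register an external parser/tagger backend.
* Divergent path series are truncated at `d_max`, which makes long-range
  path contributions depend on that cap (deterministically, and flagged).
* The SVC bias falls back to the violation-bound midpoint when no free
  support vectors exist (possible on tiny or degenerate folds).
* PubTator ingest drops annotations that cross sentence boundaries or
  disagree with the text slice, with warnings; the original large-scale
  pipeline's handling of those cases is unpublished, so these are local,
  conservative choices.
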