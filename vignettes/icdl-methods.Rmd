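---
title: "Measuring and testing word-order minimization in dependency treebanks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and testing word-order minimization in dependency treebanks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icdl)
```

## The question and the two metrics

A long tradition in quantitative linguistics holds that natural languages
arrange words so that syntactically related words end up close together:
*dependency length minimization* (DLM). `icdl` implements a sharper variant
of that question: is it the **number** of words between a head and its
dependent that languages minimize, or the **syntactic complexity** of that
intervening material?

Both quantities are defined per dependency edge on a rooted tree over
linearly ordered words:

* **dependency length (DL)** — the number of words strictly between the head
  and the dependent (adjacent words have DL 0);
* **intervener complexity (IC)** — the number of those intervening words
  that are themselves heads, i.e. have at least one dependent anywhere in
  the sentence. Intervening *terminal* words (leaves) do not count.

Since every intervening head is an intervening word, IC ≤ DL on every edge —
an invariant the test suite checks on every tree the package ever produces.
Head status is **global**: a word with its only dependent outside the span
still counts, because the leaf/non-leaf distinction is a property of the
word, not of the span. The artificial root is not a word, has no linear
position, and its attachment edge is excluded from all per-sentence means.

The package's worked example is a six-word schematic: a head at position 1,
its dependent at position 6, and four intervening words. When the
interveners are all terminal dependents of the head, the edge has DL 4 and
IC 0; when they form a chain of heads, the edge still has DL 4 but IC 3.
Identical dependency length, very different structure-building load — that
wedge is what the whole analysis exploits.

## Crossing dependencies

Two counting conventions are implemented in `crossing_count()`:

* `nonprojective_edges` (default, used for all baseline matching): an edge
  h → d is counted iff some word strictly between h and d is not dominated
  (reflexive-transitively headed) by h. This is the only convention stated
  with a formal biconditional definition in the literature, so it is the one the
  rejection samplers match on.
* `crossing_pairs`: unordered pairs of edges whose linear spans strictly
  interleave, **with the root attachment participating as a virtual edge
  from position 0**. Without that virtual edge the two conventions have
  different zero sets — an edge covering the root word is non-projective
  under the domination definition yet interleaves with no word–word edge.
  Including it restores the equivalence (zero crossings ⟺ projective under
  both methods), which the suite verifies against brute-force oracles.

The two counts may still differ in *value* on non-projective trees (one
edge can cross several others); only their zero sets coincide.

## The six baselines

Each real tree is paired with a random tree that matches it in sentence
length and in crossing count, plus the constraints of its family:

| kind                           | order    | topology kept | DL multiset | IC multiset |
|--------------------------------|----------|:---:|:---:|:---:|
| `random_structures`            | uniform tree, labels = positions | – | – | – |
| `rla`                          | uniform permutation of the real tree | ✓ | – | – |
| `dl_matched_random_structures` | uniform tree | – | ✓ | – |
| `dl_matched_rla`               | uniform permutation | ✓ | ✓ | – |
| `ic_matched_random_structures` | uniform tree | – | – | ✓ |
| `ic_matched_rla`               | uniform permutation | ✓ | – | ✓ |

Structures are sampled uniformly over rooted labeled trees by drawing a
uniform Prüfer sequence, decoding it, and rooting at a uniform node (n^(n−1)
equally likely rooted trees). Linear arrangements are uniform permutations
with the head relation carried along. Constraints are imposed by rejection:
accepted samples are therefore uniform over the exact constraint-satisfying
set, which the suite confirms by exhaustive enumeration at small n.

Two reading choices deserve note. First, "matching the sequence of
dependency lengths" is implemented as **multiset** equality: a random
structure has no positional edge correspondence with the real tree, so an
ordered-sequence reading is ill-defined there; multiset matching is applied
to both families for consistency. Second, rejection budgets are real:
a deep projective tree of 11 words is a ~2.6 × 10⁻⁵ event under uniform
permutation, so `max_attempts` (default 100,000) can be exhausted. A failed
tree is a typed result; the pair (real + baseline) is dropped from model
input and recorded in the `BaselineReport`, keeping the design matched.
Per-tree RNG streams are derived from the `baseline_spec()` seed and the corpus index,
so regeneration is deterministic and order-independent.

The rejection loop is implemented in compiled code (`src/`), drawing from
R's RNG so `set.seed()` fully determines output; the R-level samplers
(`sample_random_structure()`, `sample_rla()`) are independent
implementations used by the distributional tests.

## The interaction model

For sentence i of language j, with S the sentence length, R ∈ {0, 1} the
real-tree indicator and y the per-sentence mean IC or mean DL:

y_ij = β₀ + u₀ⱼ + (β₁ + u₁ⱼ)·S_ij + (β₂ + u₂ⱼ)·R_ij + (β₃ + u₃ⱼ)·S_ij·R_ij + ε_ij

The estimand is β₃: a negative interaction means the response grows more
slowly with sentence length in real trees than in the matched baseline — the
minimization signature. The main effect β₂ is reported alongside because the
two can disagree, and a difference pooled over mixed sentence lengths is
harder to interpret than the growth-rate contrast.

Choices the model statement leaves open, and what this package does:

* **Estimation**: REML via `lme4::lmer`. Sentence length enters raw
  (uncentered); a `center_S` flag exists but is off by default.
* **Random effects**: by-language intercept and slopes for S, R and S·R,
  **uncorrelated** by default (a `correlated` flag switches to the full
  covariance); the reduction ladder needs the diagonal form anyway.
* **Non-convergence**: a documented ladder drops the S·R slope, then the R
  slope, then all slopes; the structure that converged is recorded in the
  fit. A *singular* fit (a variance component estimated at zero) is treated
  as converged — boundary estimates are expected whenever the generating
  process has no language-level variation, as in the synthetic null.
* **Significance**: t = estimate/SE with an operational |t| > 2 star rule;
  no p-values or degrees-of-freedom approximations are computed.
* **Verdicts**: `evaluate_hypothesis()` maps a fit to
  supported / contradicted / inconclusive from the sign of β̂₃ and |t₃|.

Per-language fits (`fit_per_language()`) drop the random effects and run
OLS within each language; exact reparameterization identities (flipping the
R coding negates β̂₂ and β̂₃; shifting the response moves only β̂₀) are
tested there, where they hold to machine precision.

## The synthetic generator

No external treebank ships with the package. `gen_corpus()` produces
corpora whose statistical structure mimics the short-sentence regime the
analysis targets, with word-order policies of *known* direction so the
pipeline can be validated end-to-end:

* **Sentence lengths** uniform on 3–11 words. The filter default `max_len =
  11` reflects the strict "< 12 words" reading of the regime; `min_len = 3`
  because a two-word tree admits no intervener and contributes degenerate
  model rows. Both are flags.
* **Tree shapes** grown by attaching dependents per node from a truncated
  geometric arity distribution with mean 0.9 — a tree on n words has n − 1
  dependencies, so the average node has just under one dependent. If every
  pending node draws zero, one extra dependent is attached to a uniformly
  chosen node so exactly n nodes are always reached.
* **Ordering policies**, all projective by construction: `uniform_random`
  (uniform over projective linearizations, obtained by uniformly shuffling
  each node with its child blocks); `dlm_greedy` (dependents on alternating
  sides in increasing subtree size, each subtree's root hugging the end
  facing its head — the classic length-minimizing heuristic); `icm_biased`
  (leaf dependents adjacent to the head before any head-bearing subtree,
  so near-head interveners are predominantly terminal). Ties are broken by
  the RNG so repeated generation explores the tie set.
* **Crossings** are injected afterwards: with probability `crossing_rate`
  (default 0.05 — crossing dependencies are rare in natural text) a tree
  receives one adjacent transposition that creates at least one crossing.
  Some shapes (stars) are projective under every permutation; such trees
  are left projective rather than looping forever.

What the generator does **not** emulate: lexical content, morphology,
realistic dependency labels, language-specific length/arity profiles, or
genuine cross-language variation (all languages are draws from the same
process). Passing the planted-signal tests therefore shows the pipeline
detects word-order preferences of known direction at realistic sizes — not
that any natural language has them.

A useful identity underpins the null control: conditioned on the matched
crossing count, a random linear arrangement is uniform over the crossing
class of its tree, and a uniform projective linearization is exactly the
crossing-count-zero class. A `uniform_random` corpus compared against its
`rla` baseline is therefore an *exact* null — real and baseline draws are
equidistributed — and the observed |t₃| > 2 rate must sit near the nominal
5%. Against `random_structures` the comparison is *not* null for IC, since
grown arity-geometric shapes and uniform Prüfer trees have different leaf
fractions; the planted-signal checks use that baseline, the null checks use
`rla`.

## Problem sizes and numerical tolerances used by the test suite

All sizes below are the package's own validation choices:

* sampler exactness: all 16 Prüfer sequences at n = 4; 64,000 rooted-tree
  draws over the 64 enumerable rooted labeled trees; 24,000 permutation
  draws over 4! linearizations; 20,000 accepted crossing-matched
  arrangements at n = 5 against the exhaustively enumerated acceptance
  class. Chi-square goodness of fit is tested at α = 0.001.
* constraint fidelity: a 500-tree synthetic corpus, all six baseline kinds,
  20,000-attempt budgets, exact equality on every matched statistic of
  every successful pair.
* parameter recovery: one fit at 40 languages × 200 sentences with
  β₃ = −0.15 checked within ±2 SE; 200 replications at 20 × 30 for
  unbiasedness (Monte-Carlo error) and ≈95% coverage of β₃ ± 2 SE; 200
  null replications (β₃ = 0) with the |t₃| > 2 rate required to lie in
  [0.005, 0.12] around the nominal 5%.
* planted signal: a 500-sentence length-minimized corpus against uniform
  random structures must yield "supported" for both responses; sixteen
  uniform-order corpora against their RLA baselines must yield
  "inconclusive" at least 13 times (a 3-failure allowance on a 5%-rate
  binomial).

## Known limitations

* Rejection sampling is exponentially expensive in the constraint load;
  heavily matched kinds on deep projective trees routinely exhaust budgets,
  and the analysis design accepts the resulting pairwise exclusions rather
  than biasing toward easy trees. Importance sampling or MCMC alternatives
  are out of scope by design.
* The `dlm_greedy` linearizer is a strong heuristic, not an exact optimum;
  the suite lower-bounds it with an exhaustive minimal-projective oracle at
  small n instead of asserting optimality.
* t-values carry no degrees of freedom; the |t| > 2 rule is operational,
  not inferentially exact, and with few language groups the interaction t
  is mildly heavy-tailed (the null-calibration band accounts for this).
* `filter_corpus(exclude_punct = TRUE)` drops trees in which a punctuation
  word heads a non-punctuation word, since no faithful reattachment exists;
  whether a source treebank counted punctuation as words is a corpus
  property the caller must decide (the flag defaults to counting every
  word line).
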