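---
title: "Benchmarking ontologies against a corpus: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking ontologies against a corpus: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontobench)
```

## The model

`ontobench` treats a reference corpus as the authoritative sample of a
domain's discourse and scores an ontology by the probability mass of that
discourse it captures. Three estimated quantities drive everything:

* **Concept frequency** `f_i`: the share of all recognized concept
  mentions belonging to concept `i`. Frequencies are normalized over the
  concepts actually observed, so `sum(f) == 1` by construction.
* **Pair association** `p_ij`: row-normalized unit-level co-occurrence.
  `n_ij` counts the units of text containing both `i` and `j`
  (binary per unit — repeated mentions inside one unit count once, which
  makes the estimate robust to mention-count inflation within a single
  abstract), and `p_ij = n_ij / sum_j' n_ij'`. A concept that never
  co-occurs, or never appears, has `p_ij = 0` for every `j`. This zero
  policy is deliberate: ontology content absent from the corpus is treated
  as *improbable*, not as a false positive, and simply earns no mass.
* **Typed-relation weight** `π_k|ij`: when mention triples with predicates
  are available, the share of pair `(i,j)`'s mentions carried by predicate
  `k`, summing to one within each pair.

Breadth at level 1/2/3 sums `f_i`, `f_i p_ij`, and `f_i p_ij π_k|ij` over
the ontology's covered constituents; Depth divides each Breadth by the
count of constituents charged for it (`|C_X|`, `|ℜ_X|` — ordered pairs
with at least one relation — and `|R_X|`). The level-2 denominator
deliberately ignores predicate multiplicity, so a predicate-rich ontology
is not penalized for cataloguing several relations over one pair. Both
Breadth metrics are bounded by 1 because `f` sums to one and each `p` row
sums to at most one.

Assumptions worth keeping in mind: concepts and relations are taken to be
expressed explicitly in text (co-occurrence stands in for actual semantic
relation mentions); recognition is dictionary-based, so a concept whose
every surface form is missing from the lexicon is invisible; and the
corpus is assumed large enough that absence is informative.

## Fittest ontologies and loss

The complete ontology of a corpus holds every observed concept and
co-occurring pair with their probabilities. The fittest ontology of size
`k` maximizes Depth subject to the size budget. Because Depth is an
additive sum of per-item masses divided by the fixed budget, the exact
optimizer is top-`k` selection by mass (`f_i` at level 1, `f_i p_ij` at
level 2); `fittest_of_size()` therefore needs no search, and the test
suite confirms its optimality against exhaustive subset enumeration on
small instances. Ties are broken by identifier so results are reproducible
bit for bit. Budgets exceeding availability are clamped with a warning.

Depth Loss is `Depth_fittest − Depth_X`; Relative Depth is
`Depth_X / Depth_fittest` and Relative Depth Loss its complement, the two
always summing to one. `loss_metrics()` refuses a test depth above the
fittest depth, since that can only arise from an implementation error.
The level-1 fittest budget counts concepts and the level-2 budget ordered
pairs, matching the respective Depth denominators; both are exposed, since
either convention is defensible and the loss identities are budget-
agnostic.

## Substitution probabilities

For thesauri, pair probabilities specialize to synonym substitution
probabilities estimated from shared contexts:

    p(s | w) = Σ_c  P(c | w) · P(s | c)

`P(c|w)` is the share of the headword's occurrences carrying context `c`;
`P(s|c)` is `s`'s share of the occurrences of the *candidate set* —
`{headword} ∪ synonyms`, matched at the headword's part of speech — in
context `c`. Two design choices deserve justification:

* **The headword belongs to the candidate set.** The row then answers
  "given one of this entry's words appeared in this context, which one?",
  the self-mass plus synonym mass sums to exactly one whenever the
  headword has any context support, and a single-synonym entry no longer
  degenerates to probability 1 the moment one context is shared.
* **Candidate-set normalization** (rather than whole-vocabulary
  normalization of `P(s|c)`) keeps the estimate a proper conditional on
  the entry and makes rows comparable across entries of very different
  ambient context popularity. Whole-vocabulary normalization is the main
  alternative reading; it was not adopted because it ties an entry's mass
  to unrelated vocabulary sharing its contexts.

A context is the `k` nearest content words (noun, verb, adjective, adverb)
on each side within the sentence, `2k = 4` by default, order ignored.
Windows at sentence boundaries truncate rather than pad. Content words
whose corpus-wide base-form frequency is at or below `rare_threshold`
(default 1: corpus-unique) are binned into part-of-speech pseudo-words
(`rare-noun`, `rare-verb`, `rare-adjective`, `rare-adverb`), which
densifies sparse context statistics without discarding the occurrences.
"Nearest content words" was chosen over "adjacent tokens then filter"
because it yields fuller windows on function-word-heavy prose; both
readings agree on text without function words. Hyphenated and multiword
tokens are handled at single-token granularity.

Cross-corpus comparison uses the Jensen–Shannon divergence with base-2
logarithms over each entry's candidate simplex: symmetric, finite on
disjoint support, 0 for identical distributions and 1 for disjoint ones.
Entries with all-zero rows in a corpus are excluded from that corpus's
comparisons.

## Smoothing

The zero policy punishes unobserved content but makes `p` improper for
unobserved concepts. `smooth_relation_probs()` offers a proper
alternative: each real target receives pseudo-count `α` and a reserved
null-sink pseudo-concept receives `α·M·(1−β)/β` (with `M` real candidate
targets), giving

    p_ij = (n_ij + α) / (n_i + α·M/β)

with the remainder on the sink. The two constants satisfy
`0 ≤ α < β < 1`: `α` sets the strength of smoothing and `β` is the share
of the smoothing pseudo-mass kept on real concepts. Every row sums to one
including the sink; an unobserved concept's sink mass is `1 − β` (close to
1 for small `β`) with `β/M` on each real target (close to 0); and at
`α = 0` observed rows reduce exactly to the unsmoothed estimator with zero
sink mass, so the smoothed and unsmoothed estimators agree in the
`α → 0` limit. Defaults are `α = 0.01`, `β = 0.1`, small enough that
observed counts dominate after a handful of co-occurrences.

## Concept recognition and tagging

`match_concepts()` is a deliberately lightweight stand-in for
knowledge-intensive mappers such as MetaMap: case-insensitive,
lemma-level, longest-match dictionary matching over preferred names and
synonyms, overlapping spans resolved to the longest candidate and ties to
the leftmost, never crossing sentence boundaries. It performs no
candidate scoring and no word-sense disambiguation; on specialized prose
with a curated lexicon this is a reasonable approximation, on ambiguous
general text it will conflate senses.

Tagging and lemmatization sit behind a pluggable contract — any function
returning sentences of `(surface, base_form, pos)` rows with coarse tags
in `{NOUN, VERB, ADJ, ADV, OTHER}` can be supplied. The built-in
`simple_tagger()` is a compact rule/lexicon tagger: a small function-word
and content-word lexicon, suffix heuristics, and rule-based English
lemmatization (irregular table plus plural/`-ing`/`-ed` stripping).
It is adequate for controlled and synthetic text and deterministic by
construction; for serious English corpora a real tagger should be plugged
in, and the package's estimates are only as good as the morphology
feeding them. Unknown words default to nouns, which keeps opaque
identifiers stable through the pipeline.

Concept identity *across* ontologies (for the Venn-style overlap
operations) uses case-folded, lemmatized exact string matching over
preferred names and synonyms, with concepts whose key sets intersect
merged into one union element via connected components. This replaces
curated cross-terminology concept identifiers with a deterministic,
resource-free rule; region counts always partition the union exactly.
Relation overlap is directed by default, with an undirected mode exposed
since either convention is defensible for symmetric comparisons.

## The synthetic generator

`generate_concept_corpus()` emulates the statistical skeleton of a
domain corpus: Zipf-distributed concept usage (skew exponent `zipf_s`,
default 1 — the skew typical of term frequencies in real terminologies),
opaque single-token concept names, a small filler vocabulary plus
one-off filler tokens so the rare-binning path is always exercised. Two
modes:

* **independent mentions** — each document draws
  `1 + Poisson(mentions_per_doc − 1)` mentions i.i.d. from the Zipf law;
  ground truth is the frequency vector.
* **planted pairs** — each document carries exactly one unordered concept
  pair drawn from the symmetrized joint `u_ij ∝ f_i P_ij + f_j P_ji`
  built from the requested row-stochastic matrix. The emitted truth is
  the row-normalized joint, which is precisely the population value of
  the unit-level co-occurrence estimator, so recovery tests are unbiased
  by construction rather than by luck.

`generate_substitution_corpus()` plants per-entry candidate mixtures into
template sentences (shared context words flanking a target slot), and
`generate_ontology_family()` cuts top/random/bottom frequency strata of
equal size so metric orderings are predictable. All generation is driven
by a single integer seed through an RNG-state-preserving wrapper: the
same seed yields byte-identical corpora, and generation never disturbs
the ambient RNG stream.

What the generator does **not** emulate: English syntax, sense ambiguity,
multiword concept surface variation, discourse structure, or the long-tail
vocabulary of real abstracts. Passing recovery tests therefore
demonstrates the estimators' correctness on the statistical structure the
metrics consume, not end-to-end robustness of concept recognition on real
clinical text — the latter depends on the tagger and lexicon supplied.

## Numerical and degenerate-input choices

* Frequencies on an empty mention set are an error, not `NaN`; empty
  documents are dropped with a warning at ingestion.
* Precision/recall with undefined denominators are reported `NA`, never
  silently 0; `F = 0` when both are defined and zero.
* Depth on an empty ontology is an error (`size 0` denominators are
  refused); Breadth of an ontology disjoint from the corpus is 0, and its
  Depth is 0.
* All probability-conservation checks in the test suite use a tolerance
  of `1e-9`; context keys are canonical sorted strings, so equality of
  contexts is exact, not floating-point.
* Duplicate relation triples collapse on construction; relations with
  dangling endpoints are an integrity error rather than being silently
  dropped.

## Problem sizes in the test suite

The suite checks oracle equivalence on corpora of up to 50 documents
(exact equality against an independent naive scanner), fittest optimality
on 200 seeded instances of up to 12 candidate pairs (exhaustive
enumeration), conservation laws on 1,000+ seeded random fixtures per
property, and parameter recovery at 5,000 documents / 5,000 planted
substitution occurrences within three standard errors on entries with
adequate support (row counts of at least 50, the usual multinomial
normality floor). These sizes give the Monte-Carlo checks comfortable
power while keeping the default test run quick.

## Known limitations

* Dictionary recognition has no disambiguation: polysemous surface forms
  are credited to whichever concept claims them first in the lexicon.
* Co-occurrence is a proxy for stated relations; it cannot distinguish
  relation types, which is why typed weights must come from an external
  extractor or fixtures.
* The built-in tagger is rule-based English; agglutinative morphology,
  clinical shorthand and tokenization edge cases are out of scope.
* Relative metrics require a positive fittest depth — a corpus with no
  recognized concepts cannot anchor any comparison.
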