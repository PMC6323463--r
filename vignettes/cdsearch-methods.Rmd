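---
title: "Methods: ontology-driven passage retrieval with multilevel feedback and negation weighting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ontology-driven passage retrieval with multilevel feedback and negation weighting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdsearch)
```

# The retrieval problem

`cdsearch` retrieves paragraph-level passages from biomedical textbooks in
response to free-text laboratory test reports ("AFP is normal",
"Eosinophil has been increased"). Two report properties drive the design:
surface forms vary wildly (abbreviations, long forms, local-language
terms), and the polarity of a finding (normal vs. abnormal) changes what a
useful passage looks like. The engine therefore couples a lexicon-bearing
domain ontology with a negation-aware ranking function, and uses
pseudo-relevance feedback at two corpus levels to reach passages that
never mention the query concept literally.

# The model, stage by stage

## Ontology and concept detection

The ontology is a deliberately flat schema: four classes (Test, Specimen,
Category, Disease); instances with exactly one representative term, a
multilingual synonym set, optional external vocabulary codes; and typed
properties (test–specimen, test–category, test–disease). Every surface
form maps to exactly one instance — a validated invariant — which makes
translation a lookup: scan the token stream with longest-match-first,
leftmost n-gram matching (up to 4 tokens), rewrite each hit to its
representative English term, and drop unmapped tokens. Longest-match-first
is our resolution of partially overlapping multi-word synonyms; the choice
is recorded here because nothing in the problem statement forces it.

Case folding lowercases ASCII; non-Latin surfaces are matched verbatim.
A semantic-type restriction list for external concept-mapper plugins is
carried as configuration only; the packaged detector needs no filter
because the ontology's classes already delimit its scope.

## Synonym expansion

Detected concepts contribute their synonyms at weight 0.5 (originals stay
at 1). The weight acts on the *score contribution* of the term, not on its
frequency — the scorers are linear in query weights, so this is
well-defined and testable. The synonym provider is a plug point; the
default is the ontology's own lexicon.

## Negation

Polarity detection is a trigger-window simplification of NegEx: a concept
mention is negated if a pre-trigger ("no", "not", "negative", "normal")
occurs within 5 tokens before it, or a post-trigger ("negative", "normal")
within 5 tokens after it, never crossing a sentence boundary. "normal" and
"negative" act on both sides because report language places them after the
concept ("AFP is normal"); "no"/"not" act before. Pseudo-triggers and
termination terms of full NegEx are out of scope; the four-cue list is the
documented default and the lexicon is a plain JSON file users can edit.

A query is classified abnormal when affirmed mentions are at least as many
as negated ones (inclusive inequality, so a concept-free query counts as
abnormal — a literal reading we keep and document). Before retrieval, the
synonyms of each negated concept are rewritten to `no-` + term. Prefixed
terms simply fail to match the index; no scorer special-cases them. The
original term is never rewritten, preserving query intent; feedback-derived
terms are never rewritten either.

## Multilevel pseudo-relevance feedback

For a query `Q`, the top `k = 5` units of a corpus are mined. With `N` the
token count of the concatenated feedback units, `tf_t` the frequency of
`t` in that concatenation, `I_Q` and `I_Pi` membership indicators, and
`ipf_t` the inverse unit frequency of `t` in the corpus the feedback came
from, each root-set term receives

$$S_t(t) = \alpha\, I_Q(t)\, \frac{tf_t}{N} +
  \frac{\beta}{k} \sum_{i=1}^{k} I_{P_i}(t)\, \mathrm{ipf}_t, \qquad
  S_l(t) = \log_{10}(10 + S_t(t)),$$

with `alpha = 2`, `beta = 0.75`. The damping anchors "no support" at
exactly 1, which the fusion step exploits.

Two conventions deserve a note because the formula alone does not fix
them:

* `tf_t` counts occurrences in the concatenated feedback units (the root
  *set* has no frequencies), and `N` is the feedback token total.
* `ipf_t` is **corpus-level**: `log10((C + 1) / df_t)` over the corpus
  supplying the feedback, gated by the per-unit indicator. An alternative
  reading — inverse frequency *within* the top-k — inverts the intended
  behavior: a term present in all k feedback units (the classic latent
  associate, e.g. a disease that accompanies an elevated analyte) would
  then score *lowest*, because `pf · log((k+1)/pf)` peaks at `pf = 2` and
  collapses at `pf = k`. Corpus-level ipf makes pervasive-but-rare terms
  the strongest candidates, which is both the behavior the feedback
  recovery acceptance property demands and the point of IDF-weighted
  feedback in the first place.

Local feedback runs on the passage index, global feedback on the document
index — same code, different corpus. The two tables fuse as
`S_prf = lambda * S_l + (1 - lambda) * S_g` with `lambda = 0.65`; a term
absent from one side takes that side's degenerate value 1. The top
`m = 35` terms not already in the query join it with origin `prf` and
weight `S_prf / max S_prf` over the added set — the source method adds
terms but never states their weight, so max-normalization into `(0, 1]`
is our documented choice. Feedback rankings themselves are produced by the
fused three-model score (below); the single-model alternative is a
configuration away.

## Scoring, fusion, boost

Three models score the final weighted query, all linear in query weights:

* TF-IDF: `sum w_t (1 + ln tf) log10(C / df_t)` (variant tag
  `lnc-log10`);
* BM25, Robertson form with the non-negative idf
  `ln(1 + (C - df + .5)/(df + .5))`, `k1 = 1.2`, `b = 0.75`;
* Dirichlet language model, `mu = 2500`; query terms with zero collection
  frequency are skipped (the standard convention — otherwise every
  document would score `-Inf`).

Per model, the union of top-`M = 100` candidates is pooled; scores are
min-max normalized over the pool (units a model did not score take the
pool minimum, so absence is never rewarded; a degenerate model contributes
zero), summed across models, and divided by the pool total. Fused scores
therefore form a probability distribution over the pool — an invariant the
tests assert — and if every model is degenerate the distribution is
uniform. The printed form of the fusion formula is notationally ambiguous
about its denominator; the pooled-total reading is implemented and
recorded here so alternates can be compared.

If the query is abnormal, every pooled passage `i` with affirmed/negated
mention counts `A_i`/`N_i` gains
`gamma * (1 + A_i / (A_i + N_i))`, `gamma = 2`; a mention-free passage
takes the fraction as 0 (still gaining `gamma`), so the added mass lies in
`[gamma, 2 gamma]` exactly for mention-bearing passages. Since fused
scores are at most 1, the boost dominates: the final order is "affirmed
passages by fused score, then the rest" — a deliberate, simple re-ranking
that can run on-the-fly. Normal queries bypass the boost entirely; their
benefit from negation handling comes from the `no-` prefix filtering noisy
synonyms of negated concepts.

Final ranking is by descending score, ties broken by ascending passage id
(determinism), truncated to 500 entries per query.

# Evaluation

Binary relevance conflates "possibly" and "definitely" relevant; unjudged
pairs are not relevant (the standard pooled-assessment convention). P@N,
R-precision, nDCG (rank-1 gain undiscounted, `log2` discount from rank 2 —
the discount base is unstated in the source, `log2` is the standard
choice), and MRR (queries retrieving no relevant passage contribute 0,
also a documented choice) are implemented directly and checked against
brute-force oracles. Paired run comparison uses a paired t-test on
per-query metric vectors; degenerate difference vectors (numerically
constant) report p = 0 for a nonzero shift and p = 1 for identical runs
rather than erroring.

# The synthetic world

The generator builds, from one seed, an ontology (tests with an
abbreviation, an English variant and an ASCII-safe surrogate "Korean"
surface; linked diseases, specimens, categories), a passage corpus, a
larger document corpus, 30 queries (half normal, half abnormal phrasing)
and graded qrels. Its structure encodes exactly the assumptions the engine
exploits:

* Per concept, ~20 on-topic passages mention the test (30% via a synonym),
  40% phrased as abnormal findings (affirmed language), 60% as normal
  findings carrying a negation trigger; ~6 further passages discuss only
  the linked disease.
* Disease co-mention is asymmetric: abnormal-phrased passages and relevant
  documents name the linked disease with probability 0.8, normal-phrased
  passages only 0.05. This mirrors how textbooks work — disease discussion
  accompanies the description of an abnormality, not the statement that a
  value is normal — and it is what makes the mined latent term informative
  about *relevance* rather than mere topicality. With a symmetric rate the
  feedback stages cannot help early precision in principle, because
  concept match alone already saturates topical ranking.
* Sentence templates are balanced to equal content-token counts after
  stopword removal. An earlier draft had abnormal templates systematically
  shorter; BM25/LM length normalization then mimicked a polarity signal
  and inflated the no-feedback tiers by artifact. Generated worlds need
  the same confound hygiene as real experiments.
* Judgments encode the two clinical intents: a normal-result query is
  answered by normal-phrased passages (definitely relevant) and
  abnormal-phrased ones (possibly relevant); an abnormal-result query by
  abnormal-phrased passages (definitely) and disease-only passages
  (possibly), while normal-phrased passages do not answer it. This gives
  abnormal queries the systematic difficulty the negation boost is
  designed to remove, and is the package's resolution of a grading detail
  the module contract left open.
* Background text is Zipf-distributed over a 500-word pseudo-vocabulary
  (7 tokens/sentence, 2–4 sentences per passage); queries use the
  surrogate-Korean surface 25% of the time and an English synonym 40% of
  the time, exercising translation and normalization.

What the generator does **not** emulate: real textbook length statistics,
realistic sentence grammar, polysemy/ambiguity of surface forms,
cross-concept semantic relatedness, and assessor noise. A green ablation
therefore establishes that each pipeline stage exploits the structure it
is designed for — not that effect sizes transfer to real corpora.

# Numerical and degenerate-input conventions

* Empty feedback set: all terms get `S_t = 0`, `S_l = 1`.
* `expand_query` with `m = 0`, or with no candidates outside the query, is
  the identity.
* Queries whose concept detection finds nothing fall back to raw
  stopword-filtered tokens with a warning (the baseline behavior).
* Zero-relevant queries: R-precision is undefined (NA with a warning, the
  query is skipped in means); nDCG is 0; MRR contributes 0.
* All randomness flows from explicit seeds; identical seed and
  configuration reproduce collections and run files byte-for-byte.
* Ranking ties anywhere break by ascending id; expansion-term ties by
  ascending term string.

# Known limitations

The negation module is a four-cue trigger window, not full NegEx;
uncertainty/hedging is out of scope. The baseline's "noun detection" is
approximated by stopword-filtered token passthrough (a POS tagger is a
plug point). Feedback depth, expansion size and mixing weight are fixed at
the published operating point (`k = 5`, `m = 35`, `lambda = 0.65`,
`gamma = 2`); no parameter search is performed. Proximity information and
learned fusion weights are explicitly out of scope.
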