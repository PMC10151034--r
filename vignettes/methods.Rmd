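---
title: "Evidence-weighted knowledge graphs for drug repositioning: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-weighted knowledge graphs for drug repositioning: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugrepo)
```

This vignette documents the statistical model behind `drugrepo`, the
parameters a user may want to move, the choices made where the design was
genuinely open, and the limits of what the shipped synthetic fixtures can
demonstrate.

## The model

### Assertion probabilities

Every ingested row is one *assertion*: a subject–type–object triple plus its
provenance (source database, evidence, publication reference), analogous to
a nanopublication. Each assertion receives a probability representing how
often evidence of its kind turns out to be correct:

* **Curated** assertions — drug–target entries, gene–disease associations
  from curated catalogues — get `curated_probability`, default **0.999**.
  The value encodes "curation errors exist but are rare"; it is deliberately
  not 1, both on principle and because the probability 1 has an infinite
  normal quantile.
* **Experimental** assertions get the probability of their detection
  method's confidence level. The default mapping is level 1 → **0.8**
  (weak evidence needing independent verification, e.g. yeast two-hybrid),
  level 2 → **0.95** (generally reliable, e.g. pull-down), level 3 →
  **0.99** (few false positives, e.g. X-ray crystallography).

These numbers are interpretable operating assumptions, not fitted
quantities. They live in the evidence configuration
(`evidence_config()`, YAML-serialisable), together with the method→level
table, which is data: the shipped `default_evidence_config()` covers a small
illustrative set of PSI-MI codes and is meant to be replaced wholesale for
real corpora. Method codes missing from the table are governed by
`unknown_method_policy`: `"error"` (fail loudly) or `"default_level_1"`
(treat unknown evidence as weak). The configuration enforces
`curated_probability >` every level probability, keeping the evidence
hierarchy coherent under user overrides.

The two experts who produce such method ratings will not agree perfectly;
`scotts_pi()` quantifies their chance-corrected agreement. Scott's Pi uses
*pooled* marginal category proportions (unlike Cohen's kappa, which keeps
per-annotator marginals), which is appropriate when neither annotator is
privileged.

### Combining redundant records

The graph keeps exactly one edge per (subject, interaction type, object)
triple; all records for that triple hang off the edge. Redundant records are
combined by unweighted Stouffer voting on the probability scale:

$$P(x_1 \ldots x_n) = \Phi\!\left(\sum_{i=1}^{n} \Phi^{-1}(P(x_i))\right)$$

A single record is a fixed point ($\Phi(\Phi^{-1}(p)) = p$); two records at
0.8 combine to ≈ 0.954; evidence at $p$ and $1-p$ cancels to 0.5. This
reinforcement is the reason the combiner is the default: the geometric mean
(also provided, `combiner_spec("geometric_mean")`) maps $n$ identical
reports of $p$ to exactly $p$, i.e. it cannot express that independent
replication should increase confidence.

Two open choices were resolved as follows:

* **Curated and experimental records for one triple are combined
  uniformly**, rather than letting a curated record short-circuit the vote.
  With the default values a curated record ($\Phi^{-1}(0.999) \approx 3.09$)
  dominates the sum anyway, and a uniform rule keeps the combiner a pure
  function of the probability list. The alternative (curated precedence) is
  a one-line filter on the records before combination if a user wants it.
* **Near-duplicate records are dropped before combining** (toggleable via
  `combiner_spec(deduplicate = FALSE)`). Interaction databases mirror each
  other; two copies of the same (method, publication) pair are one
  experiment, and counting them twice inflates the combined probability.
  Deduplication keys on (triple, source database, method code, publication);
  it is a cheap mitigation, not a full non-independence correction — two
  *different* publications describing one physical experiment still count
  twice.

### Path expansion and candidates

The joint probability of an interaction chain is the product of its edge
probabilities — the probability that every link is simultaneously true,
assuming independence of the (already-combined) edges. `kg_expand()`
enumerates simple paths from a seed entity under two user limits: a maximum
step count and a minimum joint probability, defaulting to the operating
point **≤ 3 steps, p ≥ 0.93**. Since every edge probability is ≤ 1, a
partial path below threshold can never recover, so the depth-first search
prunes it immediately; the brute-force enumeration oracle in the test suite
confirms the pruned search is exact.

Traversal rules, all of which the oracle tests pin down:

* Directed edges (drug→target, gene→disease) are walked only along the
  query direction; undirected PPI edges are walked freely. Most PPI
  detection methods do not orient the interaction, while drug→target and
  gene→disease assertions are intrinsically directional.
* Paths are simple (no node revisits): a revisit cannot raise the joint
  probability and has no biological reading here.
* Self-interactions are stored but never advance a path.
* The endpoint type filter (`drug` for candidate search) constrains only
  the terminal node; intervening proteins/genes are unrestricted.

`find_candidates()` groups the surviving paths by terminal drug and reports
each drug's best path — highest joint probability, ties broken by fewer
steps, then by the lexicographic node sequence, making output deterministic.
"Steps" counts edges on the drug→…→disease chain.

### Evaluation

Ground truth is a status per (drug, disease) pair —
`approved`, `phase_iii`, `phase_ii`, `phase_i`, `case_study`, `in_vitro`,
`in_vivo`, `novel` — and a **hit** is any status except `novel`: the pair
has a published positive experiment or a clinical-trial record. Precision is
hits among returned candidates; recall is returned hits among all known
hits. Candidate pairs missing from the label table count as non-hits by
default (with the count reported), or raise an error in strict mode.

The **f-measure defaults to the harmonic mean** of precision and recall,
the conventional F1. The geometric mean $\sqrt{PR}$ — which some accounts of
this procedure describe as the f-measure — is selectable
(`f_mean = "geometric"`); the discrepancy is surfaced as an option rather
than silently resolved. On the replica both variants have their optimum at
the same thresholds. `threshold_sweep()` holds one axis at its default
(steps ≤ 3 while sweeping probability over 0.50–0.99; p ≥ 0.93 while
sweeping steps over 1–6) and breaks f-measure ties toward the stricter
threshold, so a flat plateau reports its conservative edge.

## Numerical choices

* **Clamping.** Probabilities are clamped into $[\varepsilon, 1-\varepsilon]$,
  $\varepsilon = 10^{-6}$, before the quantile transform, which diverges at
  0 and 1. The default evidence values (max 0.999) are unaffected.
* **Saturation.** For roughly $\sum \Phi^{-1}(p_i) > 8.2$ the normal CDF is
  indistinguishable from 1 in double precision; the combiner then returns a
  value clamped just below 1 so the (0, 1) contract and downstream products
  stay well-defined. Strict reinforcement monotonicity is only asserted on
  grids that stay inside double resolution.
* **Undirected canonicalisation.** Undirected records are stored with the
  lexicographically smaller endpoint as subject, so (A, t, B) and (B, t, A)
  are one edge regardless of source row order.
* **Degenerate inputs.** Empty probability lists, probabilities outside
  (0, 1), unknown entities, malformed rows, and an all-`novel` label table
  raise typed conditions (`drugrepo_validation`, `drugrepo_missing_entity`,
  `drugrepo_io`); zero-denominator metrics return 0 with a warning rather
  than NaN.

## What the synthetic fixtures are — and are not

`generate_random_kg()` emulates desk-scale extracts of the real sources: a
MITAB-like PPI table with redundant records (multiplicity 1 + Poisson,
mean 1.5 by default), a drug–target table (1–3 targets per drug), and
gene–disease tables (2–5 genes per disease), over 12 drugs / 25 proteins /
2 diseases by default with PPI density 0.08 — sizes chosen so that graphs
are connected enough to have multi-step paths yet small enough for
exhaustive oracle comparison. The curated share of `evidence_mix` is
realised through the curated-table sizes and is therefore approximate;
the level-1/2/3 proportions are exact sampling weights. All randomness
flows from the single seed in `fixture_spec()`; generation is byte-identical
under a repeated seed and leaves the session's RNG state untouched.

`generate_table1_replica()` rebuilds the published melanoma worked example:
25 drugs reaching melanoma in 2 or 3 steps with joint probabilities that
round to the printed 0.93/0.95/0.97/0.98, five low-probability decoys
(joint ≈ 0.72) that penalise permissive thresholds, and one 4-step decoy
(joint ≈ 0.97) that penalises relaxed step limits — jointly making
0.93 / 3 steps the f-measure optimum. The original knowledge base's
per-edge probabilities are not recoverable from the published table, so the
replica ships its own evidence configuration (curated 0.99; levels
0.73/0.95/0.97) chosen to reproduce the printed roundings: 2-step paths are
two curated edges (0.99² = 0.9801 → 0.98); 3-step paths place one PPI edge
between two curated edges, a single level-2 or level-3 record
(→ 0.9311 → 0.93, → 0.9507 → 0.95), or a level-3 + level-1 pair whose
composite-Z is ≈ 0.9937 (→ 0.9739 → 0.97). These planted values are a
*construction*, not a claim about the original data.

Passing tests on these fixtures therefore show that the machinery —
ingestion, probability assignment, combination, pruned search, metrics — is
exact and deterministic at desk scale. They do not show that the method's
headline network statistics transfer to full source-database snapshots
(millions of interactions), nor that the 0.93 / 3-step operating point is
optimal outside the replica's construction, nor anything about the
biological validity of candidates on real data.

## Problem sizes used in the test suite

Oracle equivalence for the combiner runs 1,000 random probability lists of
sizes 1–10 against an independently implemented quantile/CDF (bisection on
the complementary error function); path-expansion equivalence runs 200
random graphs of up to 30 nodes against exhaustive enumeration. These sizes
give dense coverage of the combinatorics while keeping the whole suite
under a minute on a laptop.

## Known limitations

* Only binary PPI records are ingested; n-ary complex rows are skipped and
  counted. Pairwise expansion of complexes is a possible extension.
* GO/process-membership edges are not generated or scored; the `process`
  entity type exists in the vocabulary but no shipped reader emits it.
* Edge independence is assumed when multiplying along a path; shared
  evidence between *different* edges is not modelled.
* The identifier alias map is static and exact-match; no fuzzy cross-source
  entity resolution is attempted, by design (reproducibility over recall).
* Combined edge probabilities are recomputed, not incrementally updated;
  graphs at the intended desk scale make this a non-issue.
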