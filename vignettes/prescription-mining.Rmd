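---
title: "Mining herbal prescription corpora: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining herbal prescription corpora: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbminer)
```

## The problem and the data model

Clinical TCM records for coronary heart disease arrive as *prescriptions*:
one case = one set of herbs, optionally tagged with the patient's syndrome
pattern (e.g. "qi deficiency" + "blood stasis") and a patient identifier
when the same patient contributed follow-up visits. `herbminer` treats a
corpus as a market-basket dataset — cases are transactions, canonical herb
names are items — and derives four products from it: a use-frequency
profile, frequent multi-herb combinations, a basic/core prescription, and
high-support herbal pairs on a syndrome-filtered subset.

Two corpus-loading contracts precede any statistics:

* **Standardization.** Raw herb spellings are mapped to canonical
  hyphenated-pinyin names through an idempotently closed synonym map;
  unknown names are errors naming the offender, never silently kept.
  Matching is case-sensitive after whitespace trimming, so set operations
  are bit-stable.
* **First-prescription rule.** For each patient with follow-up records only
  the first prescription (by input order — the records carry no
  timestamps, so file order is the only defensible tiebreak) is kept, and
  exact repeats are dropped. Cases without a patient identifier are kept
  unless they repeat an earlier id-less case verbatim (same herb and
  syndrome sets); this is the narrowest reading that satisfies both "take
  the first prescription" and "repeated cases excluded" without discarding
  genuinely distinct anonymous cases. The operation is idempotent.

## Frequency statistics and rounding

`herb_frequency()` counts cases containing each herb; percentages are
`100·c(h)/N`. The attribute profile weights each herb's property, tastes
and meridians by its occurrence count. Every percentage in the profile —
including the multi-valued taste and meridian sections — uses one shared
denominator: the total number of herb occurrences (equal to the sum of the
property counts, since each herb carries exactly one property). This
convention is the only one consistent with published reference values
(44.95% warm, 58.15% sweet and 56.75% heart-meridian all against 10549
occurrences); per-section denominators reproduce none of them.

Display rounding is half-away-from-zero at two decimals (`round2()`), with
a `1e-9` epsilon against binary representation error. The printed
reference tables themselves contain two rows inconsistent with *any*
single rounding rule (a support printed 0.51 where the counts give 0.5049,
and 0.46 where they give 0.4657); `herbminer` follows the counts and
documents the discrepancy rather than reproducing it. All comparisons and
thresholds operate on exact unrounded fractions; rounding is display-only.

Thresholds are strict (`>`), matching the "used more than 100 times"
phrasing: on the printed 48-row table, 27 herbs exceed 100 uses and 6
herbs exceed 60%.

## Apriori mining

Support is the exact containment fraction `|{cases ⊇ S}|/N`; the empty set
has support 1 by vacuous containment. Level 1 keeps single herbs with
`supp ≥ s_min` — the threshold is inclusive, since combinations *below*
the minimum are what gets deleted. Level `k` candidates come from the
classic sorted-prefix join of level `k−1` (join two `(k−1)`-sets sharing
their first `k−2` sorted items), pruned by downward closure (every
`(k−1)`-subset must be frequent) before exact counting against a
case-by-herb incidence matrix. Iteration stops at `max_k` (default 5) or
at the first empty level.

Within a level, itemsets are ordered by support descending, ties broken by
the lexicographic herb tuple in the C locale — deterministic output
independent of case order and of the order herbs are listed within a case
(both invariances are property-tested).

Correctness is established against `brute_force_frequent()`, an
independent oracle that enumerates *every* subset of the vocabulary up to
`max_k` (guarded to ≤ 20 herbs) and filters by exact support. The
acceptance suite equates the two on 200 random corpora of up to 12 herbs;
downward closure, anti-monotonicity, and integrality of `supp·N` are
asserted on every mined level.

A terminological note: the published combination tables label their value
column "Confidence", but the values behave as joint supports (each is
bounded by both marginals). `herbminer` treats them as joint supports and
reserves *confidence* for the rule ratio `supp(A∪B)/supp(A)`
(`rule_confidence()`).

## "Top N groups", core prescription, herbal pairs

`top_n_groups()` formalises the basic-prescription procedure: at the
deepest non-empty level, the top-ranked itemset is the motherboard; the
remaining itemsets are consumed in rank order and every herb not yet in
the accumulating union is appended as a daughterboard. Defaults encode two
decisions left open by the source procedure:

* `n = ALL` — the published worked example applies the rule to *all seven*
  itemsets of its deepest level, and no numeric `N` is ever fixed, so the
  default consumes the whole level; `n` remains a parameter.
* The deepest level is *defined* as the largest `k` non-empty at the run's
  threshold. The source hand-picked its threshold until a 5-herb level
  appeared; no tuning rule is given, so `herbminer` takes `min_support` as
  input, reports the level reached, and offers a `level` override.

Daughterboard order is itemset rank, then within-itemset lexicographic —
purely for determinism; the basic prescription is a set. `n = 1` returns
exactly the motherboard, and the union is non-decreasing in `n` (both
property-tested).

`core_prescription()` intersects the basic prescription with the top-`m`
high-frequency herbs (default `m = 6`, the herbs above 60%). On the
published inputs this yields the 5-herb core (Gan-cao, Huang-qi,
Yan-hu-suo, San-qi, Dang-gui): Mai-dong and Wu-wei-zi fall outside the top
six, Chuan-xiong outside the basic prescription.

`mine_herbal_pairs()` is the level-2 slice of the miner at a higher
threshold (default 0.6) on a syndrome-filtered sub-corpus; its output
provably equals the level-2 slice of the brute-force oracle.

## The synthetic corpus generator

The study's 715 raw case records are not deposited, so the package ships a
generator whose *stated world* reproduces what the published summaries pin
down, and nothing more.

**Model.** Each case draws at most one template prescription (probability
= template weight; residual mass = no template), includes each template
herb independently with the template's inclusion probability, then adds
each background herb independently with its marginal probability; the
union is the case. Empty draws are redrawn. The single-template-per-case
mixture — rather than additive templates — keeps every planted itemset's
expected support in closed form:

> P(S ⊆ case) = Σ_t w_t · Π_{h∈S} p(h | t), with
> p(h | t) = 1 − (1 − inc_t)(1 − bg_h) for template herbs and bg_h
> otherwise,

and `planted_truth()` conditions this exactly on the case being non-empty
(division by `1 − P(empty draw)`), so the generator and its ground truth
agree *identically*, not just asymptotically. For realistic configs the
conditioning factor is 1 to nine decimals; it only matters for degenerate
toy configs with expected case sizes near zero.

**Default world** (`default_sim_config()`), fixed before any test was
run:

* 715 cases over 182 herbs. The top 48 herb names and marginal
  probabilities are the published frequency table; the remaining 134 herbs
  are reported only as "used fewer than 50 times", so they are synthetic
  placeholders `Herb-049`…`Herb-182` with counts decaying linearly 49 → 2.
* One planted template: the seven basic-prescription herbs, weight 0.45,
  inclusion 0.85 — chosen so the joint support of 5-herb subsets lands
  near the published ~0.3 while each template herb's *overall* marginal
  still matches the published table (its background probability is reduced
  to `(p − w·inc)/(1 − w·inc)`).
* Syndrome tags: template cases are tagged "qi deficiency" + "blood
  stasis" with probability 0.9, residual cases with probability 0.2,
  putting the expected tagged subset at ≈372 of 715 — the published subset
  size.

**What the generator does not emulate:** the real corpus's dependence
structure beyond the planted template (the published pairwise-support
tables are an under-determined inverse problem and are *not* jointly
matched), dose information, and temporal ordering. A green test on
synthetic data therefore establishes that the *pipeline* is correct under
a known truth — not that the generator is a statistical twin of the
clinical corpus.

`calibrate_marginals()` builds the template-free special case (background
probabilities = printed count/N); the acceptance suite checks every
empirical count at n = 715 against 3 binomial standard errors under a
fixed seed. `corpus_from_frequency()` is the deterministic counterpart
used by the worked examples: it realizes the printed counts *exactly* via
staggered assignment, so frequency statistics can be recomputed from an
actual corpus rather than read off the table; its joint structure is an
artifact and is never used for itemset-level claims.

**Recovery criterion world.** The planted-recovery test uses two disjoint
templates (weights 0.5/0.3, inclusion 0.9, sizes 4 and 2) whose herbs also
carry background probability 0.2, over 20 pure-background herbs at
0.05–0.2, n = 5000. The overlap is deliberate: with disjoint namespaces a
2-herb template at weight 0.3 has expected support 0.3·0.81 = 0.243,
*below* the 0.25 mining threshold; background overlap lifts it to 0.282
(5 standard errors above threshold), making the stated world actually
satisfiable. Recovery means both template herb sets appear among the
maximal frequent itemsets; the criterion demands ≥ 19 of 20 seeds.

## Determinism and degenerate inputs

Same seed + config ⇒ bit-identical corpus (the generator consumes one RNG
stream in fixed per-case order and restores the caller's RNG state). The
pipeline writes byte-identical bundles on identical inputs: JSON dumps
carry exact values, TSVs are pure two-decimal views of them, and the run
log records config and input digest but no timestamps. Degenerate inputs
fail loudly with typed conditions: empty corpora, thresholds outside
(0, 1], all-zero generation probabilities, motherboard selection on empty
levels, confidence with a zero-support antecedent.

## Known limitations

* Only support and confidence are implemented — no lift/leverage, no
  FP-growth; the analysis this package reproduces uses neither.
* The brute-force oracle is exponential and guarded at 20 herbs; it is a
  testing device, not an analysis path.
* The first-prescription rule trusts input order; with unordered exports
  it silently keeps whichever case came first in the file.
* Herb attributes must be supplied; the package never infers property,
  taste or meridian from a name.
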