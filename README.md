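# herbminer

Association-rule mining of clinical herbal prescription corpora.

`herbminer` is aimed at the prescription-pattern question that recurs in
traditional Chinese medicine (TCM) research on coronary heart disease (CHD):
given a few hundred clinical case records, each listing the herbs of one
prescription and the patient's syndrome tags, which herbs dominate, which
multi-herb combinations co-occur far more often than chance, and what
"basic" and "core" prescriptions do those combinations imply? The package
is written for clinical data miners who have such case records (or need a
calibrated stand-in for them) and want the full analysis as tested,
reproducible code rather than spreadsheet steps.

## What it computes

For a corpus of `N` prescriptions over a vocabulary of herbs:

* **Frequency profile** — for each herb `h`, the case count `c(h)` and
  percentage `100·c(h)/N`; for each property/taste/meridian category, the
  occurrence-weighted count and its percentage over the total number of
  herb occurrences.
* **Frequent itemsets (Apriori)** — the support of an herb set `S` is
  `supp(S) = |{cases ⊇ S}| / N`. Level `L_k` holds all `k`-sets with
  `supp ≥ s_min` (default 0.3), built level-wise by the sorted-prefix join
  with downward-closure pruning; a brute-force subset enumerator provides
  an independent oracle. Rule confidence is
  `conf(A→B) = supp(A ∪ B) / supp(A)`.
* **"Top N groups" basic prescription** — the highest-support itemset at
  the deepest non-empty level is the *motherboard*; walking the rest of
  that level in rank order, each unseen herb is appended as a
  *daughterboard*; the union is the basic prescription.
* **Core prescription** — the intersection of the basic prescription with
  the top-`m` high-frequency herbs (default `m = 6`).
* **Herbal pairs** — all 2-sets with `supp ≥ 0.6` (default) on a
  syndrome-filtered sub-corpus (e.g. qi deficiency + blood stasis).
* **Synthetic corpora** — a single-template-per-case mixture generator with
  per-herb background marginals, planted template combinations with
  closed-form expected supports, and syndrome tagging; calibratable to a
  published frequency table.

## Worked example

The published summaries of a 715-case CHD corpus ship as reference inputs.
Extracting the basic and core prescriptions from the seven printed frequent
5-herb combinations:

```r
library(herbminer)

l5 <- chd_l5_itemsets()          # the 7 frequent 5-itemsets, support >= 0.3
basic <- top_n_groups(l5)        # n = ALL: consume the whole level
basic
#> <basic_prescription> motherboard {Huang-qi, Mai-dong, San-qi, Wu-wei-zi, Yan-hu-suo} @ 0.33
#>   + daughterboards: Gan-cao, Dang-gui
#>   = basic prescription (7 herbs): Huang-qi, Mai-dong, San-qi, Wu-wei-zi, Yan-hu-suo, Gan-cao, Dang-gui

core_prescription(basic, chd_herb_frequency(), top_m = 6)
#> [1] "Gan-cao"    "Huang-qi"   "Dang-gui"   "Yan-hu-suo" "San-qi"
```

The motherboard is the top 5-herb combination (joint support 0.33 — a third
of all 715 prescriptions contain all five herbs); the two daughterboards
extend it to the 7-herb basic prescription; intersecting with the six herbs
used in more than 60% of cases leaves the 5-herb core prescription.

A full pipeline on a synthetic corpus:

```r
corpus <- generate_corpus(default_sim_config(seed = 42))
corpus
#> <prescription_corpus> 715 cases, 181 herbs
sub <- filter_by_syndromes(corpus, c("qi deficiency", "blood stasis"))
sub$n_cases
#> [1] 387
head(mine_herbal_pairs(sub, 0.6), 3)
#>      herb1    herb2     score
#> 1  Gan-cao Huang-qi 0.8036176
#> 2 Dang-gui Huang-qi 0.7855297
#> 3 Dang-gui  Gan-cao 0.7803618
```

The same stages are scriptable via the CLI launcher
(`system.file("cli", "herbminer.R", package = "herbminer")`) with
subcommands `mine`, `pairs`, `simulate` and `profile`.

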