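test_that("select_motherboard takes the deepest level's top itemset with tie rule", {
  l5 <- chd_l5_itemsets()
  mb <- select_motherboard(l5)
  expect_equal(mb$herbs, c("Huang-qi", "Mai-dong", "San-qi", "Wu-wei-zi",
                           "Yan-hu-suo"))
  expect_equal(mb$support, 0.33)

  # single level, single itemset
  one <- apriori(prescription_corpus(list(prescription("c1", "A"))), 0.5, 1)
  expect_equal(select_motherboard(one)$herbs, "A")

  # equal support -> lexicographically smaller tuple
  tie <- prescription_corpus(list(prescription("c1", c("A", "B")),
                                  prescription("c2", c("A", "C"))))
  mb2 <- select_motherboard(apriori(tie, 0.5, 2))
  expect_equal(mb2$herbs, c("A", "B"))

  empty <- apriori(toy_corpus(), 0.9, 3)
  expect_error(select_motherboard(empty),
               class = "herbminer_no_motherboard")
})

test_that("top_n_groups accumulates daughterboards in rank order", {
  l5 <- chd_l5_itemsets()
  bp <- top_n_groups(l5)  # n = ALL
  expect_equal(sort(bp$basic_prescription),
               sort(c("Gan-cao", "Huang-qi", "Mai-dong", "San-qi",
                      "Yan-hu-suo", "Wu-wei-zi", "Dang-gui")))
  expect_equal(length(bp$basic_prescription), 7L)
  expect_equal(bp$daughterboards, c("Gan-cao", "Dang-gui"))
  expect_equal(bp$n_used, 7L)
  expect_length(intersect(bp$daughterboards, bp$motherboard$herbs), 0)

  # n = 1 returns exactly the motherboard
  bp1 <- top_n_groups(l5, n = 1)
  expect_equal(bp1$basic_prescription, bp1$motherboard$herbs)
  expect_length(bp1$daughterboards, 0)

  # monotone in n
  sizes <- vapply(1:7, function(n)
    length(top_n_groups(l5, n)$basic_prescription), integer(1))
  expect_true(all(diff(sizes) >= 0))

  # all itemsets identical -> no daughterboards
  same <- prescription_corpus(list(prescription("c1", c("A", "B")),
                                   prescription("c2", c("A", "B"))))
  expect_length(top_n_groups(apriori(same, 1, 2))$daughterboards, 0)
  expect_error(top_n_groups(l5, n = 0), class = "herbminer_arg_error")
})

test_that("core_prescription intersects with the top high-frequency herbs", {
  bp <- top_n_groups(chd_l5_itemsets())
  freq <- chd_herb_frequency()
  core <- core_prescription(bp, freq, top_m = 6)
  expect_equal(sort(core), sort(c("Gan-cao", "Huang-qi", "Yan-hu-suo",
                                  "San-qi", "Dang-gui")))
  # nested in top_m
  for (m in c(1, 3, 6, 20, 48)) {
    expect_true(all(core_prescription(bp, freq, m) %in%
                      core_prescription(bp, freq, min(m + 5, 48))))
  }
  # full table -> basic prescription itself (all its herbs are in the table)
  expect_equal(sort(core_prescription(bp, freq, 48)),
               sort(bp$basic_prescription))
  # disjoint top herbs -> empty, not an error
  other <- frequency_table(c("X", "Y"), c(5L, 4L), 10L)
  expect_length(core_prescription(bp, other, 2), 0)
  expect_error(core_prescription(bp, freq, 0), class = "herbminer_arg_error")
  expect_error(core_prescription(bp, freq, 49), class = "herbminer_arg_error")
})

test_that("mine_herbal_pairs ranks exact joint supports above the threshold", {
  # 10 cases: {A,B} in 9, {A,C} in 6 (overlapping memberships)
  cases <- lapply(1:10, function(i) {
    herbs <- c("A", if (i <= 9) "B", if (i <= 6) "C")
    prescription(sprintf("c%02d", i), unique(herbs))
  })
  co <- prescription_corpus(cases)
  pr <- mine_herbal_pairs(co, 0.6)
  expect_equal(paste(pr$herb1, pr$herb2), c("A B", "A C", "B C"))
  expect_equal(pr$score, c(0.9, 0.6, 0.6))

  # equals the level-2 slice of the brute-force oracle
  bf <- brute_force_frequent(co, 0.6, 2)
  l2 <- bf$levels[[2]]
  expect_equal(nrow(pr), length(l2))
  expect_equal(pr$score, vapply(l2, `[[`, numeric(1), "support"))

  hetero <- toy_corpus()
  expect_equal(nrow(mine_herbal_pairs(hetero, 1.0)), 0L)
})

test_that("pair_ranking orders printed scores with deterministic ties", {
  pr <- pair_ranking(c("B", "A", "C"), c("C", "B", "D"), c(0.7, 0.9, 0.7),
                     min_score = 0.6)
  expect_equal(paste(pr$herb1, pr$herb2), c("A B", "B C", "C D"))
  expect_equal(pr$score, c(0.9, 0.7, 0.7))
  expect_error(pair_ranking("A", "A", 0.9), class = "herbminer_arg_error")
  expect_error(pair_ranking(c("A", "A"), c("B", "B"), c(0.9, 0.8)),
               class = "herbminer_arg_error")
  expect_error(pair_ranking("A", "B", 0.5, min_score = 0.6),
               class = "herbminer_arg_error")
})
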