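test_that("generate_corpus is a pure function of config and seed", {
  cfg <- sim_config(
    n_cases = 50,
    templates = list(template_spec(c("A", "B", "C"), 0.6, 0.9)),
    background_probs = c(D = 0.3, E = 0.2),
    syndrome_rules = list(`1` = list(tags = "qi deficiency", prob = 0.8)),
    seed = 99)
  co1 <- generate_corpus(cfg)
  co2 <- generate_corpus(cfg)
  expect_identical(co1, co2)
  expect_equal(co1$n_cases, 50L)
  # different seed differs
  cfg2 <- sim_config(n_cases = 50, templates = cfg$templates,
                     background_probs = cfg$background_probs,
                     syndrome_rules = cfg$syndrome_rules, seed = 100)
  expect_false(identical(generate_corpus(cfg2), co1))
  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(generate_corpus(cfg))
  expect_identical(stats::runif(1), before)
})

test_that("degenerate template and config specs are rejected", {
  expect_error(template_spec(character(), 0.5), class = "herbminer_arg_error")
  expect_error(template_spec("A", 0), class = "herbminer_arg_error")
  expect_error(sim_config(n_cases = 0), class = "herbminer_arg_error")
  expect_error(sim_config(templates = list(template_spec("A", 0.6),
                                           template_spec("B", 0.6))),
               class = "herbminer_arg_error")  # weights sum > 1
  expect_error(sim_config(background_probs = c(A = 0)),
               class = "herbminer_degenerate_config")
  expect_error(sim_config(), class = "herbminer_degenerate_config")
})

test_that("a deterministic template is reproduced exactly and recovered", {
  cfg <- sim_config(n_cases = 40,
                    templates = list(template_spec(c("A", "B", "C"), 1, 1)),
                    seed = 5)
  co <- generate_corpus(cfg)
  expect_true(all(vapply(co$cases, function(p)
    identical(p$herbs, c("A", "B", "C")), logical(1))))
  expect_equal(support(co, c("A", "B", "C")), 1.0)
  lv <- apriori(co, 0.9, 3)
  expect_equal(lv$levels[[3]][[1]]$herbs, c("A", "B", "C"))
})

test_that("empirical supports match planted_truth within 3 binomial SEs", {
  cfg <- sim_config(
    n_cases = 5000,
    templates = list(template_spec(c("A", "B"), 0.6, 0.9)),
    background_probs = c(C = 0.3),
    seed = 2024)
  truth <- planted_truth(cfg)
  # closed form with exact non-empty conditioning: the raw-draw probability
  # 0.6 * 0.9^2 = 0.486 scaled by 1/(1 - P(empty draw)), where
  # P(empty) = (0.4 + 0.6 * 0.1^2) * 0.7 for this config
  p_empty <- (0.4 + 0.6 * 0.1^2) * 0.7
  expect_equal(truth$expected_support[truth$herbs == "A, B"],
               0.6 * 0.81 / (1 - p_empty))
  co <- generate_corpus(cfg)
  for (i in seq_len(nrow(truth))) {
    p <- truth$expected_support[i]
    emp <- support(co, strsplit(truth$herbs[i], ", ", fixed = TRUE)[[1]])
    se <- sqrt(p * (1 - p) / cfg$n_cases)
    expect_lt(abs(emp - p), 3 * se + 1e-12,
              label = sprintf("itemset {%s}", truth$herbs[i]))
  }
  # padded config whose empty-draw probability is zero recovers the
  # uncorrected closed forms exactly: 0.486 for the full template, 0.3 for
  # the background-only herb
  cfg2 <- sim_config(
    n_cases = 5000,
    templates = list(template_spec(c("A", "B"), 0.6, 0.9)),
    background_probs = c(C = 0.3, Z = 1.0),
    seed = 2024)
  t2 <- planted_truth(cfg2)
  expect_equal(t2$expected_support[t2$herbs == "A, B"], 0.486)
  co2 <- generate_corpus(cfg2)
  expect_lt(abs(support(co2, c("A", "B")) - 0.486),
            3 * sqrt(0.486 * 0.514 / 5000))
  expect_lt(abs(support(co2, "C") - 0.3), 3 * sqrt(0.3 * 0.7 / 5000))
})

test_that("planted_truth handles background overlap and full-template cases", {
  cfg <- sim_config(
    n_cases = 10,
    templates = list(template_spec(c("A", "B"), 0.5, 1)),
    background_probs = c(A = 0.2, D = 1.0),  # D at 1 => no empty draws
    seed = 1)
  truth <- planted_truth(cfg)
  # inclusion 1, weight w, overlap on A: P(A,B) = 0.5*1 (template) + 0
  expect_equal(truth$expected_support[truth$herbs == "A, B"], 0.5)
  # marginal of A: 0.5*1 + 0.5*0.2
  expect_equal(truth$expected_support[truth$herbs == "A"], 0.6)
  expect_equal(truth$expected_support[truth$herbs == "B"], 0.5)
})

test_that("calibrate_marginals targets count/n_cases per herb", {
  freq <- frequency_table(c("A", "B"), c(543L, 100L), 715L)
  cfg <- calibrate_marginals(freq, 715, seed = 3)
  expect_equal(unname(cfg$background_probs["A"]), 543 / 715)
  expect_length(cfg$templates, 0)
  expect_error(calibrate_marginals(freq, 500), class = "herbminer_arg_error")
  # single herb at count = n_cases appears in every generated case
  all_cfg <- calibrate_marginals(frequency_table("A", 20L, 20L), 20,
                                 seed = 4)
  co <- generate_corpus(all_cfg)
  expect_equal(support(co, "A"), 1.0)
})

test_that("default config states the published world", {
  cfg <- default_sim_config(seed = 8)
  expect_equal(cfg$n_cases, 715L)
  expect_length(cfg$templates, 1)
  expect_equal(length(cfg$background_probs), 182L)  # 48 named + 134 rare
  # template-herb marginals are preserved by the background reduction (up
  # to the ~1 + 2e-9 non-empty conditioning factor of this dense config)
  truth <- planted_truth(cfg, max_size = 1)
  freq <- chd_herb_frequency()
  for (h in cfg$templates[[1]]$herbs) {
    expect_equal(truth$expected_support[truth$herbs == h],
                 freq$count[freq$herb == h] / 715, tolerance = 1e-8)
  }
  co <- generate_corpus(cfg)
  expect_equal(co$n_cases, 715L)
  # syndrome-tagged subset lands near the published 372 of 715
  sub <- filter_by_syndromes(co, c("qi deficiency", "blood stasis"))
  expect_gt(sub$n_cases, 300); expect_lt(sub$n_cases, 450)
})
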