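# Fixtures are built in code; no binary data.

# 4-case toy used across modules: {A,B}, {A}, {B,C}, {A,B,C}
toy_corpus <- function() {
  prescription_corpus(list(
    prescription("c1", c("A", "B")),
    prescription("c2", "A"),
    prescription("c3", c("B", "C")),
    prescription("c4", c("A", "B", "C"))))
}

# independent-bernoulli random corpus over a small herb namespace;
# empty cases are redrawn so corpus invariants hold
random_corpus <- function(n_cases, n_herbs, seed) {
  set.seed(seed)
  herbs <- sprintf("H%02d", seq_len(n_herbs))
  probs <- stats::runif(n_herbs, 0.1, 0.8)
  cases <- lapply(seq_len(n_cases), function(i) {
    repeat {
      inc <- stats::runif(n_herbs) < probs
      if (any(inc)) break
    }
    prescription(sprintf("c%03d", i), herbs[inc])
  })
  prescription_corpus(cases)
}

# attribute table covering herbs A, B, C of the toy corpus
toy_attrs <- function() {
  herb_attribute_table(
    herb = c("A", "B", "C"),
    property = c("Warm", "Cold", "Warm"),
    tastes = list("Sweet", c("Bitter", "Sweet"), "Pungent"),
    meridians = list("Heart", c("Heart", "Liver"), "Liver"))
}

# flat view of mined levels for oracle comparisons: k, tuple-key, support
levels_signature <- function(lv) {
  df <- as.data.frame(lv)
  df[order(df$k, df$herbs, method = "radix"), c("k", "herbs", "support")]
}

# maximal frequent itemsets (no frequent strict superset) as tuple keys
maximal_itemsets <- function(lv) {
  all_sets <- list()
  for (k in seq_along(lv$levels))
    for (it in lv$levels[[k]])
      all_sets[[length(all_sets) + 1L]] <- it$herbs
  is_max <- vapply(seq_along(all_sets), function(i) {
    !any(vapply(seq_along(all_sets), function(j) {
      j != i && length(all_sets[[j]]) > length(all_sets[[i]]) &&
        all(all_sets[[i]] %in% all_sets[[j]])
    }, logical(1)))
  }, logical(1))
  vapply(all_sets[is_max], paste, character(1), collapse = ",")
}

extdata <- function(name) system.file("extdata", name, package = "herbminer")
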