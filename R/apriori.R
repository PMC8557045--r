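#' @title Frequent-itemset mining over prescription corpora
#' @name itemset_mining
#' @description
#' Level-wise Apriori mining of herb combinations: the frequent set
#' \eqn{L_1} holds every single herb whose support (fraction of cases
#' containing it) meets the minimum-support threshold, and \eqn{L_k} is
#' derived from \eqn{L_{k-1}} by the sorted-prefix join, downward-closure
#' pruning and exact support filtering. Supports are kept as exact fractions
#' of the case count; two-decimal rounding is display-only. A brute-force
#' subset enumerator over small vocabularies serves as an independent oracle.
NULL

# cases x herbs logical incidence matrix in vocabulary order
corpus_incidence <- function(corpus) {
  vocab <- corpus$vocabulary
  m <- matrix(FALSE, nrow = corpus$n_cases, ncol = length(vocab),
              dimnames = list(NULL, vocab))
  sets <- corpus_herb_sets(corpus)
  for (i in seq_along(sets)) m[i, sets[[i]]] <- TRUE
  m
}

#' Exact support of an herb combination
#'
#' @param corpus a non-empty [prescription_corpus()].
#' @param herbs character vector of herb names (an itemset; duplicates
#'   collapse). The empty itemset has support 1 by vacuous containment.
#' @return fraction of cases whose herb set contains every herb of `herbs`,
#'   unrounded.
#' @export
support <- function(corpus, herbs) {
  stopifnot(inherits(corpus, "prescription_corpus"))
  if (corpus$n_cases == 0L)
    abort2("support is undefined on an empty corpus",
           "herbminer_empty_input")
  herbs <- sort_herbs(herbs)
  if (length(herbs) == 0L) return(1.0)
  if (!all(herbs %in% corpus$vocabulary)) return(0.0)
  sets <- corpus_herb_sets(corpus)
  n <- sum(vapply(sets, function(s) all(herbs %in% s), logical(1)))
  n / corpus$n_cases
}

new_frequent_itemsets <- function(levels, min_support, max_k, n_cases) {
  structure(list(min_support = min_support, max_k = max_k,
                 n_cases = n_cases, levels = levels),
            class = "frequent_itemsets")
}

# sort itemsets of one level: support desc, then lexicographic tuple
sort_level <- function(items) {
  if (length(items) == 0L) return(items)
  supp <- vapply(items, `[[`, numeric(1), "support")
  keys <- vapply(items, function(x) itemset_key(x$herbs), character(1))
  items[order_by_support(supp, keys)]
}

#' Apriori frequent-itemset mining
#'
#' @param corpus a non-empty [prescription_corpus()].
#' @param min_support minimum support threshold in (0, 1]; itemsets with
#'   support `>= min_support` are retained.
#' @param max_k deepest level to mine (itemset size bound).
#' @return an object of class `"frequent_itemsets"`: fields `min_support`,
#'   `max_k`, `n_cases` and `levels`, where `levels[[k]]` lists the frequent
#'   k-itemsets (each with sorted `herbs`, exact `support` and case `count`)
#'   ordered by support descending then lexicographic herb tuple. Levels
#'   past the first empty one are absent.
#' @examples
#' co <- prescription_corpus(list(
#'   prescription("c1", c("A", "B")), prescription("c2", "A"),
#'   prescription("c3", c("B", "C")), prescription("c4", c("A", "B", "C"))))
#' apriori(co, min_support = 0.5, max_k = 3)
#' @export
apriori <- function(corpus, min_support, max_k = 5L) {
  stopifnot(inherits(corpus, "prescription_corpus"))
  check_mining_args(corpus, min_support, max_k)
  m <- corpus_incidence(corpus)
  n <- corpus$n_cases
  count_of <- function(herbs) {
    if (length(herbs) == 1L) sum(m[, herbs]) else
      sum(rowSums(m[, herbs, drop = FALSE]) == length(herbs))
  }
  # L1
  counts1 <- colSums(m)
  keep <- which(counts1 / n >= min_support)
  level <- lapply(keep, function(j) {
    list(herbs = colnames(m)[j], support = counts1[[j]] / n,
         count = as.integer(counts1[[j]]))
  })
  levels <- list()
  k <- 1L
  while (length(level) > 0L && k <= max_k) {
    levels[[k]] <- sort_level(level)
    if (k == max_k) break
    prev_tuples <- lapply(level, `[[`, "herbs")
    prev_keys <- vapply(prev_tuples, itemset_key, character(1))
    # canonical order for the prefix join
    o <- order(prev_keys, method = "radix")
    prev_tuples <- prev_tuples[o]
    prev_keys <- prev_keys[o]
    cands <- generate_candidates(prev_tuples, prev_keys)
    level <- list()
    for (cand in cands) {
      cnt <- count_of(cand)
      if (cnt / n >= min_support)
        level[[length(level) + 1L]] <-
          list(herbs = cand, support = cnt / n, count = as.integer(cnt))
    }
    k <- k + 1L
  }
  new_frequent_itemsets(levels, min_support, max_k, n)
}

# sorted-prefix join + downward-closure prune; prev_tuples sorted by key
generate_candidates <- function(prev_tuples, prev_keys) {
  np <- length(prev_tuples)
  if (np < 2L) return(list())
  k1 <- length(prev_tuples[[1]])
  prefixes <- vapply(prev_tuples, function(t)
    itemset_key(t[seq_len(k1 - 1L)]), character(1))
  cands <- list()
  i <- 1L
  while (i <= np) {
    j <- i
    while (j < np && prefixes[j + 1L] == prefixes[i]) j <- j + 1L
    if (j > i) {
      block <- i:j
      for (a in seq_along(block)) {
        for (b in seq_along(block)) {
          if (b <= a) next
          cand <- sort_herbs(c(prev_tuples[[block[a]]],
                               prev_tuples[[block[b]]]))
          # prune: every k-subset must be frequent
          ok <- TRUE
          for (drop in seq_along(cand)) {
            if (!(itemset_key(cand[-drop]) %in% prev_keys)) { ok <- FALSE; break }
          }
          if (ok) cands[[length(cands) + 1L]] <- cand
        }
      }
    }
    i <- j + 1L
  }
  cands
}

check_mining_args <- function(corpus, min_support, max_k) {
  if (corpus$n_cases == 0L)
    abort2("cannot mine an empty corpus", "herbminer_empty_input")
  if (!is.numeric(min_support) || length(min_support) != 1L ||
      min_support <= 0 || min_support > 1)
    abort2("min_support must lie in (0, 1]", "herbminer_arg_error")
  if (!is.numeric(max_k) || length(max_k) != 1L || max_k < 1)
    abort2("max_k must be a positive integer", "herbminer_arg_error")
}

#' Brute-force frequent-itemset oracle
#'
#' Enumerates every non-empty subset of the vocabulary up to size `max_k`
#' and keeps those with exact support at or above the threshold. Output is
#' structured identically to [apriori()] and serves as its independent
#' correctness oracle on small vocabularies.
#'
#' @inheritParams apriori
#' @return a `"frequent_itemsets"` object.
#' @export
brute_force_frequent <- function(corpus, min_support, max_k = 5L) {
  stopifnot(inherits(corpus, "prescription_corpus"))
  check_mining_args(corpus, min_support, max_k)
  vocab <- corpus$vocabulary
  if (length(vocab) > 20L)
    abort2("brute-force oracle is guarded to vocabularies of <= 20 herbs",
           "herbminer_arg_error")
  m <- corpus_incidence(corpus)
  n <- corpus$n_cases
  levels <- list()
  for (k in seq_len(min(max_k, length(vocab)))) {
    combos <- utils::combn(vocab, k, simplify = FALSE)
    level <- list()
    for (cand in combos) {
      cnt <- if (k == 1L) sum(m[, cand]) else
        sum(rowSums(m[, cand, drop = FALSE]) == k)
      if (cnt / n >= min_support)
        level[[length(level) + 1L]] <-
          list(herbs = cand, support = cnt / n, count = as.integer(cnt))
    }
    if (length(level) == 0L) break
    levels[[k]] <- sort_level(level)
  }
  new_frequent_itemsets(levels, min_support, max_k, n)
}

#' Confidence of an association rule antecedent -> consequent
#'
#' @param corpus a non-empty [prescription_corpus()].
#' @param antecedent non-empty itemset (character vector).
#' @param consequent itemset disjoint from `antecedent`.
#' @return `support(antecedent U consequent) / support(antecedent)`, exact.
#' @export
rule_confidence <- function(corpus, antecedent, consequent) {
  antecedent <- sort_herbs(antecedent)
  consequent <- sort_herbs(consequent)
  if (length(antecedent) == 0L)
    abort2("antecedent must be non-empty", "herbminer_arg_error")
  if (length(intersect(antecedent, consequent)) > 0L)
    abort2("antecedent and consequent must be disjoint",
           "herbminer_arg_error")
  s_a <- support(corpus, antecedent)
  if (s_a == 0)
    abort2("confidence undefined: antecedent has zero support",
           "herbminer_zero_support")
  support(corpus, c(antecedent, consequent)) / s_a
}

#' Flatten mined levels to a data.frame
#'
#' @param x a `"frequent_itemsets"` object.
#' @param row.names,optional,... ignored (data.frame method signature).
#' @return data.frame with columns `k`, `herbs` (comma-joined sorted tuple),
#'   `support` (exact), `count`.
#' @export
as.data.frame.frequent_itemsets <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  rows <- list()
  for (k in seq_along(x$levels)) {
    for (it in x$levels[[k]]) {
      rows[[length(rows) + 1L]] <-
        data.frame(k = k, herbs = paste(it$herbs, collapse = ", "),
                   support = it$support, count = it$count,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(k = integer(), herbs = character(),
                      support = numeric(), count = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.frequent_itemsets <- function(x, ...) {
  cat(sprintf(
    "<frequent_itemsets> min_support=%g, n_cases=%d, %d level(s)\n",
    x$min_support, x$n_cases, length(x$levels)))
  for (k in seq_along(x$levels))
    cat(sprintf("  L%d: %d itemset(s)\n", k, length(x$levels[[k]])))
  invisible(x)
}

#' Index of the deepest non-empty mined level
#'
#' @param levels a `"frequent_itemsets"` object.
#' @return integer level index, or 0 when every level is empty.
#' @export
deepest_level <- function(levels) {
  stopifnot(inherits(levels, "frequent_itemsets"))
  non_empty <- which(vapply(levels$levels, length, integer(1)) > 0L)
  if (length(non_empty) == 0L) 0L else max(non_empty)
}
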