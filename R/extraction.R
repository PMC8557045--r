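#' @title Basic and core prescription extraction ("Top N groups")
#' @name prescription_extraction
#' @description
#' The "Top N groups" procedure summarises an empirical prescription from
#' mined herb combinations: the highest-support itemset at the deepest
#' non-empty level is the *motherboard*; walking the remaining top-ranked
#' itemsets of that level in order, every herb not yet seen is appended as a
#' *daughterboard*; the union is the *basic prescription*. Intersecting the
#' basic prescription with the top high-frequency herbs gives the *core*
#' prescription.
NULL

#' Select the motherboard itemset
#'
#' @param levels a `"frequent_itemsets"` object with at least one non-empty
#'   level (optionally restricted via `level`).
#' @param level optional level override; default is the deepest non-empty
#'   level.
#' @return the highest-support itemset at that level (ties broken by the
#'   lexicographically smallest herb tuple), as a list with `herbs`,
#'   `support`, `count`.
#' @export
select_motherboard <- function(levels, level = NULL) {
  stopifnot(inherits(levels, "frequent_itemsets"))
  k <- if (is.null(level)) deepest_level(levels) else as.integer(level)
  if (k < 1L || k > length(levels$levels) ||
      length(levels$levels[[k]]) == 0L)
    abort2("no non-empty frequent level to select a motherboard from",
           "herbminer_no_motherboard")
  levels$levels[[k]][[1L]]  # levels are pre-sorted: support desc, then tuple
}

#' Extract the basic prescription by the "Top N groups" rule
#'
#' @inheritParams select_motherboard
#' @param n how many top-ranked itemsets of the deepest level to consume
#'   (the motherboard is the first); `Inf` (default) consumes them all.
#' @return an object of class `"basic_prescription"`: `motherboard` (the
#'   itemset), `daughterboards` (herbs appended, in itemset-rank then
#'   within-itemset lexicographic order), `basic_prescription` (motherboard
#'   herbs followed by daughterboards) and `n_used`.
#' @export
top_n_groups <- function(levels, n = Inf, level = NULL) {
  stopifnot(inherits(levels, "frequent_itemsets"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    abort2("n must be a positive integer or Inf", "herbminer_arg_error")
  mb <- select_motherboard(levels, level)
  k <- if (is.null(level)) deepest_level(levels) else as.integer(level)
  items <- levels$levels[[k]]
  n_used <- min(n, length(items))
  union_herbs <- mb$herbs
  daughters <- character()
  for (i in seq_len(n_used)[-1L]) {
    new <- setdiff(items[[i]]$herbs, union_herbs)  # herbs already sorted
    daughters <- c(daughters, new)
    union_herbs <- c(union_herbs, new)
  }
  structure(list(motherboard = mb, daughterboards = daughters,
                 basic_prescription = union_herbs,
                 n_used = as.integer(n_used)),
            class = "basic_prescription")
}

#' @export
print.basic_prescription <- function(x, ...) {
  cat(sprintf("<basic_prescription> motherboard {%s} @ %.2f\n",
              paste(x$motherboard$herbs, collapse = ", "),
              x$motherboard$support))
  cat(sprintf("  + daughterboards: %s\n",
              if (length(x$daughterboards)) paste(x$daughterboards,
                                                  collapse = ", ")
              else "(none)"))
  cat(sprintf("  = basic prescription (%d herbs): %s\n",
              length(x$basic_prescription),
              paste(x$basic_prescription, collapse = ", ")))
  invisible(x)
}

#' Core prescription: basic prescription restricted to high-frequency herbs
#'
#' @param basic a `"basic_prescription"` object.
#' @param freq a `"herb_frequency"` table.
#' @param top_m how many top-frequency herbs to intersect with
#'   (`1 <= top_m <= nrow(freq)`).
#' @return character vector: the basic-prescription herbs that are among the
#'   first `top_m` rows of `freq`, in frequency order. May be empty.
#' @export
core_prescription <- function(basic, freq, top_m) {
  stopifnot(inherits(basic, "basic_prescription"),
            inherits(freq, "herb_frequency"), nrow(freq) > 0L)
  if (!is.numeric(top_m) || length(top_m) != 1L || top_m < 1)
    abort2("top_m must be a positive integer", "herbminer_arg_error")
  if (top_m > nrow(freq))
    abort2("top_m exceeds the number of frequency-table rows",
           "herbminer_arg_error")
  top <- freq$herb[seq_len(top_m)]
  top[top %in% basic$basic_prescription]
}

#' Rank herbal pairs by score
#'
#' Builds the canonical pair ranking (score descending, ties by
#' lexicographic pair) from (pair, score) rows, e.g. supports printed in a
#' published pair table.
#'
#' @param herb1,herb2 character vectors naming the two herbs of each pair
#'   (order within a pair is irrelevant).
#' @param score numeric scores (joint supports), all `>= min_score`.
#' @param min_score threshold the ranking is declared at (default 0).
#' @return data.frame of class `"herbal_pairs"` with columns `herb1`,
#'   `herb2` (sorted within pair), `score`; attribute `min_score`.
#' @export
pair_ranking <- function(herb1, herb2, score, min_score = 0) {
  stopifnot(length(herb1) == length(herb2), length(score) == length(herb1))
  pairs <- mapply(function(a, b) sort_herbs(c(a, b)), herb1, herb2,
                  SIMPLIFY = FALSE, USE.NAMES = FALSE)
  if (any(vapply(pairs, length, integer(1)) != 2L))
    abort2("each pair needs two distinct herbs", "herbminer_arg_error")
  keys <- vapply(pairs, itemset_key, character(1))
  if (anyDuplicated(keys))
    abort2("duplicate pair in ranking", "herbminer_arg_error")
  if (any(score < min_score))
    abort2("every score must be >= min_score", "herbminer_arg_error")
  o <- order_by_support(score, keys)
  out <- data.frame(herb1 = vapply(pairs, `[`, character(1), 1L)[o],
                    herb2 = vapply(pairs, `[`, character(1), 2L)[o],
                    score = score[o], stringsAsFactors = FALSE)
  structure(out, class = c("herbal_pairs", "data.frame"),
            min_score = min_score)
}

#' Mine high-support herbal pairs from a corpus
#'
#' All 2-herb combinations with exact joint support at or above the
#' threshold, ranked by support descending. Typically run on a
#' syndrome-filtered sub-corpus (see [filter_by_syndromes()]).
#'
#' @param corpus a non-empty [prescription_corpus()].
#' @param min_support support threshold in (0, 1].
#' @return a `"herbal_pairs"` ranking (see [pair_ranking()]), scores being
#'   exact joint supports.
#' @export
mine_herbal_pairs <- function(corpus, min_support) {
  stopifnot(inherits(corpus, "prescription_corpus"))
  check_mining_args(corpus, min_support, 2L)
  lv <- apriori(corpus, min_support, max_k = 2L)
  items <- if (length(lv$levels) >= 2L) lv$levels[[2L]] else list()
  pair_ranking(vapply(items, function(x) x$herbs[1L], character(1)),
               vapply(items, function(x) x$herbs[2L], character(1)),
               vapply(items, `[[`, numeric(1), "support"),
               min_score = min_support)
}
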