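#' Herb use-frequency table
#'
#' Counts, for every herb in the vocabulary, the number of cases whose herb
#' set contains it, with the percentage of cases (two decimals, half away
#' from zero). Rows are sorted by count descending, ties broken
#' lexicographically by herb name.
#'
#' @param corpus a non-empty [prescription_corpus()].
#' @return a data.frame of class `"herb_frequency"` with columns `herb`,
#'   `count`, `percentage`, and attribute `n_cases`.
#' @examples
#' co <- prescription_corpus(list(
#'   prescription("c1", c("A", "B")), prescription("c2", "A"),
#'   prescription("c3", c("B", "C")), prescription("c4", c("A", "B", "C"))))
#' herb_frequency(co)
#' @export
herb_frequency <- function(corpus) {
  stopifnot(inherits(corpus, "prescription_corpus"))
  if (corpus$n_cases == 0L)
    abort2("cannot profile an empty corpus", "herbminer_empty_input")
  counts <- table(unlist(corpus_herb_sets(corpus), use.names = FALSE))
  herb <- names(counts)
  count <- as.integer(counts)
  o <- order(-count, herb, method = "radix")
  out <- data.frame(herb = herb[o], count = count[o],
                    percentage = round2(100 * count[o] / corpus$n_cases),
                    stringsAsFactors = FALSE)
  structure(out, class = c("herb_frequency", "data.frame"),
            n_cases = corpus$n_cases)
}

#' Construct a frequency table from printed counts
#'
#' Builds the same object as [herb_frequency()] from already-tabulated
#' (herb, count) pairs and a corpus size, re-deriving percentages and sort
#' order. Used when the corpus itself is unavailable but its published
#' frequency table is.
#'
#' @param herb character vector of herb names.
#' @param count integer vector of case counts (`0 < count <= n_cases`).
#' @param n_cases corpus size.
#' @return a `"herb_frequency"` data.frame.
#' @export
frequency_table <- function(herb, count, n_cases) {
  herb <- as.character(herb); count <- as.integer(count)
  stopifnot(length(herb) == length(count), n_cases >= 1)
  if (anyDuplicated(herb))
    abort2("duplicate herb in frequency table", "herbminer_arg_error")
  if (any(count < 1L) || any(count > n_cases))
    abort2("counts must lie in 1..n_cases", "herbminer_arg_error")
  o <- order(-count, herb, method = "radix")
  structure(data.frame(herb = herb[o], count = count[o],
                       percentage = round2(100 * count[o] / n_cases),
                       stringsAsFactors = FALSE),
            class = c("herb_frequency", "data.frame"), n_cases = n_cases)
}

#' Herbs used strictly more often than a threshold
#'
#' @param table a `"herb_frequency"` data.frame.
#' @param threshold non-negative cutoff; herbs with `count > threshold` (or
#'   `percentage > threshold`) are returned.
#' @param mode `"count"` or `"percentage"`.
#' @return character vector of herbs, in table (descending-frequency) order.
#' @export
herbs_above <- function(table, threshold, mode = c("count", "percentage")) {
  stopifnot(inherits(table, "herb_frequency"), nrow(table) > 0L)
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    abort2("threshold must be a single non-negative number",
           "herbminer_arg_error")
  table$herb[table[[mode]] > threshold]
}

#' Percentages over a shared occurrence denominator
#'
#' The profile convention: every category percentage, whichever section it
#' belongs to, is taken over the total number of herb occurrences (the sum
#' of the property-section counts, since each herb has exactly one
#' property), rounded at two decimals half away from zero.
#'
#' @param counts named numeric vector of category counts.
#' @param total_occurrences the shared denominator.
#' @return named numeric vector of percentages.
#' @export
profile_percentages <- function(counts, total_occurrences) {
  stopifnot(total_occurrences > 0)
  round2(100 * counts / total_occurrences)
}

#' Property/taste/meridian profile of a corpus
#'
#' Each herb occurrence (a herb appearing in a case) contributes one count
#' to its property category and one to every taste and meridian category it
#' carries. Percentages for all three sections share the denominator
#' `total_occurrences` = total number of herb occurrences; property
#' percentages therefore sum to 100 (within rounding) while taste and
#' meridian percentages may exceed it (multi-valued attributes).
#'
#' @param corpus a non-empty [prescription_corpus()].
#' @param attrs an [herb_attribute_table()] covering the corpus vocabulary.
#' @return data.frame of class `"attribute_profile"` with columns `section`
#'   (`property` / `taste` / `meridian`), `category`, `count`, `percentage`,
#'   rows sorted within section by count descending then category; attribute
#'   `total_occurrences`.
#' @export
attribute_profile <- function(corpus, attrs) {
  stopifnot(inherits(corpus, "prescription_corpus"),
            inherits(attrs, "herb_attribute_table"))
  if (corpus$n_cases == 0L)
    abort2("cannot profile an empty corpus", "herbminer_empty_input")
  missing <- setdiff(corpus$vocabulary, attrs$herb)
  if (length(missing) > 0L)
    abort2(sprintf("herbs missing from attribute table: %s",
                   paste(missing, collapse = ", ")),
           "herbminer_unknown_attribute")
  occ <- table(unlist(corpus_herb_sets(corpus), use.names = FALSE))
  idx <- match(names(occ), attrs$herb)
  n_occ <- as.numeric(occ)
  total <- sum(n_occ)

  tally <- function(universe, values_per_herb) {
    counts <- stats::setNames(numeric(length(universe)), universe)
    for (i in seq_along(n_occ)) {
      v <- values_per_herb[[i]]
      counts[v] <- counts[v] + n_occ[i]
    }
    counts
  }
  prop_counts <- tally(herb_properties(),
                       as.list(attrs$property[idx]))
  taste_counts <- tally(herb_tastes(), attrs$tastes[idx])
  mer_counts <- tally(herb_meridians(), attrs$meridians[idx])

  section_df <- function(section, counts) {
    counts <- counts[counts > 0]
    if (length(counts) == 0L)
      return(data.frame(section = character(), category = character(),
                        count = numeric(), percentage = numeric()))
    o <- order(-counts, names(counts), method = "radix")
    data.frame(section = section, category = names(counts)[o],
               count = unname(counts[o]),
               percentage = unname(profile_percentages(counts[o], total)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(section_df("property", prop_counts),
               section_df("taste", taste_counts),
               section_df("meridian", mer_counts))
  rownames(out) <- NULL
  structure(out, class = c("attribute_profile", "data.frame"),
            total_occurrences = total)
}
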