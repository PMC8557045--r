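#' Round half away from zero at two decimals
#'
#' Display rounding used throughout: percentages and supports are shown at
#' two decimal places with halves rounded away from zero (so 0.005 -> 0.01),
#' unlike [base::round()]'s round-half-to-even. A tiny epsilon absorbs
#' binary-representation error in values such as `0.005` whose product with
#' 100 is not exactly representable.
#'
#' @param x numeric vector, finite.
#' @return `x` rounded at the second decimal place.
#' @examples
#' round2(0.759441)  # 0.76
#' round2(0.005)     # 0.01
#' @export
round2 <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  sign(x) * floor(abs(x) * 100 + 0.5 + 1e-9) / 100
}

# Locale-independent lexicographic sort key for an already-sorted herb tuple.
# \x1f (unit separator) sorts below all printable characters so that a tuple
# that is a prefix of another sorts first.
itemset_key <- function(herbs) paste(herbs, collapse = "\x1f")

# Sort herbs in the C locale so itemset tuples are bit-stable across systems.
sort_herbs <- function(herbs) {
  herbs <- unique(as.character(herbs))
  herbs[order(herbs, method = "radix")]
}

# order() by support descending then lexicographic tuple key, C locale.
order_by_support <- function(support, keys) {
  order(-support, keys, method = "radix")
}

trimws2 <- function(x) trimws(x, which = "both")

abort2 <- function(msg, class) {
  stop(structure(class = c(class, "herbminer_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
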