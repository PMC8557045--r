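#' @title Synthetic prescription-corpus generator
#' @name synthetic_data
#' @description
#' Generates prescription corpora with the statistical structure the mining
#' pipeline assumes: per-herb background marginals (calibratable to a
#' published frequency table), planted template prescriptions — correlated
#' herb blocks drawn as a single-template-per-case mixture so every planted
#' itemset has a closed-form expected support — and per-case syndrome tags.
#' Each case draws at most one template by weight (the residual mass draws
#' none), includes each template herb independently with the template's
#' inclusion probability, and adds each background herb independently with
#' its marginal probability; empty draws are redrawn.
NULL

#' Specify a template prescription
#'
#' @param herbs character vector of template herb names (non-empty).
#' @param weight probability in (0, 1] that a case draws this template.
#' @param inclusion_prob probability in (0, 1] that each template herb
#'   enters the case, given the template is drawn.
#' @return an object of class `"template_spec"`.
#' @export
template_spec <- function(herbs, weight, inclusion_prob = 1) {
  herbs <- sort_herbs(herbs)
  if (length(herbs) == 0L)
    abort2("template needs at least one herb", "herbminer_arg_error")
  if (!is.numeric(weight) || weight <= 0 || weight > 1)
    abort2("template weight must lie in (0, 1]", "herbminer_arg_error")
  if (!is.numeric(inclusion_prob) || inclusion_prob <= 0 ||
      inclusion_prob > 1)
    abort2("inclusion_prob must lie in (0, 1]", "herbminer_arg_error")
  structure(list(herbs = herbs, weight = weight,
                 inclusion_prob = inclusion_prob),
            class = "template_spec")
}

#' Assemble a simulation configuration
#'
#' @param n_cases corpus size (default 715, the published corpus size).
#' @param templates list of [template_spec()]s; weights must sum to at most
#'   1, the residual mass being template-free cases.
#' @param background_probs named numeric vector: per-herb marginal inclusion
#'   probability in `[0, 1]`; may overlap the template namespaces.
#' @param syndrome_rules named list keyed by template index as a string
#'   (`"0"` = template-free cases); each entry a list with `tags` (character
#'   vector) and `prob` (tagging probability).
#' @param seed integer RNG seed; the generated corpus is a pure function of
#'   (config, seed).
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(n_cases = 715L, templates = list(),
                       background_probs = numeric(),
                       syndrome_rules = list(), seed = 1L) {
  n_cases <- as.integer(n_cases)
  if (is.na(n_cases) || n_cases < 1L)
    abort2("n_cases must be >= 1", "herbminer_arg_error")
  ok <- vapply(templates, inherits, logical(1), "template_spec")
  if (!all(ok))
    abort2("templates must be template_spec objects", "herbminer_arg_error")
  w <- vapply(templates, `[[`, numeric(1), "weight")
  if (length(w) > 0L && sum(w) > 1 + 1e-12)
    abort2("template weights must sum to at most 1", "herbminer_arg_error")
  if (length(background_probs) > 0L) {
    if (is.null(names(background_probs)) ||
        any(!nzchar(names(background_probs))))
      abort2("background_probs must be a named vector",
             "herbminer_arg_error")
    if (any(background_probs < 0 | background_probs > 1))
      abort2("background probabilities must lie in [0, 1]",
             "herbminer_arg_error")
    background_probs <- background_probs[order(names(background_probs),
                                               method = "radix")]
  }
  can_draw <- any(background_probs > 0) ||
    (length(templates) > 0L)  # template weights/inclusions are > 0 by type
  if (!can_draw)
    abort2("degenerate config: no herb can ever be drawn",
           "herbminer_degenerate_config")
  structure(list(n_cases = n_cases, templates = templates,
                 background_probs = background_probs,
                 syndrome_rules = syndrome_rules, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic prescription corpus
#'
#' Fully reproducible: the same config (including its `seed`) yields a
#' bit-identical corpus. Empty herb draws are redrawn, which scales every
#' support by `1/(1 - P(empty draw))`; [planted_truth()] applies that
#' conditioning exactly, and the factor is ~1 for realistic configs
#' (expected case sizes of 3+).
#'
#' @param config a [sim_config()].
#' @return a [prescription_corpus()] with cases `case_0001`, ...;
#'   syndrome tags attached per `config$syndrome_rules`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(config$seed)
  K <- length(config$templates)
  w <- vapply(config$templates, `[[`, numeric(1), "weight")
  cum_w <- if (K > 0L) cumsum(w) else numeric()
  bg_names <- names(config$background_probs)
  bg_p <- unname(config$background_probs)
  n <- config$n_cases
  width <- max(4L, nchar(as.character(n)))
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      t_idx <- 0L
      if (K > 0L) {
        u <- stats::runif(1)
        hit <- which(u <= cum_w)
        if (length(hit) > 0L) t_idx <- hit[1L]
      }
      herbs <- character()
      if (t_idx > 0L) {
        tp <- config$templates[[t_idx]]
        inc <- stats::runif(length(tp$herbs)) < tp$inclusion_prob
        herbs <- tp$herbs[inc]
      }
      if (length(bg_p) > 0L) {
        inc <- stats::runif(length(bg_p)) < bg_p
        herbs <- c(herbs, bg_names[inc])
      }
      if (length(herbs) > 0L) break
    }
    syndromes <- character()
    rule <- config$syndrome_rules[[as.character(t_idx)]]
    if (!is.null(rule) && stats::runif(1) < rule$prob)
      syndromes <- rule$tags
    cases[[i]] <- prescription(sprintf("case_%0*d", width, i), herbs,
                               syndromes)
  }
  prescription_corpus(cases)
}

#' Calibrate a template-free config to a frequency table
#'
#' Sets each herb's background probability to `count / n_cases`, so the
#' expected frequency table of the generated corpus matches the target
#' (each empirical count is Binomial(n_cases, count/n_cases)).
#'
#' @param freq a `"herb_frequency"` table.
#' @param n_cases corpus size to generate; all counts must be `<= n_cases`.
#' @param seed RNG seed for the resulting config.
#' @return a template-free [sim_config()].
#' @export
calibrate_marginals <- function(freq, n_cases, seed = 1L) {
  stopifnot(inherits(freq, "herb_frequency"), nrow(freq) > 0L)
  n_cases <- as.integer(n_cases)
  if (any(freq$count > n_cases))
    abort2("a frequency count exceeds n_cases", "herbminer_arg_error")
  sim_config(n_cases = n_cases, templates = list(),
             background_probs = stats::setNames(freq$count / n_cases,
                                                freq$herb),
             seed = seed)
}

# P(h present in one case | template t_idx drawn); t_idx 0 = no template
herb_prob_given_template <- function(h, config, t_idx) {
  bg <- config$background_probs
  p_bg <- if (h %in% names(bg)) unname(bg[[h]]) else 0
  if (t_idx > 0L) {
    tp <- config$templates[[t_idx]]
    if (h %in% tp$herbs)
      return(1 - (1 - tp$inclusion_prob) * (1 - p_bg))
  }
  p_bg
}

# unconditional P(S subset of one raw draw) under the template mixture
raw_draw_prob <- function(config, herbs) {
  K <- length(config$templates)
  w <- vapply(config$templates, `[[`, numeric(1), "weight")
  residual <- 1 - sum(w)
  total <- residual *
    prod(vapply(herbs, herb_prob_given_template, numeric(1), config, 0L))
  for (t in seq_len(K)) {
    total <- total + w[t] *
      prod(vapply(herbs, herb_prob_given_template, numeric(1), config, t))
  }
  total
}

# P(a raw draw is empty): complement-product within each mixture component
empty_draw_prob <- function(config) {
  all_herbs <- sort_herbs(c(unlist(lapply(config$templates, `[[`, "herbs")),
                            names(config$background_probs)))
  K <- length(config$templates)
  w <- vapply(config$templates, `[[`, numeric(1), "weight")
  residual <- 1 - sum(w)
  total <- residual * prod(1 - vapply(all_herbs, herb_prob_given_template,
                                      numeric(1), config, 0L))
  for (t in seq_len(K)) {
    total <- total + w[t] *
      prod(1 - vapply(all_herbs, herb_prob_given_template, numeric(1),
                      config, t))
  }
  total
}

# exact expected support of a non-empty itemset in the generated corpus:
# the non-empty-redraw rule conditions every case on being non-empty, so
# P(S | non-empty) = P(S) / (1 - P(empty)). The correction factor is ~1
# whenever expected case sizes are realistic.
expected_support <- function(config, herbs) {
  herbs <- sort_herbs(herbs)
  raw_draw_prob(config, herbs) / (1 - empty_draw_prob(config))
}

#' Closed-form expected supports of the planted template subsets
#'
#' For every template and every non-empty subset of its herbs, the exact
#' expected per-case probability that all subset herbs are present, under
#' the single-template mixture with background overlap (marginalising over
#' which template, if any, a case draws) and conditioned on the case being
#' non-empty (the generator redraws empty cases, so the realized support of
#' `S` is `P(S)/(1 - P(empty draw))`; the correction is negligible for
#' realistic configs and reduces the full-template value to
#' `weight * inclusion_prob^k` when templates and background are disjoint).
#'
#' @param config a [sim_config()].
#' @param max_size cap on enumerated subset size (default: full template
#'   size, guarded at 12 herbs).
#' @return data.frame with columns `template` (index), `herbs`
#'   (comma-joined sorted subset), `size`, `expected_support`.
#' @export
planted_truth <- function(config, max_size = NULL) {
  stopifnot(inherits(config, "sim_config"))
  rows <- list()
  for (t in seq_along(config$templates)) {
    th <- config$templates[[t]]$herbs
    if (length(th) > 12L)
      abort2("planted_truth is guarded to templates of <= 12 herbs",
             "herbminer_arg_error")
    top <- if (is.null(max_size)) length(th) else min(max_size, length(th))
    for (k in seq_len(top)) {
      for (sub in utils::combn(th, k, simplify = FALSE)) {
        rows[[length(rows) + 1L]] <- data.frame(
          template = t, herbs = paste(sub, collapse = ", "), size = k,
          expected_support = expected_support(config, sub),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(template = integer(), herbs = character(),
                      size = integer(), expected_support = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Deterministically realize a frequency table as a corpus
#'
#' Builds an `n_cases`-case corpus whose herb counts equal the target
#' frequency table exactly: herb `i` (in table order) occupies the `count_i`
#' cases at staggered positions `(offset_i + 0..count_i-1) mod n_cases`,
#' with offsets spread by a stride coprime to typical corpus sizes so that
#' every case receives at least one herb. No randomness is involved; the
#' corpus carries the target marginals bit-exactly (the joint structure is
#' an arbitrary artifact and carries no meaning).
#'
#' @param freq a `"herb_frequency"` table.
#' @param n_cases corpus size; defaults to the table's `n_cases` attribute.
#' @return a [prescription_corpus()] with `herb_frequency()` equal to the
#'   re-sorted target table.
#' @export
corpus_from_frequency <- function(freq, n_cases = attr(freq, "n_cases")) {
  stopifnot(inherits(freq, "herb_frequency"), nrow(freq) > 0L)
  n <- as.integer(n_cases)
  if (is.na(n) || n < 1L || any(freq$count > n))
    abort2("n_cases must be >= every frequency count",
           "herbminer_arg_error")
  herbs_per_case <- vector("list", n)
  stride <- 271L  # prime, coprime to 715 = 5 * 11 * 13
  for (i in seq_len(nrow(freq))) {
    pos <- (((i - 1L) * stride + seq_len(freq$count[i]) - 1L) %% n) + 1L
    for (j in pos)
      herbs_per_case[[j]] <- c(herbs_per_case[[j]], freq$herb[i])
  }
  empty <- which(lengths(herbs_per_case) == 0L)
  if (length(empty) > 0L)
    abort2("frequency table too sparse to cover every case",
           "herbminer_arg_error")
  width <- max(4L, nchar(as.character(n)))
  prescription_corpus(lapply(seq_len(n), function(j)
    prescription(sprintf("case_%0*d", width, j), herbs_per_case[[j]])))
}

#' Default simulation config emulating the published CHD corpus
#'
#' The stated world of the generator: 715 cases over 182 herbs. The top-48
#' herb names and target marginals come from the published frequency table
#' ([chd_herb_frequency()]); the remaining 134 herbs — reported only as
#' "used less than 50 times" — are synthetic placeholders `Herb-049` ..
#' `Herb-182` with linearly decaying counts from 49 down to 2. One planted
#' template holds the seven published basic-prescription herbs (weight
#' 0.45, inclusion probability 0.85) so that high-support multi-herb
#' combinations of those herbs emerge; the background probability of each
#' template herb is reduced to `(p - w*q)/(1 - w*q)` so its overall
#' marginal still matches the published table. Template cases are tagged
#' "qi deficiency" + "blood stasis" with probability 0.9 and residual cases
#' with probability 0.2, putting the expected tagged subset at ~372 of 715
#' cases, the published subset size.
#'
#' @param seed integer RNG seed.
#' @param n_cases corpus size (default 715).
#' @return a [sim_config()].
#' @export
default_sim_config <- function(seed = 1L, n_cases = 715L) {
  freq <- chd_herb_frequency()
  targets <- stats::setNames(freq$count / 715, freq$herb)
  extra <- round(seq(49, 2, length.out = 134))
  names(extra) <- sprintf("Herb-%03d", 49:182)
  targets <- c(targets, extra / 715)

  basic7 <- c("Dang-gui", "Gan-cao", "Huang-qi", "Mai-dong", "San-qi",
              "Wu-wei-zi", "Yan-hu-suo")
  w <- 0.45; inc <- 0.85
  q <- w * inc  # per-case probability a template herb enters via template
  bg <- targets
  bg[basic7] <- pmax(0, (targets[basic7] - q) / (1 - q))
  tags <- c("blood stasis", "qi deficiency")
  sim_config(
    n_cases = n_cases,
    templates = list(template_spec(basic7, weight = w,
                                   inclusion_prob = inc)),
    background_probs = bg,
    syndrome_rules = list(`1` = list(tags = tags, prob = 0.9),
                          `0` = list(tags = tags, prob = 0.2)),
    seed = seed)
}
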