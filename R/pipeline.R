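#' @title End-to-end mining pipeline and report bundle
#' @name cli_report
#' @description
#' Ties the stages together in the analysis order: load and deduplicate the
#' corpus, profile herb frequencies (and attributes when a dictionary is
#' given), mine frequent itemset levels, extract the basic and core
#' prescriptions, and — when syndrome tags are given — mine herbal pairs on
#' the filtered sub-corpus. All outputs are deterministic: identical inputs
#' and config produce byte-identical bundles (TSV tables are pure views of
#' the JSON dumps).
NULL

#' Assemble a pipeline configuration
#'
#' @param input path to a prescriptions CSV/JSON file.
#' @param out_dir output directory for the report bundle.
#' @param attrs optional path to an herb attribute CSV.
#' @param synonyms optional path to a synonym-map CSV.
#' @param min_support_main minimum support for level mining (default 0.3).
#' @param min_support_pairs minimum support for pair mining (default 0.6).
#' @param max_k deepest level to mine (default 5).
#' @param top_m_highfreq high-frequency herb count for the core-prescription
#'   intersection (default 6).
#' @param top_n_groups_n "Top N groups" N; `Inf` consumes the whole deepest
#'   level (default).
#' @param syndromes character vector of syndrome tags for pair mining;
#'   `NULL` skips the pair stage.
#' @param level optional level override for [top_n_groups()].
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input, out_dir, attrs = NULL, synonyms = NULL,
                            min_support_main = 0.3,
                            min_support_pairs = 0.6, max_k = 5L,
                            top_m_highfreq = 6L, top_n_groups_n = Inf,
                            syndromes = NULL, level = NULL) {
  for (s in c(min_support_main, min_support_pairs))
    if (!is.numeric(s) || s <= 0 || s > 1)
      abort2("support thresholds must lie in (0, 1]", "herbminer_arg_error")
  if (max_k < 1) abort2("max_k must be >= 1", "herbminer_arg_error")
  structure(list(input = input, out_dir = out_dir, attrs = attrs,
                 synonyms = synonyms, min_support_main = min_support_main,
                 min_support_pairs = min_support_pairs,
                 max_k = as.integer(max_k),
                 top_m_highfreq = as.integer(top_m_highfreq),
                 top_n_groups_n = top_n_groups_n, syndromes = syndromes,
                 level = level),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

levels_to_json <- function(lv) {
  list(min_support = lv$min_support, max_k = lv$max_k,
       n_cases = lv$n_cases,
       levels = lapply(lv$levels, function(level)
         lapply(level, function(it)
           list(herbs = as.list(it$herbs), support = it$support,
                count = it$count))))
}

pairs_tsv_view <- function(pairs) {
  data.frame(herbs = paste(pairs$herb1, pairs$herb2, sep = ", "),
             support = sprintf("%.2f", round2(pairs$score)),
             stringsAsFactors = FALSE)
}

#' Run the full mining pipeline
#'
#' @param config a [pipeline_config()].
#' @param log a function receiving progress messages (default
#'   [message()], i.e. stderr); pass `function(...) {}` to silence.
#' @return the report bundle, invisibly: a list with `corpus`, `frequency`,
#'   `profile`, `levels`, `basic`, `core`, `pairs` (entries `NULL` when
#'   their stage was skipped). Side effect: TSV/JSON files under
#'   `config$out_dir` plus `run_log.json` (config echo and input digest).
#' @export
run_pipeline <- function(config, log = message) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  syn <- if (!is.null(config$synonyms))
    stage("synonyms", load_synonym_map(config$synonyms)) else NULL
  corpus <- stage("load", load_corpus(config$input, synonyms = syn))
  log(sprintf("loaded %d cases, %d herbs", corpus$n_cases,
              length(corpus$vocabulary)))
  corpus <- stage("deduplicate", deduplicate_first_prescription(corpus))
  log(sprintf("%d cases after first-prescription deduplication",
              corpus$n_cases))

  freq <- stage("frequency", herb_frequency(corpus))
  write_tsv(data.frame(herb = freq$herb, frequency = freq$count,
                       percentage = sprintf("%.2f", freq$percentage)),
            file.path(config$out_dir, "frequency.tsv"))

  profile <- NULL
  if (!is.null(config$attrs)) {
    attrs <- stage("attributes", load_herb_attributes(config$attrs))
    profile <- stage("profile", attribute_profile(corpus, attrs))
    write_tsv(data.frame(section = profile$section,
                         category = profile$category,
                         frequency = profile$count,
                         percentage = sprintf("%.2f", profile$percentage)),
              file.path(config$out_dir, "attribute_profile.tsv"))
  }

  levels <- stage("apriori",
                  apriori(corpus, config$min_support_main, config$max_k))
  for (k in seq_along(levels$levels)) {
    lvl <- levels$levels[[k]]
    write_tsv(data.frame(
      herbs = vapply(lvl, function(it) paste(it$herbs, collapse = ", "),
                     character(1)),
      support = vapply(lvl, function(it) sprintf("%.2f", round2(it$support)),
                       character(1))),
      file.path(config$out_dir, sprintf("level_%d.tsv", k)))
  }
  write_json_stable(levels_to_json(levels),
                    file.path(config$out_dir, "itemsets.json"))

  basic <- NULL; core <- NULL
  if (deepest_level(levels) > 0L) {
    basic <- stage("top_n_groups",
                   top_n_groups(levels, config$top_n_groups_n,
                                config$level))
    core <- stage("core_prescription",
                  core_prescription(basic, freq,
                                    min(config$top_m_highfreq, nrow(freq))))
  } else {
    log("warning: no frequent itemsets at this threshold; ",
        "basic/core prescriptions skipped")
  }

  pairs <- NULL
  if (!is.null(config$syndromes)) {
    sub <- stage("filter", filter_by_syndromes(corpus, config$syndromes))
    log(sprintf("%d cases match syndrome filter {%s}", sub$n_cases,
                paste(config$syndromes, collapse = ", ")))
    if (sub$n_cases == 0L) {
      log("warning: syndrome filter matched no case; empty pair report")
      pairs <- pair_ranking(character(), character(), numeric(),
                            config$min_support_pairs)
    } else {
      pairs <- stage("pairs",
                     mine_herbal_pairs(sub, config$min_support_pairs))
    }
    write_tsv(pairs_tsv_view(pairs),
              file.path(config$out_dir, "pairs.tsv"))
  }

  report <- list(
    motherboard = if (!is.null(basic))
      list(herbs = as.list(basic$motherboard$herbs),
           support = basic$motherboard$support),
    daughterboards = if (!is.null(basic)) as.list(basic$daughterboards),
    basic_prescription = if (!is.null(basic))
      as.list(basic$basic_prescription),
    core_prescription = if (!is.null(core)) as.list(core),
    herbal_pairs = if (!is.null(pairs))
      lapply(seq_len(nrow(pairs)), function(i)
        list(herbs = list(pairs$herb1[i], pairs$herb2[i]),
             support = pairs$score[i])))
  write_json_stable(report, file.path(config$out_dir, "report.json"))

  run_log <- list(
    config = list(input = config$input,
                  min_support_main = config$min_support_main,
                  min_support_pairs = config$min_support_pairs,
                  max_k = config$max_k,
                  top_m_highfreq = config$top_m_highfreq,
                  top_n_groups_n =
                    if (is.finite(config$top_n_groups_n))
                      config$top_n_groups_n else "ALL",
                  syndromes = config$syndromes),
    input_md5 = unname(tools::md5sum(config$input)),
    n_cases = corpus$n_cases,
    n_herbs = length(corpus$vocabulary),
    package_version = as.character(utils::packageVersion("herbminer")))
  write_json_stable(run_log, file.path(config$out_dir, "run_log.json"))

  invisible(list(corpus = corpus, frequency = freq, profile = profile,
                 levels = levels, basic = basic, core = core,
                 pairs = pairs))
}
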