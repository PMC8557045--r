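#' @title Prescription corpora: construction, I/O, standardization, filtering
#' @name corpus_io
#' @description
#' A prescription corpus is an ordered collection of clinical cases, each
#' carrying a case identifier, a set of canonical herb names, an optional
#' patient identifier (used by the first-prescription rule) and a possibly
#' empty set of syndrome tags. Herb names are treated as opaque canonical
#' strings (hyphenated pinyin, e.g. `"Gan-cao"`); matching is case-sensitive
#' after trimming surrounding whitespace.
NULL

# Category vocabularies for herb attributes. One property per herb; tastes
# and meridians are non-empty subsets.
#' Herb attribute category vocabularies
#'
#' The five properties, seven tastes and twelve meridians recognised by
#' [herb_attribute_table()].
#' @return character vector of category names.
#' @export
herb_properties <- function() c("Warm", "Cold", "Mild", "Cool", "Hot")

#' @rdname herb_properties
#' @export
herb_tastes <- function() {
  c("Pungent", "Bitter", "Sweet", "Mild", "Puckery", "Sour", "Salty")
}

#' @rdname herb_properties
#' @export
herb_meridians <- function() {
  c("Heart", "Liver", "Spleen", "Lung", "Stomach", "Kidney",
    "Large Intestine", "Gallbladder", "Bladder", "Pericardium",
    "Tri-jiao", "Small Intestine")
}

#' Construct a single prescription case
#'
#' @param case_id opaque case identifier (non-empty string).
#' @param herbs character vector of canonical herb names; duplicates collapse
#'   (set semantics); must be non-empty.
#' @param syndromes character vector of syndrome tags (possibly empty).
#' @param patient_id optional patient identifier; `NA` when unknown.
#' @return an object of class `"prescription"`.
#' @export
prescription <- function(case_id, herbs, syndromes = character(),
                         patient_id = NA_character_) {
  case_id <- as.character(case_id)
  if (length(case_id) != 1L || is.na(case_id) || !nzchar(case_id))
    abort2("case_id must be a non-empty string", "herbminer_parse_error")
  herbs <- sort_herbs(trimws2(as.character(herbs)))
  herbs <- herbs[nzchar(herbs)]
  if (length(herbs) == 0L)
    abort2(sprintf("case '%s' has an empty herb set", case_id),
           "herbminer_parse_error")
  syndromes <- sort_herbs(trimws2(as.character(syndromes)))
  syndromes <- syndromes[nzchar(syndromes)]
  patient_id <- as.character(patient_id)
  if (length(patient_id) != 1L) patient_id <- NA_character_
  if (!is.na(patient_id) && !nzchar(patient_id)) patient_id <- NA_character_
  structure(list(case_id = case_id, herbs = herbs, syndromes = syndromes,
                 patient_id = patient_id),
            class = "prescription")
}

#' Construct a prescription corpus
#'
#' @param cases list of [prescription()] objects (order is meaningful: the
#'   first-prescription rule resolves ties by position).
#' @return an object of class `"prescription_corpus"` with fields `cases`,
#'   `n_cases` and `vocabulary` (union of all case herb sets, sorted).
#' @export
prescription_corpus <- function(cases) {
  stopifnot(is.list(cases))
  ok <- vapply(cases, inherits, logical(1), "prescription")
  if (!all(ok)) abort2("all cases must be prescription objects",
                       "herbminer_parse_error")
  vocab <- sort_herbs(unlist(lapply(cases, `[[`, "herbs"), use.names = FALSE))
  structure(list(cases = cases, n_cases = length(cases),
                 vocabulary = if (is.null(vocab)) character() else vocab),
            class = "prescription_corpus")
}

#' @export
print.prescription_corpus <- function(x, ...) {
  cat(sprintf("<prescription_corpus> %d cases, %d herbs\n",
              x$n_cases, length(x$vocabulary)))
  invisible(x)
}

#' @export
print.prescription <- function(x, ...) {
  cat(sprintf("<prescription %s> %s\n", x$case_id,
              paste(x$herbs, collapse = ", ")))
  invisible(x)
}

corpus_herb_sets <- function(corpus) lapply(corpus$cases, `[[`, "herbs")

#' Build a synonym map for herb-name standardization
#'
#' The map sends raw (source-spelling) names to canonical names and is closed
#' so that every canonical name maps to itself (idempotence).
#'
#' @param raw character vector of raw names.
#' @param canonical character vector, parallel to `raw`, of canonical names.
#' @param canonical_set optionally, further names that are canonical without
#'   appearing as a mapping target.
#' @return an object of class `"synonym_map"`.
#' @export
synonym_map <- function(raw = character(), canonical = character(),
                        canonical_set = character()) {
  raw <- trimws2(as.character(raw))
  canonical <- trimws2(as.character(canonical))
  stopifnot(length(raw) == length(canonical))
  canon <- sort_herbs(c(canonical, canonical_set))
  map <- stats::setNames(canonical, raw)
  # idempotent closure: canonical names map to themselves
  self <- stats::setNames(canon, canon)
  map <- c(map, self[!names(self) %in% names(map)])
  structure(list(map = map, canonical = canon), class = "synonym_map")
}

#' Standardize raw herb names against a synonym map
#'
#' Names are trimmed, then looked up in the map; names already canonical pass
#' through. Order is preserved and duplicates are kept (they collapse when
#' the result is turned into a case herb set).
#'
#' @param raw_herbs character vector of raw names.
#' @param syn a [synonym_map()].
#' @return character vector of canonical names, same length as `raw_herbs`.
#' @export
standardize_names <- function(raw_herbs, syn) {
  stopifnot(inherits(syn, "synonym_map"))
  raw <- trimws2(as.character(raw_herbs))
  out <- unname(syn$map[raw])
  unknown <- raw[is.na(out)]
  if (length(unknown) > 0L)
    abort2(sprintf("unknown herb name(s): %s",
                   paste(unique(unknown), collapse = ", ")),
           "herbminer_unknown_herb")
  out
}

split_multi <- function(x) {
  if (is.na(x) || !nzchar(trimws2(x))) return(character())
  trimws2(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Read a prescription corpus from CSV or JSON
#'
#' CSV schema: header `case_id,patient_id,herbs,syndromes`, with `herbs` and
#' `syndromes` `;`-separated and UTF-8 encoded; empty `patient_id` /
#' `syndromes` are allowed. JSON schema: an array of objects with the same
#' keys, `herbs` and `syndromes` as arrays.
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`; inferred from the file extension when
#'   missing.
#' @param synonyms optional [synonym_map()]; when supplied every herb name is
#'   standardized on load.
#' @return a [prescription_corpus()].
#' @export
load_corpus <- function(path, format = c("auto", "csv", "json"),
                        synonyms = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path))
    abort2(sprintf("no such file: %s", path), "herbminer_io_error")
  rows <- if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character",
                          fileEncoding = "UTF-8")
    need <- c("case_id", "herbs")
    if (!all(need %in% names(df)))
      abort2("prescriptions CSV must have case_id and herbs columns",
             "herbminer_parse_error")
    lapply(seq_len(nrow(df)), function(i) {
      list(case_id = df$case_id[i],
           patient_id = if ("patient_id" %in% names(df)) df$patient_id[i]
                        else NA_character_,
           herbs = split_multi(df$herbs[i]),
           syndromes = if ("syndromes" %in% names(df))
                         split_multi(df$syndromes[i]) else character())
    })
  } else {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    lapply(recs, function(r) {
      list(case_id = if (is.null(r$case_id)) "" else as.character(r$case_id),
           patient_id = if (is.null(r$patient_id) ||
                            identical(r$patient_id, "")) NA_character_
                        else as.character(r$patient_id),
           herbs = as.character(unlist(r$herbs)),
           syndromes = as.character(unlist(r$syndromes)))
    })
  }
  cases <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    herbs <- r$herbs
    if (!is.null(synonyms)) herbs <- standardize_names(herbs, synonyms)
    cases[[i]] <- tryCatch(
      prescription(r$case_id, herbs, r$syndromes, r$patient_id),
      herbminer_parse_error = function(e)
        abort2(sprintf("row %d: %s", i, conditionMessage(e)),
               "herbminer_parse_error"))
  }
  prescription_corpus(cases)
}

#' Write a prescription corpus to CSV or JSON
#'
#' Inverse of [load_corpus()]: `load_corpus(write_corpus(x, f))` reproduces
#' `x` exactly (case order, herb sets, syndromes, patient ids).
#'
#' @param corpus a [prescription_corpus()].
#' @param path output path.
#' @param format `"csv"` or `"json"`; inferred from extension when missing.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(corpus, "prescription_corpus"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    df <- data.frame(
      case_id = vapply(corpus$cases, `[[`, character(1), "case_id"),
      patient_id = vapply(corpus$cases, function(p)
        if (is.na(p$patient_id)) "" else p$patient_id, character(1)),
      herbs = vapply(corpus$cases, function(p)
        paste(p$herbs, collapse = ";"), character(1)),
      syndromes = vapply(corpus$cases, function(p)
        paste(p$syndromes, collapse = ";"), character(1)),
      stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                     quote = TRUE)
  } else {
    recs <- lapply(corpus$cases, function(p) {
      list(case_id = p$case_id,
           patient_id = if (is.na(p$patient_id)) NULL else p$patient_id,
           herbs = as.list(p$herbs), syndromes = as.list(p$syndromes))
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, null = "null",
                         digits = NA)
  }
  invisible(path)
}

#' Apply the first-prescription and repeat-exclusion rules
#'
#' For every patient with follow-up records only the first prescription (by
#' input order) is retained. Cases without a patient identifier are all
#' retained unless they are exact repeats (identical herb set and syndrome
#' set) of an earlier id-less case.
#'
#' @param corpus a [prescription_corpus()].
#' @return the deduplicated corpus; idempotent.
#' @export
deduplicate_first_prescription <- function(corpus) {
  stopifnot(inherits(corpus, "prescription_corpus"))
  seen_patient <- character()
  seen_anon <- character()
  keep <- logical(corpus$n_cases)
  for (i in seq_len(corpus$n_cases)) {
    p <- corpus$cases[[i]]
    if (!is.na(p$patient_id)) {
      keep[i] <- !(p$patient_id %in% seen_patient)
      seen_patient <- c(seen_patient, p$patient_id)
    } else {
      sig <- paste(itemset_key(p$herbs), itemset_key(p$syndromes),
                   sep = "\x1e")
      keep[i] <- !(sig %in% seen_anon)
      seen_anon <- c(seen_anon, sig)
    }
  }
  prescription_corpus(corpus$cases[keep])
}

#' Filter a corpus to cases carrying every required syndrome tag
#'
#' @param corpus a [prescription_corpus()].
#' @param required non-empty character vector of syndrome tags; a case is
#'   kept iff its syndrome set contains every one of them.
#' @return the (possibly empty) sub-corpus, input order preserved.
#' @export
filter_by_syndromes <- function(corpus, required) {
  stopifnot(inherits(corpus, "prescription_corpus"))
  required <- unique(trimws2(as.character(required)))
  required <- required[nzchar(required)]
  if (length(required) == 0L)
    abort2("required syndrome set must be non-empty", "herbminer_arg_error")
  keep <- vapply(corpus$cases, function(p) all(required %in% p$syndromes),
                 logical(1))
  prescription_corpus(corpus$cases[keep])
}

#' Construct an herb attribute table
#'
#' Records, per herb, its single property (warm/cold/mild/cool/hot), its
#' non-empty taste subset and its non-empty meridian subset.
#'
#' @param herb character vector of canonical herb names (unique).
#' @param property character vector, one of [herb_properties()] per herb.
#' @param tastes list of character vectors, each a non-empty subset of
#'   [herb_tastes()].
#' @param meridians list of character vectors, each a non-empty subset of
#'   [herb_meridians()].
#' @return an object of class `"herb_attribute_table"`.
#' @export
herb_attribute_table <- function(herb, property, tastes, meridians) {
  herb <- trimws2(as.character(herb))
  if (anyDuplicated(herb))
    abort2("duplicate herb in attribute table", "herbminer_parse_error")
  stopifnot(length(property) == length(herb), length(tastes) == length(herb),
            length(meridians) == length(herb))
  if (!all(property %in% herb_properties()))
    abort2("unknown property value", "herbminer_parse_error")
  check_subset <- function(vals, universe, what) {
    for (v in vals) {
      v <- unlist(v)
      if (length(v) == 0L || !all(v %in% universe))
        abort2(sprintf("each herb needs a non-empty valid %s set", what),
               "herbminer_parse_error")
    }
  }
  check_subset(tastes, herb_tastes(), "taste")
  check_subset(meridians, herb_meridians(), "meridian")
  structure(list(herb = herb, property = as.character(property),
                 tastes = lapply(tastes, as.character),
                 meridians = lapply(meridians, as.character)),
            class = "herb_attribute_table")
}

#' Read an herb attribute table from CSV
#'
#' Schema: header `herb,property,tastes,meridians`; `tastes` and `meridians`
#' are `;`-separated and restricted to the category vocabularies of
#' [herb_properties()], [herb_tastes()] and [herb_meridians()].
#'
#' @param path file path.
#' @return an [herb_attribute_table()].
#' @export
load_herb_attributes <- function(path) {
  if (!file.exists(path))
    abort2(sprintf("no such file: %s", path), "herbminer_io_error")
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  need <- c("herb", "property", "tastes", "meridians")
  if (!all(need %in% names(df)))
    abort2("attribute CSV must have herb,property,tastes,meridians columns",
           "herbminer_parse_error")
  herb_attribute_table(df$herb, trimws2(df$property),
                       lapply(df$tastes, split_multi),
                       lapply(df$meridians, split_multi))
}

#' Read a synonym map from CSV (header `raw,canonical`)
#'
#' @param path file path.
#' @param canonical_set optional extra canonical names.
#' @return a [synonym_map()].
#' @export
load_synonym_map <- function(path, canonical_set = character()) {
  if (!file.exists(path))
    abort2(sprintf("no such file: %s", path), "herbminer_io_error")
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  if (!all(c("raw", "canonical") %in% names(df)))
    abort2("synonym CSV must have raw,canonical columns",
           "herbminer_parse_error")
  synonym_map(df$raw, df$canonical, canonical_set)
}
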