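test_that("standardize_names maps raw names, passes canonical, errors on unknown", {
  syn <- synonym_map(raw = "Gancao", canonical = "Gan-cao",
                     canonical_set = c("Huang-qi"))
  expect_equal(standardize_names(c("Gancao", "Gan-cao"), syn),
               c("Gan-cao", "Gan-cao"))
  expect_equal(standardize_names("Huang-qi", syn), "Huang-qi")
  expect_equal(standardize_names(" Gan-cao ", syn), "Gan-cao")  # trimming
  expect_error(standardize_names("Danggui", syn),
               class = "herbminer_unknown_herb")
  expect_error(standardize_names("Danggui", syn), "Danggui")
  # idempotent closure: canonical names map to themselves
  expect_equal(unname(syn$map["Gan-cao"]), "Gan-cao")
})

test_that("load_corpus parses CSV/JSON, dedupes herb sets, flags bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("case_id,patient_id,herbs,syndromes",
               "c1,p1,Gan-cao;Huang-qi,qi deficiency",
               "c2,,Gan-cao;Gan-cao;San-qi,",
               "c3,p2,San-qi,blood stasis;qi deficiency"), path)
  co <- load_corpus(path)
  expect_equal(co$n_cases, 3L)
  expect_equal(co$cases[[2]]$herbs, c("Gan-cao", "San-qi"))  # set semantics
  expect_equal(co$vocabulary, c("Gan-cao", "Huang-qi", "San-qi"))
  expect_true(is.na(co$cases[[2]]$patient_id))
  expect_equal(co$cases[[3]]$syndromes, c("blood stasis", "qi deficiency"))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("case_id,patient_id,herbs,syndromes", "c1,p1,,"), bad)
  expect_error(load_corpus(bad), "row 1", class = "herbminer_parse_error")
})

test_that("write/load round-trips both formats exactly", {
  co <- prescription_corpus(list(
    prescription("c1", c("Gan-cao", "Huang-qi"),
                 c("qi deficiency", "blood stasis"), "p1"),
    prescription("c2", "San-qi"),
    prescription("c3", c("Mai-dong", "Wu-wei-zi"), character(), "p2")))
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_corpus(co, path)
    expect_identical(load_corpus(path), co, label = ext)
  }
})

test_that("first-prescription rule keeps earliest per patient, drops exact repeats", {
  co <- prescription_corpus(list(
    prescription("c1", c("A", "B"), patient_id = "p1"),
    prescription("c2", c("A", "C"), patient_id = "p1"),  # follow-up: dropped
    prescription("c3", c("A", "B")),                     # anonymous
    prescription("c4", c("A", "B")),                     # exact repeat: dropped
    prescription("c5", c("B", "C"))))
  out <- deduplicate_first_prescription(co)
  expect_equal(vapply(out$cases, `[[`, character(1), "case_id"),
               c("c1", "c3", "c5"))
  # idempotent
  expect_identical(deduplicate_first_prescription(out), out)
  # anonymous cases with different herbs are all retained
  co2 <- prescription_corpus(list(prescription("c1", "A"),
                                  prescription("c2", "B")))
  expect_equal(deduplicate_first_prescription(co2)$n_cases, 2L)
})

test_that("syndrome filter requires every tag and composes over tag unions", {
  qb <- c("qi deficiency", "blood stasis")
  co <- prescription_corpus(list(
    prescription("c1", "A", qb),
    prescription("c2", "B", "qi deficiency"),
    prescription("c3", "C", qb),
    prescription("c4", "D")))
  out <- filter_by_syndromes(co, qb)
  expect_equal(vapply(out$cases, `[[`, character(1), "case_id"),
               c("c1", "c3"))
  expect_identical(
    filter_by_syndromes(co, qb),
    filter_by_syndromes(filter_by_syndromes(co, "qi deficiency"),
                        "blood stasis"))
  expect_equal(filter_by_syndromes(co, "no such tag")$n_cases, 0L)
  expect_error(filter_by_syndromes(co, character()),
               class = "herbminer_arg_error")
})

test_that("herb attribute table validates category vocabularies", {
  at <- load_herb_attributes(extdata("synthetic_herb_attributes.csv"))
  expect_s3_class(at, "herb_attribute_table")
  expect_equal(length(at$herb), 8L)
  expect_error(
    herb_attribute_table("A", "Tepid", list("Sweet"), list("Heart")),
    class = "herbminer_parse_error")
  expect_error(
    herb_attribute_table("A", "Warm", list(character()), list("Heart")),
    class = "herbminer_parse_error")
})
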