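test_that("a fixtures-driven run populates all 8 sections and 7 criteria", {
  card <- demo_evaluation(seed = 3)
  expect_s3_class(card, "smd_scorecard")
  expect_length(card$sections, 8L)
  q <- card$sections$section_2_quality
  expect_length(q, 7L)
  expect_setequal(names(q), smd_criteria())
  statuses <- vapply(q, `[[`, character(1), "status")
  expect_true(all(statuses == "computed"))
  report <- validate_scorecard(card)
  expect_true(report$pass)
  # user fields recorded verbatim, absent ones marked explicitly
  expect_equal(card$sections$section_1_general$name, "fixture-smd")
  expect_equal(card$sections$section_4_human$human_study_design, "not provided")
})

test_that("criterion entries carry raw, normalized and params together", {
  card <- demo_evaluation(seed = 3)
  cong <- card$sections$section_2_quality$congruence
  expect_true(length(cong$metrics) >= 5)
  for (m in cong$metrics) {
    expect_false(is.null(m$raw_value))
    expect_false(is.null(m$params))
  }
  fid_entry <- Filter(function(m) m$name == "Fréchet Inception Distance",
                      cong$metrics)[[1]]
  expect_true(fid_entry$normalized >= 0 && fid_entry$normalized <= 1)
  expect_equal(fid_entry$direction, "minimize")
})

test_that("validation itemizes structural violations instead of raising", {
  card <- demo_evaluation(seed = 3)
  broken <- card
  broken$sections$section_2_quality$coverage <- NULL
  rep1 <- validate_scorecard(broken)
  expect_false(rep1$pass)
  expect_true(any(grepl("missing criterion", rep1$violations)))

  bad_score <- card
  bad_score$sections$section_2_quality$congruence$score <- 1.2
  rep2 <- validate_scorecard(bad_score)
  expect_false(rep2$pass)
  expect_true(any(grepl("out of range", rep2$violations)))

  no_field <- card
  no_field$sections$section_5_ethics$biases <- NULL
  rep3 <- validate_scorecard(no_field)
  expect_false(rep3$pass)
  expect_true(any(grepl("missing field 'biases'", rep3$violations)))
})

test_that("not-applicable criteria render with their reason", {
  pair <- gen_embedding_pair(40, 2, seed = 1)
  card <- run_evaluation(config = list(seed = 1),
                         data = list(reference = pair$reference,
                                     synthetic = pair$synthetic))
  q <- card$sections$section_2_quality
  expect_equal(q$comprehension$status, "not-applicable")
  expect_true(nzchar(q$comprehension$reason))
  expect_true(validate_scorecard(card)$pass)
  md <- render_scorecard(card, "markdown")
  expect_true(grepl("not applicable", md))
})

test_that("JSON rendering round-trips byte-identically", {
  card <- demo_evaluation(seed = 3)
  j1 <- render_scorecard(card, "json")
  j2 <- render_scorecard(parse_scorecard(j1), "json")
  expect_identical(j1, j2)
})

test_that("two runs with identical config and seeds are byte-identical", {
  j1 <- render_scorecard(demo_evaluation(seed = 3), "json")
  j2 <- render_scorecard(demo_evaluation(seed = 3), "json")
  expect_identical(j1, j2)
  j3 <- render_scorecard(demo_evaluation(seed = 4), "json")
  expect_false(identical(j1, j3))
})

test_that("markdown rendering lists the 8 template sections in order", {
  card <- demo_evaluation(seed = 3)
  md <- render_scorecard(card, "markdown")
  lines <- strsplit(md, "\n")[[1]]
  headings <- grep("^## ", lines, value = TRUE)
  expect_length(headings, 8L)
  expect_match(headings[1], "1\\. Synthetic Data General Information")
  expect_match(headings[2], "2\\. Data Quality Evaluation")
  expect_match(headings[8], "8\\. Reference Dataset General Information")
  # quality table shows raw and normalized columns
  expect_true(any(grepl("\\| Metric \\| Raw value \\| Normalized \\| Direction \\|",
                        lines)))
})

test_that("a failing metric leaves a note and never blocks the scorecard", {
  pair <- gen_embedding_pair(40, 2, seed = 1)
  # constraints targeting a feature that does not exist -> stage failure
  config <- list(seed = 1,
                 constraints = list(list(id = "ghost", target = "nope",
                                         kind = "interval", lo = 0, hi = 1)))
  card <- run_evaluation(config,
                         data = list(reference = pair$reference,
                                     synthetic = pair$synthetic))
  expect_true(any(grepl("ghost|not found|constraint", card$failure_notes)))
  expect_true(validate_scorecard(card)$pass)
  expect_equal(card$sections$section_2_quality$constraint$status,
               "not-applicable")
})

test_that("the shipped JSON schema stays in step with the validator", {
  schema_path <- system.file("schema", "smd-scorecard.schema.json",
                             package = "smdscorecard")
  expect_true(nzchar(schema_path))
  schema <- jsonlite::fromJSON(schema_path, simplifyVector = FALSE)
  req <- schema$properties$sections$required
  expect_setequal(unlist(req), names(smdscorecard:::scorecard_section_titles()))
  crit_req <- schema$properties$sections$properties$section_2_quality$required
  expect_setequal(unlist(crit_req), smd_criteria())
  # every template field named in the validator appears in the schema
  fields <- smdscorecard:::scorecard_section_fields()
  for (sec in names(fields)) {
    schema_req <- unlist(schema$properties$sections$properties[[sec]]$required)
    expect_setequal(schema_req, fields[[sec]])
  }
})
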