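# Canonical survey dialect: reading, validation, encoding, metadata.

test_that("a well-formed file reads into a validated dataset and round-trips", {
  path <- write_tiny_survey()
  ds <- read_survey(path, tiny_schema())
  expect_s3_class(ds, "survey_dataset")
  expect_equal(nrow(ds), 3)
  expect_equal(ds$q_support, c(2L, dk_sentinel(), 5L))
  expect_equal(ds$q_trend, c(3L, 5L, NA))
  expect_equal(ds$politics, c("centre", "left", "right"))
  # byte-stable round trip for canonical inputs
  out <- file.path(withr::local_tempdir(), "roundtrip.csv")
  write_survey(ds, out)
  expect_identical(readLines(out), readLines(path))
  ds2 <- read_survey(out, tiny_schema())
  expect_equal(as.data.frame(ds2), as.data.frame(ds))
})

test_that("invalid rows are reported by row and column, never dropped", {
  dir <- withr::local_tempdir()
  # answer code 9 on a K = 5 question without DK
  p1 <- write_tiny_survey(dir, rows = c(
    "r1,ES,rural,female,44,centre,2,9"))
  expect_error(read_survey(p1, tiny_schema()), "row 1, column 'q_trend'.*9")
  # DK on a question that has no don't-know option
  p2 <- write_tiny_survey(dir, rows = c(
    "r1,ES,rural,female,44,centre,2,DK"))
  expect_error(read_survey(p2, tiny_schema()), "without a don't-know")
  # bad demographics
  p3 <- write_tiny_survey(dir, rows = c(
    "r1,ES,countryside,female,-3,centre,2,3"))
  expect_error(read_survey(p3, tiny_schema()), "location")
  expect_error(read_survey(p3, tiny_schema()), "age")
  # duplicated respondent ids
  p4 <- write_tiny_survey(dir, rows = c(
    "r1,ES,rural,female,44,centre,2,3",
    "r1,ES,urban,male,30,left,4,4"))
  expect_error(read_survey(p4, tiny_schema()), "duplicate respondent_id")
})

test_that("a missing demographic column is a schema error", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.csv")
  writeLines(c("respondent_id,country,location,age,politics,q_support,q_trend",
               "r1,ES,rural,44,centre,2,3"), path)
  expect_error(read_survey(path, tiny_schema()), "missing required columns: sex")
})

test_that("a column-mapping config renames deposit headers to canonical names", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "renamed.csv")
  writeLines(c("id,cntry,location,sex,age,politics,q_support,q_trend",
               "r1,ES,rural,female,44,centre,2,3"), path)
  ds <- read_survey(path, tiny_schema(),
                    col_map = c(id = "respondent_id", cntry = "country"))
  expect_equal(ds$respondent_id, "r1")
})

test_that("blank politics is stored as the explicit missing level", {
  path <- write_tiny_survey(rows = "r1,ES,rural,female,44,,2,3")
  ds <- read_survey(path, tiny_schema())
  expect_equal(ds$politics, "missing")
})

test_that("encoding separates ordinal codes, DK and missing", {
  path <- write_tiny_survey(rows = c(
    "r1,ES,rural,female,44,centre,2,3",
    "r2,ES,rural,male,31,left,DK,5",
    "r3,ES,urban,male,60,right,5,1",
    "r4,ES,rural,female,52,centre,,2"))
  ds <- read_survey(path, tiny_schema())
  enc <- encode_responses(ds, "q_support", "ES", "rural")
  expect_equal(enc$codes, 2L)
  expect_equal(enc$dk_count, 1L)
  expect_equal(enc$n_total, 2L)
  expect_equal(enc$n_missing, 1L)
  # the full-country encoding has [2, DK, 5, missing] -> codes (2, 5), dk 1
  enc_all <- encode_responses(ds, "q_support", "ES", "all")
  expect_equal(sort(enc_all$codes), c(2L, 5L))
  expect_equal(enc_all$dk_count, 1L)
  expect_equal(enc_all$n_total, 3L)
})

test_that("rural and urban encodings partition the country encoding", {
  scn <- default_scenario(n_per_country = 60, seed = 5)
  ds <- simulate_survey(scn)
  for (code in c("ES", "SK", "FR")) {
    n_r <- encode_responses(ds, "recovery_support", code, "rural")$n_total
    n_u <- encode_responses(ds, "recovery_support", code, "urban")$n_total
    n_all <- encode_responses(ds, "recovery_support", code, "all")$n_total
    expect_equal(n_r + n_u, n_all)
  }
})

test_that("an empty stratum is signalled and fitting refuses it", {
  path <- write_tiny_survey(rows = "r1,ES,rural,female,44,centre,2,3")
  ds <- read_survey(path, tiny_schema())
  enc <- encode_responses(ds, "q_support", "ES", "urban")
  expect_equal(enc$n_total, 0L)
  expect_error(fit_ordinal(enc), "empty stratum")
  expect_error(fit_group(encode_responses(ds, "q_support", "ES", "rural"),
                         enc), "empty stratum")
})

test_that("country metadata is validated", {
  dir <- withr::local_tempdir()
  ok <- file.path(dir, "meta.csv")
  writeLines(c("country,rural_proportion,median_age",
               "ES,0.19,44.9", "SK,0.46,41.3"), ok)
  meta <- read_country_meta(ok)
  expect_equal(meta$rural_proportion[meta$country == "ES"], 0.19)
  bad <- file.path(dir, "bad.csv")
  writeLines(c("country,rural_proportion", "XX,1.3"), bad)
  expect_error(read_country_meta(bad), "outside \\[0, 1\\].*XX")
  dup <- file.path(dir, "dup.csv")
  writeLines(c("country,rural_proportion", "ES,0.19", "ES,0.21"), dup)
  expect_error(read_country_meta(dup), "duplicate")
})

test_that("question schemas round-trip through YAML", {
  sch <- tiny_schema()
  path <- file.path(withr::local_tempdir(), "schema.yaml")
  write_schema(sch, path)
  sch2 <- read_schema(path)
  expect_equal(names(sch2), names(sch))
  expect_equal(sch2$q_support$K, 5)
  expect_true(sch2$q_support$has_dont_know)
  expect_false(sch2$q_trend$has_dont_know)
  expect_equal(sch2$q_support$labels, sch$q_support$labels)
})

test_that("schema constructors enforce their invariants", {
  expect_error(question_spec("q", 2), "K")
  expect_error(question_spec("q", 5, labels = c("a", "b")), "labels")
  expect_error(survey_schema(question_spec("a", 5), question_spec("a", 5)),
               "duplicate")
})
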