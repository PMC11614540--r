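test_that("quote tables round-trip through write/read, tab or comma delimited", {
  q <- quotes_df(
    quote_row(society_id = "s1", modality = "running",
              proficiency_evidence = "higher",
              functional_domains = "subsistence;conflict",
              special_activity = "persistence_hunting",
              gender_evidence = "male_bias"),
    quote_row(society_id = "s1", modality = "climbing",
              functional_domains = "observation"),
    quote_row(society_id = "s2", modality = "diving",
              functional_domains = "subsistence",
              special_activity = "underwater_hunting"),
    quote_row(society_id = "s2", modality = "swimming",
              proficiency_evidence = "none"),
    quote_row(society_id = "s3", modality = "running", excluded = TRUE,
              exclusion_reason = "myth_story_legend"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_quotes(q, tsv)
  back <- read_quotes(tsv)
  expect_equal(back, q)

  # comma dialect and case-insensitive enumerations are accepted
  csv <- withr::local_tempfile(fileext = ".csv")
  q2 <- q
  q2$modality <- toupper(q2$modality)
  q2$excluded <- ifelse(q2$excluded, "TRUE", "FALSE")
  utils::write.table(q2, csv, sep = ",", quote = TRUE, row.names = FALSE,
                     na = "")
  expect_equal(read_quotes(csv), q)

  # writing identical records twice is byte-identical
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  write_quotes(back, tsv2)
  expect_identical(readLines(tsv), readLines(tsv2))
})

test_that("invalid quote rows are rejected with row diagnostics", {
  write_and_read <- function(q) {
    f <- withr::local_tempfile(fileext = ".tsv")
    utils::write.table(q, f, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    read_quotes(f)
  }
  expect_error(
    write_and_read(quote_row(modality = "diving",
                             proficiency_evidence = "basic",
                             special_activity = "honey_climbing")),
    "not legal for modality")
  expect_error(
    write_and_read(quote_row(proficiency_evidence = "none",
                             functional_domains = "leisure")),
    "further variables")
  expect_error(
    write_and_read(quote_row(modality = "levitating")),
    "unknown modality")
  expect_error(
    write_and_read(quote_row(society_id = "bad id!")),
    "society_id format")
  expect_error(
    write_and_read(quote_row(modality = "running",
                             functional_domains = "observation")),
    "not applicable")
  # all offending rows are listed at once
  err <- tryCatch(
    write_and_read(quotes_df(quote_row(modality = "flying"),
                             quote_row(modality = "teleporting"))),
    error = conditionMessage)
  expect_match(err, "row 1")
  expect_match(err, "row 2")
})

test_that("society table parsing validates ecology and dependence bounds", {
  write_and_read <- function(s) {
    f <- withr::local_tempfile(fileext = ".tsv")
    utils::write.table(s, f, sep = "\t", quote = FALSE, row.names = FALSE)
    read_societies(f)
  }
  s <- write_and_read(society_row(mht_category = "Tundra"))
  expect_equal(s$biome6, "Tundra")
  expect_equal(s$mean_annual_temp_C, -10)

  # 40 + 30 + 20 = 90 accepted; 60 + 50 + 10 = 120 rejected
  ok <- write_and_read(society_row(dependence_gathering = 40,
                                   dependence_hunting = 30,
                                   dependence_fishing = 20))
  expect_equal(ok$dependence_hunting, 30)
  expect_error(write_and_read(society_row(dependence_gathering = 60,
                                          dependence_hunting = 50,
                                          dependence_fishing = 10)),
               "sum to 120")
  expect_error(write_and_read(society_row(coast_distance_km = -3)),
               "negative coast_distance_km")
  expect_error(write_and_read(society_row(mht_category = "Atlantis")),
               "unknown mht_category.*Atlantis")
})

test_that("eligibility gate enforces strict dependence and quote thresholds", {
  soc <- rbind(
    society_row(society_id = "boundary_56", dependence_gathering = 30,
                dependence_hunting = 16, dependence_fishing = 10),
    society_row(society_id = "boundary_57", dependence_gathering = 30,
                dependence_hunting = 17, dependence_fishing = 10),
    society_row(society_id = "one_quote", dependence_gathering = 80,
                dependence_hunting = 10, dependence_fishing = 5),
    society_row(society_id = "myth_only", dependence_gathering = 80,
                dependence_hunting = 10, dependence_fishing = 5))
  soc$biome6 <- "Tundra"
  q <- quotes_df(
    quote_row(society_id = "boundary_56"), quote_row(society_id = "boundary_56"),
    quote_row(society_id = "boundary_57"), quote_row(society_id = "boundary_57"),
    quote_row(society_id = "one_quote"),
    quote_row(society_id = "myth_only"),
    quote_row(society_id = "myth_only", excluded = TRUE,
              exclusion_reason = "myth_story_legend"))

  gate <- eligible_societies(soc, q)
  expect_setequal(gate$eligible$society_id, "boundary_57")
  excl <- setNames(gate$excluded$reason, gate$excluded$society_id)
  expect_equal(excl[["boundary_56"]], "low_dependence")   # exactly 56 fails ">"
  expect_equal(excl[["one_quote"]], "insufficient_quotes")
  # excluded quotes do not count towards the >= 2 quote threshold
  expect_equal(excl[["myth_only"]], "insufficient_quotes")

  # idempotent and independent of row order
  gate2 <- eligible_societies(gate$eligible, q)
  expect_equal(gate2$eligible, gate$eligible)
  perm <- sample(nrow(soc))
  gate3 <- eligible_societies(soc[perm, ], q[sample(nrow(q)), ])
  expect_setequal(gate3$eligible$society_id, gate$eligible$society_id)
})
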