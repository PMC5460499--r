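test_that("header-only files give empty tables with clean reports", {
  pp <- read_persons(write_lines_tmp(persons_header))
  cc <- read_claims(write_lines_tmp(claims_header))
  expect_equal(nrow(pp), 0L)
  expect_equal(nrow(cc), 0L)
  expect_equal(validation_report(pp)$rows_rejected, 0L)
  expect_equal(validation_report(cc)$rows_rejected, 0L)
})

test_that("rows violating person invariants are rejected and reported", {
  pp <- read_persons(write_lines_tmp(c(
    persons_header,
    person_line("a", death = "2010-05-01"),
    person_line("b", death = "01/05/2010"),   # malformed date
    person_line("c"))))
  expect_equal(nrow(pp), 2L)
  rep <- validation_report(pp)
  expect_equal(rep$rows_read, 3L)
  expect_equal(rep$rows_accepted, 2L)
  expect_equal(rep$rows_rejected, 1L)
  expect_match(rep$violations$message, "death_date")

  # death before coverage start and inverted coverage also reject
  pp2 <- read_persons(write_lines_tmp(c(
    persons_header,
    person_line("d", death = "2003-01-01"),
    paste("e", "female", 1940, "", "2010-01-01", "2005-01-01", sep = ","))))
  expect_equal(nrow(pp2), 0L)
  expect_equal(validation_report(pp2)$rows_rejected, 2L)
})

test_that("missing required columns raise a schema error naming the column", {
  bad <- write_lines_tmp("person_id,sex,birth_year,coverage_start,coverage_end")
  expect_error(read_persons(bad), "death_date")
})

test_that("claims parse, normalize and reject on ICD-10 syntax", {
  cc <- read_claims(write_lines_tmp(c(
    claims_header,
    claim_line("a", "2010-01-01", "inpatient", "S72.1"),
    claim_line("b", "2010-01-02", "outpatient", "s72.1"),
    claim_line("c", "2010-01-03", "outpatient", "S721"),
    claim_line("d", "2010-01-04", "outpatient", "ZZZ"))))
  expect_equal(nrow(cc), 3L)
  expect_equal(cc$primary_dx, c("S72.1", "S72.1", "S72.1"))
  expect_identical(cc$secondary_dx[[1]], character(0))
  rep <- validation_report(cc)
  expect_equal(rep$rows_rejected, 1L)
  expect_match(rep$violations$message, "ICD-10")
})

test_that("secondary diagnosis lists are split on ';' and normalized", {
  cc <- read_claims(write_lines_tmp(c(
    claims_header,
    claim_line("a", "2010-01-01", "inpatient", "S72.0", "i21.9;E11.5"))))
  expect_equal(cc$secondary_dx[[1]], c("I21.9", "E11.5"))
})

test_that("write/read round-trip is the identity on accepted records", {
  sim <- simulate_cohort(sim_params(n_persons = 60L), seed = 3L)
  pp_path <- tempfile(); cc_path <- tempfile()
  write_persons(sim$persons, pp_path)
  write_claims(sim$claims, cc_path)
  pp <- read_persons(pp_path)
  cc <- read_claims(cc_path)
  expect_equal(as.data.frame(pp), as.data.frame(sim$persons),
               ignore_attr = TRUE)
  for (col in c("person_id", "service_date", "setting", "primary_dx",
                "specialty"))
    expect_equal(cc[[col]], sim$claims[[col]])
  expect_equal(lapply(cc$secondary_dx, as.character),
               lapply(sim$claims$secondary_dx, as.character))
})

test_that("validation report counts are conserved on randomized fixtures", {
  set.seed(20)
  for (rep_i in 1:5) {
    n <- sample(5:40, 1)
    lines <- vapply(seq_len(n), function(i) {
      if (runif(1) < 0.3)  # corrupt a random field
        person_line(paste0("x", i), by = sample(c(1700, 2050), 1))
      else person_line(paste0("x", i), by = sample(1900:1960, 1))
    }, character(1))
    pp <- read_persons(write_lines_tmp(c(persons_header, lines)))
    r <- validation_report(pp)
    expect_equal(r$rows_read, r$rows_accepted + r$rows_rejected)
    expect_equal(r$rows_accepted, nrow(pp))
  }
})

test_that("linkage validation flags orphans, coverage and post-death claims", {
  pp <- read_persons(write_lines_tmp(c(
    persons_header,
    person_line("a", death = "2010-06-30"),
    person_line("b"))))
  cc_ok <- dt_claims(c("a", "b"), c("2010-01-01", "2012-01-01"),
                     "outpatient", "I10")
  expect_equal(validate_linkage(pp, cc_ok)$rows_rejected, 0L)

  cc_orphan <- dt_claims("ghost", "2010-01-01", "outpatient", "I10")
  r <- validate_linkage(pp, cc_orphan)
  expect_equal(r$rows_rejected, 1L)
  expect_match(r$violations$message, "ghost")

  cc_dead <- dt_claims("a", "2010-07-15", "outpatient", "I10")
  r2 <- validate_linkage(pp, cc_dead)
  expect_equal(r2$rows_rejected, 1L)
  expect_match(r2$violations$message, "post-death")
})
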