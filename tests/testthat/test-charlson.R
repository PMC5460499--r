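test_that("code-to-category mapping follows the Quan prefix table", {
  expect_identical(map_code_to_categories("S72.0"), character(0))
  expect_identical(map_code_to_categories("I21.9"), "myocardial_infarction")
  expect_identical(map_code_to_categories("C78.0"), "metastatic_solid_tumour")
  expect_identical(map_code_to_categories("E11.5"), "diabetes_with_complication")
  expect_identical(map_code_to_categories("E11.9"), "diabetes_without_complication")
  # lower case / undotted inputs normalize before matching
  expect_identical(map_code_to_categories("i219"), "myocardial_infarction")
  # 3-character parent codes map when the prefix is 3 characters
  expect_identical(map_code_to_categories("K25"), "peptic_ulcer_disease")
})

test_that("scores sum updated weights after hierarchy resolution", {
  w <- charlson_weights()
  expect_equal(charlson_score(character()), 0)
  expect_equal(charlson_score(c("congestive_heart_failure", "dementia")), 4)
  expect_equal(
    charlson_score(c("mild_liver_disease", "moderate_severe_liver_disease")),
    unname(w["moderate_severe_liver_disease"]))
  expect_equal(
    charlson_score(c("any_malignancy", "metastatic_solid_tumour")),
    unname(w["metastatic_solid_tumour"]))
  expect_equal(
    charlson_score(c("diabetes_without_complication",
                     "diabetes_with_complication")),
    unname(w["diabetes_with_complication"]))
  expect_error(charlson_score("not_a_category"), "unknown")
})

test_that("original 1987 weights are selectable and differ where expected", {
  w0 <- charlson_weights("original")
  w1 <- charlson_weights("updated")
  expect_equal(unname(w0["myocardial_infarction"]), 1)
  expect_equal(unname(w1["myocardial_infarction"]), 0)
  expect_equal(unname(w0["aids_hiv"]), 6)
  expect_equal(unname(w1["aids_hiv"]), 4)
  expect_equal(unname(w0["metastatic_solid_tumour"]),
               unname(w1["metastatic_solid_tumour"]))
})

test_that("outpatient evidence needs two claims at least 7 days apart", {
  idx <- as.Date("2010-06-01")
  # 8 days apart: present
  cl <- dt_claims("p", idx + c(-10, -2), "outpatient", "I21.9")
  expect_identical(eligible_category_evidence(cl, idx), "myocardial_infarction")
  # 3 days apart: absent
  cl2 <- dt_claims("p", idx + c(-10, -7), "outpatient", "I21.9")
  expect_identical(eligible_category_evidence(cl2, idx), character(0))
  # exactly 7 days apart: present (rule is "at least 7")
  cl3 <- dt_claims("p", idx + c(-10, -3), "outpatient", "I21.9")
  expect_identical(eligible_category_evidence(cl3, idx), "myocardial_infarction")
  # a single outpatient claim never qualifies
  cl4 <- dt_claims("p", idx - 100, "outpatient", "I21.9")
  expect_identical(eligible_category_evidence(cl4, idx), character(0))
})

test_that("one inpatient claim in the lookback year qualifies", {
  idx <- as.Date("2010-06-01")
  cl <- dt_claims("p", idx - 100, "inpatient", "I21.9")
  expect_identical(eligible_category_evidence(cl, idx), "myocardial_infarction")
})

test_that("the 365-day lookback boundary is half-open at the index date", {
  idx <- as.Date("2010-06-01")
  in_window <- dt_claims("p", idx - 365, "inpatient", "I21.9")
  expect_identical(eligible_category_evidence(in_window, idx),
                   "myocardial_infarction")
  too_old <- dt_claims("p", idx - 366, "inpatient", "I21.9")
  expect_identical(eligible_category_evidence(too_old, idx), character(0))
  # an index-day claim is outside the lookback window...
  on_index_primary <- dt_claims("p", idx, "inpatient", "I21.9")
  expect_identical(eligible_category_evidence(on_index_primary, idx),
                   character(0))
})

test_that("index-claim secondary diagnoses count, its primary does not", {
  idx <- as.Date("2010-06-01")
  cl <- dt_claims("p", idx, "inpatient", "S72.0",
                  secondary_dx = list(c("I21.9", "C78.0")))
  expect_setequal(eligible_category_evidence(cl, idx),
                  c("myocardial_infarction", "metastatic_solid_tumour"))
  # outpatient same-day claims contribute nothing
  cl2 <- dt_claims("p", idx, "outpatient", "S72.0",
                   secondary_dx = list("I21.9"))
  expect_identical(eligible_category_evidence(cl2, idx), character(0))
})

test_that("scores are invariant to claim order and duplication, monotone in categories", {
  idx <- as.Date("2010-06-01")
  set.seed(7)
  codes <- c("I21.9", "I50.0", "F03", "C78.0", "E11.5", "N18.9")
  for (i in 1:10) {
    k <- sample(2:6, 1)
    pick <- sample(codes, k)
    dates <- idx - sample(10:300, k)
    cl <- dt_claims(rep("p", k), dates, "inpatient", pick)
    base_cats <- eligible_category_evidence(cl, idx)
    # permute and duplicate rows
    perm <- cl[sample(nrow(cl)), ]
    dup <- rbind(cl, cl[sample(nrow(cl), 2), ])
    expect_setequal(eligible_category_evidence(perm, idx), base_cats)
    expect_setequal(eligible_category_evidence(dup, idx), base_cats)
    # adding a category never decreases the score
    s0 <- charlson_score(base_cats)
    expect_gte(charlson_score(union(base_cats, "chronic_pulmonary_disease")), s0)
    # adding a zero-weight category never changes it
    expect_equal(charlson_score(union(base_cats, "peptic_ulcer_disease")), s0)
  }
})

test_that("batch cohort scorer agrees with the per-person reference path", {
  sim <- simulate_cohort(sim_params(n_persons = 150L), seed = 9L)
  idx <- as.Date("2010-06-01")
  ev <- data.table::data.table(person_id = sim$persons$person_id,
                               index_date = idx)
  batch <- score_cohort(ev, sim$claims)
  ref <- vapply(ev$person_id, function(p) {
    cl <- sim$claims[sim$claims$person_id == p, ]
    charlson_score(eligible_category_evidence(cl, idx))
  }, numeric(1))
  expect_equal(batch, as.integer(unname(ref)))
})
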