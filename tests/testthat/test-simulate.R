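test_that("an empty population yields empty, valid tables", {
  sim <- simulate_cohort(sim_params(n_persons = 0L), seed = 1L)
  expect_equal(nrow(sim$persons), 0L)
  expect_equal(nrow(sim$claims), 0L)
  d <- simulate_to_dir(sim, tempfile())
  expect_equal(nrow(read_persons(file.path(d, "persons.csv"))), 0L)
  expect_equal(nrow(read_claims(file.path(d, "claims.csv"))), 0L)
})

test_that("the generator is byte-identical under a fixed seed", {
  p <- sim_params(n_persons = 300L)
  s1 <- simulate_cohort(p, seed = 77L)
  s2 <- simulate_cohort(p, seed = 77L)
  d1 <- simulate_to_dir(s1, tempfile())
  d2 <- simulate_to_dir(s2, tempfile())
  for (f in c("persons.csv", "claims.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  s3 <- simulate_cohort(p, seed = 78L)
  expect_false(identical(s1$persons$death_date, s3$persons$death_date))
})

test_that("invalid parameters are rejected up front", {
  expect_error(sim_params(cci_hr = -1))
  expect_error(sim_params(frac_tau = 0))
  expect_error(sim_params(comorbidity = c(dementia = 1.4)))
  expect_error(sim_params(comorbidity = c(made_up = 0.1)), "unknown")
})

test_that("with fracture incidence zero, mortality matches the planted baseline", {
  p <- sim_params(n_persons = 20000L,
                  fracture_incidence = list(male = rep(0, 5),
                                            female = rep(0, 5)),
                  comorbidity = c(dementia = 0),  # CCI identically 0
                  decoy_rate = 0, noise_rate = 0)
  sim <- simulate_cohort(p, seed = 88L)
  expect_false(any(startsWith(sim$claims$primary_dx, "S72")))
  # one-year death probability in a narrow age-sex cell vs analytic truth
  for (s in c("male", "female")) {
    cell <- sim$truth$sex == s & sim$truth$age0 >= 70 & sim$truth$age0 < 75
    n <- sum(cell)
    died_1y <- !is.na(sim$persons$death_date[cell]) &
      sim$persons$death_date[cell] < p$data_start + 365L
    p_true <- mean(true_cumulative_risk(p, FALSE, s,
                                        sim$truth$age0[cell], 0, 12))
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(mean(died_1y) - p_true), 3 * se + 1e-12)
  }
})

test_that("planted analytic risk matches closed forms and a Riemann oracle", {
  # constant hazard: theta = 0 collapses Gompertz to an exponential
  p0 <- sim_params(gompertz = list(male = c(b = 0.02, theta = 0),
                                   female = c(b = 0.02, theta = 0)),
                   cci_hr = 1)
  lam <- 0.02
  for (t in c(6, 12, 60))
    expect_equal(true_cumulative_risk(p0, FALSE, "male", 70, 0, t),
                 1 - exp(-lam * t / 12), tolerance = 1e-12)

  # no fracture effect: exposed equals unexposed
  pnull <- sim_params(frac_A = 0, frac_B = 0)
  expect_equal(true_cumulative_risk(pnull, TRUE, "female", 80, 2, 60),
               true_cumulative_risk(pnull, FALSE, "female", 80, 2, 60))

  # decay-plus-plateau multiplier vs a fine-grid Riemann sum
  pr <- sim_params(frac_A = 1, frac_B = 0.2, frac_tau = 6,
                   gompertz = list(male = c(b = 0.05, theta = 0),
                                   female = c(b = 0.05, theta = 0)),
                   cci_hr = 1)
  t_months <- 24
  uu <- seq(0, t_months / 12, length.out = 200001)
  du <- uu[2] - uu[1]
  mult <- 1 + 1 * exp(-uu * 12 / 6) + 0.2
  haz <- 0.05 * mult
  riemann <- 1 - exp(-sum((haz[-1] + haz[-length(haz)]) / 2 * du))
  expect_equal(true_cumulative_risk(pr, TRUE, "male", 70, 0, t_months),
               riemann, tolerance = 1e-6)
})

test_that("two-state reference truth matches limits and a direct oracle", {
  # zero incidence: reduces to the unexposed single-state risk
  p0 <- sim_params(fracture_incidence = list(male = rep(0, 5),
                                             female = rep(0, 5)))
  expect_equal(true_reference_risk(p0, "female", 78, 1, 60),
               true_cumulative_risk(p0, FALSE, "female", 78, 1, 60),
               tolerance = 1e-10)
  # null fracture effect: future fractures change nothing
  pn <- sim_params(frac_A = 0, frac_B = 0)
  expect_equal(true_reference_risk(pn, "male", 75, 0, 120),
               true_cumulative_risk(pn, FALSE, "male", 75, 0, 120),
               tolerance = 1e-4)
  # with an active effect the reference risk sits between the two states
  p <- sim_params()
  lo <- true_cumulative_risk(p, FALSE, "female", 80, 1, 120)
  hi <- true_cumulative_risk(p, TRUE, "female", 80, 1, 120)
  mid <- true_reference_risk(p, "female", 80, 1, 120)
  expect_gt(mid, lo)
  expect_lt(mid, hi)
})

test_that("decoy outpatient patterns are never scored", {
  p <- sim_params(n_persons = 400L,
                  comorbidity = c(dementia = 0),  # no true conditions
                  decoy_rate = 1, noise_rate = 0,
                  fracture_incidence = list(male = rep(0, 5),
                                            female = rep(0, 5)))
  sim <- simulate_cohort(p, seed = 99L)
  expect_gt(nrow(sim$claims), 0L)   # decoys were emitted
  ev <- data.table::data.table(person_id = sim$persons$person_id,
                               index_date = as.Date("2012-06-01"))
  expect_true(all(score_cohort(ev, sim$claims) == 0L))
})

test_that("planted comorbidity-fracture confounding surfaces in the scored cohort", {
  sim <- simulate_cohort(sim_params(n_persons = 12000L), seed = 13L)
  co <- build_cohort(sim$persons, sim$claims, seed = 14L)
  mean_cci <- tapply(co$cci_score, co$arm, mean)
  expect_gt(mean_cci["case"], mean_cci["reference"])
})
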