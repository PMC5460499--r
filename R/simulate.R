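#' Simulation parameters with known ground truth
#'
#' Defaults are the "estonia-like" preset: a >=50 population with an Eastern
#' European age pyramid, Gompertz baseline mortality per sex, Charlson
#' comorbidity with prevalences chosen so the reference-arm mean score sits
#' near 0.7, hip-fracture incidence rising steeply with age, and a fracture
#' effect on the death hazard of the form
#' `h(u) = 1 + A * exp(-u / tau) + B` at `u` months post fracture — a large
#' early excess decaying to a persistent plateau. The preset is a
#' convenience: its rates put crude 1-year case mortality in the 20-35%
#' range typical of >=50 hip-fracture cohorts, not a calibration claim.
#'
#' @param n_persons population size.
#' @param male_share proportion male.
#' @param age_band_weights weights over starting-age decades
#'   50-59, 60-69, 70-79, 80-89, 90-99.
#' @param comorbidity named numeric vector: prevalence per Charlson
#'   category (categories not named have prevalence 0).
#' @param cci_hr multiplicative death-hazard ratio per Charlson point.
#' @param frac_cci_hr fracture-incidence hazard ratio per Charlson point
#'   (`> 1` plants comorbidity-fracture confounding; `1` switches it off).
#' @param gompertz list with `male`/`female`, each `c(b, theta)`: baseline
#'   hazard `b * exp(theta * age)` per person-year.
#' @param fracture_incidence list with `male`/`female`, each length-5 vector
#'   of first-fracture rates per person-year by age decade (50s..90s).
#' @param frac_A,frac_tau,frac_B fracture-effect multiplier parameters
#'   (`frac_tau` in months; `frac_A = frac_B = 0` is the null).
#' @param s72_props proportions of S72.0 / S72.1 / S72.2 among fracture
#'   claims.
#' @param p_claim_year probability a true category generates claims in a
#'   given calendar year.
#' @param p_inpatient probability such evidence is a single inpatient claim
#'   (otherwise an outpatient pair >= 7 days apart).
#' @param index_secondary_prob probability a true category is coded as a
#'   secondary diagnosis on the index fracture claim.
#' @param decoy_rate probability a person carries one decoy category:
#'   outpatient claims that appear exactly once, or twice under 7 days
#'   apart, and must be excluded by the comorbidity scorer.
#' @param noise_rate expected non-Charlson outpatient claims per person-year.
#' @param data_start,enrol_start,enrol_end,closure_date study calendar.
#' @return validated `"sim_params"` list.
#' @export
sim_params <- function(
    n_persons = 20000L,
    male_share = 0.41,
    age_band_weights = c(0.35, 0.27, 0.22, 0.12, 0.04),
    comorbidity = c(congestive_heart_failure = 0.10,
                    dementia = 0.04,
                    chronic_pulmonary_disease = 0.07,
                    diabetes_with_complication = 0.05,
                    renal_disease = 0.03,
                    any_malignancy = 0.06,
                    metastatic_solid_tumour = 0.01,
                    mild_liver_disease = 0.02),
    cci_hr = 1.35,
    frac_cci_hr = 1.3,
    gompertz = list(male = c(b = 2.4e-5, theta = 0.095),
                    female = c(b = 0.85e-5, theta = 0.105)),
    fracture_incidence = list(
      male = c(0.0006, 0.0013, 0.0035, 0.008, 0.012),
      female = c(0.0004, 0.0013, 0.0050, 0.013, 0.018)),
    frac_A = 13, frac_tau = 2.5, frac_B = 0.5,
    s72_props = c(0.55, 0.35, 0.10),
    p_claim_year = 0.85,
    p_inpatient = 0.3,
    index_secondary_prob = 0.5,
    decoy_rate = 0.08,
    noise_rate = 0.3,
    data_start = as.Date("2004-01-01"),
    enrol_start = as.Date("2005-01-01"),
    enrol_end = as.Date("2013-12-31"),
    closure_date = as.Date("2016-05-04")) {
  p <- as.list(environment())
  stopifnot(p$n_persons >= 0, p$male_share >= 0, p$male_share <= 1,
            length(p$age_band_weights) == 5, all(p$age_band_weights >= 0),
            all(p$comorbidity >= 0), all(p$comorbidity <= 1),
            p$cci_hr > 0, p$frac_cci_hr > 0,
            p$frac_A >= 0, p$frac_B >= 0, p$frac_tau > 0,
            all(unlist(p$fracture_incidence) >= 0),
            all(abs(p$s72_props) >= 0), sum(p$s72_props) > 0)
  unknown <- setdiff(names(p$comorbidity), names(charlson_weights()))
  if (length(unknown))
    stop("unknown comorbidity category: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(p, class = "sim_params")
}

# --- planted-hazard machinery (time in years, ages in years) --------------

.gomp <- function(params, sex) {
  g <- params$gompertz[[sex]]
  list(b = unname(g["b"]), theta = unname(g["theta"]))
}

# cumulative death hazard over u years from age `age`, multiplier M,
# exposed = fracture multiplier applied from u = 0
.cum_hazard <- function(params, sex, age, M, u, exposed = FALSE) {
  g <- .gomp(params, sex)
  base <- M * g$b * exp(g$theta * age)
  # (exp(k*u) - 1)/k with the k -> 0 limit (constant-hazard case)
  expm1_over <- function(k, u) if (abs(k) < 1e-12) u else expm1(k * u) / k
  if (!exposed)
    return(base * expm1_over(g$theta, u))
  r <- 12 / params$frac_tau            # per-year decay of the early excess
  term1 <- (1 + params$frac_B) * expm1_over(g$theta, u)
  term2 <- params$frac_A * expm1_over(g$theta - r, u)
  base * (term1 + term2)
}

# invert .cum_hazard in u for a vector of exponential thresholds E
.invert_cum_hazard <- function(params, sex, age, M, E, exposed = FALSE,
                               u_max = 200) {
  n <- length(E)
  lo <- rep(0, n); hi <- rep(u_max, n)
  top <- .cum_hazard(params, sex, age, M, rep(u_max, n), exposed)
  never <- E >= top
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    f <- .cum_hazard(params, sex, age, M, mid, exposed) < E
    lo[f] <- mid[f]; hi[!f] <- mid[!f]
  }
  out <- (lo + hi) / 2
  out[never] <- Inf
  out
}

# first-fracture time (years from start) under piecewise-constant incidence
# over age decades (50s..80s, then 90+ open-ended); Inf if none before
# `horizon`. Each person crosses at most 5 band segments, laid out as a
# matrix so the inversion is a single vectorized pass.
.draw_fracture_time <- function(rates5, age0, fcci, horizon) {
  n <- length(age0)
  if (!n) return(numeric())
  E <- rexp(n)
  # segment j = age band j; entry/exit times relative to start
  starts <- pmax(outer(age0, 50 + 10 * (0:4), function(a, lo) lo - a), 0)
  ends <- cbind(starts[, -1, drop = FALSE], horizon)
  ends <- pmin(ends, horizon)
  dur <- pmax(ends - starts, 0)
  haz <- sweep(dur, 2, rates5, `*`) * fcci
  Hcum <- haz
  for (j in 2:5) Hcum[, j] <- Hcum[, j - 1] + haz[, j]
  Hprev <- cbind(0, Hcum[, -5, drop = FALSE])
  hit <- E <= Hcum[, 5]
  tf <- rep(Inf, n)
  if (any(hit)) {
    j <- max.col(sweep(Hcum, 1, E, `>=`), ties.method = "first")
    i <- which(hit)
    rate <- rates5[j[i]] * fcci[i]
    tf[i] <- starts[cbind(i, j[i])] + (E[i] - Hprev[cbind(i, j[i])]) / rate
  }
  tf
}

#' Simulate a claims-shaped population with known hazards
#'
#' Generates a person table and a claims table in the package's interchange
#' layout, with death times drawn from the planted piecewise hazard (Gompertz
#' baseline per sex, Charlson multiplier per point, fracture multiplier from
#' the fracture date onward) and comorbidity claims emitted with in/outpatient
#' repeat patterns that exercise the outpatient 7-day rule — including decoy
#' categories that appear exactly once, or twice under 7 days apart, which a
#' correct scorer must exclude. Deterministic given `seed`.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed.
#' @return list with `persons`, `claims` (tables as produced by the readers)
#'   and `truth`: per-person planted values (`age0` exact age at data start,
#'   `cci` planted Charlson score, `frac_time_years` time from data start to
#'   fracture, or `NA`).
#' @export
simulate_cohort <- function(params = sim_params(), seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  restore <- .with_seed(seed)
  on.exit(restore())

  n <- params$n_persons
  t0 <- params$data_start
  horizon <- as.numeric(params$closure_date - t0) / 365.25
  weights <- charlson_weights()

  empty_claims <- data.table(
    person_id = character(), service_date = as.Date(character()),
    setting = character(), primary_dx = character(),
    secondary_dx = list(), specialty = character())
  if (n == 0L) {
    persons <- data.table(person_id = character(), sex = character(),
                          birth_year = integer(),
                          death_date = as.Date(character()),
                          coverage_start = as.Date(character()),
                          coverage_end = as.Date(character()))
    return(list(persons = persons, claims = empty_claims,
                truth = data.table(person_id = character(), age0 = numeric(),
                                   cci = integer(),
                                   frac_time_years = numeric())))
  }

  person_id <- sprintf("P%06d", seq_len(n))
  sex <- ifelse(runif(n) < params$male_share, "male", "female")
  band <- sample.int(5L, n, replace = TRUE, prob = params$age_band_weights)
  age0 <- 50L + (band - 1L) * 10L + sample.int(10L, n, replace = TRUE) - 1L
  birth_year <- as.integer(format(t0, "%Y")) - age0

  # planted comorbidity: independent category draws at the given prevalences
  cats <- names(params$comorbidity)
  has_cat <- matrix(runif(n * length(cats)) <
                      rep(params$comorbidity, each = n), nrow = n)
  colnames(has_cat) <- cats
  # planted score applies the same hierarchy resolution as the scorer
  eff <- has_cat
  for (h in .charlson_hierarchy)
    if (all(h %in% cats))
      eff[, h[["mild"]]] <- eff[, h[["mild"]]] & !eff[, h[["severe"]]]
  cci <- as.integer(eff %*% weights[cats])
  M <- params$cci_hr^cci
  fcci <- params$frac_cci_hr^cci

  # fracture and death times per sex (years from data start)
  t_frac <- rep(Inf, n); t_death <- rep(Inf, n)
  for (s in c("male", "female")) {
    i <- which(sex == s)
    if (!length(i)) next
    tf <- .draw_fracture_time(params$fracture_incidence[[s]],
                              age0[i], fcci[i], horizon)
    g <- .gomp(params, s)
    # pre-fracture death: closed-form Gompertz inversion
    E1 <- rexp(length(i))
    scale <- M[i] * g$b * exp(g$theta * age0[i])
    td <- if (abs(g$theta) < 1e-12) E1 / scale
          else log1p(g$theta * E1 / scale) / g$theta
    pre <- td <= tf
    t_death[i[pre]] <- td[pre]
    t_frac[i[pre]] <- Inf
    post <- which(!pre)
    if (length(post)) {
      j <- i[post]
      t_frac[j] <- tf[post]
      # residual death time from the fracture-multiplied hazard (memoryless)
      u <- .invert_cum_hazard(params, s, age0[j] + tf[post], M[j],
                              rexp(length(j)), exposed = TRUE)
      t_death[j] <- tf[post] + u
    }
  }

  death_date <- t0 + floor(t_death * 365.25)
  death_date[!is.finite(t_death) | death_date > params$closure_date] <- NA
  coverage_end <- pmin(params$closure_date, death_date, na.rm = TRUE)
  persons <- data.table(person_id, sex, birth_year, death_date,
                        coverage_start = t0, coverage_end)

  last_day <- fifelse(is.na(death_date), params$closure_date, death_date)

  claims <- list()

  # fracture claims (inpatient, S72.x primary, true categories as secondary)
  fx <- which(is.finite(t_frac) & t_frac < t_death)
  if (length(fx)) {
    fdate <- t0 + floor(t_frac[fx] * 365.25)
    code <- c("S72.0", "S72.1", "S72.2")[
      sample.int(3L, length(fx), replace = TRUE,
                 prob = params$s72_props / sum(params$s72_props))]
    sec <- lapply(fx, function(i) {
      cc <- cats[has_cat[i, ]]
      cc[runif(length(cc)) < params$index_secondary_prob]
    })
    sec <- lapply(sec, function(cc) unname(vapply(cc, .example_code_for, "")))
    claims$fracture <- data.table(
      person_id = person_id[fx], service_date = fdate,
      setting = "inpatient", primary_dx = code, secondary_dx = sec,
      specialty = "traumatology")
  }

  # recurring comorbidity evidence, per (person, true category, year)
  pc <- which(has_cat, arr.ind = TRUE)
  if (nrow(pc)) {
    years <- seq(as.integer(format(t0, "%Y")),
                 as.integer(format(params$closure_date, "%Y")))
    per_year <- lapply(years, function(y) {
      emit <- runif(nrow(pc)) < params$p_claim_year
      if (!any(emit)) return(NULL)
      i <- pc[emit, 1]; cat_i <- cats[pc[emit, 2]]
      inpt <- runif(length(i)) < params$p_inpatient
      d1 <- as.Date(sprintf("%d-01-01", y)) +
        sample.int(330L, length(i), replace = TRUE) - 1L
      code <- unname(vapply(cat_i, .example_code_for, ""))
      one <- data.table(person_id = person_id[i], service_date = d1,
                        setting = fifelse(inpt, "inpatient", "outpatient"),
                        primary_dx = code,
                        secondary_dx = vector("list", length(i)),
                        specialty = "internal medicine")
      # outpatient evidence needs a second visit >= 7 days later
      rep2 <- which(!inpt)
      if (length(rep2)) {
        gap <- 7L + sample.int(54L, length(rep2), replace = TRUE) - 1L
        two <- one[rep2]
        two[, service_date := service_date + gap]
        one <- rbind(one, two)
      }
      one
    })
    claims$comorbidity <- rbindlist(per_year)
  }

  # decoy categories: insufficient outpatient patterns, emitted once ever
  dk <- which(runif(n) < params$decoy_rate)
  if (length(dk) && length(cats)) {
    dcat <- vapply(dk, function(i) {
      free <- cats[!has_cat[i, ]]
      if (length(free)) sample(free, 1L) else NA_character_
    }, character(1))
    ok <- !is.na(dcat)
    dk <- dk[ok]; dcat <- dcat[ok]
    if (length(dk)) {
      d1 <- t0 + sample.int(4200L, length(dk), replace = TRUE) - 1L
      code <- unname(vapply(dcat, .example_code_for, ""))
      one <- data.table(person_id = person_id[dk], service_date = d1,
                        setting = "outpatient", primary_dx = code,
                        secondary_dx = vector("list", length(dk)),
                        specialty = "internal medicine")
      pair <- which(runif(length(dk)) < 0.5)
      if (length(pair)) {
        two <- one[pair]
        two[, service_date := service_date +
              sample.int(6L, length(pair), replace = TRUE)]
        one <- rbind(one, two)
      }
      claims$decoy <- one
    }
  }

  # non-Charlson background claims
  if (params$noise_rate > 0) {
    n_noise <- rbinom(1L, n * 12L, params$noise_rate / 12)
    if (n_noise > 0) {
      i <- sample.int(n, n_noise, replace = TRUE)
      noise_codes <- c("I10", "Z00.0", "M16.9", "J06.9", "K21.9", "H52.4")
      claims$noise <- data.table(
        person_id = person_id[i],
        service_date = t0 + sample.int(4500L, n_noise, replace = TRUE) - 1L,
        setting = "outpatient",
        primary_dx = sample(noise_codes, n_noise, replace = TRUE),
        secondary_dx = vector("list", n_noise),
        specialty = "family medicine")
    }
  }

  claims <- rbindlist(claims, use.names = TRUE)
  if (!nrow(claims)) claims <- empty_claims
  if (nrow(claims)) {
    # clamp to the person's observable window
    last <- last_day[match(claims$person_id, person_id)]
    claims <- claims[service_date >= t0 & service_date <= last]
    setorder(claims, person_id, service_date)
  }

  truth <- data.table(person_id, sex, age0 = as.numeric(age0), cci,
                      frac_time_years = fifelse(is.finite(t_frac) &
                                                  t_frac < t_death,
                                                t_frac, NA_real_))
  list(persons = persons, claims = claims, truth = truth)
}

# one representative ICD-10 code per Charlson category, used when the
# simulator emits claims
.example_codes <- c(
  myocardial_infarction = "I21.9",
  congestive_heart_failure = "I50.0",
  peripheral_vascular_disease = "I70.2",
  cerebrovascular_disease = "I63.9",
  dementia = "F03",
  chronic_pulmonary_disease = "J44.9",
  rheumatic_disease = "M05.9",
  peptic_ulcer_disease = "K25.9",
  mild_liver_disease = "K74.6",
  diabetes_without_complication = "E11.9",
  diabetes_with_complication = "E11.5",
  hemiplegia_paraplegia = "G81.9",
  renal_disease = "N18.9",
  any_malignancy = "C34.9",
  moderate_severe_liver_disease = "K72.9",
  metastatic_solid_tumour = "C78.0",
  aids_hiv = "B20")

.example_code_for <- function(category) {
  code <- .example_codes[[category]]
  if (is.null(code)) stop("no example code for category ", category)
  code
}

#' Write a simulated population as a persons.csv / claims.csv pair
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
simulate_to_dir <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_persons(sim$persons, file.path(dir, "persons.csv"))
  write_claims(sim$claims, file.path(dir, "claims.csv"))
  invisible(dir)
}
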