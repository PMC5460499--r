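HIP_FRACTURE_PREFIXES <- c("S72.0", "S72.1", "S72.2")

.is_hip_fracture_code <- function(code) {
  code <- as.character(code)  # list entries may be NULL (no secondary dx)
  out <- rep(FALSE, length(code))
  for (p in HIP_FRACTURE_PREFIXES) out <- out | startsWith(code, p)
  out
}

#' Ascertain incident hip-fracture cases
#'
#' A case is a person's first inpatient claim carrying a hip-fracture code
#' (S72.0 femoral neck, S72.1 pertrochanteric, S72.2 subtrochanteric) as the
#' *primary* diagnosis, dated inside the enrolment window, at or above the
#' minimum age, with no hip-fracture claim of any kind (primary or
#' secondary, any setting) anywhere earlier in the claims history. The index
#' date is the claim's first day of care.
#'
#' @param claims,persons validated tables.
#' @param enrol_start,enrol_end enrolment window (dates).
#' @param min_age minimum age in completed calendar years (index year minus
#'   birth year).
#' @return `data.table` of case index events: `person_id, index_date, arm,
#'   matched_set_id, sex, birth_year, age_at_index`. Exclusion counts are
#'   attached as attribute `"exclusions"`.
#' @export
find_incident_fractures <- function(claims, persons,
                                    enrol_start = as.Date("2005-01-01"),
                                    enrol_end = as.Date("2013-12-31"),
                                    min_age = 50L) {
  claims <- as.data.table(claims)
  persons <- as.data.table(persons)
  enrol_start <- as.Date(enrol_start); enrol_end <- as.Date(enrol_end)

  # any hip-fracture mention (primary or secondary) -> earliest such date
  prim_hit <- .is_hip_fracture_code(claims$primary_dx)
  sec_hit <- vapply(claims$secondary_dx,
                    function(v) any(.is_hip_fracture_code(v)), logical(1))
  any_hit <- claims[prim_hit | sec_hit,
                    list(first_any = min(service_date)), by = person_id]

  cand <- claims[prim_hit & setting == "inpatient",
                 list(index_date = min(service_date)), by = person_id]
  n0 <- nrow(cand)
  cand <- merge(cand, any_hit, by = "person_id", all.x = TRUE)
  non_incident <- cand[first_any < index_date | is.na(match(person_id, persons$person_id))]
  cand <- cand[first_any >= index_date]
  cand <- merge(cand, persons[, list(person_id, sex, birth_year)],
                by = "person_id")
  n_prior <- n0 - nrow(cand)
  out_window <- cand[index_date < enrol_start | index_date > enrol_end]
  cand <- cand[index_date >= enrol_start & index_date <= enrol_end]
  cand[, age_at_index := as.integer(format(index_date, "%Y")) - birth_year]
  under_age <- cand[age_at_index < min_age]
  cand <- cand[age_at_index >= min_age]

  setorder(cand, person_id)
  cand[, `:=`(arm = "case", matched_set_id = seq_len(.N), first_any = NULL)]
  setcolorder(cand, c("person_id", "index_date", "arm", "matched_set_id",
                      "sex", "birth_year", "age_at_index"))
  data.table::setattr(cand, "exclusions", c(prior_fracture_or_unlinked = n_prior,
                                outside_window = nrow(out_window),
                                under_age = nrow(under_age)))
  cand[]
}

#' Match reference subjects to cases
#'
#' For each case, samples without replacement (globally across the run — a
#' person serves as a reference at most once) up to `ratio` persons of the
#' same sex and birth year who, at the case's index date, are alive, inside
#' their coverage window, and have no hip-fracture claim dated on or before
#' that date. References inherit the case's index date. Candidate order is
#' randomized by the run seed. Cases are processed in index-date order so
#' that eligibility at the index date is evaluated consistently.
#'
#' @param cases case table from [find_incident_fractures()].
#' @param persons person table.
#' @param claims claims table (used to exclude candidates with fracture
#'   history).
#' @param ratio references per case (default 4).
#' @param seed integer seed controlling the sampling.
#' @return `data.table` of case + reference index events (same columns as
#'   the case table); short matched sets are counted in attribute
#'   `"short_sets"`.
#' @export
match_references <- function(cases, persons, claims, ratio = 4L, seed = 1L) {
  cases <- as.data.table(cases)
  persons <- as.data.table(persons)
  claims <- as.data.table(claims)

  prim_hit <- .is_hip_fracture_code(claims$primary_dx)
  sec_hit <- vapply(claims$secondary_dx,
                    function(v) any(.is_hip_fracture_code(v)), logical(1))
  first_frac <- claims[prim_hit | sec_hit,
                       list(first_frac = min(service_date)), by = person_id]
  pool <- merge(persons, first_frac, by = "person_id", all.x = TRUE)

  rng <- .with_seed(seed)
  on.exit(rng())

  # a person serves as a reference at most once (global sampling without
  # replacement), but someone who fractures *after* an index date may stand
  # as a reference for that set and still found their own later case record
  used <- new.env(hash = TRUE, parent = emptyenv())

  strata <- split(pool, by = c("sex", "birth_year"))
  key_of <- function(s, b) paste(s, b, sep = ".")

  ord <- order(cases$index_date, cases$matched_set_id)
  refs <- vector("list", nrow(cases))
  short <- 0L
  for (k in seq_along(ord)) {
    i <- ord[k]
    st <- strata[[key_of(cases$sex[i], cases$birth_year[i])]]
    idate <- cases$index_date[i]
    if (!is.null(st)) {
      elig <- st[coverage_start <= idate & coverage_end >= idate &
                   (is.na(death_date) | death_date > idate) &
                   (is.na(first_frac) | first_frac > idate)]
      elig <- elig[!vapply(person_id, exists, logical(1), envir = used)]
    } else elig <- pool[0]
    n_take <- min(ratio, nrow(elig))
    if (n_take < ratio) short <- short + 1L
    if (n_take > 0L) {
      take <- elig[sample.int(nrow(elig), n_take)]
      for (p in take$person_id) assign(p, TRUE, envir = used)
      refs[[i]] <- data.table(
        person_id = take$person_id, index_date = idate, arm = "reference",
        matched_set_id = cases$matched_set_id[i], sex = take$sex,
        birth_year = take$birth_year,
        age_at_index = as.integer(format(idate, "%Y")) - take$birth_year)
    }
  }
  out <- rbind(cases, rbindlist(refs))
  setorder(out, matched_set_id, arm)
  data.table::setattr(out, "short_sets", short)
  out[]
}

# run expr under a local RNG state seeded with `seed`; returns a restore fn
.with_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Follow-up and censoring bookkeeping
#'
#' Follow-up runs from the index date until death or the study closure date,
#' whichever comes first. Duration is expressed in months of 365.25/12 days.
#' A subject dying on the index date receives a minimum duration of half a
#' day.
#'
#' @param index_events case + reference table.
#' @param persons person table (supplies death dates).
#' @param closure_date administrative end of follow-up.
#' @return the input table with `end_date`, `event` (`"death"`/`"censored"`)
#'   and `duration_months` appended.
#' @export
build_follow_up <- function(index_events, persons,
                            closure_date = as.Date("2016-05-04")) {
  ev <- copy(as.data.table(index_events))
  persons <- as.data.table(persons)
  closure_date <- as.Date(closure_date)
  dd <- persons$death_date[match(ev$person_id, persons$person_id)]
  bad <- !is.na(dd) & dd < ev$index_date
  if (any(bad))
    stop("death before index date for person(s): ",
         paste(head(ev$person_id[bad], 5L), collapse = ", "), call. = FALSE)
  died <- !is.na(dd) & dd <= closure_date
  ev[, end_date := fifelse(died, dd, closure_date)]
  ev[, event := fifelse(died, "death", "censored")]
  ev[, duration_months := as.numeric(end_date - index_date) / DAYS_PER_MONTH]
  ev[duration_months <= 0, duration_months := 0.5 / DAYS_PER_MONTH]
  ev[]
}

#' Build the full matched cohort from raw tables
#'
#' Driver chaining case ascertainment, reference matching, Charlson scoring
#' and follow-up bookkeeping.
#'
#' @inheritParams find_incident_fractures
#' @inheritParams match_references
#' @inheritParams build_follow_up
#' @param weights Charlson weight vector.
#' @param score compute Charlson scores (default `TRUE`); skipping them
#'   (`FALSE`, scores set to 0) saves time when only the crude model is
#'   needed.
#' @return cohort `data.table`: one row per subject with
#'   `person_id, arm, matched_set_id, index_date, sex, birth_year,
#'   age_at_index, cci_score, end_date, event, duration_months`.
#' @export
build_cohort <- function(persons, claims,
                         ratio = 4L, min_age = 50L,
                         enrol_start = as.Date("2005-01-01"),
                         enrol_end = as.Date("2013-12-31"),
                         closure_date = as.Date("2016-05-04"),
                         seed = 1L,
                         weights = charlson_weights(),
                         score = TRUE) {
  cases <- find_incident_fractures(claims, persons, enrol_start, enrol_end,
                                   min_age)
  matched <- match_references(cases, persons, claims, ratio = ratio,
                              seed = seed)
  matched[, cci_score := if (score) score_cohort(matched, claims,
                                                 weights = weights) else 0L]
  fu <- build_follow_up(matched, persons, closure_date)
  setcolorder(fu, c("person_id", "arm", "matched_set_id", "index_date",
                    "sex", "birth_year", "age_at_index", "cci_score",
                    "end_date", "event", "duration_months"))
  fu[]
}
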