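#' Analytic cumulative risk under the planted hazards
#'
#' Evaluates `CR(t) = 1 - exp(-integral of the planted hazard)` for a
#' subject of given sex, exact age at index and Charlson score, with or
#' without the fracture multiplier applied from the index onward. The
#' Gompertz-times-exponential integrand has a closed antiderivative, so the
#' integral is evaluated exactly; the test suite checks it against a
#' fine-grid Riemann-sum oracle.
#'
#' @param params a [sim_params()] object.
#' @param exposed logical: apply the fracture effect from time 0.
#' @param sex `"male"` or `"female"`.
#' @param age exact age in years at the index date (vectorized).
#' @param cci Charlson score (vectorized).
#' @param t_months horizon in months (scalar or vectorized with `age`).
#' @return probability vector.
#' @export
true_cumulative_risk <- function(params, exposed, sex, age, cci, t_months) {
  if (any(t_months < 0)) stop("t_months must be non-negative", call. = FALSE)
  u <- t_months / 12
  M <- params$cci_hr^cci
  1 - exp(-.cum_hazard(params, sex, age, M, u, exposed = exposed))
}

#' Analytic effect measures for a realized cohort
#'
#' The estimand of the matched analysis at horizon `t`: the exposed risk is
#' the mean of per-subject true exposed risks over the case arm, the
#' reference risk the mean of true unexposed risks over the reference arm
#' (both conditional on being alive at the index date, which the planted
#' hazards encode by integrating forward from the index age). Excess risk,
#' risk ratio and attributable fraction follow by their defining identities.
#'
#' The reference arm keeps subjects who fracture after the index date, so
#' its truth is by default the two-state [true_reference_risk()]; set
#' `future_fractures = FALSE` for the pure no-fracture counterfactual.
#'
#' @param params simulation parameters.
#' @param covariates table with `arm`, `sex`, `age` (exact, years), `cci`.
#' @param horizons_months numeric vector of horizons.
#' @param future_fractures account for post-index fractures in the
#'   reference arm (default `TRUE`).
#' @return `data.table`: one row per horizon with true risks and measures
#'   (risks and excess in percentage points).
#' @export
true_effects <- function(params, covariates, horizons_months,
                         future_fractures = TRUE) {
  cv <- as.data.table(covariates)
  rbindlist(lapply(horizons_months, function(t) {
    # grouped by sex because the hazard parameters are scalar per sex
    cr_e <- cv[arm == "case",
               list(cr = true_cumulative_risk(params, TRUE, sex[1], age, cci, t)),
               by = sex][, mean(cr)]
    cr_r <- if (future_fractures) {
      cv[arm == "reference",
         list(cr = true_reference_risk(params, sex[1], age, cci, t)),
         by = sex][, mean(cr)]
    } else cv[arm == "reference",
              list(cr = true_cumulative_risk(params, FALSE, sex[1], age, cci, t)),
              by = sex][, mean(cr)]
    data.table(horizon_months = t,
               cr_exposed = 100 * cr_e, cr_reference = 100 * cr_r,
               excess_risk = 100 * (cr_e - cr_r),
               risk_ratio = cr_e / cr_r,
               attributable_fraction = (cr_e - cr_r) / cr_e)
  }))
}

#' Side-by-side truth versus estimate table
#'
#' @param truth output of [true_effects()].
#' @param estimates `data.table` with `horizon_months` and the same measure
#'   columns (`cr_exposed`, `cr_reference`, `excess_risk`, `risk_ratio`,
#'   `attributable_fraction`).
#' @return long `data.table`: `(horizon_months, measure, truth, estimate,
#'   abs_error, rel_error)`.
#' @export
recovery_report <- function(truth, estimates) {
  measures <- c("cr_exposed", "cr_reference", "excess_risk", "risk_ratio",
                "attributable_fraction")
  tr <- data.table::melt(as.data.table(truth), id.vars = "horizon_months",
                         measure.vars = measures, variable.name = "measure",
                         value.name = "truth")
  es <- data.table::melt(as.data.table(estimates), id.vars = "horizon_months",
                         measure.vars = measures, variable.name = "measure",
                         value.name = "estimate")
  out <- merge(tr, es, by = c("horizon_months", "measure"))
  out[, abs_error := abs(estimate - truth)]
  out[, rel_error := abs_error / abs(truth)]
  setorder(out, horizon_months, measure)
  out[]
}

#' Exact covariates of a simulated cohort for truth evaluation
#'
#' Joins the simulator's hidden truth table onto a built cohort, recovering
#' each subject's exact (fractional) age at the index date and planted
#' Charlson score.
#'
#' @param cohort cohort table from [build_cohort()].
#' @param sim result of [simulate_cohort()] the cohort was built from.
#' @return `data.table` with `arm`, `sex`, `age`, `cci` per cohort row.
#' @export
cohort_truth_covariates <- function(cohort, sim) {
  co <- as.data.table(cohort)
  tr <- sim$truth
  i <- match(co$person_id, tr$person_id)
  t0 <- as.Date(sim$persons$coverage_start[1])
  data.table(arm = co$arm, sex = co$sex,
             age = tr$age0[i] +
               as.numeric(as.Date(co$index_date) - t0) / 365.25,
             cci = tr$cci[i])
}

# cumulative first-fracture hazard over u years from exact age `age`
# (piecewise-constant over age decades, per-point incidence multiplier fcci)
.cum_frac_hazard <- function(params, sex, age, fcci, u) {
  rates5 <- params$fracture_incidence[[sex]]
  lo <- 50 + 10 * (0:4)
  hi <- c(lo[-1], Inf)
  out <- 0
  for (j in 1:5) {
    ov <- pmax(0, pmin(age + u, hi[j]) - pmax(age, lo[j]))
    out <- out + rates5[j] * ov
  }
  out * fcci
}

.frac_rate_at <- function(params, sex, age, fcci) {
  band <- pmin(pmax(floor((age - 50) / 10) + 1, 1), 5)
  params$fracture_incidence[[sex]][band] * fcci
}

#' True reference-arm risk allowing for post-index fractures
#'
#' A matched reference subject is fracture-free at the index date but may
#' fracture later and then carries the multiplied death hazard — the study
#' design keeps such subjects in the reference arm. The reference-arm truth
#' is therefore a two-state quantity: survival equals the fracture-free
#' survival plus the integral, over possible fracture times `s`, of
#' (probability of reaching `s` alive and unfractured) x (fracture rate at
#' `s`) x (post-fracture survival from `s` to the horizon). The time
#' integral is evaluated by Simpson quadrature on a fine grid; all hazard
#' integrals are closed-form.
#'
#' @inheritParams true_cumulative_risk
#' @param n_nodes quadrature nodes (odd; default 401).
#' @return probability vector of death by `t_months`.
#' @export
true_reference_risk <- function(params, sex, age, cci, t_months,
                                n_nodes = 401L) {
  if (t_months < 0) stop("t_months must be non-negative", call. = FALSE)
  t <- t_months / 12
  M <- params$cci_hr^cci
  fcci <- params$frac_cci_hr^cci
  if (t == 0) return(rep(0, length(age)))
  s_nodes <- seq(0, t, length.out = n_nodes)
  wts <- .simpson_weights(n_nodes) * (t / (n_nodes - 1))
  integrand <- vapply(s_nodes, function(s) {
    reach <- exp(-.cum_hazard(params, sex, age, M, s, exposed = FALSE) -
                   .cum_frac_hazard(params, sex, age, fcci, s))
    phi <- .frac_rate_at(params, sex, age + s, fcci)
    surv_post <- exp(-.cum_hazard(params, sex, age + s, M, t - s,
                                  exposed = TRUE))
    reach * phi * surv_post
  }, numeric(length(age)))
  if (length(age) == 1L) integrand <- matrix(integrand, nrow = 1)
  S_nofrac <- exp(-.cum_hazard(params, sex, age, M, t, exposed = FALSE) -
                    .cum_frac_hazard(params, sex, age, fcci, t))
  S <- S_nofrac + as.vector(integrand %*% wts)
  1 - S
}

.simpson_weights <- function(n) {
  stopifnot(n %% 2L == 1L, n >= 3L)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1; w[n] <- 1
  w / 3
}
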