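#' Chain interval rates into a cumulative risk curve
#'
#' Under the piecewise-exponential model the probability of death inside
#' interval `i`, given survival to its start, is
#' `p_i = 1 - exp(-rate_i * width_i)`; the cumulative risk at cut point
#' `t_k` is `1 - prod_{i<=k} (1 - p_i)`. Undefined rates (cells with zero
#' person-time) are skipped with a warning — they contribute no mortality.
#'
#' @param rates numeric vector, one rate (deaths per person-month) per grid
#'   interval; `NA` marks an undefined cell.
#' @param grid the matching [build_grid()].
#' @return numeric vector of cumulative risks at each cut point, in `[0,1]`
#'   and non-decreasing.
#' @export
rates_to_risk <- function(rates, grid = build_grid()) {
  w <- interval_widths(grid)
  if (length(rates) != length(w))
    stop("need one rate per grid interval", call. = FALSE)
  if (any(rates < 0, na.rm = TRUE))
    stop("negative rate", call. = FALSE)
  if (anyNA(rates)) {
    warning(sum(is.na(rates)),
            " interval(s) with undefined rate skipped in risk chaining")
    rates[is.na(rates)] <- 0
  }
  p <- 1 - exp(-rates * w)
  1 - cumprod(1 - p)
}

#' Risk curves for both arms from crude rates
#'
#' @param crude output of [fit_crude()] on cells grouped by `arm` x
#'   `interval` (optionally within one stratum).
#' @param grid the interval grid.
#' @return `data.table`: `arm, cut_point_months, cumulative_risk`.
#' @export
crude_risk_curves <- function(crude, grid = build_grid()) {
  cp <- as.numeric(grid)
  crude <- as.data.table(crude)
  rbindlist(lapply(split(crude, by = "arm"), function(d) {
    # intervals beyond the last one entered are structurally empty: rate 0
    r <- numeric(length(cp))
    r[d$interval] <- d$rate
    data.table(arm = d$arm[1], cut_point_months = cp,
               cumulative_risk = rates_to_risk(r, grid))
  }))
}

#' Marginally standardized risk curves from an adjusted fit
#'
#' Predicts interval rates for every covariate pattern of the standard
#' population (by convention the case arm's observed `(age, cci)` patterns)
#' under each arm in turn, chains each pattern's interval death
#' probabilities into its cumulative risk curve, and averages the curves
#' across patterns (model-based standardization / g-computation: the
#' standardized risk is the mean of per-pattern risks, so population
#' survival is the mean of pattern survival). Both arms standardized to the
#' case distribution makes the excess-risk contrast an exposed-standardized
#' (attributable) one.
#'
#' @param fit an `"adjusted_fit"`.
#' @param standard data with `age_at_index` and `cci_score` columns (one row
#'   per subject of the standard population).
#' @return `data.table`: `arm, cut_point_months, cumulative_risk`.
#' @export
standardize <- function(fit, standard) {
  std <- as.data.table(standard)
  if (!nrow(std)) stop("empty standard population", call. = FALSE)
  cp <- as.numeric(fit$grid)
  w <- interval_widths(fit$grid)
  # collapse duplicated covariate patterns, keep multiplicity weights
  pat <- std[, list(n = .N), by = list(age_at_index, cci_score)]
  rbindlist(lapply(c("case", "reference"), function(a) {
    lam <- predict_rates(fit, a, pat$age_at_index, pat$cci_score)
    logs <- -sweep(lam, 2, w, `*`)           # log interval survival
    Scum <- exp(t(apply(logs, 1, cumsum)))   # per-pattern survival curve
    cr <- 1 - colSums(Scum * pat$n) / sum(pat$n)
    data.table(arm = a, cut_point_months = cp, cumulative_risk = cr)
  }))
}

#' Weighted aggregation of stratum risk curves
#'
#' Point-wise weighted mean of per-stratum curves, weights normalized; the
#' convention is to weight by case-group stratum sizes.
#'
#' @param curves `data.table` with `stratum, arm, cut_point_months,
#'   cumulative_risk`.
#' @param weights named numeric vector: one weight per stratum.
#' @return `data.table` with `arm, cut_point_months, cumulative_risk`
#'   (stratum = `"overall"`).
#' @export
aggregate_curves <- function(curves, weights) {
  cv <- as.data.table(curves)
  if (!all(unique(cv$stratum) %in% names(weights)))
    stop("every stratum needs a weight", call. = FALSE)
  grids <- cv[, list(g = list(sort(unique(cut_point_months)))), by = stratum]
  if (length(unique(vapply(grids$g, paste, character(1), collapse = ","))) > 1L)
    stop("mismatched grids across strata", call. = FALSE)
  cv[, weight := weights[stratum]]
  out <- cv[, list(cumulative_risk = sum(cumulative_risk * weight) / sum(weight)),
            by = list(arm, cut_point_months)]
  out[, stratum := "overall"]
  setcolorder(out, c("arm", "stratum", "cut_point_months", "cumulative_risk"))
  out[]
}

#' Read a risk value off a curve at a horizon
#'
#' @param curve `data.table` with `cut_point_months`, `cumulative_risk` (one
#'   arm).
#' @param horizon_months a cut point of the grid.
#' @return the cumulative risk at that horizon.
#' @export
risk_at <- function(curve, horizon_months) {
  i <- which(abs(curve$cut_point_months - horizon_months) < 1e-9)
  if (!length(i)) stop("horizon ", horizon_months,
                       " is not a grid cut point", call. = FALSE)
  curve$cumulative_risk[i[1]]
}
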