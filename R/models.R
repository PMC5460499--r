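#' Crude piecewise-exponential rates
#'
#' The crude model is saturated in arm x interval (main effects of both
#' plus their interaction, log person-time offset), so its fitted rates
#' equal cell-wise `deaths / person_months`; the closed form is used
#' directly, with the iteratively fitted Poisson model kept as an oracle in
#' the test suite. Cells with zero person-time carry an undefined (`NA`)
#' rate and are skipped, with a warning, when risks are chained.
#'
#' @param cells exposure cells from [exposure_cells()] aggregated at least
#'   by `arm` and `interval` (extra grouping columns are retained).
#' @return the cells with a `rate` column (deaths per person-month).
#' @export
fit_crude <- function(cells) {
  out <- copy(as.data.table(cells))
  out[, rate := fifelse(person_months > 0, deaths / person_months, NA_real_)]
  out[]
}

#' Adjusted piecewise-exponential Poisson model
#'
#' Log-linear Poisson model on subject-interval person-time with main
#' effects of hip fracture, Charlson score, age and follow-up interval, the
#' interactions fracture x interval, fracture x CCI, fracture x age and
#' interval x age, and the log of interval person-time as offset. Age enters
#' centred at its person-time-weighted mean; CCI enters as an integer-valued
#' linear covariate truncated at 10. Rows are aggregated over identical
#' covariate patterns before fitting (the Poisson likelihood is additive, so
#' the fit is unchanged).
#'
#' @param split subject-interval rows from [split_person_time()] carrying
#'   `age_at_index` and `cci_score`.
#' @param grid the interval grid the split was computed on.
#' @return object of class `"adjusted_fit"`: the `glm` fit plus the age
#'   centring constant and grid.
#' @export
fit_adjusted <- function(split, grid = build_grid()) {
  dat <- as.data.table(split)[time_months > 0]
  dat <- dat[, list(deaths = sum(death), person_months = sum(time_months)),
             by = list(arm, interval, age_at_index,
                       cci = pmin(cci_score, 10L))]
  age_center <- dat[, sum(age_at_index * person_months) / sum(person_months)]
  dat[, `:=`(frac = as.integer(arm == "case"),
             age_c = age_at_index - age_center,
             interval = factor(interval, levels = seq_along(as.numeric(grid))))]
  fit <- glm(deaths ~ frac + cci + age_c + interval +
               frac:interval + frac:cci + frac:age_c + interval:age_c +
               offset(log(person_months)),
             family = poisson(), data = dat,
             control = list(epsilon = 1e-10, maxit = 100))
  if (!fit$converged)
    stop("adjusted Poisson model did not converge; last deviance ",
         format(fit$deviance), call. = FALSE)
  structure(list(glm = fit, age_center = age_center, grid = grid),
            class = "adjusted_fit")
}

#' @export
print.adjusted_fit <- function(x, ...) {
  cat(sprintf("<adjusted_fit> %d coefficients, deviance %.2f, age centred at %.1f\n",
              length(coef(x$glm)), x$glm$deviance, x$age_center))
  invisible(x)
}

#' Predict interval-specific rates from an adjusted fit
#'
#' @param fit an `"adjusted_fit"`.
#' @param arm `"case"` or `"reference"` (the fracture indicator).
#' @param age,cci covariate values (vectors of equal length, recycled).
#' @return matrix of rates (deaths per person-month), one row per covariate
#'   pattern, one column per grid interval.
#' @export
predict_rates <- function(fit, arm, age, cci) {
  K <- length(as.numeric(fit$grid))
  pat <- data.table(age = age, cci = pmin(cci, 10L))
  nd <- pat[rep(seq_len(nrow(pat)), each = K)]
  nd[, `:=`(interval = factor(rep(seq_len(K), nrow(pat)), levels = seq_len(K)),
            frac = as.integer(arm == "case"),
            person_months = 1)]
  nd[, age_c := age - fit$age_center]
  lam <- predict(fit$glm, newdata = nd, type = "response")
  matrix(lam, nrow = nrow(pat), ncol = K, byrow = TRUE)
}
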