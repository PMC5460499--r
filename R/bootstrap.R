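#' Bias-corrected and percentile bootstrap intervals
#'
#' `bc_interval()` implements the bias-corrected (BC, no acceleration)
#' percentile method: with `z0 = qnorm(F_boot(theta_hat))` the interval
#' endpoints are the bootstrap quantiles at `pnorm(2*z0 + qnorm(alpha/2))`
#' and `pnorm(2*z0 + qnorm(1 - alpha/2))`. `percentile_interval()` is the
#' plain quantile method. Used for cumulative/excess risks (BC) and risk
#' ratios (percentile) respectively.
#'
#' @param boot numeric vector of bootstrap replicate statistics.
#' @param theta_hat point estimate on the original data.
#' @param conf confidence level.
#' @return length-2 numeric vector `(low, high)`.
#' @export
bc_interval <- function(boot, theta_hat, conf = 0.95) {
  boot <- boot[is.finite(boot)]
  alpha <- 1 - conf
  if (all(boot == boot[1])) return(c(boot[1], boot[1]))
  # median-bias constant; ties split, proportion clamped away from 0/1
  pr <- (sum(boot < theta_hat) + 0.5 * sum(boot == theta_hat)) / length(boot)
  pr <- min(max(pr, 0.5 / length(boot)), 1 - 0.5 / length(boot))
  z0 <- qnorm(pr)
  a1 <- pnorm(2 * z0 + qnorm(alpha / 2))
  a2 <- pnorm(2 * z0 + qnorm(1 - alpha / 2))
  unname(quantile(boot, c(a1, a2), type = 6))
}

#' @rdname bc_interval
#' @export
percentile_interval <- function(boot, conf = 0.95) {
  boot <- boot[is.finite(boot)]
  alpha <- 1 - conf
  if (all(boot == boot[1])) return(c(boot[1], boot[1]))
  unname(quantile(boot, c(alpha / 2, 1 - alpha / 2), type = 6))
}

# Pre-computed per-matched-set exposure: deaths and person-time per
# (set x arm x interval), laid out as matrices so one bootstrap replicate is
# a single cross-product with the set multiplicity vector.
.set_exposure <- function(cohort, grid) {
  sp <- split_person_time(cohort, grid)
  K <- length(as.numeric(grid))
  sets <- sort(unique(cohort$matched_set_id))
  sp[, set_row := match(matched_set_id, sets)]
  sp[, is_case := arm == "case"]
  # accumulate with rowsum on a combined key (faster than matrix indexing loop)
  acc <- function(case, val) {
    d <- sp[is_case == case]
    v <- if (val == "deaths") d$death else d$time_months
    key <- (d$interval - 1L) * length(sets) + d$set_row
    out <- numeric(length(sets) * K)
    s <- rowsum(v, key)
    out[as.integer(rownames(s))] <- s[, 1]
    matrix(out, nrow = length(sets), ncol = K)
  }
  list(sets = sets,
       D_case = acc(TRUE, "deaths"),  T_case = acc(TRUE, "time"),
       D_ref  = acc(FALSE, "deaths"), T_ref  = acc(FALSE, "time"))
}

# crude excess/RR/AF at a horizon from summed deaths/person-time vectors
.crude_measures <- function(Dc, Tc, Dr, Tr, grid, horizon) {
  w <- interval_widths(grid)
  k <- which(abs(as.numeric(grid) - horizon) < 1e-9)[1]
  rate_c <- ifelse(Tc > 0, Dc / Tc, 0)
  rate_r <- ifelse(Tr > 0, Dr / Tr, 0)
  cr_c <- 1 - prod(1 - (1 - exp(-rate_c[1:k] * w[1:k])))
  cr_r <- 1 - prod(1 - (1 - exp(-rate_r[1:k] * w[1:k])))
  c(cr_exposed = cr_c, cr_reference = cr_r,
    excess = cr_c - cr_r,
    rr = if (cr_r > 0) cr_c / cr_r else NA_real_,
    af = if (cr_c > 0) (cr_c - cr_r) / cr_c else NA_real_)
}

#' Bootstrap confidence intervals for the effect measures
#'
#' Resamples matched sets (a case together with its references) with
#' replacement, recomputes cumulative risks at the horizon for each
#' replicate, and forms bias-corrected intervals for the cumulative and
#' excess risks and percentile intervals for the risk ratio (the
#' attributable fraction, a monotone transform of the ratio, also gets the
#' percentile method). The crude model is recomputed in closed form per
#' replicate; the adjusted model is refitted per replicate.
#'
#' @param cohort cohort table from [build_cohort()] (or the simulator).
#' @param horizon_months horizon, must be a grid cut point.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed; results are fully reproducible given it.
#' @param model `"crude"` or `"adjusted"` (adjusted = marginally
#'   standardized to the case arm, considerably slower).
#' @param grid interval grid.
#' @param conf confidence level.
#' @param max_fail_frac abort if more than this fraction of replicates fail.
#' @return `data.table` with one row per measure: point estimate, CI bounds,
#'   CI method, `n_boot`, `seed`. Risks and the excess risk are reported in
#'   percentage points, the ratio and fraction on their natural scales.
#' @export
bootstrap_cis <- function(cohort, horizon_months, n_boot = 1000L, seed = 1L,
                          model = c("crude", "adjusted"),
                          grid = build_grid(), conf = 0.95,
                          max_fail_frac = 0.05) {
  model <- match.arg(model)
  if (n_boot < 200L) stop("n_boot must be at least 200", call. = FALSE)
  cohort <- as.data.table(cohort)

  restore <- .with_seed(seed)
  on.exit(restore())

  if (model == "crude") {
    ex <- .set_exposure(cohort, grid)
    n_sets <- length(ex$sets)
    point <- .crude_measures(colSums(ex$D_case), colSums(ex$T_case),
                             colSums(ex$D_ref), colSums(ex$T_ref),
                             grid, horizon_months)
    stat_one <- function() {
      idx <- sample.int(n_sets, n_sets, replace = TRUE)
      mult <- tabulate(idx, nbins = n_sets)
      .crude_measures(crossprod(ex$D_case, mult), crossprod(ex$T_case, mult),
                      crossprod(ex$D_ref, mult), crossprod(ex$T_ref, mult),
                      grid, horizon_months)
    }
  } else {
    sets <- split(cohort, by = "matched_set_id")
    fit0 <- fit_adjusted(split_person_time(cohort, grid), grid)
    std0 <- cohort[arm == "case"]
    curves0 <- standardize(fit0, std0)
    point <- .std_measures(curves0, horizon_months)
    stat_one <- function() {
      idx <- sample.int(length(sets), length(sets), replace = TRUE)
      boot_cohort <- rbindlist(sets[idx], idcol = NULL)
      fit <- fit_adjusted(split_person_time(boot_cohort, grid), grid)
      .std_measures(standardize(fit, boot_cohort[arm == "case"]),
                    horizon_months)
    }
  }

  boot <- matrix(NA_real_, nrow = n_boot, ncol = 5L,
                 dimnames = list(NULL, names(point)))
  fails <- 0L
  for (b in seq_len(n_boot)) {
    for (try in 1:3) {
      r <- tryCatch(stat_one(), error = function(e) NULL)
      if (!is.null(r)) break
      fails <- fails + 1L
    }
    if (is.null(r)) stop("bootstrap replicate kept failing", call. = FALSE)
    boot[b, ] <- r
  }
  if (fails > max_fail_frac * n_boot)
    stop(sprintf("%d of %d bootstrap replicates failed", fails, n_boot),
         call. = FALSE)

  ci <- rbind(
    cr_exposed = bc_interval(boot[, "cr_exposed"], point["cr_exposed"], conf),
    cr_reference = bc_interval(boot[, "cr_reference"], point["cr_reference"], conf),
    excess = bc_interval(boot[, "excess"], point["excess"], conf),
    rr = percentile_interval(boot[, "rr"], conf),
    af = percentile_interval(boot[, "af"], conf))
  method <- c("bias_corrected", "bias_corrected", "bias_corrected",
              "percentile", "percentile")
  scale <- c(100, 100, 100, 1, 1)  # risks in percentage points
  out <- data.table(
    measure = c("cumulative_risk_exposed", "cumulative_risk_reference",
                "excess_risk", "risk_ratio", "attributable_fraction"),
    horizon_months = horizon_months,
    estimate = unname(point) * scale,
    ci_low = ci[, 1] * scale,
    ci_high = ci[, 2] * scale,
    method = method, n_boot = n_boot, seed = seed)
  cv <- stats::sd(boot[, "rr"], na.rm = TRUE) / mean(boot[, "rr"], na.rm = TRUE)
  attr(out, "rr_unreliable") <- is.finite(cv) && cv > 0.5
  out[]
}

.std_measures <- function(curves, horizon) {
  cr_c <- risk_at(curves[curves$arm == "case", ], horizon)
  cr_r <- risk_at(curves[curves$arm == "reference", ], horizon)
  c(cr_exposed = cr_c, cr_reference = cr_r, excess = cr_c - cr_r,
    rr = if (cr_r > 0) cr_c / cr_r else NA_real_,
    af = if (cr_c > 0) (cr_c - cr_r) / cr_c else NA_real_)
}
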