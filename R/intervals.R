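#' Graduated follow-up interval grid
#'
#' The default grid places cut-points densely where post-fracture mortality
#' changes fastest and widens them later: every 0.5 months up to 3, every
#' month up to 12, every 3 months up to 24, every 6 months up to 48, and
#' every 12 months up to 120. Intervals are the half-open spans between
#' consecutive cut-points, the first starting at 0.
#'
#' @param cut_points_months optional custom strictly increasing positive cut
#'   points (months).
#' @return numeric vector of cut points with class `"interval_grid"`.
#' @export
build_grid <- function(cut_points_months = NULL) {
  if (is.null(cut_points_months))
    cut_points_months <- c(seq(0.5, 3, by = 0.5), seq(4, 12, by = 1),
                           seq(15, 24, by = 3), seq(30, 48, by = 6),
                           seq(60, 120, by = 12))
  cp <- as.numeric(cut_points_months)
  if (length(cp) < 1L || any(!is.finite(cp)) || cp[1] <= 0 ||
      any(diff(cp) <= 0))
    stop("cut points must be strictly increasing and positive", call. = FALSE)
  structure(cp, class = "interval_grid")
}

#' @export
print.interval_grid <- function(x, ...) {
  cat(sprintf("<interval_grid> %d intervals over (0, %g] months\n",
              length(x), max(x)))
  invisible(x)
}

interval_widths <- function(grid) diff(c(0, as.numeric(grid)))

#' Split follow-up into interval person-time
#'
#' Each subject contributes the full width to every interval fully survived,
#' a partial width to the interval containing the end of follow-up, and
#' nothing beyond; the death indicator lands in the interval containing the
#' death time. Follow-up beyond the last cut point is truncated (a death
#' after the grid end counts as censored at the grid end). Person-time is
#' conserved exactly: each subject's rows sum to
#' `min(duration, max(grid))` months.
#'
#' @param follow_up cohort rows with at least `arm`, `duration_months`,
#'   `event`; other columns (`person_id`, `matched_set_id`, `sex`,
#'   `age_at_index`, `cci_score`) are carried through when present.
#' @param grid an [build_grid()] object.
#' @return long `data.table`: one row per subject x entered interval with
#'   `interval` (1-based index), `time_months`, `death` (0/1).
#' @export
split_person_time <- function(follow_up, grid = build_grid()) {
  fu <- as.data.table(follow_up)
  cp <- as.numeric(grid)
  lo <- c(0, cp[-length(cp)])
  n <- nrow(fu)
  K <- length(cp)

  dur <- pmin(fu$duration_months, cp[K])
  died <- fu$event == "death" & fu$duration_months <= cp[K]
  # number of intervals entered: smallest k with dur <= cp[k]
  k_end <- findInterval(dur, cp, left.open = TRUE) + 1L
  k_end <- pmin(k_end, K)

  idx <- sequence(k_end)               # interval index within subject
  row <- rep(seq_len(n), k_end)
  time <- pmin(dur[row], cp[idx]) - lo[idx]
  death <- as.integer(died[row] & idx == k_end[row])

  keep <- c("person_id", "arm", "matched_set_id", "sex", "birth_year",
            "age_at_index", "cci_score")
  keep <- intersect(keep, names(fu))
  out <- fu[row, ..keep]
  out[, `:=`(interval = idx, time_months = time, death = death)]
  out[]
}

#' Aggregate split person-time into exposure cells
#'
#' @param split output of [split_person_time()].
#' @param by extra grouping columns beyond `arm` and `interval` (e.g.
#'   `"sex"`, strata).
#' @return `data.table` of cells: grouping columns, `deaths`,
#'   `person_months`, and (when available) `mean_age`, `mean_cci` weighted
#'   by person-time.
#' @export
exposure_cells <- function(split, by = character()) {
  grp <- c("arm", by, "interval")
  has_age <- "age_at_index" %in% names(split)
  has_cci <- "cci_score" %in% names(split)
  cells <- as.data.table(split)[, {
    r <- list(deaths = sum(death), person_months = sum(time_months))
    if (has_age) r$mean_age <- sum(age_at_index * time_months) / sum(time_months)
    if (has_cci) r$mean_cci <- sum(cci_score * time_months) / sum(time_months)
    r
  }, by = grp]
  setorderv(cells, grp)
  cells[]
}
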