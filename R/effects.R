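.check_units <- function(cr_exposed, cr_reference) {
  pe <- cr_exposed > 1; pr <- cr_reference > 1
  if (any(cr_exposed < 0) || any(cr_reference < 0) ||
      any(cr_exposed > 100) || any(cr_reference > 100))
    stop("risks must be proportions in [0,1] or percentages in [0,100]",
         call. = FALSE)
  if (any(xor(pe, pr)))
    stop("mixed units: one risk looks like a percentage, the other like a proportion",
         call. = FALSE)
  invisible(TRUE)
}

#' Excess risk, risk ratio and attributable fraction
#'
#' The three effect measures derived from a pair of cumulative risks.
#' `excess_risk()` is the exposed-minus-reference difference, returned in
#' the unit of its inputs (both proportions or both percentages — mixing is
#' an error). `risk_ratio()` is the exposed/reference ratio.
#' `attributable_fraction()` is the share of exposed-group risk attributable
#' to the exposure, `(exposed - reference) / exposed`, always a unitless
#' proportion; it equals `1 - 1/RR`.
#'
#' @param cr_exposed,cr_reference cumulative risks at a common horizon.
#' @return numeric vector.
#' @export
excess_risk <- function(cr_exposed, cr_reference) {
  .check_units(cr_exposed, cr_reference)
  cr_exposed - cr_reference
}

#' @rdname excess_risk
#' @export
risk_ratio <- function(cr_exposed, cr_reference) {
  .check_units(cr_exposed, cr_reference)
  if (any(cr_reference == 0))
    stop("risk ratio undefined: reference risk is zero", call. = FALSE)
  cr_exposed / cr_reference
}

#' @rdname excess_risk
#' @export
attributable_fraction <- function(cr_exposed, cr_reference) {
  .check_units(cr_exposed, cr_reference)
  if (any(cr_exposed == 0))
    stop("attributable fraction undefined: exposed risk is zero", call. = FALSE)
  (cr_exposed - cr_reference) / cr_exposed
}
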