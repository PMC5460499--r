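#' Charlson condition map and weight tables
#'
#' The 17-category Quan ICD-10 coding algorithm ships as a packaged CSV of
#' `(category, icd10_prefix)` pairs; matching is prefix-based on dotted
#' upper-case codes. Two weight tables are packaged: the updated
#' (2011-revision) weights used by default, and the original 1987 weights
#' for comparability work. Both are plain CSVs under `inst/extdata` and may
#' be replaced by user files of the same layout.
#'
#' @param path optional path to an alternative map/weight CSV.
#' @return `charlson_map()`: a `data.table` with columns `category`,
#'   `icd10_prefix`. `charlson_weights()`: a named integer vector of weights
#'   over the 17 categories.
#' @export
charlson_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "charlson_map.csv", package = "fracexcess")
  fread(path, colClasses = list(character = c("category", "icd10_prefix")))
}

#' @rdname charlson_map
#' @param weights `"updated"` (default) or `"original"`; ignored when `path`
#'   is given.
#' @export
charlson_weights <- function(weights = c("updated", "original"), path = NULL) {
  if (is.null(path)) {
    weights <- match.arg(weights)
    path <- system.file("extdata",
                        sprintf("charlson_weights_%s.csv", weights),
                        package = "fracexcess")
  }
  w <- fread(path)
  setNames(as.integer(w$weight), w$category)
}

# hierarchy pairs: when both members are present only the severer one scores
.charlson_hierarchy <- list(
  c(mild = "mild_liver_disease",            severe = "moderate_severe_liver_disease"),
  c(mild = "diabetes_without_complication", severe = "diabetes_with_complication"),
  c(mild = "any_malignancy",                severe = "metastatic_solid_tumour")
)

#' Map one or more ICD-10 codes to Charlson categories
#'
#' Deterministic prefix match against the packaged Quan table; codes that hit
#' no prefix return nothing (e.g. fracture codes are not Charlson
#' conditions).
#'
#' @param codes character vector of ICD-10 codes (normalized internally).
#' @param map a map table from [charlson_map()].
#' @return character vector of distinct category names (possibly empty).
#' @export
map_code_to_categories <- function(codes, map = charlson_map()) {
  codes <- icd10_normalize(codes)
  hit <- outer(codes, map$icd10_prefix, startsWith)
  unique(map$category[colSums(hit) > 0L])
}

# vectorized per-claim-code categorization: returns a data.table
# (claim_row, category), one row per (code, matched category)
.categorize_codes <- function(codes, claim_row, map) {
  keep <- icd10_is_valid(codes)
  codes <- codes[keep]; claim_row <- claim_row[keep]
  if (!length(codes))
    return(data.table(claim_row = integer(), category = character()))
  # match on the 3-char stem first, then confirm the full prefix
  stems <- substr(map$icd10_prefix, 1L, 3L)
  cand <- data.table(stem = substr(codes, 1L, 3L), code = codes,
                     claim_row = claim_row)
  mp <- data.table(stem = stems, prefix = map$icd10_prefix,
                   category = map$category)
  j <- mp[cand, on = "stem", allow.cartesian = TRUE, nomatch = NULL]
  j <- j[startsWith(code, prefix)]
  unique(j[, list(claim_row, category)])
}

#' Charlson categories with eligible claim evidence before an index date
#'
#' Applies the ascertainment rules for pre-fracture comorbidity: a category
#' counts iff it appears (a) among the secondary/other diagnoses of the
#' index-date inpatient claim, or (b) on at least one inpatient claim in the
#' 365 days preceding the index date, or (c) on two or more outpatient
#' claims in that window whose service dates differ by at least 7 days.
#' The lookback window is the half-open interval
#' `[index_date - 365, index_date)`; the index claim contributes only its
#' secondary diagnoses.
#'
#' @param claims claims restricted to one person (any order; duplicates are
#'   harmless).
#' @param index_date the anchoring date.
#' @param map Quan prefix table.
#' @return character vector of category names present.
#' @export
eligible_category_evidence <- function(claims, index_date, map = charlson_map()) {
  claims <- as.data.table(claims)
  if (!nrow(claims)) return(character())
  index_date <- as.Date(index_date)

  all_codes <- function(cl) {
    prim <- data.table(code = cl$primary_dx, row = seq_len(nrow(cl)))
    sec <- data.table(code = as.character(unlist(cl$secondary_dx, use.names = FALSE)),
                      row = rep(seq_len(nrow(cl)), lengths(cl$secondary_dx)))
    rbind(prim, sec)
  }

  present <- character()

  # (a) secondary diagnoses of the index-date inpatient claim(s)
  idx <- claims[service_date == index_date & setting == "inpatient"]
  if (nrow(idx)) {
    sec <- unlist(idx$secondary_dx, use.names = FALSE)
    if (length(sec))
      present <- c(present,
                   .categorize_codes(sec, seq_along(sec), map)$category)
  }

  # lookback window claims, any diagnosis position
  win <- claims[service_date >= index_date - 365L & service_date < index_date]
  if (nrow(win)) {
    cd <- all_codes(win)
    cats <- .categorize_codes(cd$code, cd$row, map)
    if (nrow(cats)) {
      cats[, setting := win$setting[claim_row]]
      cats[, service_date := win$service_date[claim_row]]
      # (b) any inpatient mention
      present <- c(present, unique(cats[setting == "inpatient"]$category))
      # (c) outpatient repeat rule: max pairwise date gap >= 7 days
      outp <- unique(cats[setting == "outpatient",
                          list(category, service_date)])
      if (nrow(outp)) {
        span <- outp[, list(span = as.integer(max(service_date) - min(service_date))),
                     by = category]
        present <- c(present, span[span >= 7L]$category)
      }
    }
  }
  sort(unique(present))
}

#' Charlson comorbidity score from resolved categories
#'
#' Applies the hierarchy rules (mild vs moderate/severe liver disease,
#' diabetes without vs with complications, any malignancy vs metastatic
#' solid tumour: only the severer member scores), then sums weights.
#'
#' @param categories character vector of category names.
#' @param weights named weight vector from [charlson_weights()].
#' @return integer score, `>= 0`.
#' @export
charlson_score <- function(categories, weights = charlson_weights()) {
  categories <- unique(categories)
  unknown <- setdiff(categories, names(weights))
  if (length(unknown))
    stop("unknown Charlson category: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (h in .charlson_hierarchy)
    if (all(h %in% categories))
      categories <- setdiff(categories, h[["mild"]])
  sum(weights[categories])
}

#' Score every index event of a cohort
#'
#' Vectorized batch scorer: applies the same ascertainment rules as
#' [eligible_category_evidence()] plus the hierarchy/weight resolution of
#' [charlson_score()] to every `(person_id, index_date)` pair at once.
#' The single-person functions are the reference implementation; this path
#' is the one used on full cohorts.
#'
#' @param index_events table with `person_id`, `index_date` columns.
#' @param claims full claims table.
#' @param map,weights configuration tables.
#' @return integer vector of scores aligned with `index_events` rows.
#' @export
score_cohort <- function(index_events, claims,
                         map = charlson_map(),
                         weights = charlson_weights()) {
  ev <- as.data.table(index_events)[, list(person_id, index_date)]
  ev[, event_id := .I]
  claims <- as.data.table(claims)
  n_ev <- nrow(ev)
  if (!nrow(claims) || !n_ev) return(integer(n_ev))

  # categorize every diagnosis code once, keeping its claim row and whether
  # it sat in a secondary position
  prim <- data.table(claim_row = seq_len(nrow(claims)),
                     code = claims$primary_dx, secondary = FALSE)
  sec <- data.table(
    claim_row = rep(seq_len(nrow(claims)), lengths(claims$secondary_dx)),
    code = as.character(unlist(claims$secondary_dx, use.names = FALSE)),
    secondary = TRUE)
  codes <- rbind(prim, sec)
  cats <- .categorize_codes(codes$code, seq_len(nrow(codes)), map)
  if (!nrow(cats)) return(integer(n_ev))
  cats[, secondary := codes$secondary[claim_row]]
  cats[, claim_row := codes$claim_row[claim_row]]
  cats[, `:=`(person_id = claims$person_id[claim_row],
              service_date = claims$service_date[claim_row],
              setting = claims$setting[claim_row])]
  cats <- unique(cats[, list(person_id, service_date, setting, secondary, category)])

  j <- cats[ev, on = "person_id", allow.cartesian = TRUE, nomatch = NULL]
  idx_hit <- j[secondary == TRUE & setting == "inpatient" &
                 service_date == index_date, list(event_id, category)]
  win <- j[service_date >= index_date - 365L & service_date < index_date]
  inpat_hit <- win[setting == "inpatient", list(event_id, category)]
  outp <- unique(win[setting == "outpatient",
                     list(event_id, category, service_date)])
  outp_hit <- if (nrow(outp)) {
    sp <- outp[, list(span = as.integer(max(service_date) - min(service_date))),
               by = list(event_id, category)]
    sp[span >= 7L, list(event_id, category)]
  } else data.table(event_id = integer(), category = character())

  evid <- unique(rbind(idx_hit, inpat_hit, outp_hit))
  # hierarchy: drop the mild member when the severe one is present
  for (h in .charlson_hierarchy) {
    sev <- evid[category == h[["severe"]], event_id]
    evid <- evid[!(category == h[["mild"]] & event_id %in% sev)]
  }
  evid[, weight := weights[category]]
  sc <- evid[, list(score = sum(weight)), by = event_id]
  out <- integer(n_ev)
  out[sc$event_id] <- as.integer(sc$score)
  out
}
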