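#' Normalize an ICD-10 code to the dotted upper-case form
#'
#' Codes are stored upper-case with the dot retained (`"S72.0"`); downstream
#' matching is prefix-based on this dotted form. Undotted four-plus character
#' codes (`"S720"`) gain a dot after the third character.
#'
#' @param code character vector of raw codes.
#' @return character vector of normalized codes (not yet validated).
#' @export
icd10_normalize <- function(code) {
  x <- toupper(trimws(code))
  nodot <- !grepl(".", x, fixed = TRUE) & nchar(x) > 3L
  x[nodot] <- paste0(substr(x[nodot], 1L, 3L), ".", substring(x[nodot], 4L))
  x
}

#' Check ICD-10 syntax
#'
#' Accepts a letter followed by two digits, optionally a dot and one or two
#' further alphanumeric characters (ICD-10 allows letter subdivisions).
#'
#' @param code character vector of normalized codes.
#' @return logical vector.
#' @export
icd10_is_valid <- function(code) {
  grepl("^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,2})?$", code)
}

.parse_date <- function(x) {
  out <- as.Date(rep(NA_real_, length(x)))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

.new_report <- function(table, rows_read, rejected_rows, messages) {
  structure(
    list(table = table,
         rows_read = rows_read,
         rows_accepted = rows_read - length(rejected_rows),
         rows_rejected = length(rejected_rows),
         violations = data.table(row = rejected_rows, message = messages)),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> table '%s': %d read, %d accepted, %d rejected\n",
              x$table, x$rows_read, x$rows_accepted, x$rows_rejected))
  if (nrow(x$violations)) {
    show <- head(x$violations, 10L)
    for (i in seq_len(nrow(show)))
      cat(sprintf("  row %s: %s\n", show$row[i], show$message[i]))
    if (nrow(x$violations) > 10L)
      cat(sprintf("  ... and %d more\n", nrow(x$violations) - 10L))
  }
  invisible(x)
}

.require_columns <- function(dt, required, what) {
  missing <- setdiff(required, names(dt))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Read a person table
#'
#' Expected columns: `person_id,sex,birth_year,death_date,coverage_start,
#' coverage_end`. An empty `death_date` means alive at data extraction.
#' Rows violating record invariants (implausible birth year, unparseable
#' date, death before coverage start, inverted coverage window) are rejected
#' and recorded in the attached report; accepted rows keep their file order.
#'
#' @param path delimited text file with a header row.
#' @param delim field delimiter, `","` (default) or `"\t"`.
#' @return `data.table` of accepted person records with a
#'   `"validation_report"` attribute (see [validation_report()]).
#' @export
read_persons <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- fread(path, sep = delim, colClasses = "character",
               na.strings = NULL, keepLeadingZeros = TRUE)
  .require_columns(raw, c("person_id", "sex", "birth_year", "death_date",
                          "coverage_start", "coverage_end"), "persons")
  n <- nrow(raw)
  if (n == 0L) {
    out <- data.table(person_id = character(), sex = character(),
                      birth_year = integer(), death_date = as.Date(character()),
                      coverage_start = as.Date(character()),
                      coverage_end = as.Date(character()))
    data.table::setattr(out, "validation_report",
                        .new_report("persons", 0L, integer(), character()))
    return(out)
  }
  sex <- tolower(trimws(raw$sex))
  by  <- suppressWarnings(as.integer(raw$birth_year))
  dd  <- .parse_date(raw$death_date)
  cs  <- .parse_date(raw$coverage_start)
  ce  <- .parse_date(raw$coverage_end)

  bad <- character(n)
  bad[!(sex %in% c("male", "female"))] <- "sex must be male/female"
  bad[is.na(by) | by < 1890L | by > 2000L] <- "implausible birth_year"
  bad[trimws(raw$death_date) != "" & is.na(dd)] <- "unparseable death_date"
  bad[is.na(cs)] <- "unparseable coverage_start"
  bad[is.na(ce)] <- "unparseable coverage_end"
  ok0 <- bad == ""
  bad[ok0 & cs > ce] <- "coverage_start after coverage_end"
  bad[bad == "" & !is.na(dd) & dd < cs] <- "death_date before coverage_start"
  ok <- bad == ""

  out <- data.table(person_id = raw$person_id[ok], sex = sex[ok],
                    birth_year = by[ok], death_date = dd[ok],
                    coverage_start = cs[ok], coverage_end = ce[ok])
  data.table::setattr(out, "validation_report",
                      .new_report("persons", n, which(!ok), bad[!ok]))
  out
}

#' Read a claims table
#'
#' Expected columns: `person_id,service_date,setting,primary_dx,secondary_dx,
#' specialty`; secondary codes are joined by `";"`. Codes are normalized to
#' dotted upper-case; rows whose primary code fails ICD-10 syntax, or whose
#' date does not parse, are rejected. Invalid secondary codes are dropped
#' silently from the list (the row survives).
#'
#' @inheritParams read_persons
#' @return `data.table` of accepted claim records; `secondary_dx` is a list
#'   column of character vectors. Carries a `"validation_report"` attribute.
#' @export
read_claims <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- fread(path, sep = delim, colClasses = "character",
               na.strings = NULL, keepLeadingZeros = TRUE)
  .require_columns(raw, c("person_id", "service_date", "setting",
                          "primary_dx", "secondary_dx"), "claims")
  if (!"specialty" %in% names(raw)) raw[, specialty := ""]
  n <- nrow(raw)
  if (n == 0L) {
    out <- data.table(person_id = character(), service_date = as.Date(character()),
                      setting = character(), primary_dx = character(),
                      secondary_dx = list(), specialty = character())
    data.table::setattr(out, "validation_report",
                        .new_report("claims", 0L, integer(), character()))
    return(out)
  }
  sd  <- .parse_date(raw$service_date)
  set <- tolower(trimws(raw$setting))
  pdx <- icd10_normalize(raw$primary_dx)

  bad <- character(n)
  bad[!(set %in% c("inpatient", "outpatient"))] <- "setting must be inpatient/outpatient"
  bad[is.na(sd)] <- "unparseable service_date"
  bad[!icd10_is_valid(pdx)] <- "primary_dx fails ICD-10 syntax"
  ok <- bad == ""

  sec <- strsplit(raw$secondary_dx, ";", fixed = TRUE)
  sec <- lapply(sec, function(v) {
    v <- icd10_normalize(v[trimws(v) != ""])
    v[icd10_is_valid(v)]
  })

  out <- data.table(person_id = raw$person_id[ok], service_date = sd[ok],
                    setting = set[ok], primary_dx = pdx[ok],
                    secondary_dx = sec[ok], specialty = trimws(raw$specialty)[ok])
  data.table::setattr(out, "validation_report",
                      .new_report("claims", n, which(!ok), bad[!ok]))
  out
}

#' Write person / claims tables in the interchange layout
#'
#' Inverse of [read_persons()] / [read_claims()]: reading a written file
#' recovers the accepted records bit-exactly.
#'
#' @param persons,claims tables as returned by the readers (or by
#'   [simulate_cohort()]).
#' @param path output file.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_persons <- function(persons, path, delim = ",") {
  out <- data.table(
    person_id = persons$person_id,
    sex = persons$sex,
    birth_year = persons$birth_year,
    death_date = ifelse(is.na(persons$death_date), "",
                        format(persons$death_date, "%Y-%m-%d")),
    coverage_start = format(persons$coverage_start, "%Y-%m-%d"),
    coverage_end = format(persons$coverage_end, "%Y-%m-%d"))
  fwrite(out, path, sep = delim)
  invisible(path)
}

#' @rdname write_persons
#' @export
write_claims <- function(claims, path, delim = ",") {
  out <- data.table(
    person_id = claims$person_id,
    service_date = format(claims$service_date, "%Y-%m-%d"),
    setting = claims$setting,
    primary_dx = claims$primary_dx,
    secondary_dx = vapply(claims$secondary_dx, paste, character(1), collapse = ";"),
    specialty = claims$specialty)
  fwrite(out, path, sep = delim)
  invisible(path)
}

#' Retrieve the validation report attached to a read table
#'
#' @param x a table returned by [read_persons()] or [read_claims()].
#' @return the `"validation_report"` object. Its counts always satisfy
#'   `rows_read = rows_accepted + rows_rejected`.
#' @export
validation_report <- function(x) attr(x, "validation_report")

#' Cross-check claims against the person table
#'
#' Flags claims whose `person_id` is absent from the person table, claims
#' dated outside the person's coverage window, and claims dated after the
#' person's death. A pure reporting operation: nothing is dropped.
#'
#' @param persons,claims parsed tables.
#' @return a `"validation_report"` whose `rows_rejected` counts flagged
#'   claims (`rows_read` is the number of claims checked).
#' @export
validate_linkage <- function(persons, claims) {
  claims <- as.data.table(claims)
  persons <- as.data.table(persons)
  idx <- match(claims$person_id, persons$person_id)
  orphan <- is.na(idx)
  cs <- persons$coverage_start[idx]
  ce <- persons$coverage_end[idx]
  dd <- persons$death_date[idx]
  outside <- !orphan & (claims$service_date < cs | claims$service_date > ce)
  postdeath <- !orphan & !is.na(dd) & claims$service_date > dd

  msg <- character(0); row <- integer(0)
  if (any(orphan)) {
    row <- c(row, which(orphan))
    msg <- c(msg, sprintf("orphan claim: person_id '%s' not in person table",
                          claims$person_id[orphan]))
  }
  if (any(postdeath)) {
    row <- c(row, which(postdeath))
    msg <- c(msg, sprintf("post-death claim for person_id '%s'",
                          claims$person_id[postdeath]))
  }
  out_only <- outside & !postdeath
  if (any(out_only)) {
    row <- c(row, which(out_only))
    msg <- c(msg, sprintf("claim outside coverage window for person_id '%s'",
                          claims$person_id[out_only]))
  }
  o <- order(row)
  .new_report("linkage", nrow(claims), row[o], msg[o])
}
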