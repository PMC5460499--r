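# small in-code fixtures shared across test files

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

persons_header <- "person_id,sex,birth_year,death_date,coverage_start,coverage_end"
claims_header <- "person_id,service_date,setting,primary_dx,secondary_dx,specialty"

person_line <- function(id, sex = "female", by = 1940,
                        death = "", cov0 = "2004-01-01", cov1 = "2016-05-04") {
  paste(id, sex, by, death, cov0, cov1, sep = ",")
}

claim_line <- function(id, date, setting = "outpatient", primary = "I10",
                       secondary = "", specialty = "gp") {
  paste(id, date, setting, primary, secondary, specialty, sep = ",")
}

# a tiny deterministic person/claims pair used by cohort tests:
# p1 fractures (inpatient S72.1 primary) in 2007; p2 has S72.0 only as a
# secondary diagnosis; p3 fractures in 2010 but already had an S72.0 claim
# in 2004; p4..p13 are fracture-free candidates matched to p1
tiny_persons <- function() {
  read_persons(write_lines_tmp(c(
    persons_header,
    person_line("p1", "male", 1937),
    person_line("p2", "male", 1937),
    person_line("p3", "male", 1937),
    vapply(4:13, function(i) person_line(paste0("p", i), "male", 1937),
           character(1)))))
}

tiny_claims <- function() {
  read_claims(write_lines_tmp(c(
    claims_header,
    claim_line("p1", "2007-03-10", "inpatient", "S72.1"),
    claim_line("p2", "2007-05-01", "inpatient", "I21.9", "S72.0"),
    claim_line("p3", "2004-06-15", "outpatient", "S72.0"),
    claim_line("p3", "2010-02-01", "inpatient", "S72.2"))))
}

# claims table constructed directly (already-parsed form)
dt_claims <- function(person_id, service_date, setting, primary_dx,
                      secondary_dx = NULL) {
  if (is.null(secondary_dx))
    secondary_dx <- replicate(length(person_id), character(), simplify = FALSE)
  data.table::data.table(
    person_id = person_id, service_date = as.Date(service_date),
    setting = setting, primary_dx = primary_dx,
    secondary_dx = secondary_dx, specialty = "")
}
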