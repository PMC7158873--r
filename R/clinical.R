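#' Read and write the clinical TSV tables
#'
#' Plain tab-separated text, all columns kept as character so that entries
#' like `"No data"` and `"Unavailable"` round-trip verbatim: writing a table
#' that was read back produces a byte-identical file.
#'
#' @param path file path.
#' @return `read_clinical_tsv`: a tibble of character columns.
#' @export
read_clinical_tsv <- function(path) {
  if (!file.exists(path)) stop("clinical table not found: ", path)
  tibble::as_tibble(read.delim(path, sep = "\t", colClasses = "character",
                               check.names = FALSE, quote = ""))
}

#' @rdname read_clinical_tsv
#' @param x a data frame of character columns.
#' @export
write_clinical_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Packaged clinical fixtures
#'
#' Returns the transcribed per-patient clinical table of the 43-child
#' surgical cohort (id, age at surgery, post-surgical scan and
#' visual-assessment intervals, gender, surgery, seizure freedom at > 1
#' year, medication) together with the visual-field concordance table for
#' the 12 patients with complete pre- and post-operative assessments
#' (tract/resection overlap present in 7, absent in 5). The transcription
#' is verbatim, including `"No data"` and `"Unavailable"` entries; it is
#' not cleaned or corrected.
#'
#' @return a list with tibbles `patients` (43 rows) and `concordance`
#'   (12 rows).
#' @export
clinical_fixture <- function() {
  p1 <- system.file("extdata", "clinical_table1.tsv", package = "ortract")
  p2 <- system.file("extdata", "vf_concordance.tsv", package = "ortract")
  if (!nzchar(p1) || !nzchar(p2)) stop("packaged clinical fixtures are missing")
  patients <- read_clinical_tsv(p1)
  need <- c("patient", "age_at_surgery", "scan_after_surgery_days",
            "visual_assessment_days", "gender", "surgery",
            "seizure_freedom", "medication")
  if (!identical(names(patients), need))
    stop("packaged clinical table is corrupt (unexpected columns)")
  concordance <- read_clinical_tsv(p2)
  list(patients = patients, concordance = concordance)
}

#' Cohort-level clinical summary
#'
#' Counts and medians over the patient table: total n, availability of
#' seizure-freedom information (entries other than `"Unavailable"`), the
#' seizure-freedom rate among those, gender counts and the median/IQR of
#' age at surgery. The gender count is reported exactly as transcribed; a
#' `note` field records that the source text and its table disagree on the
#' male count (22 vs 21), a discrepancy this summary preserves rather than
#' resolves.
#'
#' @param records patient tibble as returned by [clinical_fixture()].
#' @return a one-row tibble with a `note` attribute.
#' @export
cohort_summary <- function(records) {
  if (!nrow(records)) stop("empty clinical table")
  if (anyDuplicated(records$patient)) stop("duplicate patient ids")
  age <- suppressWarnings(as.numeric(records$age_at_surgery))
  if (any(is.na(age) | age <= 0))
    stop("malformed age in row(s): ",
         paste(which(is.na(age) | age <= 0), collapse = ", "))
  sf <- records$seizure_freedom
  if (!all(sf %in% c("Yes", "No", "Unavailable")))
    stop("malformed seizure_freedom in row(s): ",
         paste(which(!sf %in% c("Yes", "No", "Unavailable")), collapse = ", "))
  avail <- sf != "Unavailable"
  out <- tibble::tibble(
    n = nrow(records),
    n_seizure_info = sum(avail),
    seizure_free_rate = sum(sf == "Yes") / sum(avail),
    n_male = sum(records$gender == "M"),
    n_female = sum(records$gender == "F"),
    age_median = median(age),
    age_iqr = IQR(age))
  attr(out, "note") <- paste(
    "Gender counts are as transcribed; the source text reports 22 male",
    "where the table transcription yields", out$n_male, "- preserved, not corrected.")
  out
}

#' Overlap / visual-field concordance
#'
#' Restricts to patients with complete, interpretable pre- and
#' post-operative visual-field assessments (dropping `abandoned` and
#' missing entries), computes the fraction with an acquired deficit
#' (normal before, abnormal after) accompanying a tract/resection overlap,
#' and checks the two-way correspondence: every overlap comes with a
#' deficit and every deficit with an overlap.
#'
#' @param records concordance tibble as from [clinical_fixture()]: columns
#'   `patient`, `overlap` (`yes`/`no`), `preop_vf`, `postop_vf`.
#' @return a one-row tibble: `n_complete`, `n_overlap_deficit`,
#'   `deficit_fraction`, `deficit_pct`, `correspondence` (logical).
#' @export
concordance <- function(records) {
  complete <- !records$preop_vf %in% c("abandoned", "none", "No data", "") &
    !records$postop_vf %in% c("abandoned", "none", "No data", "")
  d <- records[complete, , drop = FALSE]
  if (!nrow(d)) stop("no complete pre+post visual-field assessments")
  deficit <- d$preop_vf == "normal" & d$postop_vf != "normal"
  overlap <- d$overlap == "yes"
  tibble::tibble(
    n_complete = nrow(d),
    n_overlap_deficit = sum(deficit & overlap),
    deficit_fraction = sum(deficit & overlap) / nrow(d),
    deficit_pct = 100 * sum(deficit & overlap) / nrow(d),
    correspondence = all(deficit == overlap))
}
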