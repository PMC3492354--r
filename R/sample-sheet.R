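# Sample sheet: group label (neuroblastic tumor spectrum + normal references),
# INSS stage, MYCN status, age at diagnosis; the clinical risk label is
# derived, never supplied.

SAMPLE_GROUPS <- c("NB", "GN", "GNB", "FB", "AG")
INSS_STAGES <- c("1", "2", "3", "4", "4S")
MYCN_LEVELS <- c("amplified", "non_amplified", "undetermined")

#' Derive the clinical risk label from stage and MYCN status
#'
#' High-risk (HR) is INSS stage 4 with MYCN amplification; low-risk (LR) is
#' stage 1-3 without MYCN amplification. Everything else (stage 4S, mixed or
#' undetermined combinations, non-tumor samples) is `"other"`.
#'
#' @param inss_stage Character vector of stages (`"1"`..`"4"`, `"4S"`, `NA`).
#' @param mycn Character vector (`"amplified"`, `"non_amplified"`,
#'   `"undetermined"`).
#' @return Character vector with values `"HR"`, `"LR"`, `"other"`.
#' @export
derive_risk <- function(inss_stage, mycn) {
  stage <- toupper(as.character(inss_stage))
  mycn <- as.character(mycn)
  out <- rep("other", length(stage))
  out[!is.na(stage) & stage == "4" & !is.na(mycn) & mycn == "amplified"] <- "HR"
  out[!is.na(stage) & stage %in% c("1", "2", "3") &
        !is.na(mycn) & mycn == "non_amplified"] <- "LR"
  out
}

#' Build a sample sheet
#'
#' @param df A data.frame with columns `sample_id`, `group` (NB, GN, GNB, FB,
#'   AG), `inss_stage`, `mycn`, `age_months`. Unknown group tokens are an
#'   error; stages/MYCN may be missing for reference tissues.
#' @return A data.frame of class `SampleSheet` with a derived `risk` column
#'   (see [derive_risk()]).
#' @export
sample_sheet <- function(df) {
  required <- c("sample_id", "group", "inss_stage", "mycn", "age_months")
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    abort(sprintf("sample sheet is missing required column(s): %s",
                  paste(missing, collapse = ", ")), "methcall_format_error")
  }
  if (anyDuplicated(df$sample_id)) {
    abort("duplicate sample_id in sample sheet", "methcall_format_error")
  }
  group <- toupper(trimws(as.character(df$group)))
  bad <- setdiff(unique(group), SAMPLE_GROUPS)
  if (length(bad)) {
    abort(sprintf("unknown sample group token(s): %s (expected %s)",
                  paste(bad, collapse = ", "),
                  paste(SAMPLE_GROUPS, collapse = "/")),
          "methcall_format_error")
  }
  stage <- toupper(trimws(as.character(df$inss_stage)))
  stage[stage %in% c("", "NA")] <- NA_character_
  bad_stage <- setdiff(unique(stage[!is.na(stage)]), INSS_STAGES)
  if (length(bad_stage)) {
    abort(sprintf("unknown INSS stage value(s): %s",
                  paste(bad_stage, collapse = ", ")), "methcall_format_error")
  }
  mycn <- tolower(trimws(as.character(df$mycn)))
  mycn[mycn %in% c("", "na")] <- NA_character_
  bad_mycn <- setdiff(unique(mycn[!is.na(mycn)]), MYCN_LEVELS)
  if (length(bad_mycn)) {
    abort(sprintf("unknown MYCN status value(s): %s",
                  paste(bad_mycn, collapse = ", ")), "methcall_format_error")
  }
  age <- as.numeric(df$age_months)
  if (any(!is.na(age) & age < 0)) {
    abort("age_months must be non-negative", "methcall_format_error")
  }
  out <- data.frame(
    sample_id = as.character(df$sample_id),
    group = group, inss_stage = stage, mycn = mycn, age_months = age,
    stringsAsFactors = FALSE)
  out$risk <- derive_risk(out$inss_stage, out$mycn)
  class(out) <- c("SampleSheet", "data.frame")
  out
}

#' Read a sample sheet from TSV
#' @param path Tab-delimited file with header; see [sample_sheet()] for the
#'   required columns.
#' @return A `SampleSheet` data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  sample_sheet(df)
}

#' Write a sample sheet to TSV
#' @param sheet A [sample_sheet()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
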