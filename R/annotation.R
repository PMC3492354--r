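# Probe annotation: probe -> gene symbol, chromosome, cytoband, position,
# promoter CpG-content class and Polycomb-target status. Internal genomic
# positions are 0-based; any interval output follows the BED convention.

PROMOTER_CLASSES <- c("HCP", "ICP", "LCP", "MIXED", "UNKNOWN")

#' Build a probe annotation table
#'
#' Normalizes and validates an annotation `data.frame`. The gonosomal flag is
#' always (re)derived from the chromosome: a probe is gonosomal iff it maps to
#' chromosome X or Y (the "gender-specific" probes removed during QC).
#'
#' @param df A data.frame with required columns `probe_id`, `gene_symbol`,
#'   `chromosome` and optional `cytoband`, `position` (0-based bp),
#'   `promoter_class` (one of HCP, ICP, LCP, MIXED, UNKNOWN) and
#'   `is_pcg_target` (logical: Polycomb/PRC2 target in embryonic stem cells).
#' @return A data.frame of class `ProbeAnnotation` with all columns present,
#'   `promoter_class` defaulting to `"UNKNOWN"` and `is_pcg_target` to `NA`.
#' @export
probe_annotation <- function(df) {
  required <- c("probe_id", "gene_symbol", "chromosome")
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    abort(sprintf("annotation is missing required column(s): %s",
                  paste(missing, collapse = ", ")), "methcall_format_error")
  }
  if (anyDuplicated(df$probe_id)) {
    abort(sprintf("duplicate probe_id in annotation (e.g. '%s')",
                  df$probe_id[duplicated(df$probe_id)][1]),
          "methcall_format_error")
  }
  out <- data.frame(
    probe_id = as.character(df$probe_id),
    gene_symbol = as.character(df$gene_symbol),
    chromosome = normalize_chromosome(df$chromosome),
    stringsAsFactors = FALSE)
  out$cytoband <- if ("cytoband" %in% colnames(df))
    as.character(df$cytoband) else NA_character_
  out$position <- if ("position" %in% colnames(df))
    as.numeric(df$position) else NA_real_
  if ("promoter_class" %in% colnames(df)) {
    pc <- toupper(as.character(df$promoter_class))
    pc[is.na(pc) | pc == ""] <- "UNKNOWN"
    bad <- setdiff(unique(pc), PROMOTER_CLASSES)
    if (length(bad)) {
      abort(sprintf("unknown promoter_class value(s): %s",
                    paste(bad, collapse = ", ")), "methcall_format_error")
    }
    out$promoter_class <- pc
  } else {
    out$promoter_class <- "UNKNOWN"
  }
  out$is_pcg_target <- if ("is_pcg_target" %in% colnames(df))
    parse_flag(df$is_pcg_target) else NA
  out$is_gonosomal <- out$chromosome %in% c("X", "Y")
  class(out) <- c("ProbeAnnotation", "data.frame")
  out
}

normalize_chromosome <- function(chr) {
  chr <- sub("^chr", "", as.character(chr), ignore.case = TRUE)
  toupper(chr)
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t", "yes", "y")] <- TRUE
  out[x %in% c("0", "false", "f", "no", "n")] <- FALSE
  out
}

#' Read a probe annotation table from TSV
#'
#' @param path Tab-delimited file with header; required columns `probe_id`,
#'   `gene_symbol`, `chromosome`; optional `cytoband`, `position`,
#'   `promoter_class`, `is_pcg_target`.
#' @return A [probe_annotation()] data.frame.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  probe_annotation(df)
}

#' Write a probe annotation table to TSV
#' @param ann A [probe_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
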