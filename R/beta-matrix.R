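# BetaMatrix: probes x samples methylation fractions with optional per-probe
# detection p-values. Beta values are M/(M+U+offset) in [0, 1]; missing
# measurements are NA and are excluded pairwise downstream, never imputed
# (except transiently for ordination views).

#' Construct a BetaMatrix
#'
#' A `BetaMatrix` holds a probes-by-samples matrix of methylation beta values
#' (fractions in \[0, 1\], 0 = fully unmethylated, 1 = fully methylated) with
#' unique probe and sample identifiers, and optionally a matrix of per-probe
#' detection p-values of identical dimensions.
#'
#' @param beta Numeric matrix, probes in rows and samples in columns.
#'   `rownames` are probe ids, `colnames` sample ids; both must be unique.
#'   `NA` encodes a missing measurement.
#' @param detection_p Optional numeric matrix of detection p-values with the
#'   same dimnames as `beta`.
#' @return An object of class `BetaMatrix`: a list with elements `beta`,
#'   `detection_p` (or `NULL`), `probe_ids`, `sample_ids`.
#' @examples
#' m <- matrix(c(0.1, 0.9, 0.5, 0.2, 0.8, 0.4), nrow = 3,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' bm <- beta_matrix(m)
#' dim(bm)
#' @export
beta_matrix <- function(beta, detection_p = NULL) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    abort("`beta` must be a numeric matrix", "methcall_format_error")
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    abort("`beta` must have probe rownames and sample colnames",
          "methcall_format_error")
  }
  if (anyDuplicated(rownames(beta))) {
    abort("duplicate probe ids in beta matrix", "methcall_format_error")
  }
  if (anyDuplicated(colnames(beta))) {
    abort("duplicate sample ids in beta matrix", "methcall_format_error")
  }
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "beta value out of [0, 1] at probe '%s', sample '%s' (value %g)",
      rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]],
      beta[bad[1, , drop = FALSE]]), "methcall_format_error")
  }
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) || !identical(dim(detection_p), dim(beta))) {
      abort("`detection_p` must be a matrix with the same dimensions as `beta`",
            "methcall_format_error")
    }
    dimnames(detection_p) <- dimnames(beta)
    if (any(!is.na(detection_p) & (detection_p < 0 | detection_p > 1))) {
      abort("detection p-values must lie in [0, 1]", "methcall_format_error")
    }
  }
  structure(
    list(beta = beta, detection_p = detection_p,
         probe_ids = rownames(beta), sample_ids = colnames(beta)),
    class = "BetaMatrix")
}

#' @export
dim.BetaMatrix <- function(x) dim(x$beta)

#' @export
print.BetaMatrix <- function(x, ...) {
  cat(sprintf("BetaMatrix: %d probes x %d samples%s\n",
              nrow(x$beta), ncol(x$beta),
              if (is.null(x$detection_p)) "" else " (with detection p-values)"))
  cat(sprintf("  missing beta values: %d\n", sum(is.na(x$beta))))
  invisible(x)
}

#' Subset a BetaMatrix by probes and/or samples
#'
#' @param bm A [beta_matrix()].
#' @param probes,samples Character ids (or indices) to retain; `NULL` keeps all.
#' @return A `BetaMatrix`.
#' @export
subset_beta <- function(bm, probes = NULL, samples = NULL) {
  stopifnot(inherits(bm, "BetaMatrix"))
  probes <- probes %||% bm$probe_ids
  samples <- samples %||% bm$sample_ids
  missing_p <- setdiff(as.character(probes), bm$probe_ids)
  missing_s <- setdiff(as.character(samples), bm$sample_ids)
  if (is.character(probes) && length(missing_p)) {
    abort(sprintf("unknown probe ids: %s",
                  paste(utils::head(missing_p, 5), collapse = ", ")),
          "methcall_format_error")
  }
  if (is.character(samples) && length(missing_s)) {
    abort(sprintf("unknown sample ids: %s",
                  paste(utils::head(missing_s, 5), collapse = ", ")),
          "methcall_format_error")
  }
  b <- bm$beta[probes, samples, drop = FALSE]
  d <- if (is.null(bm$detection_p)) NULL else
    bm$detection_p[probes, samples, drop = FALSE]
  beta_matrix(b, d)
}

read_numeric_tsv <- function(path, what) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          colClasses = "character")
  if (ncol(df) < 2) {
    abort(sprintf("%s file '%s' needs an id column plus >= 1 sample column",
                  what, path), "methcall_format_error")
  }
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate probe ids in %s file '%s' (e.g. '%s')",
                  what, path, ids[duplicated(ids)][1]), "methcall_format_error")
  }
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) {
    abort(sprintf("duplicate sample ids in %s file '%s'", what, path),
          "methcall_format_error")
  }
  m <- matrix(NA_real_, nrow = nrow(df), ncol = length(samples),
              dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    raw <- trimws(df[[j + 1]])
    empty <- raw == "" | toupper(raw) %in% c("NA", "NAN", "NULL")
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!empty & is.na(val))
    if (length(bad)) {
      abort(sprintf(
        "non-numeric value '%s' in %s file '%s' at row %d (probe '%s'), column '%s'",
        raw[bad[1]], what, path, bad[1], ids[bad[1]], samples[j]),
        "methcall_parse_error")
    }
    val[empty] <- NA_real_
    m[, j] <- val
  }
  m
}

#' Read a beta-value matrix from a tab-delimited file
#'
#' Expects the dialect of series-matrix style exports: a header row of sample
#' ids, first column of probe ids, tab separated, `#` comment lines ignored,
#' empty cells treated as missing. Values outside \[0, 1\] are rejected with
#' the offending position reported.
#'
#' @param path Path to the beta-value TSV.
#' @param detection_p_path Optional path to a companion detection p-value TSV
#'   with identical probe/sample layout.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path, detection_p_path = NULL) {
  beta <- read_numeric_tsv(path, "beta matrix")
  detp <- NULL
  if (!is.null(detection_p_path)) {
    detp <- read_numeric_tsv(detection_p_path, "detection p-value")
    if (!identical(dim(detp), dim(beta)) ||
        !identical(rownames(detp), rownames(beta)) ||
        !identical(colnames(detp), colnames(beta))) {
      abort("detection p-value file does not match the beta matrix layout",
            "methcall_format_error")
    }
  }
  beta_matrix(beta, detp)
}

#' Write a BetaMatrix to tab-delimited files
#'
#' @param bm A [beta_matrix()].
#' @param path Output path for the beta values.
#' @param detection_p_path Optional output path for detection p-values.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(bm, path, detection_p_path = NULL) {
  stopifnot(inherits(bm, "BetaMatrix"))
  write_matrix_tsv(bm$beta, path, id_col = "probe_id")
  if (!is.null(detection_p_path)) {
    if (is.null(bm$detection_p)) {
      abort("BetaMatrix has no detection p-values to write",
            "methcall_format_error")
    }
    write_matrix_tsv(bm$detection_p, detection_p_path, id_col = "probe_id")
  }
  invisible(path)
}

write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
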