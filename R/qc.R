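# Quality control: remove gonosomal ("gender-specific") and low-quality
# probes, then samples with poor detection p-values, before any differential
# analysis. The mechanism mirrors standard Infinium practice; all cut-offs
# are configurable.

#' QC configuration
#'
#' @param probe_detection_alpha Detection p-value above which a single
#'   measurement counts as failed (default 0.01).
#' @param probe_fail_fraction Maximum fraction of samples in which a probe may
#'   fail detection before the probe is removed (default 0.05).
#' @param sample_fail_fraction Maximum fraction of probes a sample may fail
#'   before the sample is removed (default 0.01).
#' @param drop_gonosomal Remove chrX/chrY probes (default `TRUE`).
#' @param max_missing_fraction Maximum fraction of missing beta values per
#'   probe (default 0.20).
#' @return A list of class `QCConfig`.
#' @export
qc_config <- function(probe_detection_alpha = 0.01,
                      probe_fail_fraction = 0.05,
                      sample_fail_fraction = 0.01,
                      drop_gonosomal = TRUE,
                      max_missing_fraction = 0.20) {
  stopifnot_fraction(probe_detection_alpha, "probe_detection_alpha")
  stopifnot_fraction(probe_fail_fraction, "probe_fail_fraction")
  stopifnot_fraction(sample_fail_fraction, "sample_fail_fraction")
  stopifnot_fraction(max_missing_fraction, "max_missing_fraction")
  structure(list(probe_detection_alpha = probe_detection_alpha,
                 probe_fail_fraction = probe_fail_fraction,
                 sample_fail_fraction = sample_fail_fraction,
                 drop_gonosomal = isTRUE(drop_gonosomal),
                 max_missing_fraction = max_missing_fraction),
            class = "QCConfig")
}

#' Filter probes by annotation and quality
#'
#' Removes, in order of reported reason: gonosomal probes (when
#' `cfg$drop_gonosomal`), probes failing detection (detection p >
#' `probe_detection_alpha`) in more than `probe_fail_fraction` of samples, and
#' probes with more than `max_missing_fraction` missing beta values. Probes
#' absent from the annotation are kept but reported (`"unannotated"`). The
#' exclusion report accounts for every input probe: retained + removed =
#' input.
#'
#' @param bm A [beta_matrix()].
#' @param ann A [probe_annotation()] (may cover a superset of the probes).
#' @param cfg A [qc_config()].
#' @return A list with `beta` (filtered `BetaMatrix`) and `report` (data.frame
#'   `probe_id`, `reason`, `statistic`; reasons `gonosomal`, `low_quality`,
#'   `missing`; plus advisory `unannotated` rows for retained probes).
#' @export
filter_probes <- function(bm, ann, cfg = qc_config()) {
  stopifnot(inherits(bm, "BetaMatrix"))
  ann <- if (inherits(ann, "ProbeAnnotation")) ann else probe_annotation(ann)
  n_samp <- ncol(bm$beta)
  probes <- bm$probe_ids
  idx <- match(probes, ann$probe_id)
  unannotated <- is.na(idx)

  gono <- rep(FALSE, length(probes))
  gono[!unannotated] <- ann$is_gonosomal[idx[!unannotated]]
  drop_gono <- cfg$drop_gonosomal & gono

  if (!is.null(bm$detection_p)) {
    fail_frac <- rowMeans(bm$detection_p > cfg$probe_detection_alpha,
                          na.rm = TRUE)
    fail_frac[is.nan(fail_frac)] <- 0
  } else {
    fail_frac <- rep(0, length(probes))
  }
  drop_quality <- fail_frac > cfg$probe_fail_fraction

  miss_frac <- rowMeans(is.na(bm$beta))
  drop_missing <- miss_frac > cfg$max_missing_fraction

  reason <- rep(NA_character_, length(probes))
  statistic <- rep(NA_real_, length(probes))
  reason[drop_missing] <- "missing"
  statistic[drop_missing] <- miss_frac[drop_missing]
  reason[drop_quality] <- "low_quality"
  statistic[drop_quality] <- fail_frac[drop_quality]
  reason[drop_gono] <- "gonosomal"   # takes precedence in the report
  statistic[drop_gono] <- NA_real_

  drop <- !is.na(reason)
  report <- data.frame(probe_id = probes[drop], reason = reason[drop],
                       statistic = statistic[drop], stringsAsFactors = FALSE)
  keep_unann <- unannotated & !drop
  if (any(keep_unann)) {
    report <- rbind(report, data.frame(
      probe_id = probes[keep_unann], reason = "unannotated",
      statistic = NA_real_, stringsAsFactors = FALSE))
  }
  if (all(drop)) {
    warning("all probes removed by QC filters", call. = FALSE)
  }
  kept <- probes[!drop]
  out <- if (length(kept)) subset_beta(bm, probes = kept) else {
    empty <- bm$beta[integer(0), , drop = FALSE]
    structure(list(beta = empty,
                   detection_p = if (is.null(bm$detection_p)) NULL else
                     bm$detection_p[integer(0), , drop = FALSE],
                   probe_ids = character(0), sample_ids = bm$sample_ids),
              class = "BetaMatrix")
  }
  list(beta = out, report = report, n_samples = n_samp)
}

#' Filter samples by detection quality
#'
#' Removes samples for which more than `sample_fail_fraction` of probes fail
#' detection (p > `probe_detection_alpha`). Without a detection p-value
#' matrix this is a no-op with a warning.
#'
#' @param bm A [beta_matrix()].
#' @param cfg A [qc_config()].
#' @return A list with `beta` (filtered `BetaMatrix`) and `report` (data.frame
#'   `sample_id`, `reason`, `statistic` = failing fraction).
#' @export
filter_samples <- function(bm, cfg = qc_config()) {
  stopifnot(inherits(bm, "BetaMatrix"))
  empty_report <- data.frame(sample_id = character(0), reason = character(0),
                             statistic = numeric(0), stringsAsFactors = FALSE)
  if (is.null(bm$detection_p)) {
    warning("no detection p-values available; sample filter skipped",
            call. = FALSE)
    return(list(beta = bm, report = empty_report))
  }
  fail_frac <- colMeans(bm$detection_p > cfg$probe_detection_alpha,
                        na.rm = TRUE)
  fail_frac[is.nan(fail_frac)] <- 0
  drop <- fail_frac > cfg$sample_fail_fraction
  if (all(drop)) {
    abort("all samples failed the detection-quality filter",
          "methcall_qc_error")
  }
  report <- data.frame(sample_id = bm$sample_ids[drop],
                       reason = rep("poor_detection", sum(drop)),
                       statistic = unname(fail_frac[drop]),
                       stringsAsFactors = FALSE)
  out <- if (any(drop)) subset_beta(bm, samples = bm$sample_ids[!drop]) else bm
  list(beta = out, report = report)
}

#' Write a QC exclusion report to TSV
#' @param report A report data.frame from [filter_probes()] or
#'   [filter_samples()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
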