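# Three-criteria consensus differential-methylation calling.
#
# A probe is called only when all applicable criteria agree:
#   A (threshold):  all reference beta values on one side of a stringent cut
#                   (< low_beta or > high_beta) while at least `case_fraction`
#                   of case samples cross the opposite cut;
#   B (mean diff):  |mean(case) - mean(ref)| strictly greater than `mean_diff`,
#                   its sign fixing the direction;
#   C (test):       unpaired t test with step-down maxT permutation adjustment
#                   and BH FDR computed jointly over all probes, q < fdr_alpha.
# Criterion C is marked not-applicable (not failed) when either group is
# smaller than `min_group_for_ttest` - single-tissue references make this
# unavoidable - and the call is annotated "test-skipped".

#' Differential-methylation calling configuration
#'
#' @param low_beta Unmethylated cut-off (default 0.25).
#' @param high_beta Methylated cut-off (default 0.75).
#' @param case_fraction Minimum fraction of case samples crossing the opposite
#'   threshold, inclusive (default 0.10).
#' @param mean_diff Minimum absolute mean beta difference, strict
#'   (default 0.25).
#' @param fdr_alpha BH q cut-off for the permutation t criterion
#'   (default 0.05).
#' @param n_perm Random relabelings when exhaustive enumeration is infeasible.
#' @param seed Seed for sampled permutations.
#' @param exhaustive_limit Enumerate all relabelings up to this count.
#' @param min_group_for_ttest Minimum per-group size for the t criterion to
#'   apply (default 3).
#' @param var_equal Pooled (default) or Welch t.
#' @return A list of class `DiffMethConfig`.
#' @export
diffmeth_config <- function(low_beta = 0.25, high_beta = 0.75,
                            case_fraction = 0.10, mean_diff = 0.25,
                            fdr_alpha = 0.05, n_perm = 1000, seed = 1L,
                            exhaustive_limit = 20000,
                            min_group_for_ttest = 3, var_equal = TRUE) {
  if (!(low_beta >= 0 && low_beta < high_beta && high_beta <= 1)) {
    abort("need 0 <= low_beta < high_beta <= 1", "methcall_config_error")
  }
  if (!(case_fraction > 0 && case_fraction <= 1)) {
    abort("case_fraction must lie in (0, 1]", "methcall_config_error")
  }
  if (!(mean_diff > 0 && mean_diff < 1)) {
    abort("mean_diff must lie in (0, 1)", "methcall_config_error")
  }
  stopifnot_fraction(fdr_alpha, "fdr_alpha")
  structure(list(low_beta = low_beta, high_beta = high_beta,
                 case_fraction = case_fraction, mean_diff = mean_diff,
                 fdr_alpha = fdr_alpha, n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 exhaustive_limit = as.integer(exhaustive_limit),
                 min_group_for_ttest = as.integer(min_group_for_ttest),
                 var_equal = isTRUE(var_equal)),
            class = "DiffMethConfig")
}

#' Threshold criterion (criterion A)
#'
#' Hypermethylated when every reference value is below `low_beta` and at
#' least `case_fraction` (inclusive) of non-missing case values exceed
#' `high_beta`; hypomethylated with the sides swapped. "All reference
#' samples" is a strict consensus over individual reference values - the
#' mean-based view is criterion B's job.
#'
#' @param ref_values,case_values Numeric beta vectors (NA allowed, >= 1
#'   non-missing each).
#' @param cfg A [diffmeth_config()].
#' @return `"hyper"`, `"hypo"` or `"none"`.
#' @export
criterion_threshold <- function(ref_values, case_values, cfg = diffmeth_config()) {
  r <- ref_values[!is.na(ref_values)]
  ca <- case_values[!is.na(case_values)]
  if (length(r) == 0 || length(ca) == 0) return("none")
  if (all(r < cfg$low_beta) && mean(ca > cfg$high_beta) >= cfg$case_fraction) {
    return("hyper")
  }
  if (all(r > cfg$high_beta) && mean(ca < cfg$low_beta) >= cfg$case_fraction) {
    return("hypo")
  }
  "none"
}

#' Mean-difference criterion (criterion B)
#'
#' @param ref_values,case_values Numeric beta vectors (NA allowed).
#' @param cfg A [diffmeth_config()].
#' @return A list with `passes` (|delta| strictly greater than
#'   `cfg$mean_diff`) and `delta` (= mean(case) - mean(ref), signed).
#' @export
criterion_meandiff <- function(ref_values, case_values, cfg = diffmeth_config()) {
  delta <- mean(case_values, na.rm = TRUE) - mean(ref_values, na.rm = TRUE)
  # strict inequality, robust to float noise at the cut-off itself
  list(passes = is.finite(delta) && abs(delta) > cfg$mean_diff + 1e-12,
       delta = delta)
}

#' Call differentially methylated probes (three-criteria consensus)
#'
#' Applies the threshold, mean-difference and permutation-t criteria to every
#' probe of a beta matrix for one case/reference comparison. The t criterion
#' is computed jointly across all probes ([maxt_stepdown()] raw p-values fed
#' to [bh_fdr()]); it is skipped - and the consensus reduced to criteria A
#' and B - when either group is smaller than `cfg$min_group_for_ttest`.
#' A probe's direction is non-`"none"` only when all applicable criteria pass
#' and the threshold and mean-difference directions agree.
#'
#' @param bm A [beta_matrix()].
#' @param case_ids,ref_ids Disjoint sample id sets present in `bm`.
#' @param cfg A [diffmeth_config()].
#' @return A data.frame of class `DiffMethCalls` with one row per probe:
#'   `probe_id`, `direction` (hyper/hypo/none), `crit_threshold`,
#'   `crit_meandiff`, `crit_test` (NA when skipped), `test_skipped`,
#'   `fraction_cases_shifted`, `mean_case`, `mean_ref`, `delta`, `p_raw`,
#'   `p_adj`, `q_fdr`. The comparison metadata is stored in attributes
#'   `case_ids`, `ref_ids`, `config`.
#' @export
call_probes <- function(bm, case_ids, ref_ids, cfg = diffmeth_config()) {
  stopifnot(inherits(bm, "BetaMatrix"))
  case_ids <- as.character(case_ids)
  ref_ids <- as.character(ref_ids)
  if (length(intersect(case_ids, ref_ids))) {
    abort("case and reference sample sets overlap", "methcall_config_error")
  }
  missing_ids <- setdiff(c(case_ids, ref_ids), bm$sample_ids)
  if (length(missing_ids)) {
    abort(sprintf("sample id(s) not in matrix: %s",
                  paste(utils::head(missing_ids, 5), collapse = ", ")),
          "methcall_config_error")
  }
  if (length(case_ids) == 0 || length(ref_ids) == 0) {
    abort("case and reference sets must be non-empty", "methcall_config_error")
  }
  Bc <- bm$beta[, case_ids, drop = FALSE]
  Br <- bm$beta[, ref_ids, drop = FALSE]

  n_case_ok <- rowSums(!is.na(Bc))
  n_ref_ok <- rowSums(!is.na(Br))
  mean_case <- rowMeans(Bc, na.rm = TRUE)
  mean_ref <- rowMeans(Br, na.rm = TRUE)
  delta <- mean_case - mean_ref

  # criterion A, vectorized over probes
  ref_all_low <- rowSums(Br < cfg$low_beta, na.rm = TRUE) == n_ref_ok & n_ref_ok > 0
  ref_all_high <- rowSums(Br > cfg$high_beta, na.rm = TRUE) == n_ref_ok & n_ref_ok > 0
  frac_case_high <- rowSums(Bc > cfg$high_beta, na.rm = TRUE) / pmax(n_case_ok, 1)
  frac_case_low <- rowSums(Bc < cfg$low_beta, na.rm = TRUE) / pmax(n_case_ok, 1)
  a_hyper <- ref_all_low & frac_case_high >= cfg$case_fraction & n_case_ok > 0
  a_hypo <- ref_all_high & frac_case_low >= cfg$case_fraction & n_case_ok > 0
  dir_a <- ifelse(a_hyper, "hyper", ifelse(a_hypo, "hypo", "none"))

  # criterion B (strict, float-robust at the cut-off)
  b_pass <- is.finite(delta) & abs(delta) > cfg$mean_diff + 1e-12

  # criterion C: permutation t + FDR, jointly over all probes
  test_skipped <- min(length(case_ids), length(ref_ids)) < cfg$min_group_for_ttest
  if (!test_skipped) {
    X <- cbind(Bc, Br)
    labels <- c(rep("case", length(case_ids)), rep("ref", length(ref_ids)))
    rownames(X) <- bm$probe_ids
    perm <- maxt_stepdown(X, labels, n_perm = cfg$n_perm, seed = cfg$seed,
                          exhaustive_limit = cfg$exhaustive_limit,
                          var_equal = cfg$var_equal)
    p_raw <- perm$p_raw
    p_adj <- perm$p_adj
    q_fdr <- bh_fdr(p_raw)
    c_pass <- q_fdr < cfg$fdr_alpha
  } else {
    p_raw <- p_adj <- q_fdr <- rep(NA_real_, nrow(Bc))
    c_pass <- rep(NA, nrow(Bc))
  }

  dir_b <- ifelse(delta > 0, "hyper", ifelse(delta < 0, "hypo", "none"))
  consensus <- dir_a != "none" & b_pass & dir_a == dir_b &
    (test_skipped | (!is.na(c_pass) & c_pass))
  direction <- ifelse(consensus, dir_a, "none")

  frac_shifted <- ifelse(dir_a == "hyper", frac_case_high,
                  ifelse(dir_a == "hypo", frac_case_low,
                  ifelse(delta >= 0, frac_case_high, frac_case_low)))

  out <- data.frame(
    probe_id = bm$probe_ids,
    direction = direction,
    crit_threshold = dir_a != "none",
    crit_meandiff = b_pass,
    crit_test = if (test_skipped) NA else c_pass,
    test_skipped = test_skipped,
    fraction_cases_shifted = frac_shifted,
    mean_case = mean_case, mean_ref = mean_ref, delta = delta,
    p_raw = p_raw, p_adj = p_adj, q_fdr = q_fdr,
    stringsAsFactors = FALSE)
  attr(out, "case_ids") <- case_ids
  attr(out, "ref_ids") <- ref_ids
  attr(out, "config") <- cfg
  class(out) <- c("DiffMethCalls", "data.frame")
  out
}

#' Aggregate probe calls to genes
#'
#' A gene is called when at least one of its probes is called; its direction
#' is the common direction of the called probes. Genes whose called probes
#' disagree in direction are flagged ambiguous and excluded from ranked
#' lists.
#'
#' @param calls A `DiffMethCalls` data.frame from [call_probes()].
#' @param ann A [probe_annotation()] mapping probes to genes.
#' @return A data.frame of class `GeneCalls`: `gene_symbol`, `direction`
#'   (hyper/hypo/ambiguous), `n_supporting`, `supporting_probes`
#'   (comma-separated), `best_fraction_cases`, `max_abs_meandiff`,
#'   `ambiguous`.
#' @export
aggregate_to_genes <- function(calls, ann) {
  ann <- if (inherits(ann, "ProbeAnnotation")) ann else probe_annotation(ann)
  called <- calls[calls$direction != "none", , drop = FALSE]
  gene <- ann$gene_symbol[match(called$probe_id, ann$probe_id)]
  if (anyNA(gene) && nrow(called)) {
    warning(sprintf("%d called probe(s) without gene annotation dropped",
                    sum(is.na(gene))), call. = FALSE)
    called <- called[!is.na(gene), , drop = FALSE]
    gene <- gene[!is.na(gene)]
  }
  if (nrow(called) == 0) {
    out <- data.frame(gene_symbol = character(0), direction = character(0),
                      n_supporting = integer(0),
                      supporting_probes = character(0),
                      best_fraction_cases = numeric(0),
                      max_abs_meandiff = numeric(0), ambiguous = logical(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("GeneCalls", "data.frame")
    return(out)
  }
  pieces <- split(called, gene)
  out <- do.call(rbind, lapply(names(pieces), function(g) {
    p <- pieces[[g]]
    dirs <- unique(p$direction)
    amb <- length(dirs) > 1
    data.frame(gene_symbol = g,
               direction = if (amb) "ambiguous" else dirs,
               n_supporting = nrow(p),
               supporting_probes = paste(p$probe_id, collapse = ","),
               best_fraction_cases = max(p$fraction_cases_shifted),
               max_abs_meandiff = max(abs(p$delta)),
               ambiguous = amb, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("GeneCalls", "data.frame")
  out
}

#' Intersect gene calls across reference comparisons
#'
#' Case-specific genes are those called with the same direction in every
#' reference comparison (the Venn-diagram intersection over supervised
#' analyses against distinct reference tissues). Ambiguous genes never enter.
#'
#' @param per_reference A named list (>= 2) of `GeneCalls` data.frames, one
#'   per reference comparison.
#' @return A list of class `ConsensusGeneSets` with `hyper` and `hypo`
#'   (sorted gene vectors), `genes` (merged `GeneCalls` for the consensus
#'   genes, statistics maximized over comparisons), and `venn` (one row per
#'   gene/direction seen anywhere, with a logical membership column per
#'   comparison and a `region` label).
#' @export
consensus_across_references <- function(per_reference) {
  if (!is.list(per_reference) || length(per_reference) < 2) {
    abort("need gene calls from >= 2 reference comparisons",
          "methcall_config_error")
  }
  nms <- names(per_reference) %||% sprintf("ref%d", seq_along(per_reference))
  nms[nms == ""] <- sprintf("ref%d", which(nms == ""))
  keyed <- lapply(per_reference, function(gc) {
    gc <- gc[!gc$ambiguous, , drop = FALSE]
    paste(gc$gene_symbol, gc$direction, sep = "\r")
  })
  all_keys <- sort(unique(unlist(keyed)))
  member <- matrix(FALSE, nrow = length(all_keys), ncol = length(keyed),
                   dimnames = list(NULL, nms))
  for (i in seq_along(keyed)) member[, i] <- all_keys %in% keyed[[i]]
  in_all <- if (length(all_keys)) rowSums(member) == length(per_reference)
            else logical(0)
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  gene <- vapply(parts, `[`, "", 1)
  direction <- vapply(parts, `[`, "", 2)
  # a gene called hyper in one comparison and hypo in another is inconsistent
  inconsistent <- gene %in% gene[duplicated(gene)]
  in_all <- in_all & !inconsistent

  venn <- data.frame(gene_symbol = gene, direction = direction,
                     member, stringsAsFactors = FALSE, check.names = FALSE)
  venn$region <- if (nrow(venn))
    apply(member, 1, function(r) paste(nms[r], collapse = "&")) else
    character(0)

  cons_keys <- all_keys[in_all]
  merged <- NULL
  for (i in seq_along(per_reference)) {
    gc <- per_reference[[i]]
    gc <- gc[!gc$ambiguous &
               paste(gc$gene_symbol, gc$direction, sep = "\r") %in% cons_keys, ,
             drop = FALSE]
    if (is.null(merged)) {
      merged <- gc
    } else {
      j <- match(gc$gene_symbol, merged$gene_symbol)
      merged$best_fraction_cases[j] <-
        pmax(merged$best_fraction_cases[j], gc$best_fraction_cases)
      merged$max_abs_meandiff[j] <-
        pmax(merged$max_abs_meandiff[j], gc$max_abs_meandiff)
      merged$n_supporting[j] <- pmax(merged$n_supporting[j], gc$n_supporting)
    }
  }
  if (is.null(merged)) merged <- aggregate_to_genes(
    structure(data.frame(probe_id = character(0), direction = character(0),
                         fraction_cases_shifted = numeric(0),
                         delta = numeric(0), stringsAsFactors = FALSE),
              class = c("DiffMethCalls", "data.frame")),
    probe_annotation(data.frame(probe_id = character(0),
                                gene_symbol = character(0),
                                chromosome = character(0))))
  merged <- merged[order(merged$gene_symbol), , drop = FALSE]
  rownames(merged) <- NULL
  class(merged) <- c("GeneCalls", "data.frame")
  structure(list(
    hyper = sort(gene[in_all & direction == "hyper"]),
    hypo = sort(gene[in_all & direction == "hypo"]),
    genes = merged, venn = venn),
    class = "ConsensusGeneSets")
}

#' @export
print.ConsensusGeneSets <- function(x, ...) {
  cat(sprintf("ConsensusGeneSets: %d hyper, %d hypo (of %d genes seen)\n",
              length(x$hyper), length(x$hypo), nrow(x$venn)))
  invisible(x)
}

#' Rank gene calls
#'
#' Orders non-ambiguous gene calls by the fraction of case samples shifted
#' (descending), then the maximum absolute mean beta difference (descending),
#' then gene symbol (ascending) for a fully deterministic order.
#'
#' @param gene_calls A `GeneCalls` data.frame.
#' @return The same data.frame, ambiguous genes removed, sorted, with a
#'   `rank` column.
#' @export
rank_genes <- function(gene_calls) {
  gc <- gene_calls[!gene_calls$ambiguous, , drop = FALSE]
  ord <- order(-gc$best_fraction_cases, -gc$max_abs_meandiff, gc$gene_symbol)
  gc <- gc[ord, , drop = FALSE]
  gc$rank <- seq_len(nrow(gc))
  rownames(gc) <- NULL
  class(gc) <- c("GeneCalls", "data.frame")
  gc
}

#' Specify a subgroup contrast
#'
#' Selects two disjoint sample sets from a sample sheet by a clinical field:
#' `risk` (HR vs LR), `inss_stage`, `mycn`, or an `age` threshold in months.
#'
#' @param group_by `"risk"`, `"inss_stage"`, `"mycn"` or `"age"`.
#' @param case_levels,ref_levels Field levels defining the case and reference
#'   subgroup (ignored for `"age"`).
#' @param age_cutoff_months For `group_by = "age"`: cases are samples with
#'   age strictly below the cut-off, references those at or above it.
#' @param groups Sample-sheet groups eligible for the contrast (default
#'   `"NB"`, i.e. tumors only).
#' @return A list of class `ContrastSpec`.
#' @export
contrast_spec <- function(group_by, case_levels = NULL, ref_levels = NULL,
                          age_cutoff_months = NULL, groups = "NB") {
  group_by <- match.arg(group_by, c("risk", "inss_stage", "mycn", "age"))
  if (group_by == "age" && is.null(age_cutoff_months)) {
    abort("age contrast needs `age_cutoff_months`", "methcall_config_error")
  }
  if (group_by != "age" && (is.null(case_levels) || is.null(ref_levels))) {
    abort("need `case_levels` and `ref_levels`", "methcall_config_error")
  }
  structure(list(group_by = group_by, case_levels = case_levels,
                 ref_levels = ref_levels,
                 age_cutoff_months = age_cutoff_months, groups = groups),
            class = "ContrastSpec")
}

#' Resolve a contrast specification to sample id sets
#'
#' @param sheet A [sample_sheet()].
#' @param spec A [contrast_spec()].
#' @return A list with `case_ids` and `ref_ids` (disjoint, non-empty).
#' @export
resolve_contrast <- function(sheet, spec) {
  stopifnot(inherits(spec, "ContrastSpec"))
  s <- sheet[sheet$group %in% spec$groups, , drop = FALSE]
  if (spec$group_by == "age") {
    ok <- !is.na(s$age_months)
    case_ids <- s$sample_id[ok & s$age_months < spec$age_cutoff_months]
    ref_ids <- s$sample_id[ok & s$age_months >= spec$age_cutoff_months]
  } else {
    field <- s[[spec$group_by]]
    case_ids <- s$sample_id[!is.na(field) & field %in% spec$case_levels]
    ref_ids <- s$sample_id[!is.na(field) & field %in% spec$ref_levels]
  }
  if (length(case_ids) == 0 || length(ref_ids) == 0) {
    abort("contrast selects an empty subgroup", "methcall_config_error")
  }
  list(case_ids = case_ids, ref_ids = ref_ids)
}

#' Run a clinical-subgroup differential-methylation contrast
#'
#' Applies the consensus caller between two tumor subgroups selected from the
#' sample sheet (high vs low risk, metastatic stage 4 vs 4S, MYCN amplified
#' vs non-amplified, age cut-offs). Optionally, calls can additionally be
#' required consistent with the normal reference tissues: the threshold
#' criterion's reference-side condition must then also hold in the supplied
#' reference samples (hyper calls need all reference values < `low_beta`,
#' hypo calls all > `high_beta`).
#'
#' @param bm A [beta_matrix()].
#' @param sheet A [sample_sheet()] covering the matrix samples.
#' @param spec A [contrast_spec()].
#' @param cfg A [diffmeth_config()].
#' @param ann Optional [probe_annotation()]; when given, gene-level calls are
#'   returned as well.
#' @param reference_ids Optional tissue-reference sample ids for the
#'   three-way consistency requirement.
#' @return A list with `probe_calls` (`DiffMethCalls`), `gene_calls`
#'   (`GeneCalls` or `NULL`), `case_ids`, `ref_ids`.
#' @export
run_subgroup_contrast <- function(bm, sheet, spec, cfg = diffmeth_config(),
                                  ann = NULL, reference_ids = NULL) {
  ids <- resolve_contrast(sheet, spec)
  calls <- call_probes(bm, ids$case_ids, ids$ref_ids, cfg)
  if (!is.null(reference_ids)) {
    Rt <- bm$beta[, as.character(reference_ids), drop = FALSE]
    n_ok <- rowSums(!is.na(Rt))
    all_low <- rowSums(Rt < cfg$low_beta, na.rm = TRUE) == n_ok & n_ok > 0
    all_high <- rowSums(Rt > cfg$high_beta, na.rm = TRUE) == n_ok & n_ok > 0
    keep <- calls$direction == "none" |
      (calls$direction == "hyper" & all_low) |
      (calls$direction == "hypo" & all_high)
    calls$reference_consistent <- keep
    calls$direction[!keep] <- "none"
  }
  gene_calls <- if (!is.null(ann)) aggregate_to_genes(calls, ann) else NULL
  list(probe_calls = calls, gene_calls = gene_calls,
       case_ids = ids$case_ids, ref_ids = ids$ref_ids)
}

#' Write probe or gene calls to TSV
#' @param calls A `DiffMethCalls` or `GeneCalls` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
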