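# Calibration and parameter-recovery experiments for the consensus caller,
# run on the synthetic generator under its planted-truth registry. These are
# the package's operating-characteristic checks: family-wise error of the
# permutation t criterion under a global null, spurious consensus calls, and
# gene-level sensitivity/precision at a configured planted effect.

run_consensus <- function(ds, cfg) {
  per_ref <- lapply(ds$ref_sets, function(r)
    aggregate_to_genes(call_probes(ds$beta, ds$case_ids, r, cfg),
                       ds$annotation))
  consensus_across_references(per_ref)
}

#' Null calibration of the consensus caller
#'
#' Generates seeded synthetic datasets with no planted signal (tumor cases
#' against the default 1/1/3 reference tissues) and measures, per dataset,
#' the number of consensus gene calls and whether the step-down maxT
#' criterion declared any probe significant at `alpha` in the adequately
#' sized reference comparison (a family-wise error event under the global
#' null).
#'
#' @param n_datasets Number of simulated datasets (default 200).
#' @param n_probes,n_case Dataset dimensions (defaults 2000 probes, 20
#'   cases).
#' @param alpha Family-wise level checked on the maxT-adjusted p
#'   (default 0.05).
#' @param seed Base seed; dataset `i` uses `seed + i`.
#' @param cfg_fun Function of a seed returning the [diffmeth_config()] to
#'   use.
#' @return A list: `mean_consensus_calls`, `fwer_maxt` (fraction of datasets
#'   with any maxT-adjusted p below `alpha`), `n_datasets`, and the
#'   per-dataset data.frame `details`.
#' @export
null_calibration <- function(n_datasets = 200, n_probes = 2000, n_case = 20,
                             alpha = 0.05, seed = 1,
                             cfg_fun = function(s) diffmeth_config(seed = s)) {
  details <- do.call(rbind, lapply(seq_len(n_datasets), function(i) {
    s <- seed + i
    ds <- synthetic_dataset(synthetic_config(
      n_probes = n_probes, n_case = n_case,
      n_planted_hyper = 0, n_planted_hypo = 0, seed = s))
    cfg <- cfg_fun(s)
    per_ref <- lapply(ds$ref_sets, function(r)
      call_probes(ds$beta, ds$case_ids, r, cfg))
    genes <- lapply(per_ref, aggregate_to_genes, ann = ds$annotation)
    cons <- consensus_across_references(genes)
    tested <- Filter(function(x) !x$test_skipped[1], per_ref)
    min_padj <- if (length(tested))
      min(vapply(tested, function(x) min(x$p_adj), 0)) else NA_real_
    data.frame(seed = s,
               consensus_calls = length(cons$hyper) + length(cons$hypo),
               min_p_adj = min_padj,
               fwe_event = !is.na(min_padj) && min_padj < alpha)
  }))
  list(mean_consensus_calls = mean(details$consensus_calls),
       fwer_maxt = mean(details$fwe_event),
       n_datasets = n_datasets, details = details)
}

#' Parameter recovery of planted differential methylation
#'
#' Generates seeded replicates with planted hyper-/hypomethylated genes and
#' scores the consensus caller against the planted truth at the gene level:
#' sensitivity = recovered planted genes / planted genes, precision =
#' recovered planted genes / all consensus calls (pooled over replicates).
#'
#' @param n_replicates Number of replicates (default 25).
#' @param n_probes Probes per dataset (default 1500).
#' @param n_planted_hyper,n_planted_hypo Planted genes (defaults 10 and 30).
#' @param effect_delta Planted beta shift (default 0.6).
#' @param planted_case_fraction Carrier fraction among cases (default 0.5).
#' @param n_case Tumor cases (default 20).
#' @param seed Base seed; replicate `i` uses `seed + 1000 + i`.
#' @param cfg_fun Function of a seed returning the [diffmeth_config()].
#' @return A list: `sensitivity` and `precision` (pooled over replicates;
#'   precision is `NA` when nothing is called), `mean_sensitivity` (mean of
#'   per-replicate values), `n_replicates`, and per-replicate `details`.
#' @export
parameter_recovery <- function(n_replicates = 25, n_probes = 1500,
                               n_planted_hyper = 10, n_planted_hypo = 30,
                               effect_delta = 0.6,
                               planted_case_fraction = 0.5, n_case = 20,
                               seed = 1,
                               cfg_fun = function(s) diffmeth_config(seed = s)) {
  details <- do.call(rbind, lapply(seq_len(n_replicates), function(i) {
    s <- seed + 1000 + i
    ds <- synthetic_dataset(synthetic_config(
      n_probes = n_probes, n_case = n_case,
      n_planted_hyper = n_planted_hyper, n_planted_hypo = n_planted_hypo,
      effect_delta = effect_delta,
      planted_case_fraction = planted_case_fraction, seed = s))
    cons <- run_consensus(ds, cfg_fun(s))
    truth_hyper <- ds$truth$planted_hyper_genes
    truth_hypo <- ds$truth$planted_hypo_genes
    tp <- length(intersect(cons$hyper, truth_hyper)) +
      length(intersect(cons$hypo, truth_hypo))
    called <- length(cons$hyper) + length(cons$hypo)
    planted <- length(truth_hyper) + length(truth_hypo)
    data.frame(seed = s, true_positive = tp, called = called,
               planted = planted, sensitivity = tp / planted)
  }))
  tp <- sum(details$true_positive)
  called <- sum(details$called)
  list(sensitivity = tp / sum(details$planted),
       precision = if (called > 0) tp / called else NA_real_,
       mean_sensitivity = mean(details$sensitivity),
       n_replicates = n_replicates, details = details)
}
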