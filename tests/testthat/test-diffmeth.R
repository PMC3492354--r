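test_that("threshold criterion follows the stringent reference rule", {
  cfg <- diffmeth_config()
  # hyper: all refs < 0.25, 3/21 cases (14.3%) above 0.75
  case_hyper <- c(rep(0.8, 3), rep(0.2, 18))
  expect_identical(criterion_threshold(c(0.10, 0.15), case_hyper, cfg),
                   "hyper")
  # hypo at the inclusive 10% boundary: 2/20 cases below 0.25
  case_hypo <- c(rep(0.1, 2), rep(0.9, 18))
  expect_identical(criterion_threshold(c(0.90, 0.92), case_hypo, cfg),
                   "hypo")
  # intermediate everywhere: neither reference condition holds
  expect_identical(criterion_threshold(rep(0.5, 3), rep(0.5, 10), cfg),
                   "none")
  # one reference sample off the condition vetoes the call
  expect_identical(criterion_threshold(c(0.10, 0.30), case_hyper, cfg),
                   "none")
})

test_that("mean-difference criterion is strict at the cut-off", {
  cfg <- diffmeth_config()
  r <- criterion_meandiff(rep(0.30, 4), rep(0.60, 4), cfg)
  expect_true(r$passes)
  expect_equal(r$delta, 0.30)
  expect_false(criterion_meandiff(rep(0.30, 4), rep(0.55, 4), cfg)$passes)
  expect_false(criterion_meandiff(rep(0.5, 4), rep(0.5, 4), cfg)$passes)
})

make_two_probe_matrix <- function(n_case = 20, n_ref = 2, seed = 77) {
  set.seed(seed)
  # probe 1: planted hyper in half the cases (0.1 -> 0.9); probe 2: flat
  case_p1 <- c(rep(0.9, n_case / 2), rep(0.1, n_case / 2)) +
    runif(n_case, -0.02, 0.02)
  ref_p1 <- runif(n_ref, 0.08, 0.12)
  p2 <- runif(n_case + n_ref, 0.45, 0.55)
  m <- rbind(c(case_p1, ref_p1), p2)
  dimnames(m) <- list(c("cg_planted", "cg_flat"),
                      c(sprintf("NB%02d", seq_len(n_case)),
                        sprintf("REF%d", seq_len(n_ref))))
  beta_matrix(m)
}

test_that("a planted hyper probe passes all applicable criteria", {
  bm <- make_two_probe_matrix()
  calls <- call_probes(bm, sprintf("NB%02d", 1:20), c("REF1", "REF2"))
  planted <- calls[calls$probe_id == "cg_planted", ]
  expect_identical(planted$direction, "hyper")
  expect_true(planted$crit_threshold && planted$crit_meandiff)
  expect_true(planted$test_skipped)          # 2 references < min group of 3
  expect_true(is.na(planted$crit_test))
  expect_equal(planted$fraction_cases_shifted, 0.5)
  expect_identical(calls$direction[calls$probe_id == "cg_flat"], "none")
})

test_that("the t criterion is computed for adequately sized groups", {
  bm <- make_two_probe_matrix(n_ref = 3)
  calls <- call_probes(bm, sprintf("NB%02d", 1:20),
                       c("REF1", "REF2", "REF3"),
                       diffmeth_config(seed = 5))
  expect_false(any(calls$test_skipped))
  expect_false(anyNA(calls$crit_test))
  expect_true(all(is.finite(calls$q_fdr)))
})

test_that("overlapping or unknown sample sets are rejected", {
  bm <- make_two_probe_matrix()
  expect_error(call_probes(bm, c("NB01", "NB02"), c("NB02", "REF1")),
               class = "methcall_config_error")
  expect_error(call_probes(bm, c("NB01", "ghost"), "REF1"),
               class = "methcall_config_error")
})

test_that("a null synthetic dataset yields at most one consensus call", {
  ds <- synthetic_dataset(synthetic_config(
    n_probes = 2000, n_planted_hyper = 0, n_planted_hypo = 0, seed = 501))
  cfg <- diffmeth_config(seed = 501)
  per_ref <- lapply(ds$ref_sets, function(r)
    aggregate_to_genes(call_probes(ds$beta, ds$case_ids, r, cfg),
                       ds$annotation))
  cons <- consensus_across_references(per_ref)
  expect_lte(length(cons$hyper) + length(cons$hypo), 1)
})

test_that("gene aggregation applies the any-probe rule with direction flags", {
  ann <- probe_annotation(data.frame(
    probe_id = c("p1", "p2", "p3", "p4"),
    gene_symbol = c("A", "A", "B", "B"),
    chromosome = "1"))
  calls <- structure(data.frame(
    probe_id = c("p1", "p2", "p3", "p4"),
    direction = c("hyper", "none", "hyper", "hypo"),
    fraction_cases_shifted = c(0.6, 0.1, 0.4, 0.5),
    delta = c(0.4, 0.05, 0.3, -0.45),
    stringsAsFactors = FALSE), class = c("DiffMethCalls", "data.frame"))
  genes <- aggregate_to_genes(calls, ann)
  a <- genes[genes$gene_symbol == "A", ]
  expect_identical(a$direction, "hyper")
  expect_equal(a$n_supporting, 1L)
  expect_equal(a$best_fraction_cases, 0.6)
  b <- genes[genes$gene_symbol == "B", ]
  expect_true(b$ambiguous)
  expect_identical(b$direction, "ambiguous")
})

test_that("the CCND1-style fixture yields exactly two hypomethylated probes", {
  fx <- make_ccnd1_fixture()
  # the two 3'-UTR target probes are methylated (> 0.90) in every reference
  targets <- c("cg04717045", "cg02723533")
  expect_true(all(fx$beta$beta[targets, fx$ref_ids] > 0.90))
  # 17 of 21 tumors lose methylation there
  expect_equal(unname(rowSums(fx$beta$beta[targets, fx$case_ids] < 0.25)),
               c(17, 17))
  cfg <- diffmeth_config(seed = 11, exhaustive_limit = 70000)
  calls <- call_probes(fx$beta, fx$case_ids, fx$ref_ids, cfg)
  called <- calls$probe_id[calls$direction != "none"]
  expect_setequal(called, targets)
  expect_true(all(calls$direction[calls$probe_id %in% targets] == "hypo"))
  # gene-body probes fail the reference-consensus condition despite lower
  # tumor means (epigenetic heterogeneity in the references)
  body <- calls[grepl("body", calls$probe_id), ]
  expect_true(all(!body$crit_threshold))
  genes <- aggregate_to_genes(calls, fx$annotation)
  expect_identical(genes$gene_symbol, "CCND1")
  expect_identical(genes$direction, "hypo")
  expect_equal(genes$n_supporting, 2L)
})

test_that("consensus across references is the direction-aware intersection", {
  gc <- function(genes, dirs) {
    structure(data.frame(gene_symbol = genes, direction = dirs,
                         n_supporting = 1L, supporting_probes = "p",
                         best_fraction_cases = 0.5, max_abs_meandiff = 0.4,
                         ambiguous = FALSE, stringsAsFactors = FALSE),
              class = c("GeneCalls", "data.frame"))
  }
  same <- gc(c("A", "B"), c("hyper", "hypo"))
  cons <- consensus_across_references(list(FB = same, AG = same, GN = same))
  expect_identical(cons$hyper, "A")
  expect_identical(cons$hypo, "B")

  cons2 <- consensus_across_references(list(
    gc(c("A", "B", "C"), rep("hypo", 3)),
    gc(c("B", "C"), rep("hypo", 2)),
    gc(c("B", "C", "D"), rep("hypo", 3))))
  expect_identical(cons2$hypo, c("B", "C"))
  expect_lte(length(cons2$hypo), 2)   # <= min per-reference set size

  # direction conflict excludes the gene
  cons3 <- consensus_across_references(list(
    gc("A", "hyper"), gc("A", "hyper"), gc("A", "hypo")))
  expect_length(cons3$hyper, 0)
  expect_length(cons3$hypo, 0)

  expect_error(consensus_across_references(list(same)),
               class = "methcall_config_error")
})

test_that("gene ranking is deterministic with documented tie-breaks", {
  gc <- structure(data.frame(
    gene_symbol = c("Z", "A", "M", "B"),
    direction = "hypo", n_supporting = 1L, supporting_probes = "p",
    best_fraction_cases = c(0.5, 0.8, 0.5, 0.5),
    max_abs_meandiff = c(0.4, 0.3, 0.6, 0.4),
    ambiguous = FALSE, stringsAsFactors = FALSE),
    class = c("GeneCalls", "data.frame"))
  ranked <- rank_genes(gc)
  expect_identical(ranked$gene_symbol, c("A", "M", "B", "Z"))
  expect_identical(ranked$rank, 1:4)
})

test_that("raising thresholds never increases the number of calls", {
  ds <- synthetic_dataset(synthetic_config(n_probes = 600, seed = 502))
  base <- diffmeth_config(seed = 502)
  for (ref in ds$ref_sets) {
    n_base <- sum(call_probes(ds$beta, ds$case_ids, ref,
                              base)$direction != "none")
    for (cfg in list(diffmeth_config(mean_diff = 0.40, seed = 502),
                     diffmeth_config(case_fraction = 0.30, seed = 502))) {
      expect_lte(sum(call_probes(ds$beta, ds$case_ids, ref,
                                 cfg)$direction != "none"), n_base)
    }
  }
})

test_that("calls are invariant to probe and sample order", {
  ds <- synthetic_dataset(synthetic_config(n_probes = 200, seed = 503))
  cfg <- diffmeth_config(seed = 503)
  ref <- ds$ref_sets$FB
  calls <- call_probes(ds$beta, ds$case_ids, ref, cfg)
  set.seed(1)
  bm2 <- subset_beta(ds$beta, probes = sample(ds$beta$probe_ids),
                     samples = sample(ds$beta$sample_ids))
  calls2 <- call_probes(bm2, ds$case_ids, ref, cfg)
  calls2 <- calls2[match(calls$probe_id, calls2$probe_id), ]
  expect_identical(calls2$direction, calls$direction)
  expect_equal(calls2$delta, calls$delta, tolerance = 1e-12)
})

test_that("age contrasts partition the tumor series as configured", {
  # a series mirroring the study's age structure: 12 infants (< 18 months),
  # 4 intermediate, 5 children of five or more years
  sheet <- sample_sheet(data.frame(
    sample_id = sprintf("NB%02d", 1:21), group = "NB",
    inss_stage = rep(c("1", "2", "3", "4", "4S"), c(4, 4, 3, 6, 4)),
    mycn = replace(rep("non_amplified", 21), 12:16, "amplified"),
    age_months = c(runif(12, 0, 17), runif(4, 20, 55), runif(5, 61, 120))))
  ids <- resolve_contrast(sheet, contrast_spec("age", age_cutoff_months = 60))
  expect_length(ids$case_ids, 16)
  expect_length(ids$ref_ids, 5)
  ids18 <- resolve_contrast(sheet, contrast_spec("age", age_cutoff_months = 18))
  expect_length(ids18$case_ids, 12)

  hr_lr <- resolve_contrast(sheet, contrast_spec(
    "risk", case_levels = "HR", ref_levels = "LR"))
  expect_length(intersect(hr_lr$case_ids, hr_lr$ref_ids), 0)
  expect_error(resolve_contrast(sheet, contrast_spec(
    "inss_stage", case_levels = "4", ref_levels = character(0))),
    class = "methcall_config_error")
})

test_that("subgroup-planted signals surface only in the matching contrast", {
  ds <- synthetic_dataset(synthetic_config(
    n_probes = 2000, n_planted_hyper = 0, n_planted_hypo = 0, seed = 504,
    subgroup_specs = list(list(field = "mycn", level = "amplified",
                               n_genes = 3, direction = "hyper",
                               delta = 0.75, carrier_fraction = 1))))
  planted <- ds$truth$subgroup$gene_symbol
  cfg <- diffmeth_config(seed = 504)
  hit <- run_subgroup_contrast(
    ds$beta, ds$sheet,
    contrast_spec("mycn", case_levels = "amplified",
                  ref_levels = "non_amplified"),
    cfg, ann = ds$annotation)
  called <- hit$gene_calls$gene_symbol[hit$gene_calls$direction == "hyper"]
  expect_true(all(planted %in% called))

  miss <- run_subgroup_contrast(
    ds$beta, ds$sheet, contrast_spec("age", age_cutoff_months = 18),
    cfg, ann = ds$annotation)
  called_age <- miss$gene_calls$gene_symbol[miss$gene_calls$direction != "none"]
  expect_length(intersect(planted, called_age), 0)
})

test_that("reference consistency can veto subgroup calls", {
  ds <- synthetic_dataset(synthetic_config(
    n_probes = 400, n_planted_hyper = 0, n_planted_hypo = 0, seed = 505,
    subgroup_specs = list(list(field = "mycn", level = "amplified",
                               n_genes = 2, direction = "hyper",
                               delta = 0.75, carrier_fraction = 1))))
  cfg <- diffmeth_config(seed = 505)
  spec <- contrast_spec("mycn", case_levels = "amplified",
                        ref_levels = "non_amplified")
  plain <- run_subgroup_contrast(ds$beta, ds$sheet, spec, cfg)
  with_refs <- run_subgroup_contrast(ds$beta, ds$sheet, spec, cfg,
                                     reference_ids = unlist(ds$ref_sets))
  n_plain <- sum(plain$probe_calls$direction != "none")
  n_cons <- sum(with_refs$probe_calls$direction != "none")
  expect_lte(n_cons, n_plain)
  # planted hyper probes start unmethylated in the reference tissues, so
  # they survive the consistency requirement
  expect_gt(n_cons, 0)
})
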