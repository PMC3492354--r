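make_expr <- function(m) {
  dimnames(m) <- list(sprintf("G%02d", seq_len(nrow(m))),
                      sprintf("S%02d", seq_len(ncol(m))))
  m
}

test_that("z-score transform standardizes per gene over the population", {
  expr <- make_expr(rbind(c(1, 2, 3), c(5, 5, 5)))
  zm <- zscore_transform(expr)
  expect_equal(unname(zm$z[1, ]), c(-1, 0, 1))          # sample SD (n-1)
  expect_true(zm$source_stats$flagged[2])               # constant gene
  expect_true(all(is.na(zm$z[2, ])))
  zp <- zscore_transform(expr, sd_type = "population")
  expect_equal(unname(zp$z[1, ]), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-12)
  # population mean 0, sd 1 by construction
  set.seed(81)
  big <- make_expr(matrix(rnorm(200, 5, 3), nrow = 10))
  zb <- zscore_transform(big)
  expect_equal(unname(rowMeans(zb$z)), rep(0, 10), tolerance = 1e-9)
  expect_equal(unname(apply(zb$z, 1, sd)), rep(1, 10), tolerance = 1e-9)
})

test_that("z-scoring is idempotent and validates the population", {
  set.seed(82)
  expr <- make_expr(matrix(rnorm(60, 10, 2), nrow = 5))
  z1 <- zscore_transform(expr)$z
  z2 <- zscore_transform(z1)$z
  expect_equal(z2, z1, tolerance = 1e-9)
  expect_error(zscore_transform(expr, population = c("S01", "nope")),
               class = "methcall_config_error")
  # standardization over a sub-population applies those stats to all samples
  zs <- zscore_transform(expr, population = c("S01", "S02", "S03"))
  expect_equal(unname(rowMeans(zs$z[, 1:3])), rep(0, 5), tolerance = 1e-9)
})

test_that("differential expression needs both significance and prevalence", {
  # 10 cases vs 4 references; gene G01 strongly up in cases, G02 null
  set.seed(83)
  expr <- make_expr(rbind(c(rnorm(10, 8, 0.5), rnorm(4, 3, 0.5)),
                          rnorm(14, 5, 0.5),
                          rnorm(14, 5, 0.5)))
  # standardize over the reference population: tumors form the majority of
  # the series, so all-sample standardization would cap their attainable z
  zm <- zscore_transform(expr, population = sprintf("S%02d", 11:14))
  calls <- call_differential_expression(
    zm, sprintf("S%02d", 1:10), sprintf("S%02d", 11:14),
    expression_de_config(seed = 83))
  expect_identical(calls$direction[1], "up")
  expect_identical(calls$direction[2], "none")
  expect_true(calls$frac_above[1] > 0.5)
})

test_that("the >50% prevalence rule is strict at the boundary", {
  set.seed(84)
  z <- make_expr(rbind(
    c(rep(2, 5), rep(0, 5), rep(0, 4)),     # exactly 5/10 cases above 1
    c(rep(2, 6), rep(0, 4), rep(0, 4)),     # 6/10 cases above 1
    c(rep(-2, 6), rep(0, 4), rep(0, 4))))   # 6/10 cases below -1
  zmat <- structure(list(z = z, gene_symbols = rownames(z),
                         sample_ids = colnames(z),
                         source_stats = NULL, population = colnames(z),
                         sd_type = "sample"), class = "ExpressionZMatrix")
  # alpha = 1 on the raw p, so only the prevalence rule decides
  cfg <- expression_de_config(alpha = 1, use_adjusted = FALSE, seed = 1)
  calls <- call_differential_expression(zmat, sprintf("S%02d", 1:10),
                                        sprintf("S%02d", 11:14), cfg)
  expect_identical(calls$direction, c("none", "up", "down"))
  expect_equal(calls$frac_above[1], 0.5)
})

test_that("planted methylation-coupled expression is recovered", {
  # full-penetrance plants: the adjusted-p rule at alpha 0.01 demands a
  # permutation p near the attainable floor, which partial-carrier (bimodal)
  # case groups cannot reach against a 5-sample reference
  ds <- synthetic_dataset(synthetic_config(
    n_probes = 1000, seed = 506, planted_case_fraction = 1,
    expression_coupling = 1, expression_effect = 3))
  refs <- unlist(ds$ref_sets, use.names = FALSE)
  zm <- zscore_transform(ds$expression, population = refs)
  calls <- call_differential_expression(
    zm, ds$case_ids, refs,
    expression_de_config(seed = 506, n_perm = 4000))
  resp <- ds$truth$expression_responsive
  got <- calls$direction[match(resp$gene_symbol, calls$gene_symbol)]
  expect_gte(mean(got == resp$direction), 0.8)
  # null genes stay quiet
  null_genes <- setdiff(calls$gene_symbol, resp$gene_symbol)
  null_dir <- calls$direction[match(null_genes, calls$gene_symbol)]
  expect_lte(mean(null_dir != "none"), 0.02)
})

test_that("concordance percentages use exact counts truncated to 1 decimal", {
  gene_calls <- structure(data.frame(
    gene_symbol = c(sprintf("HY%02d", 1:13), sprintf("HO%03d", 1:136)),
    direction = c(rep("hyper", 13), rep("hypo", 136)),
    stringsAsFactors = FALSE), class = c("GeneCalls", "data.frame"))
  expr_calls <- structure(data.frame(
    gene_symbol = gene_calls$gene_symbol,
    direction = c(rep("down", 5), rep("none", 8),      # 5/13 hyper -> down
                  rep("up", 10), rep("none", 126)),    # 10/136 hypo -> up
    stringsAsFactors = FALSE), class = c("ExpressionCalls", "data.frame"))
  cs <- concordance_summary(gene_calls, expr_calls)
  hyper <- cs[cs$direction == "hyper", ]
  hypo <- cs[cs$direction == "hypo", ]
  expect_equal(hyper$n_concordant, 5)
  expect_equal(hyper$n_evaluable, 13)
  expect_equal(hyper$pct_concordant, 38.4)
  expect_equal(hypo$pct_concordant, 7.3)
})

test_that("concordance with no evaluable genes reports NA", {
  gene_calls <- structure(data.frame(gene_symbol = "A", direction = "hyper",
                                     stringsAsFactors = FALSE),
                          class = c("GeneCalls", "data.frame"))
  expr_calls <- structure(data.frame(gene_symbol = "B", direction = "up",
                                     stringsAsFactors = FALSE),
                          class = c("ExpressionCalls", "data.frame"))
  cs <- concordance_summary(gene_calls, expr_calls)
  expect_true(is.na(cs$pct_concordant[cs$direction == "hyper"]))
})
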