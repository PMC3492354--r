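# Methylation-expression concordance: z-score transformation of an
# expression matrix, the differential-expression rule (significant test AND
# |z| > 1 in more than half of case samples), and the per-direction
# concordance summary for differentially methylated genes.

#' Z-score transform an expression matrix
#'
#' Standardizes each gene over a named standardization population (default:
#' all samples): `z = (x - mean) / sd`, with the population statistics
#' applied to every sample. Genes with (near) zero standard deviation over
#' the population are flagged and their z values set missing.
#'
#' @param expr Numeric matrix, genes x samples (dimnames required).
#' @param population Sample ids over which mean and sd are computed
#'   (default all columns). Must be a subset of the matrix samples.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`
#'   (n denominator).
#' @return A list of class `ExpressionZMatrix`: `z` (matrix), `gene_symbols`,
#'   `sample_ids`, `source_stats` (data.frame `gene_symbol`, `mean`, `sd`,
#'   `flagged`), `population`, `sd_type`.
#' @export
zscore_transform <- function(expr, population = NULL,
                             sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (!is.matrix(expr) || is.null(rownames(expr)) || is.null(colnames(expr))) {
    abort("`expr` must be a matrix with gene rownames and sample colnames",
          "methcall_format_error")
  }
  population <- population %||% colnames(expr)
  outside <- setdiff(population, colnames(expr))
  if (length(outside)) {
    abort(sprintf("standardization population not in matrix: %s",
                  paste(utils::head(outside, 5), collapse = ", ")),
          "methcall_config_error")
  }
  sub <- expr[, population, drop = FALSE]
  mu <- rowMeans(sub, na.rm = TRUE)
  n_ok <- rowSums(!is.na(sub))
  ss <- rowSums((sub - mu)^2, na.rm = TRUE)
  denom <- if (sd_type == "sample") pmax(n_ok - 1, 1) else pmax(n_ok, 1)
  sdv <- sqrt(ss / denom)
  flagged <- !is.finite(sdv) | sdv < 1e-12 | n_ok < 2
  z <- (expr - mu) / sdv
  z[flagged, ] <- NA_real_
  structure(list(
    z = z, gene_symbols = rownames(expr), sample_ids = colnames(expr),
    source_stats = data.frame(gene_symbol = rownames(expr), mean = unname(mu),
                              sd = unname(sdv), flagged = unname(flagged),
                              stringsAsFactors = FALSE),
    population = population, sd_type = sd_type),
    class = "ExpressionZMatrix")
}

#' Differential-expression configuration
#'
#' @param alpha Significance cut-off applied to the (by default FDR-adjusted)
#'   permutation t p-value (default 0.01).
#' @param z_cut z-score magnitude a case sample must exceed (default 1).
#' @param min_fraction Fraction of case samples that must exceed `z_cut`,
#'   strict (default 0.5).
#' @param use_adjusted Apply `alpha` to the BH q-value (default) or to the
#'   raw permutation p.
#' @param n_perm,seed,exhaustive_limit,var_equal Passed to [maxt_stepdown()].
#' @return A list of class `ExpressionDEConfig`.
#' @export
expression_de_config <- function(alpha = 0.01, z_cut = 1, min_fraction = 0.5,
                                 use_adjusted = TRUE, n_perm = 1000,
                                 seed = 1L, exhaustive_limit = 20000,
                                 var_equal = TRUE) {
  stopifnot_fraction(alpha, "alpha")
  stopifnot_fraction(min_fraction, "min_fraction")
  structure(list(alpha = alpha, z_cut = z_cut, min_fraction = min_fraction,
                 use_adjusted = isTRUE(use_adjusted),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 exhaustive_limit = as.integer(exhaustive_limit),
                 var_equal = isTRUE(var_equal)),
            class = "ExpressionDEConfig")
}

#' Call differential expression on z-transformed data
#'
#' A gene is `"up"` when the permutation t test (step-down maxT + BH FDR,
#' computed jointly over genes) is significant at `cfg$alpha` and its z-score
#' exceeds `cfg$z_cut` in strictly more than `cfg$min_fraction` of the case
#' samples; `"down"` symmetrically with `z < -z_cut`.
#'
#' @param zmat An [zscore_transform()] result.
#' @param case_ids,ref_ids Disjoint sample id sets (each >= 2).
#' @param cfg An [expression_de_config()].
#' @return A data.frame of class `ExpressionCalls`: `gene_symbol`,
#'   `direction` (up/down/none), `frac_above`, `frac_below`, `p_raw`,
#'   `p_adj`, `q_fdr`.
#' @export
call_differential_expression <- function(zmat, case_ids, ref_ids,
                                         cfg = expression_de_config()) {
  stopifnot(inherits(zmat, "ExpressionZMatrix"))
  case_ids <- as.character(case_ids); ref_ids <- as.character(ref_ids)
  if (length(intersect(case_ids, ref_ids))) {
    abort("case and reference sample sets overlap", "methcall_config_error")
  }
  missing_ids <- setdiff(c(case_ids, ref_ids), zmat$sample_ids)
  if (length(missing_ids)) {
    abort(sprintf("sample id(s) not in expression matrix: %s",
                  paste(utils::head(missing_ids, 5), collapse = ", ")),
          "methcall_config_error")
  }
  X <- zmat$z[, c(case_ids, ref_ids), drop = FALSE]
  labels <- c(rep("case", length(case_ids)), rep("ref", length(ref_ids)))
  perm <- maxt_stepdown(X, labels, n_perm = cfg$n_perm, seed = cfg$seed,
                        exhaustive_limit = cfg$exhaustive_limit,
                        var_equal = cfg$var_equal)
  q <- bh_fdr(perm$p_raw)
  sig <- if (cfg$use_adjusted) q < cfg$alpha else perm$p_raw < cfg$alpha
  Zc <- zmat$z[, case_ids, drop = FALSE]
  frac_above <- rowMeans(Zc > cfg$z_cut, na.rm = TRUE)
  frac_below <- rowMeans(Zc < -cfg$z_cut, na.rm = TRUE)
  frac_above[is.nan(frac_above)] <- NA_real_
  frac_below[is.nan(frac_below)] <- NA_real_
  up <- sig & !is.na(frac_above) & frac_above > cfg$min_fraction
  down <- sig & !is.na(frac_below) & frac_below > cfg$min_fraction
  direction <- ifelse(up & !down, "up", ifelse(down & !up, "down", "none"))
  out <- data.frame(gene_symbol = zmat$gene_symbols, direction = direction,
                    frac_above = frac_above, frac_below = frac_below,
                    p_raw = perm$p_raw, p_adj = perm$p_adj, q_fdr = q,
                    stringsAsFactors = FALSE)
  class(out) <- c("ExpressionCalls", "data.frame")
  out
}

#' Methylation-expression concordance summary
#'
#' Counts, among differentially methylated genes with available expression
#' calls, those whose expression moved the opposite way for hypermethylation
#' (down) and the same way for hypomethylation (up). Percentages are exact
#' rational counts truncated to one decimal.
#'
#' @param gene_calls A `GeneCalls` data.frame (directions hyper/hypo).
#' @param expr_calls An `ExpressionCalls` data.frame.
#' @return A data.frame of class `ConcordanceSummary` with one row per
#'   methylation direction: `direction`, `n_meth_genes`, `n_evaluable`
#'   (genes with an expression call), `n_concordant`, `pct_concordant`
#'   (NA when nothing is evaluable).
#' @export
concordance_summary <- function(gene_calls, expr_calls) {
  one <- function(meth_dir, expr_dir) {
    genes <- gene_calls$gene_symbol[gene_calls$direction == meth_dir]
    idx <- match(genes, expr_calls$gene_symbol)
    evaluable <- genes[!is.na(idx)]
    edir <- expr_calls$direction[idx[!is.na(idx)]]
    k <- sum(edir == expr_dir)
    data.frame(direction = meth_dir, n_meth_genes = length(genes),
               n_evaluable = length(evaluable), n_concordant = k,
               pct_concordant = truncate_pct(k, length(evaluable)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("hyper", "down"), one("hypo", "up"))
  class(out) <- c("ConcordanceSummary", "data.frame")
  out
}

#' Read an expression matrix from TSV
#'
#' @param path Tab-delimited genes x samples matrix, first column gene
#'   symbols, header row of sample ids.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  read_numeric_tsv_generic(path, "expression matrix")
}

read_numeric_tsv_generic <- function(path, what) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) {
    abort(sprintf("%s file '%s' needs an id column plus sample columns",
                  what, path), "methcall_format_error")
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate ids in %s file '%s'", what, path),
          "methcall_format_error")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write an expression matrix to TSV
#' @param expr Numeric genes x samples matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  write_matrix_tsv(expr, path, id_col = "gene_symbol")
}
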