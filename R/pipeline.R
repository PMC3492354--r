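# Pipeline orchestration: one structured YAML config drives staged runs
# (simulate -> qc -> per-reference calls -> consensus -> expression /
# enrichment / profiles). Every output TSV carries a header comment with the
# stage, a hash of the configuration and the seed; chained stages refuse
# inputs written under a different config hash unless forced.

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `paths` (beta, detection_p, annotation,
#' sample_sheet, expression, out_dir), `qc`, `diffmeth`, `expression_de`,
#' `synthetic`, `comparisons` (list of `name` + `ref_groups`, with optional
#' `case_groups`, default `NB`), and `seed`.
#'
#' @param path YAML file path.
#' @return A list of class `PipelineConfig` with sub-configs instantiated
#'   and a `hash` field identifying the configuration.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(raw)
}

#' Build a pipeline configuration from a list
#'
#' @param raw A list following the layout of [read_pipeline_config()].
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(raw) {
  seed <- as.integer(raw$seed %||% 1L)
  cfg <- list(
    paths = raw$paths %||% list(),
    qc = do.call(qc_config, raw$qc %||% list()),
    diffmeth = do.call(diffmeth_config,
                       utils::modifyList(list(seed = seed),
                                         raw$diffmeth %||% list())),
    expression_de = do.call(expression_de_config,
                            utils::modifyList(list(seed = seed),
                                              raw$expression_de %||% list())),
    synthetic = raw$synthetic %||% list(),
    comparisons = raw$comparisons %||% list(
      list(name = "FB", ref_groups = "FB"),
      list(name = "AG", ref_groups = "AG"),
      list(name = "GN", ref_groups = c("GN", "GNB"))),
    seed = seed)
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "PipelineConfig"
  cfg
}

# Hash of the analytic configuration (QC/calling/expression parameters,
# comparisons, seed); file locations are deliberately excluded so the same
# analysis in a different directory chains cleanly.
config_hash <- function(cfg) {
  x <- cfg[setdiff(names(cfg), c("hash", "paths"))]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(x), collapse = "\n"), tf)
  substr(unname(tools::md5sum(tf)), 1, 8)
}

write_stage_tsv <- function(df, path, stage, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# methcall stage=%s", stage),
               sprintf("# config_hash=%s", cfg$hash),
               sprintf("# seed=%d", cfg$seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_stage_header <- function(path) {
  lines <- readLines(path, n = 5)
  hdr <- grep("^# ", lines, value = TRUE)
  get <- function(key) {
    hit <- grep(paste0(key, "="), hdr, value = TRUE)
    if (length(hit)) sub(paste0(".*", key, "="), "", hit[1]) else NA_character_
  }
  list(stage = sub(".*stage=", "", get("stage")), hash = get("config_hash"),
       seed = get("seed"))
}

check_stage_hash <- function(path, cfg, force = FALSE) {
  hdr <- read_stage_header(path)
  if (!force && !is.na(hdr$hash) && !identical(hdr$hash, cfg$hash)) {
    abort(sprintf(
      "'%s' was written under config hash %s, current config is %s (use force to override)",
      path, hdr$hash, cfg$hash), "methcall_stage_error")
  }
  invisible(TRUE)
}

out_path <- function(cfg, name) {
  dir <- cfg$paths$out_dir %||% "."
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  file.path(dir, name)
}

#' Simulate a study and write its input files
#'
#' Generates a [synthetic_dataset()] from `config$synthetic` (seeded by
#' `config$seed`) and writes the beta matrix, detection p-values,
#' annotation, sample sheet, expression matrix and planted-truth gene table
#' to the output directory, in the same formats the readers consume.
#'
#' @param config A [pipeline_config()].
#' @return The `SyntheticDataset`, invisibly; side effect: files under
#'   `config$paths$out_dir`.
#' @export
pipeline_simulate <- function(config) {
  args <- utils::modifyList(list(seed = config$seed), config$synthetic)
  ds <- synthetic_dataset(do.call(synthetic_config, args))
  write_beta_matrix(ds$beta, out_path(config, "beta.tsv"),
                    out_path(config, "detection_p.tsv"))
  write_annotation(ds$annotation, out_path(config, "annotation.tsv"))
  write_sample_sheet(ds$sheet, out_path(config, "sample_sheet.tsv"))
  write_expression_matrix(ds$expression, out_path(config, "expression.tsv"))
  truth <- rbind(
    data.frame(gene_symbol = ds$truth$planted_hyper_genes,
               direction = "hyper", stringsAsFactors = FALSE),
    data.frame(gene_symbol = ds$truth$planted_hypo_genes,
               direction = "hypo", stringsAsFactors = FALSE))
  write_stage_tsv(truth, out_path(config, "truth_genes.tsv"), "simulate",
                  config)
  invisible(ds)
}

#' Run QC and write the filtered matrix and exclusion reports
#'
#' @param config A [pipeline_config()] whose `paths` name the beta matrix,
#'   optional detection p-values and the annotation.
#' @return A list with the filtered `BetaMatrix` and both reports,
#'   invisibly; side effect: `beta_qc.tsv`, `qc_probe_report.tsv`,
#'   `qc_sample_report.tsv`.
#' @export
pipeline_qc <- function(config) {
  bm <- read_beta_matrix(config$paths$beta, config$paths$detection_p)
  ann <- read_annotation(config$paths$annotation)
  fs <- if (is.null(bm$detection_p)) list(beta = bm, report = NULL)
        else filter_samples(bm, config$qc)
  fp <- filter_probes(fs$beta, ann, config$qc)
  write_beta_matrix(fp$beta, out_path(config, "beta_qc.tsv"))
  write_stage_tsv(fp$report, out_path(config, "qc_probe_report.tsv"), "qc",
                  config)
  if (!is.null(fs$report)) {
    write_stage_tsv(fs$report, out_path(config, "qc_sample_report.tsv"),
                    "qc", config)
  }
  invisible(list(beta = fp$beta, probe_report = fp$report,
                 sample_report = fs$report))
}

#' Run one reference comparison and write probe and gene calls
#'
#' @param config A [pipeline_config()].
#' @param comparison One entry of `config$comparisons` (`name`,
#'   `ref_groups`, optional `case_groups`).
#' @param bm Optional `BetaMatrix` (defaults to reading `beta_qc.tsv` from
#'   the output directory, with a config-hash check on the QC report).
#' @return A list with `probe_calls` and `gene_calls`, invisibly.
#' @export
pipeline_call <- function(config, comparison, bm = NULL) {
  sheet <- read_sample_sheet(config$paths$sample_sheet)
  ann <- read_annotation(config$paths$annotation)
  if (is.null(bm)) {
    check_stage_hash(out_path(config, "qc_probe_report.tsv"), config)
    bm <- read_beta_matrix(out_path(config, "beta_qc.tsv"))
  }
  case_groups <- comparison$case_groups %||% "NB"
  case_ids <- intersect(sheet$sample_id[sheet$group %in% case_groups],
                        bm$sample_ids)
  ref_ids <- intersect(sheet$sample_id[sheet$group %in% comparison$ref_groups],
                       bm$sample_ids)
  calls <- call_probes(bm, case_ids, ref_ids, config$diffmeth)
  genes <- aggregate_to_genes(calls, ann)
  write_stage_tsv(as.data.frame(calls),
                  out_path(config, sprintf("probe_calls_%s.tsv",
                                           comparison$name)),
                  "call", config)
  write_stage_tsv(as.data.frame(genes),
                  out_path(config, sprintf("gene_calls_%s.tsv",
                                           comparison$name)),
                  "call", config)
  invisible(list(probe_calls = calls, gene_calls = genes))
}

read_gene_calls_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  class(df) <- c("GeneCalls", "data.frame")
  df
}

#' Intersect per-reference gene calls and write the consensus
#'
#' @param config A [pipeline_config()].
#' @param gene_call_paths Paths to >= 2 gene-call TSVs written by
#'   [pipeline_call()] (config hash checked).
#' @param force Skip the config-hash check.
#' @return The [consensus_across_references()] result, invisibly; side
#'   effect: `consensus_genes.tsv` (ranked) and `venn_regions.tsv`.
#' @export
pipeline_consensus <- function(config, gene_call_paths, force = FALSE) {
  if (length(gene_call_paths) < 2) {
    abort("consensus needs >= 2 gene-call inputs", "methcall_config_error")
  }
  per_ref <- lapply(gene_call_paths, function(p) {
    check_stage_hash(p, config, force)
    read_gene_calls_tsv(p)
  })
  names(per_ref) <- sub("^gene_calls_", "",
                        sub("\\.tsv$", "", basename(gene_call_paths)))
  cons <- consensus_across_references(per_ref)
  ranked <- rank_genes(cons$genes)
  write_stage_tsv(as.data.frame(ranked),
                  out_path(config, "consensus_genes.tsv"), "consensus",
                  config)
  write_stage_tsv(cons$venn, out_path(config, "venn_regions.tsv"),
                  "consensus", config)
  invisible(cons)
}

#' Differential expression and methylation-expression concordance
#'
#' @param config A [pipeline_config()] naming the expression matrix and
#'   sample sheet.
#' @param gene_calls A `GeneCalls` data.frame (e.g. the ranked consensus).
#' @return A list with `expr_calls` and `concordance`, invisibly; side
#'   effect: `expression_calls.tsv`, `concordance.tsv`.
#' @export
pipeline_expression <- function(config, gene_calls) {
  expr <- read_expression_matrix(config$paths$expression)
  sheet <- read_sample_sheet(config$paths$sample_sheet)
  zm <- zscore_transform(expr)
  case_ids <- intersect(sheet$sample_id[sheet$group == "NB"],
                        colnames(expr))
  ref_ids <- intersect(sheet$sample_id[sheet$group != "NB"], colnames(expr))
  ec <- call_differential_expression(zm, case_ids, ref_ids,
                                     config$expression_de)
  conc <- concordance_summary(gene_calls, ec)
  write_stage_tsv(ec, out_path(config, "expression_calls.tsv"),
                  "expression", config)
  write_stage_tsv(conc, out_path(config, "concordance.tsv"), "expression",
                  config)
  invisible(list(expr_calls = ec, concordance = conc))
}

#' Annotation enrichment of a called gene set
#'
#' Runs chromosome/cytoband distribution plus promoter-class and
#' Polycomb-target enrichment against the post-QC background.
#'
#' @param config A [pipeline_config()].
#' @param genes Called gene symbols.
#' @param label Output file tag (e.g. `"hypo"`).
#' @return A list of enrichment tables, invisibly; side effects:
#'   `enrichment_<label>_*.tsv`.
#' @export
pipeline_enrich <- function(config, genes, label = "genes") {
  ann <- read_annotation(config$paths$annotation)
  gmap <- unique(data.frame(gene = ann$gene_symbol,
                            promoter_class = ann$promoter_class,
                            pcg = ann$is_pcg_target, stringsAsFactors = FALSE))
  gmap <- gmap[!duplicated(gmap$gene), , drop = FALSE]
  background <- gmap$gene
  genes <- intersect(genes, background)
  chrom <- chromosome_distribution(genes, ann)
  prom <- enrich_category(genes, background,
                          split(gmap$gene, gmap$promoter_class))
  pcg_map <- list(PcG_target = gmap$gene[!is.na(gmap$pcg) & gmap$pcg])
  pcg <- enrich_category(genes, background, pcg_map)
  write_stage_tsv(chrom$chromosomes,
                  out_path(config, sprintf("enrichment_%s_chromosomes.tsv",
                                           label)), "enrich", config)
  write_stage_tsv(chrom$cytobands,
                  out_path(config, sprintf("enrichment_%s_cytobands.tsv",
                                           label)), "enrich", config)
  write_stage_tsv(rbind(prom, pcg),
                  out_path(config, sprintf("enrichment_%s_categories.tsv",
                                           label)), "enrich", config)
  invisible(list(chromosomes = chrom$chromosomes,
                 cytobands = chrom$cytobands, promoter = prom, pcg = pcg))
}

#' PCA and hierarchical-clustering views
#'
#' @param config A [pipeline_config()].
#' @param bm A `BetaMatrix` (e.g. the QC output).
#' @param probe_subset Optional probes for the supervised view.
#' @return A list with `pca` and `dendrogram`, invisibly; side effects:
#'   `pca_scores.tsv`, `dendrogram.nwk`.
#' @export
pipeline_profiles <- function(config, bm, probe_subset = NULL) {
  pca <- beta_pca(bm)
  dend <- beta_hclust(bm, probe_subset = probe_subset)
  write_pca_scores(pca, out_path(config, "pca_scores.tsv"))
  dendrogram_newick(dend, out_path(config, "dendrogram.nwk"))
  invisible(list(pca = pca, dendrogram = dend))
}

#' Run the full pipeline on simulated data
#'
#' Convenience chain: simulate, QC, one call per configured comparison,
#' consensus, expression concordance, enrichment of the hypomethylated
#' consensus set, and profile views; all files land in
#' `config$paths$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return A list with the main stage results.
#' @export
run_pipeline <- function(config) {
  ds <- pipeline_simulate(config)
  config$paths$beta <- out_path(config, "beta.tsv")
  config$paths$detection_p <- out_path(config, "detection_p.tsv")
  config$paths$annotation <- out_path(config, "annotation.tsv")
  config$paths$sample_sheet <- out_path(config, "sample_sheet.tsv")
  config$paths$expression <- out_path(config, "expression.tsv")
  qc <- pipeline_qc(config)
  calls <- lapply(config$comparisons, function(cmp)
    pipeline_call(config, cmp, bm = qc$beta))
  names(calls) <- vapply(config$comparisons, `[[`, "", "name")
  cons <- consensus_across_references(lapply(calls, `[[`, "gene_calls"))
  ranked <- rank_genes(cons$genes)
  write_stage_tsv(as.data.frame(ranked),
                  out_path(config, "consensus_genes.tsv"), "consensus",
                  config)
  write_stage_tsv(cons$venn, out_path(config, "venn_regions.tsv"),
                  "consensus", config)
  expr <- pipeline_expression(config, ranked)
  enr <- if (length(cons$hypo))
    pipeline_enrich(config, cons$hypo, "hypo") else NULL
  prof <- pipeline_profiles(config, qc$beta)
  list(dataset = ds, qc = qc, calls = calls, consensus = cons,
       ranked = ranked, expression = expr, enrichment = enr,
       profiles = prof)
}
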