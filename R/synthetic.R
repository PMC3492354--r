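# Seeded synthetic-data generator emulating the statistical structure of a
# 27K-style tumor methylation study: bimodal per-probe beta baselines
# (unmethylated ~0.10, methylated ~0.85), a tumor case series against three
# small reference tissue sets (two single-sample tissues plus one
# three-sample tissue), planted hyper-/hypomethylated genes carried by a
# configurable fraction of cases, gonosomal probes, detection p-values with
# plantable failures, clinical subgroup signals, and an expression matrix
# anti-/co-varying with the planted methylation. Every draw is seeded; the
# planted truth is returned as a registry for sensitivity/precision scoring.

#' Synthetic dataset configuration
#'
#' Defaults emulate a small neuroblastic-tumor study: ~2 CpG probes per
#' gene, 20 tumor cases, reference tissues of sizes 1/1/3, a bimodal beta
#' baseline (means 0.10 / 0.85, concentration 50), and differential signals
#' of Δβ = 0.6 carried by half of the cases.
#'
#' @param n_probes Number of probes (default 2000).
#' @param probes_per_gene Probes per gene (default 2; the gene count is
#'   `ceiling(n_probes / probes_per_gene)`).
#' @param n_case Number of tumor cases (default 20).
#' @param ref_sizes Named integer vector of reference tissue sizes
#'   (default `c(FB = 1, AG = 1, GN = 3)`; within a size-3 `GN` tissue the
#'   last sample is labeled `GNB` to mirror a mixed neuroblastic reference
#'   set).
#' @param mix_fractions Baseline state mixture over probes
#'   (unmethylated / methylated / intermediate; default 0.45/0.35/0.20).
#' @param mix_means Beta means of the three baseline states
#'   (default 0.10/0.85/0.50).
#' @param concentration Beta-distribution concentration (a+b); noise sd at
#'   mean m is `sqrt(m (1-m) / (concentration + 1))` (default 50).
#' @param n_planted_hyper,n_planted_hypo Planted differential genes
#'   (defaults 10 and 30; hypomethylation dominates, as in neuroblastic
#'   tumors).
#' @param effect_delta Planted beta shift in carrier cases (default 0.6,
#'   clipped so means stay in \[0, 1\]).
#' @param planted_case_fraction Fraction of cases carrying each planted
#'   signal (default 0.5; realized carrier count is the rounded value).
#' @param subgroup_specs List of subgroup signals, each a list with `field`
#'   (sample-sheet column), `level`, `n_genes`, `direction`, and optional
#'   `delta`, `carrier_fraction`.
#' @param expression_coupling Fraction of planted genes with an expression
#'   response (default 0.5).
#' @param expression_effect Expression response magnitude in z units
#'   (default 2; hypermethylation couples to down-, hypomethylation to
#'   up-regulation).
#' @param gonosomal_fraction Fraction of probes on chrX/chrY (default 0.05).
#' @param bad_sample_count Cases with planted detection failures
#'   (default 0).
#' @param bad_sample_fail_fraction Fraction of probes failing in a bad
#'   sample (default 0.05).
#' @param n_bad_probes Probes with planted detection failures across many
#'   samples (default 0).
#' @param bad_probe_fail_fraction Fraction of samples in which a bad probe
#'   fails (default 0.20).
#' @param missing_fraction Fraction of beta entries set missing
#'   (default 0).
#' @param detection_p_max Upper bound of clean detection p-values
#'   (default 0.005).
#' @param seed Mandatory RNG seed.
#' @return A list of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_probes = 2000, probes_per_gene = 2,
                             n_case = 20,
                             ref_sizes = c(FB = 1, AG = 1, GN = 3),
                             mix_fractions = c(unmeth = 0.45, meth = 0.35,
                                               mid = 0.20),
                             mix_means = c(unmeth = 0.10, meth = 0.85,
                                           mid = 0.50),
                             concentration = 50,
                             n_planted_hyper = 10, n_planted_hypo = 30,
                             effect_delta = 0.6,
                             planted_case_fraction = 0.5,
                             subgroup_specs = list(),
                             expression_coupling = 0.5,
                             expression_effect = 2,
                             gonosomal_fraction = 0.05,
                             bad_sample_count = 0,
                             bad_sample_fail_fraction = 0.05,
                             n_bad_probes = 0,
                             bad_probe_fail_fraction = 0.20,
                             missing_fraction = 0,
                             detection_p_max = 0.005,
                             seed) {
  if (missing(seed)) abort("`seed` is mandatory", "methcall_config_error")
  stopifnot_fraction(planted_case_fraction, "planted_case_fraction")
  stopifnot_fraction(expression_coupling, "expression_coupling")
  stopifnot_fraction(gonosomal_fraction, "gonosomal_fraction")
  stopifnot_fraction(missing_fraction, "missing_fraction")
  if (is.null(names(ref_sizes))) {
    abort("`ref_sizes` must be a named vector of reference tissue sizes",
          "methcall_config_error")
  }
  n_genes <- as.integer(ceiling(n_probes / probes_per_gene))
  n_gono_genes <- round(gonosomal_fraction * n_genes)
  n_planted <- n_planted_hyper + n_planted_hypo +
    sum(vapply(subgroup_specs, function(s) s$n_genes, 0))
  if (n_planted > n_genes - n_gono_genes) {
    abort("infeasible config: more planted genes than autosomal genes",
          "methcall_config_error")
  }
  cfg <- list(n_probes = as.integer(n_probes),
              probes_per_gene = as.integer(probes_per_gene),
              n_genes = n_genes, n_case = as.integer(n_case),
              ref_sizes = ref_sizes, mix_fractions = mix_fractions,
              mix_means = mix_means, concentration = concentration,
              n_planted_hyper = as.integer(n_planted_hyper),
              n_planted_hypo = as.integer(n_planted_hypo),
              effect_delta = effect_delta,
              planted_case_fraction = planted_case_fraction,
              subgroup_specs = subgroup_specs,
              expression_coupling = expression_coupling,
              expression_effect = expression_effect,
              gonosomal_fraction = gonosomal_fraction,
              bad_sample_count = as.integer(bad_sample_count),
              bad_sample_fail_fraction = bad_sample_fail_fraction,
              n_bad_probes = as.integer(n_bad_probes),
              bad_probe_fail_fraction = bad_probe_fail_fraction,
              missing_fraction = missing_fraction,
              detection_p_max = detection_p_max,
              seed = as.integer(seed))
  class(cfg) <- "SyntheticConfig"
  cfg
}

rbeta_mean <- function(n, mu, conc) {
  mu <- pmin(pmax(mu, 1e-3), 1 - 1e-3)
  stats::rbeta(n, mu * conc, (1 - mu) * conc)
}

# Fixed clinical composition of the case series (INSS stage, MYCN status,
# age bins), scaled to n_case and shuffled under the dataset seed.
make_case_sheet <- function(case_ids) {
  n <- length(case_ids)
  alloc <- function(props) {
    k <- floor(props * n)
    rem <- n - sum(k)
    if (rem > 0) {
      extra <- order(props * n - k, decreasing = TRUE)[seq_len(rem)]
      k[extra] <- k[extra] + 1
    }
    k
  }
  st <- alloc(c(`1` = 0.15, `2` = 0.20, `3` = 0.15, `4` = 0.30, `4S` = 0.20))
  stage <- rep(names(st), st)
  n_amp <- max(1L, round(0.25 * n))
  mycn <- rep("non_amplified", n)
  stage4 <- which(stage == "4")
  amp_idx <- c(stage4, setdiff(seq_len(n), stage4))[seq_len(n_amp)]
  mycn[amp_idx] <- "amplified"
  ages_bins <- alloc(c(young = 0.60, mid = 0.20, old = 0.20))
  age <- c(stats::runif(ages_bins[1], 0, 18),
           stats::runif(ages_bins[2], 18, 60),
           stats::runif(ages_bins[3], 60, 120))
  ord <- sample.int(n)
  sample_sheet(data.frame(
    sample_id = case_ids, group = "NB", inss_stage = stage[ord],
    mycn = mycn[ord], age_months = round(age[ord], 1),
    stringsAsFactors = FALSE))
}

#' Generate a synthetic methylation study with planted truth
#'
#' @param cfg A [synthetic_config()].
#' @return A list of class `SyntheticDataset`:
#'   \describe{
#'     \item{beta}{A [beta_matrix()] with detection p-values.}
#'     \item{annotation}{A [probe_annotation()].}
#'     \item{sheet}{A [sample_sheet()] covering cases and references.}
#'     \item{expression}{Genes x samples expression matrix.}
#'     \item{truth}{`SyntheticTruth` registry: planted gene/probe sets per
#'       direction, per-gene carrier samples, subgroup plant table, bad
#'       samples/probes, expression-responsive genes.}
#'     \item{case_ids, ref_sets}{Sample ids of the case series and a named
#'       list of reference-tissue id sets.}
#'   }
#' @export
synthetic_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  with_seed(cfg$seed, {
    n_probes <- cfg$n_probes
    n_genes <- cfg$n_genes
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
    probe_gene <- rep(gene_ids, each = cfg$probes_per_gene)[seq_len(n_probes)]
    probe_ids <- sprintf("cg%06d", seq_len(n_probes))

    # chromosomes: a block of genes on X/Y supplies the gonosomal fraction
    n_gono_genes <- round(cfg$gonosomal_fraction * n_genes)
    chrom_gene <- sample(as.character(1:22), n_genes, replace = TRUE)
    if (n_gono_genes > 0) {
      gono_genes <- sample(gene_ids, n_gono_genes)
      chrom_gene[match(gono_genes, gene_ids)] <-
        sample(c("X", "Y"), n_gono_genes, replace = TRUE)
    } else {
      gono_genes <- character(0)
    }
    band_gene <- paste0(sample(c("p", "q"), n_genes, replace = TRUE),
                        sample(11:36, n_genes, replace = TRUE))
    autosomal_genes <- setdiff(gene_ids, gono_genes)

    # planted genes (autosomal only)
    pool <- sample(autosomal_genes)
    hyper_genes <- pool[seq_len(cfg$n_planted_hyper)]
    pool <- setdiff(pool, hyper_genes)
    hypo_genes <- pool[seq_len(cfg$n_planted_hypo)]
    pool <- setdiff(pool, hypo_genes)
    sub_plants <- list()
    for (sp in cfg$subgroup_specs) {
      g <- pool[seq_len(sp$n_genes)]
      pool <- setdiff(pool, g)
      sub_plants[[length(sub_plants) + 1L]] <-
        list(field = sp$field, level = sp$level, genes = g,
             direction = sp$direction,
             delta = sp$delta %||% cfg$effect_delta,
             carrier_fraction = sp$carrier_fraction %||% 1)
    }

    # baseline state per probe; planted probes start from the state their
    # direction moves away from
    state <- sample(names(cfg$mix_fractions), n_probes, replace = TRUE,
                    prob = cfg$mix_fractions)
    state[probe_gene %in% hyper_genes] <- "unmeth"
    state[probe_gene %in% hypo_genes] <- "meth"
    for (sp in sub_plants) {
      state[probe_gene %in% sp$genes] <-
        if (sp$direction == "hyper") "unmeth" else "meth"
    }
    base_mean <- unname(cfg$mix_means[state])

    # samples
    case_ids <- sprintf("NB%02d", seq_len(cfg$n_case))
    ref_sets <- list()
    ref_rows <- list()
    for (tissue in names(cfg$ref_sizes)) {
      size <- cfg$ref_sizes[[tissue]]
      ids <- sprintf("%s%02d", tissue, seq_len(size))
      grp <- rep(tissue, size)
      if (tissue == "GN" && size >= 3) {    # mixed neuroblastic reference set
        ids[size] <- sprintf("GNB%02d", 1L)
        grp[size] <- "GNB"
      }
      ref_sets[[tissue]] <- ids
      ref_rows[[tissue]] <- data.frame(
        sample_id = ids, group = grp, inss_stage = NA_character_,
        mycn = NA_character_, age_months = NA_real_, stringsAsFactors = FALSE)
    }
    ref_ids <- unlist(ref_sets, use.names = FALSE)
    sample_ids <- c(case_ids, ref_ids)
    n_samples <- length(sample_ids)

    sheet_cases <- make_case_sheet(case_ids)
    core_cols <- c("sample_id", "group", "inss_stage", "mycn", "age_months")
    sheet <- sample_sheet(rbind(as.data.frame(sheet_cases)[, core_cols],
                                do.call(rbind, ref_rows)))

    # baseline beta
    beta <- matrix(NA_real_, n_probes, n_samples,
                   dimnames = list(probe_ids, sample_ids))
    for (j in seq_len(n_samples)) {
      beta[, j] <- rbeta_mean(n_probes, base_mean, cfg$concentration)
    }

    # planted shifts in carrier cases (shared carriers per gene)
    carriers <- list()
    n_carrier <- round(cfg$planted_case_fraction * cfg$n_case)
    plant <- function(genes, direction, delta, carrier_pool, frac) {
      k <- round(frac * length(carrier_pool))
      for (g in genes) {
        carr <- sample(carrier_pool, k)
        carriers[[g]] <<- carr
        idx <- which(probe_gene == g)
        mu <- clip01(base_mean[idx] + if (direction == "hyper") delta else -delta)
        for (s in carr) {
          beta[idx, s] <<- rbeta_mean(length(idx), mu, cfg$concentration)
        }
      }
    }
    plant(hyper_genes, "hyper", cfg$effect_delta, case_ids,
          cfg$planted_case_fraction)
    plant(hypo_genes, "hypo", cfg$effect_delta, case_ids,
          cfg$planted_case_fraction)
    subgroup_tab <- data.frame(field = character(0), level = character(0),
                               gene_symbol = character(0),
                               direction = character(0),
                               stringsAsFactors = FALSE)
    for (sp in sub_plants) {
      members <- sheet$sample_id[sheet$group == "NB" &
                                   !is.na(sheet[[sp$field]]) &
                                   sheet[[sp$field]] == sp$level]
      if (length(members) == 0) {
        abort(sprintf("subgroup spec selects no samples (%s == %s)",
                      sp$field, sp$level), "methcall_config_error")
      }
      plant(sp$genes, sp$direction, sp$delta, members, sp$carrier_fraction)
      subgroup_tab <- rbind(subgroup_tab, data.frame(
        field = sp$field, level = sp$level, gene_symbol = sp$genes,
        direction = sp$direction, stringsAsFactors = FALSE))
    }

    # detection p-values with planted failures
    detp <- matrix(stats::runif(n_probes * n_samples, 0, cfg$detection_p_max),
                   n_probes, n_samples,
                   dimnames = list(probe_ids, sample_ids))
    bad_samples <- character(0)
    if (cfg$bad_sample_count > 0) {
      bad_samples <- sample(case_ids, cfg$bad_sample_count)
      for (s in bad_samples) {
        idx <- sample.int(n_probes,
                          round(cfg$bad_sample_fail_fraction * n_probes))
        detp[idx, s] <- stats::runif(length(idx), 0.05, 1)
      }
    }
    bad_probes <- character(0)
    if (cfg$n_bad_probes > 0) {
      bad_probes <- sample(probe_ids, cfg$n_bad_probes)
      k <- round(cfg$bad_probe_fail_fraction * n_samples)
      for (p in bad_probes) {
        detp[p, sample.int(n_samples, k)] <- stats::runif(k, 0.05, 1)
      }
    }

    if (cfg$missing_fraction > 0) {
      idx <- sample.int(length(beta),
                        round(cfg$missing_fraction * length(beta)))
      beta[idx] <- NA_real_
    }

    # expression, coupled to the planted methylation
    resp <- data.frame(gene_symbol = character(0), direction = character(0),
                       stringsAsFactors = FALSE)
    take <- function(genes, dir_expr) {
      k <- round(cfg$expression_coupling * length(genes))
      if (k > 0) data.frame(gene_symbol = sample(genes, k),
                            direction = dir_expr, stringsAsFactors = FALSE)
      else NULL
    }
    resp <- rbind(resp, take(hyper_genes, "down"), take(hypo_genes, "up"))
    mu_g <- stats::rnorm(n_genes, 8, 1.5)
    sd_g <- stats::runif(n_genes, 0.5, 2)
    zsig <- matrix(0, n_genes, n_samples,
                   dimnames = list(gene_ids, sample_ids))
    for (i in seq_len(nrow(resp))) {
      g <- resp$gene_symbol[i]
      shift <- if (resp$direction[i] == "up") cfg$expression_effect else
        -cfg$expression_effect
      zsig[g, carriers[[g]]] <- shift
    }
    expr <- mu_g + sd_g * (zsig + matrix(stats::rnorm(n_genes * n_samples),
                                         n_genes, n_samples))
    dimnames(expr) <- list(gene_ids, sample_ids)

    ann <- probe_annotation(data.frame(
      probe_id = probe_ids, gene_symbol = probe_gene,
      chromosome = chrom_gene[match(probe_gene, gene_ids)],
      cytoband = paste0(chrom_gene[match(probe_gene, gene_ids)],
                        band_gene[match(probe_gene, gene_ids)]),
      position = sample.int(2e8, n_probes, replace = TRUE) - 1L,
      promoter_class = sample(c("HCP", "ICP", "LCP", "MIXED"), n_probes,
                              replace = TRUE,
                              prob = c(0.535, 0.117, 0.226, 0.122)),
      is_pcg_target = stats::runif(n_probes) < 0.096,
      stringsAsFactors = FALSE))

    truth <- structure(list(
      planted_hyper_genes = hyper_genes, planted_hypo_genes = hypo_genes,
      planted_hyper_probes = probe_ids[probe_gene %in% hyper_genes],
      planted_hypo_probes = probe_ids[probe_gene %in% hypo_genes],
      carriers = carriers, n_carriers_per_gene = n_carrier,
      subgroup = subgroup_tab, bad_samples = bad_samples,
      bad_probes = bad_probes, expression_responsive = resp,
      gonosomal_probes = probe_ids[probe_gene %in% gono_genes]),
      class = "SyntheticTruth")

    structure(list(beta = beta_matrix(beta, detp), annotation = ann,
                   sheet = sheet, expression = expr, truth = truth,
                   case_ids = case_ids, ref_sets = ref_sets, config = cfg),
              class = "SyntheticDataset")
  })
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat(sprintf(
    "SyntheticDataset: %d probes x %d samples (%d cases, %d reference tissues)\n",
    nrow(x$beta$beta), ncol(x$beta$beta), length(x$case_ids),
    length(x$ref_sets)))
  cat(sprintf("  planted: %d hyper / %d hypo genes; seed %d\n",
              length(x$truth$planted_hyper_genes),
              length(x$truth$planted_hypo_genes), x$config$seed))
  invisible(x)
}

#' Single-gene fixture with a complex epigenetic pattern
#'
#' A synthetic 17-probe, single-gene beta matrix modeled on the methylation
#' landscape of the CCND1 locus in neuroblastic tumors: an unmethylated
#' promoter everywhere, a gene body that is epigenetically heterogeneous in
#' the reference samples (so the stringent threshold criterion cannot fire
#' despite lower tumor values), a partially reduced 3' region, and two
#' 3'-UTR probes that are consistently methylated (beta > 0.90) in every
#' reference sample while 17 of 21 tumors lose methylation (11 markedly).
#' Under default calling parameters exactly those two probes are called
#' hypomethylated.
#'
#' @return A list with `beta` (a [beta_matrix()], 17 probes x 26 samples),
#'   `annotation`, `case_ids` (21 tumors) and `ref_ids` (5 reference
#'   samples).
#' @export
make_ccnd1_fixture <- function() {
  n_case <- 21
  case_ids <- sprintf("NB%02d", seq_len(n_case))
  ref_ids <- c("FB01", "AG01", "GN01", "GN02", "GNB01")
  samples <- c(case_ids, ref_ids)
  probe_ids <- c(sprintf("ccnd1_prom_%02d", 1:5),
                 sprintf("ccnd1_body_%02d", 1:7),
                 sprintf("ccnd1_utr3_%02d", 1:3),
                 "cg04717045", "cg02723533")
  with_seed(1102L, {
    m <- matrix(NA_real_, 17, length(samples),
                dimnames = list(probe_ids, samples))
    jit <- function(n, s = 0.015) stats::runif(n, -s, s)
    for (i in 1:5) {                       # promoter: unmethylated everywhere
      m[i, ] <- clip01(0.05 + jit(length(samples)))
    }
    for (i in 6:12) {                      # body: heterogeneous references
      m[i, ref_ids] <- c(0.28, 0.45, 0.62, 0.80, 0.88) + jit(5)
      m[i, case_ids] <- clip01(0.32 + jit(n_case, 0.08))
    }
    for (i in 13:15) {                     # 3' region: one reference < 0.75
      m[i, ref_ids] <- c(0.80, 0.85, 0.90, 0.92, 0.70) + jit(5, 0.01)
      m[i, case_ids] <- clip01(0.35 + jit(n_case, 0.10))
    }
    for (i in 16:17) {                     # 3'-UTR: all references > 0.90
      m[i, ref_ids] <- 0.93 + jit(5, 0.012)
      m[i, case_ids] <- clip01(c(0.05 + jit(11, 0.03),   # markedly low
                                 0.18 + jit(6, 0.04),    # low
                                 0.85 + jit(4, 0.04)))   # retained
    }
    ann <- probe_annotation(data.frame(
      probe_id = probe_ids, gene_symbol = "CCND1", chromosome = "11",
      cytoband = "11q13", position = seq(69455000, 69468000, length.out = 17),
      stringsAsFactors = FALSE))
    list(beta = beta_matrix(m), annotation = ann, case_ids = case_ids,
         ref_ids = ref_ids)
  })
}
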