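test_that("category enrichment reproduces the 2x2 arithmetic", {
  # 23 called genes of which 8 are ICP (34.78%) against a background where
  # 146/1250 = 11.68% are ICP: clearly enriched
  background <- sprintf("G%04d", 1:1250)
  icp <- background[1:146]
  called <- c(background[1:8], background[200:214])   # 8 ICP + 15 others
  res <- enrich_category(called, background, list(ICP = icp))
  expect_equal(res$k, 8)
  expect_equal(res$n, 23)
  expect_equal(res$K, 146)
  expect_equal(res$N, 1250)
  expect_equal(round(100 * res$k / res$n, 2), 34.78)
  expect_true(res$significant)
  expect_equal(res$p_hyper,
               oracle_hyper_tail(8, 23, 146, 1250), tolerance = 1e-12)
})

test_that("empty overlap gives p = 1 and list membership is validated", {
  background <- letters
  res <- enrich_category(c("a", "b"), background, list(grp = c("x", "y")))
  expect_equal(res$p_hyper, 1)
  expect_false(res$significant)
  err <- expect_error(
    enrich_category(c("a", "zz"), background, list(grp = "a")),
    class = "methcall_config_error")
  expect_match(conditionMessage(err), "zz")
})

test_that("per-category counts over a partition sum to the list size", {
  set.seed(71)
  background <- sprintf("G%03d", 1:300)
  part <- split(background, sample(c("u", "v", "w"), 300, replace = TRUE))
  called <- sample(background, 40)
  res <- enrich_category(called, background, part)
  expect_equal(sum(res$k), 40)
  # optional BH adjustment across categories
  res_adj <- enrich_category(called, background, part, adjust = TRUE)
  expect_true(all(res_adj$q >= res_adj$p_hyper - 1e-15))
})

test_that("chromosome distribution reports band shares within chromosomes", {
  # 58 called genes on chr19, 43 of them in 19p13 (74.1%), against a
  # background spread over chromosomes
  genes19 <- sprintf("C19_%02d", 1:58)
  other <- sprintf("BG_%03d", 1:542)
  ann <- probe_annotation(data.frame(
    probe_id = sprintf("cg%04d", 1:600),
    gene_symbol = c(genes19, other),
    chromosome = c(rep("19", 58), rep(as.character(1:18), length.out = 542)),
    cytoband = c(rep("19p13", 43), rep("19q13", 15),
                 rep("1p36", 542))))
  res <- chromosome_distribution(genes19, ann)
  chr19 <- res$chromosomes[res$chromosomes$chromosome == "19", ]
  expect_equal(chr19$k, 58)
  expect_true(chr19$significant)
  expect_equal(chr19$p_hyper, min(res$chromosomes$p_hyper))
  band <- res$cytobands[res$cytobands$cytoband == "19p13", ]
  expect_equal(band$n_in_band, 43)
  expect_equal(band$n_called_on_chromosome, 58)
  expect_equal(round(100 * band$band_share, 1), 74.1)
})

test_that("unannotated called genes are excluded with a warning", {
  ann <- probe_annotation(data.frame(
    probe_id = c("p1", "p2"), gene_symbol = c("A", "B"),
    chromosome = c("1", "2"), cytoband = c("1p1", "2q1")))
  expect_warning(res <- chromosome_distribution(c("A", "GHOST"), ann),
                 "without annotation")
  expect_equal(sum(res$chromosomes$k), 1)
})

test_that("promoter classes follow the sliding-window CpG arithmetic", {
  cfg <- promoter_classifier_config()
  expect_identical(classify_promoter(strrep("A", 500), cfg), "LCP")
  # CG repeats: GC = 1.0 and CpG o/e = (250 * 500) / (250 * 250) = 2.0
  expect_identical(classify_promoter(strrep("CG", 250), cfg), "HCP")
  # CpG-rich but only 50% GC: misses the HCP GC requirement, far above the
  # LCP o/e ceiling -> intermediate
  expect_identical(classify_promoter(strrep("CGAT", 150), cfg), "ICP")
  expect_error(classify_promoter(strrep("A", 100), cfg),
               class = "methcall_format_error")
  expect_error(classify_promoter("ACGTB", cfg),
               class = "methcall_format_error")
})

test_that("classification only depends on the window around the TSS", {
  cfg <- promoter_classifier_config()
  core <- strrep("CG", 450)                       # 900 bp promoter window
  with_flank_a <- paste0(strrep("A", 300), core, strrep("A", 300))
  with_flank_t <- paste0(strrep("T", 300), core, strrep("T", 300))
  # TSS placed so that -700..+200 covers exactly the CpG-rich core
  tss <- 300 + 700 + 1
  expect_identical(classify_promoter(with_flank_a, cfg, tss = tss),
                   classify_promoter(with_flank_t, cfg, tss = tss))
  expect_identical(classify_promoter(with_flank_a, cfg, tss = tss), "HCP")
})

test_that("adding CpGs never demotes a promoter from HCP toward LCP", {
  cfg <- promoter_classifier_config()
  rank_class <- c(LCP = 1, ICP = 2, HCP = 3)
  base <- strsplit(strrep("ATGA", 150), "")[[1]]
  prev_rank <- rank_class[[classify_promoter(paste(base, collapse = ""), cfg)]]
  set.seed(72)
  for (i in 1:12) {
    pos <- sample(seq(1, length(base) - 1, by = 2), 1)
    base[pos] <- "C"; base[pos + 1] <- "G"
    cls <- classify_promoter(paste(base, collapse = ""), cfg)
    expect_gte(rank_class[[cls]], prev_rank)
    prev_rank <- rank_class[[cls]]
  }
})

test_that("FASTA promoter classification keeps record names", {
  skip_if_not_installed("Biostrings")
  f <- tempfile(fileext = ".fa")
  writeLines(c(">GENE_HI extra description", strrep("CG", 250),
               ">GENE_LO", strrep("AT", 250)), f)
  cls <- classify_promoters_fasta(f)
  expect_identical(cls[["GENE_HI"]], "HCP")
  expect_identical(cls[["GENE_LO"]], "LCP")
})
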