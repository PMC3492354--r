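# Annotation-level enrichment of called gene sets. The background universe is
# the set of genes surviving QC on the array (platform-relative), not the
# whole genome. Raw hypergeometric tail probabilities are reported by
# default; BH correction across categories is optional.

#' Gene-set enrichment by hypergeometric tail
#'
#' For each category, tests whether the gene list is enriched relative to the
#' background universe: with `N` background genes of which `K` carry the
#' category and `k` of the `n` list genes carrying it, reports
#' `P(X >= k)` from the hypergeometric distribution.
#'
#' @param list_genes Character vector of called genes (must be a subset of
#'   the background).
#' @param background_genes Character vector, the gene universe.
#' @param category_map Either a data.frame with columns `term` and `gene`, or
#'   a named list of gene vectors.
#' @param alpha Significance flag cut-off on the raw tail probability
#'   (default 0.05).
#' @param adjust Add a BH-adjusted column `q` across categories
#'   (default `FALSE`).
#' @return A data.frame of class `EnrichmentResults`: `term`, `k`, `n`, `K`,
#'   `N`, `p_hyper`, `significant` (and `q` when `adjust`).
#' @export
enrich_category <- function(list_genes, background_genes, category_map,
                            alpha = 0.05, adjust = FALSE) {
  list_genes <- unique(as.character(list_genes))
  background_genes <- unique(as.character(background_genes))
  outside <- setdiff(list_genes, background_genes)
  if (length(outside)) {
    abort(sprintf("list gene(s) absent from the background: %s",
                  paste(utils::head(outside, 5), collapse = ", ")),
          "methcall_config_error")
  }
  if (is.data.frame(category_map)) {
    if (!all(c("term", "gene") %in% colnames(category_map))) {
      abort("category_map data.frame needs columns `term` and `gene`",
            "methcall_format_error")
    }
    category_map <- split(as.character(category_map$gene),
                          as.character(category_map$term))
  }
  n <- length(list_genes)
  N <- length(background_genes)
  rows <- lapply(names(category_map), function(term) {
    members <- intersect(unique(as.character(category_map[[term]])),
                         background_genes)
    K <- length(members)
    k <- length(intersect(list_genes, members))
    p <- hypergeom_tail(k, n, K, N)
    data.frame(term = term, k = k, n = n, K = K, N = N, p_hyper = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(term = character(0), k = integer(0), n = integer(0),
               K = integer(0), N = integer(0), p_hyper = numeric(0),
               significant = logical(0), stringsAsFactors = FALSE)
  if (adjust && nrow(out)) out$q <- bh_fdr(out$p_hyper)
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResults", "data.frame")
  out
}

#' Chromosomal distribution of called genes
#'
#' Tests each chromosome for enrichment of the called genes against the
#' background universe defined by the annotation, and, within each
#' chromosome, reports the share of its called genes per cytoband.
#'
#' @param genes Character vector of called gene symbols.
#' @param ann A [probe_annotation()]; the distinct genes it contains form the
#'   background universe. Genes mapping to several chromosomes use their
#'   first annotated mapping.
#' @param alpha Significance cut-off (default 0.05).
#' @return A list with `chromosomes` (an `EnrichmentResults` data.frame, one
#'   row per chromosome) and `cytobands` (data.frame `chromosome`,
#'   `cytoband`, `n_called_on_chromosome`, `n_in_band`, `band_share`).
#' @export
chromosome_distribution <- function(genes, ann, alpha = 0.05) {
  ann <- if (inherits(ann, "ProbeAnnotation")) ann else probe_annotation(ann)
  gmap <- unique(data.frame(gene = ann$gene_symbol, chrom = ann$chromosome,
                            band = ann$cytoband, stringsAsFactors = FALSE))
  gmap <- gmap[!duplicated(gmap$gene), , drop = FALSE]
  background <- gmap$gene
  genes <- unique(as.character(genes))
  unknown <- setdiff(genes, background)
  if (length(unknown)) {
    warning(sprintf("%d called gene(s) without annotation excluded",
                    length(unknown)), call. = FALSE)
    genes <- setdiff(genes, unknown)
  }
  chrom_map <- split(gmap$gene, gmap$chrom)
  chroms <- enrich_category(genes, background, chrom_map, alpha = alpha)
  names(chroms)[names(chroms) == "term"] <- "chromosome"

  called <- gmap[gmap$gene %in% genes, , drop = FALSE]
  bands <- do.call(rbind, lapply(split(called, called$chrom), function(cc) {
    tab <- table(cc$band, useNA = "ifany")
    data.frame(chromosome = cc$chrom[1],
               cytoband = names(tab),
               n_called_on_chromosome = nrow(cc),
               n_in_band = as.integer(tab),
               band_share = as.numeric(tab) / nrow(cc),
               stringsAsFactors = FALSE)
  })) %||% data.frame(chromosome = character(0), cytoband = character(0),
                      n_called_on_chromosome = integer(0),
                      n_in_band = integer(0), band_share = numeric(0))
  rownames(bands) <- NULL
  list(chromosomes = chroms, cytobands = bands)
}

#' Promoter CpG-content classifier configuration
#'
#' Constants follow the usual sliding-window CpG-density scheme for dividing
#' promoters into high (HCP), intermediate (ICP) and low (LCP) CpG content.
#'
#' @param window_start,window_end Promoter span around the TSS in bp
#'   (defaults -700 and +200).
#' @param sliding_length Sliding window length in bp (default 500).
#' @param gc_high Minimum window GC fraction for HCP (default 0.55).
#' @param cpg_oe_high Minimum window CpG observed/expected ratio for HCP
#'   (default 0.75).
#' @param cpg_oe_low CpG o/e below which no window may rise for LCP
#'   (default 0.48).
#' @return A list of class `PromoterClassifierConfig`.
#' @export
promoter_classifier_config <- function(window_start = -700, window_end = 200,
                                       sliding_length = 500, gc_high = 0.55,
                                       cpg_oe_high = 0.75, cpg_oe_low = 0.48) {
  if (!(cpg_oe_low > 0 && cpg_oe_low < cpg_oe_high)) {
    abort("need 0 < cpg_oe_low < cpg_oe_high", "methcall_config_error")
  }
  if (!(gc_high > 0 && gc_high < 1)) {
    abort("gc_high must lie in (0, 1)", "methcall_config_error")
  }
  structure(list(window_start = window_start, window_end = window_end,
                 sliding_length = as.integer(sliding_length),
                 gc_high = gc_high, cpg_oe_high = cpg_oe_high,
                 cpg_oe_low = cpg_oe_low),
            class = "PromoterClassifierConfig")
}

#' Classify a promoter by CpG content
#'
#' Slides windows of `cfg$sliding_length` bp (step 1) over the promoter
#' region and computes per window the GC fraction and the CpG
#' observed/expected ratio `o/e = #CpG * L / (#C * #G)` with `L` the window
#' length net of N bases (N bases are excluded from all counts). HCP when
#' some window has GC >= `gc_high` and o/e >= `cpg_oe_high`; LCP when no
#' window reaches `cpg_oe_low`; ICP otherwise.
#'
#' @param sequence A promoter DNA string (alphabet ACGTN). When `tss` is
#'   given (1-based position of the TSS within `sequence`), only the
#'   `cfg$window_start..cfg$window_end` region around it is considered;
#'   otherwise the whole sequence is taken as the promoter region.
#' @param cfg A [promoter_classifier_config()].
#' @param tss Optional 1-based TSS position within `sequence`.
#' @return `"HCP"`, `"ICP"` or `"LCP"`.
#' @export
classify_promoter <- function(sequence, cfg = promoter_classifier_config(),
                              tss = NULL) {
  s <- toupper(as.character(sequence))
  if (length(s) != 1L || is.na(s)) {
    abort("`sequence` must be a single DNA string", "methcall_format_error")
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N")))) {
    abort(sprintf("sequence contains non-ACGTN character(s): %s",
                  paste(bad, collapse = ", ")), "methcall_format_error")
  }
  if (!is.null(tss)) {
    from <- max(1L, tss + cfg$window_start)
    to <- min(length(chars), tss + cfg$window_end)
    chars <- chars[from:to]
  }
  L <- length(chars)
  w <- cfg$sliding_length
  if (L < w) {
    abort(sprintf("promoter region (%d bp) shorter than the sliding window (%d bp)",
                  L, w), "methcall_format_error")
  }
  isC <- chars == "C"
  isG <- chars == "G"
  isN <- chars == "N"
  isCG <- c(isC[-L] & isG[-1], FALSE)  # CpG dinucleotide starting here
  cumC <- cumsum(isC); cumG <- cumsum(isG)
  cumN <- cumsum(isN); cumCG <- cumsum(isCG)
  win_sum <- function(cum, from, to) cum[to] - c(0, cum)[from]
  starts <- seq_len(L - w + 1L)
  ends <- starts + w - 1L
  nC <- win_sum(cumC, starts, ends)
  nG <- win_sum(cumG, starts, ends)
  nN <- win_sum(cumN, starts, ends)
  nCG <- win_sum(cumCG, starts, ends - 1L)  # dinucleotide fully inside
  eff <- w - nN
  gc <- ifelse(eff > 0, (nC + nG) / eff, 0)
  oe <- ifelse(nC * nG > 0, nCG * eff / (nC * nG), 0)
  if (any(gc >= cfg$gc_high & oe >= cfg$cpg_oe_high)) return("HCP")
  if (all(oe < cfg$cpg_oe_low)) return("LCP")
  "ICP"
}

#' Classify promoters from a FASTA file
#'
#' Convenience wrapper reading promoter sequences (record id = gene symbol)
#' and applying [classify_promoter()] to each. Requires the Biostrings
#' package.
#'
#' @param fasta_path Path to a FASTA file of promoter sequences.
#' @param cfg A [promoter_classifier_config()].
#' @param tss Optional 1-based TSS position, shared by all records.
#' @return Named character vector of classes.
#' @export
classify_promoters_fasta <- function(fasta_path,
                                     cfg = promoter_classifier_config(),
                                     tss = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("classify_promoters_fasta requires the Biostrings package",
          "methcall_config_error")
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  out <- vapply(as.character(seqs), classify_promoter, "", cfg = cfg,
                tss = tss, USE.NAMES = FALSE)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}
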