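# Sample-structure views: principal component analysis and agglomerative
# hierarchical clustering of beta profiles. These are reproducible stand-ins
# for the vendor tools' ordination/cluster displays, not bit-match claims:
# PCA is probe-centered SVD without unit-variance scaling (beta is already
# bounded and comparable across probes); clustering defaults to average
# linkage on Euclidean distance.

# Missing beta values are replaced by the probe mean for these views only;
# differential calling never imputes.
impute_probe_means <- function(B) {
  if (!anyNA(B)) return(B)
  mu <- rowMeans(B, na.rm = TRUE)
  mu[is.nan(mu)] <- 0.5
  idx <- which(is.na(B), arr.ind = TRUE)
  B[idx] <- mu[idx[, 1]]
  B
}

#' Principal component analysis of beta profiles
#'
#' Samples are observations, probes variables. Probes are mean-centered, not
#' scaled; components come from the singular value decomposition. The sign
#' of each component is fixed deterministically so that its
#' largest-magnitude probe loading is positive.
#'
#' @param bm A [beta_matrix()] with >= 2 samples.
#' @param n_components Number of components to retain (clipped with a
#'   warning when larger than `min(dim)`); default all.
#' @return A list of class `PCAResult`: `sample_ids`, `scores` (samples x
#'   components), `explained_variance_fraction` (per retained component,
#'   non-increasing), `centering` (probe means), `loadings`.
#' @export
beta_pca <- function(bm, n_components = NULL) {
  stopifnot(inherits(bm, "BetaMatrix"))
  if (ncol(bm$beta) < 2) {
    abort("PCA needs >= 2 samples", "methcall_config_error")
  }
  B <- impute_probe_means(bm$beta)
  X <- t(B)                              # samples x probes
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  k_max <- min(dim(Xc))
  k <- n_components %||% k_max
  if (k > k_max) {
    warning(sprintf("n_components clipped from %d to %d", k, k_max),
            call. = FALSE)
    k <- k_max
  }
  sv <- svd(Xc, nu = k_max, nv = k_max)
  ev <- sv$d^2
  explained <- if (sum(ev) > 0) ev / sum(ev) else rep(0, length(ev))
  scores <- sv$u %*% diag(sv$d, nrow = k_max)
  loadings <- sv$v
  for (j in seq_len(k_max)) {           # deterministic sign convention
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  scores <- scores[, seq_len(k), drop = FALSE]
  dimnames(scores) <- list(bm$sample_ids, paste0("PC", seq_len(k)))
  structure(list(sample_ids = bm$sample_ids, scores = scores,
                 explained_variance_fraction = explained[seq_len(k)],
                 centering = center,
                 loadings = loadings[, seq_len(k), drop = FALSE]),
            class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  cat(sprintf("PCAResult: %d samples, %d components (PC1 %.1f%% variance)\n",
              length(x$sample_ids), ncol(x$scores),
              100 * x$explained_variance_fraction[1]))
  invisible(x)
}

#' Agglomerative hierarchical clustering of samples
#'
#' Clusters samples on their beta profiles, optionally restricted to a probe
#' subset (supervised mode passes the probes of called genes; unsupervised
#' passes everything).
#'
#' @param bm A [beta_matrix()].
#' @param probe_subset Optional probe ids to cluster on (default all).
#' @param linkage Agglomeration method for [stats::hclust()]
#'   (default `"average"`).
#' @param metric Distance metric for [stats::dist()]
#'   (default `"euclidean"`).
#' @return A list of class `BetaDendrogram`: `hclust` (a [stats::hclust]
#'   object, or `NULL` for a single sample), `labels` (= the sample set),
#'   `linkage`, `metric`.
#' @export
beta_hclust <- function(bm, probe_subset = NULL, linkage = "average",
                        metric = "euclidean") {
  stopifnot(inherits(bm, "BetaMatrix"))
  if (!is.null(probe_subset)) {
    if (length(probe_subset) == 0) {
      abort("probe_subset must be non-empty", "methcall_config_error")
    }
    bm <- subset_beta(bm, probes = probe_subset)
  }
  labels <- bm$sample_ids
  if (length(labels) == 1) {
    return(structure(list(hclust = NULL, labels = labels, linkage = linkage,
                          metric = metric), class = "BetaDendrogram"))
  }
  B <- impute_probe_means(bm$beta)
  d <- stats::dist(t(B), method = metric)
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc, labels = labels, linkage = linkage,
                 metric = metric), class = "BetaDendrogram")
}

#' Cut a sample dendrogram into k clusters
#' @param dend A [beta_hclust()] result.
#' @param k Number of clusters.
#' @return Named integer vector of cluster memberships.
#' @export
cut_dendrogram <- function(dend, k) {
  stopifnot(inherits(dend, "BetaDendrogram"))
  if (is.null(dend$hclust)) {
    out <- 1L; names(out) <- dend$labels
    return(out)
  }
  stats::cutree(dend$hclust, k = k)
}

#' Serialize a sample dendrogram as Newick
#'
#' Leaf names are sample ids; branch lengths are merge-height differences.
#'
#' @param dend A [beta_hclust()] result (>= 2 samples).
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  stopifnot(inherits(dend, "BetaDendrogram"))
  if (is.null(dend$hclust)) {
    nwk <- sprintf("(%s);", dend$labels)
  } else {
    nwk <- ape::write.tree(ape::as.phylo(dend$hclust))
  }
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Write PCA scores to TSV
#' @param pca A [beta_pca()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pca_scores <- function(pca, path) {
  df <- data.frame(sample_id = pca$sample_ids, pca$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
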