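# Statistical primitives: unpaired t statistic, Westfall-Young free step-down
# maxT permutation adjustment, BH FDR, hypergeometric upper tail, Pearson
# correlation. The maxT procedure is implemented here in full (vectorized
# over features and relabelings, exhaustive enumeration when feasible);
# textbook adjustments delegate to stats::p.adjust / stats::phyper /
# stats::cor.test.

T_SENTINEL <- 1e6  # |t| when a group has zero variance but a nonzero shift
T_EPS <- 1e-12     # tie guard when comparing permutation statistics

#' Unpaired t statistic
#'
#' Pooled-variance (classic unpaired) t by default, Welch optionally. Missing
#' values are dropped per group. A feature with zero pooled variance and zero
#' mean difference is uninformative and gets t = 0; zero variance with a
#' nonzero difference is guarded to a large finite sentinel (its p-value is
#' meant to come from permutation, not from the t distribution).
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 non-missing
#'   values (otherwise a classed `methcall_insufficient_replication` error).
#' @param var_equal Pooled variance (`TRUE`, default) or Welch (`FALSE`).
#' @return The t statistic for mean(a) - mean(b).
#' @export
t_statistic <- function(group_a, group_b, var_equal = TRUE) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs >= 2 non-missing values for a t statistic",
          "methcall_insufficient_replication")
  }
  d <- mean(a) - mean(b)
  if (var_equal) {
    sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
      (length(a) + length(b) - 2)
    se <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  } else {
    se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  }
  if (!is.finite(se) || se == 0) {
    if (d == 0) return(0)
    return(sign(d) * T_SENTINEL)
  }
  d / se
}

# Vectorized row-wise t statistics for many relabelings at once.
# X: features x samples; P: samples x B 0/1 matrix, 1 = member of group A.
# Returns an m x B matrix of t statistics (0 where a group has < 2 values
# or both the pooled variance and the mean difference vanish; sentinel where
# only the variance vanishes). NA values in X are excluded per cell.
row_t_perm <- function(X, P, var_equal = TRUE) {
  storage.mode(P) <- "double"
  has_na <- anyNA(X)
  if (has_na) {
    Z <- !is.na(X)
    X0 <- X; X0[!Z] <- 0
    nA <- Z %*% P
    nTot <- rowSums(Z)
  } else {
    X0 <- X
    nA <- matrix(colSums(P), nrow = nrow(X), ncol = ncol(P), byrow = TRUE)
    nTot <- rep(ncol(X), nrow(X))
  }
  X2 <- X0 * X0
  SA <- X0 %*% P
  QA <- X2 %*% P
  SB <- rowSums(X0) - SA
  QB <- rowSums(X2) - QA
  nB <- nTot - nA
  ok <- nA >= 2 & nB >= 2
  meanA <- ifelse(nA > 0, SA / nA, 0)
  meanB <- ifelse(nB > 0, SB / nB, 0)
  ssA <- pmax(QA - nA * meanA^2, 0)
  ssB <- pmax(QB - nB * meanB^2, 0)
  d <- meanA - meanB
  if (var_equal) {
    sp2 <- (ssA + ssB) / pmax(nA + nB - 2, 1)
    se <- sqrt(sp2 * (1 / pmax(nA, 1) + 1 / pmax(nB, 1)))
  } else {
    se <- sqrt(ssA / (pmax(nA - 1, 1) * pmax(nA, 1)) +
               ssB / (pmax(nB - 1, 1) * pmax(nB, 1)))
  }
  t <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * T_SENTINEL))
  t[!ok] <- 0
  t
}

#' Westfall-Young step-down maxT permutation test
#'
#' Computes per-feature unpaired t statistics for a two-group comparison and
#' adjusts them for multiplicity by the free step-down maxT resampling
#' procedure: features are ordered by decreasing `|t|`, the null distribution
#' of each feature is the successive maximum of permuted `|t|` over itself and
#' all less significant features, and monotonicity is enforced by a running
#' maximum down the ordering. When the number of distinct two-group
#' relabelings `choose(n, n_a)` does not exceed `exhaustive_limit`, all are
#' enumerated and p-values are exact permutation fractions (the observed
#' labeling is part of the enumeration, so p > 0); otherwise `n_perm` random
#' relabelings are drawn and the add-one estimator
#' `p = (1 + #\{perm >= obs\}) / (1 + B)` is used.
#'
#' @param X Numeric matrix, features x samples (rownames = feature ids).
#' @param labels Two-group assignment for the columns (factor or character).
#' @param n_perm Number of random relabelings when not exhaustive.
#' @param seed Seed for the random relabelings (ignored in exhaustive mode).
#' @param exhaustive_limit Enumerate all relabelings when their count is at
#'   most this (default 20000).
#' @param var_equal Pooled (default) or Welch t.
#' @param chunk_size Relabelings processed per block (memory control).
#' @return A list of class `PermTestResult`: `feature_ids`, `t_obs`, `p_raw`,
#'   `p_adj` (step-down maxT), `n_perm` (relabelings actually used),
#'   `exhaustive`, `seed`. `p_adj >= p_raw` elementwise and `p_adj` is
#'   non-decreasing in the significance ordering.
#' @references Westfall, P.H. and Young, S.S. (1993) Resampling-Based
#'   Multiple Testing. Wiley.
#' @export
maxt_stepdown <- function(X, labels, n_perm = 1000, seed = NULL,
                          exhaustive_limit = 20000, var_equal = TRUE,
                          chunk_size = 2048) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  labels <- as.character(labels)
  if (length(labels) != ncol(X)) {
    abort("`labels` length must equal ncol(X)", "methcall_config_error")
  }
  lev <- unique(labels)
  if (length(lev) != 2) {
    abort("`labels` must contain exactly two groups", "methcall_config_error")
  }
  n <- ncol(X)
  idx_a <- which(labels == lev[1])
  n_a <- length(idx_a)
  if (n_a < 2 || n - n_a < 2) {
    abort("each group needs >= 2 samples for the permutation t test",
          "methcall_insufficient_replication")
  }
  m <- nrow(X)
  ids <- rownames(X) %||% sprintf("feature_%d", seq_len(m))

  obs_P <- matrix(0, nrow = n, ncol = 1)
  obs_P[idx_a, 1] <- 1
  t_obs <- as.numeric(row_t_perm(X, obs_P, var_equal))
  abs_obs <- abs(t_obs)

  n_splits <- choose(n, n_a)
  exhaustive <- n_splits <= exhaustive_limit
  ord <- order(-abs_obs)   # stable: ties keep input order
  abs_ord <- abs_obs[ord]

  make_chunks <- function() {
    if (exhaustive) {
      combs <- utils::combn(n, n_a)
      B <- ncol(combs)
      starts <- seq(1, B, by = chunk_size)
      lapply(starts, function(s) {
        cols <- s:min(s + chunk_size - 1, B)
        P <- matrix(0, nrow = n, ncol = length(cols))
        for (j in seq_along(cols)) P[combs[, cols[j]], j] <- 1
        P
      })
    } else {
      draw <- function(b) {
        P <- matrix(0, nrow = n, ncol = b)
        for (j in seq_len(b)) P[sample.int(n, n_a), j] <- 1
        P
      }
      sizes <- diff(unique(c(seq(0, n_perm, by = chunk_size), n_perm)))
      lapply(sizes, draw)
    }
  }
  run <- function() {
    counts_raw <- numeric(m)
    counts_step <- numeric(m)  # in significance order
    B_used <- 0
    for (P in make_chunks()) {
      Tm <- abs(row_t_perm(X, P, var_equal))
      B_used <- B_used + ncol(P)
      counts_raw <- counts_raw + unname(rowSums(Tm >= abs_obs - T_EPS))
      u <- rep(-Inf, ncol(P))
      for (i in m:1) {
        u <- pmax(u, Tm[ord[i], ])
        counts_step[i] <- counts_step[i] + sum(u >= abs_ord[i] - T_EPS)
      }
    }
    list(raw = counts_raw, step = counts_step, B = B_used)
  }
  res <- if (exhaustive) run() else with_seed(seed %||% 1L, run())

  if (exhaustive) {
    p_raw <- res$raw / res$B
    p_step <- res$step / res$B
  } else {
    p_raw <- (1 + res$raw) / (1 + res$B)
    p_step <- (1 + res$step) / (1 + res$B)
  }
  p_adj <- numeric(m)
  p_adj[ord] <- cummax(p_step)
  structure(list(feature_ids = ids, t_obs = t_obs, p_raw = p_raw,
                 p_adj = p_adj, n_perm = res$B, exhaustive = exhaustive,
                 seed = if (exhaustive) NA_integer_ else as.integer(seed %||% 1L)),
            class = "PermTestResult")
}

#' @export
print.PermTestResult <- function(x, ...) {
  cat(sprintf(
    "PermTestResult: %d features, %d relabelings (%s)\n  min p_adj = %.4g\n",
    length(x$feature_ids), x$n_perm,
    if (x$exhaustive) "exhaustive" else "sampled", min(x$p_adj)))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH q-values via [stats::p.adjust()]: `q_i` is the smallest
#' `p_(j) * m / j` over `j` with `p_(j) >= p_(i)`, clipped to 1.
#'
#' @param p_raw Numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and names as `p_raw`.
#' @export
bh_fdr <- function(p_raw) {
  if (length(p_raw) == 0) return(numeric(0))
  if (any(!is.na(p_raw) & (p_raw < 0 | p_raw > 1))) {
    abort("p-values must lie in [0, 1]", "methcall_config_error")
  }
  stats::p.adjust(p_raw, method = "BH")
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` where `X` is the number of category members in a draw of `n`
#' genes from a background of `N` genes of which `K` are in the category.
#'
#' @param k Observed in-list successes.
#' @param n List size.
#' @param K Background successes.
#' @param N Background size.
#' @return The exact upper-tail probability (1 when `k = 0`).
#' @export
hypergeom_tail <- function(k, n, K, N) {
  vals <- c(k = k, n = n, K = K, N = N)
  if (any(vals < 0) || any(vals != round(vals))) {
    abort("k, n, K, N must be non-negative integers", "methcall_config_error")
  }
  if (k > min(n, K) || n > N || K > N) {
    abort(sprintf("inconsistent hypergeometric counts: k=%d n=%d K=%d N=%d",
                  k, n, K, N), "methcall_config_error")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation over pairwise-complete observations with the
#' usual t-based two-sided p-value, as used to compare array methylation with
#' bisulfite pyrosequencing measurements.
#'
#' @param x,y Numeric vectors of equal length; at least 3 complete pairs.
#' @return A list of class `ConcordanceResult`: `r`, `p`, `n_pairs`.
#' @export
pearson_concordance <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length", "methcall_config_error")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    abort("need >= 3 complete pairs for a correlation",
          "methcall_insufficient_replication")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined: zero variance in one of the vectors",
          "methcall_undefined_correlation")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n_pairs = length(x)),
            class = "ConcordanceResult")
}
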