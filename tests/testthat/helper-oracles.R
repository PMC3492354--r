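# Independent oracle implementations used to cross-check the package:
# literal textbook formulas, explicit enumeration, no shared code with R/.

# Textbook pooled-variance t computed step by step.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  if (sp2 == 0) {
    if (mean(a) == mean(b)) return(0)
    return(sign(mean(a) - mean(b)) * 1e6)
  }
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Brute-force free step-down maxT over the full enumeration of two-group
# relabelings: builds the complete |t| matrix (features x relabelings) one
# scalar t at a time, then applies successive maxima and the running
# maximum literally.
oracle_maxt_exhaustive <- function(X, labels) {
  lev <- unique(labels)
  ia <- which(labels == lev[1])
  n <- ncol(X); m <- nrow(X)
  combs <- utils::combn(n, length(ia))
  B <- ncol(combs)
  Tm <- matrix(0, m, B)
  for (b in seq_len(B)) {
    sel <- combs[, b]
    for (i in seq_len(m)) {
      Tm[i, b] <- abs(oracle_pooled_t(X[i, sel], X[i, -sel]))
    }
  }
  t_obs <- vapply(seq_len(m), function(i)
    abs(oracle_pooled_t(X[i, ia], X[i, -ia])), 0)
  p_raw <- vapply(seq_len(m), function(i)
    mean(Tm[i, ] >= t_obs[i] - 1e-12), 0)
  ord <- order(-t_obs)
  u <- rep(-Inf, B)
  p_step <- numeric(m)
  for (i in m:1) {
    u <- pmax(u, Tm[ord[i], ])
    p_step[i] <- mean(u >= t_obs[ord[i]] - 1e-12)
  }
  p_adj <- numeric(m)
  p_adj[ord] <- cummax(p_step)
  list(t_obs = t_obs, p_raw = p_raw, p_adj = p_adj)
}

# Hand application of the BH step-up formula:
# q_i = min over j with p_(j) >= p_(i) of p_(j) * m / j, clipped to 1.
oracle_bh <- function(p) {
  m <- length(p)
  ps <- sort(p)
  vapply(p, function(pi) {
    cand <- vapply(seq_len(m), function(j)
      if (ps[j] >= pi) ps[j] * m / j else Inf, 0)
    min(1, cand)
  }, 0)
}

# Exhaustive hypergeometric upper tail from binomial coefficients.
oracle_hyper_tail <- function(k, n, K, N) {
  js <- k:min(n, K)
  if (k > min(n, K)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# A small random BetaMatrix with optional missing values and detection p.
random_beta_matrix <- function(seed, n_probes = 6, n_samples = 4,
                               missing = TRUE, detection = TRUE) {
  set.seed(seed)
  b <- matrix(round(runif(n_probes * n_samples), 4), n_probes,
              dimnames = list(sprintf("cg%05d", seq_len(n_probes)),
                              sprintf("S%02d", seq_len(n_samples))))
  if (missing) b[sample(length(b), 2)] <- NA
  d <- if (detection)
    matrix(round(runif(n_probes * n_samples, 0, 0.02), 5), n_probes,
           dimnames = dimnames(b)) else NULL
  beta_matrix(b, d)
}

write_tsv_text <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
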