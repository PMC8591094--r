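# Independent oracles, coded directly from the defining formulas and kept
# free of any package internals.

# Benjamini-Hochberg step-up, literally: for each i, the minimum over all j
# with rank(j) >= rank(i) of p_j * m / rank_j, capped at 1.
brute_bh <- function(p) {
  m <- length(p)
  rk <- order(order(p))  # stable ranks, ties by input order
  out <- numeric(m)
  for (i in seq_len(m)) {
    cand <- which(rk >= rk[i])
    out[i] <- min(1, min(p[cand] * m / rk[cand]))
  }
  out
}

# Dense-iteration MCL oracle: explicit loops throughout, BFS components.
# Returns a canonical list of sorted clusters (size desc, then first member).
oracle_mcl <- function(adj, expansion = 2, inflation = 2, loop = 1,
                       prune = 1e-5, max_iter = 200, tol = 1e-8) {
  n <- nrow(adj)
  A <- (adj > 0) * 1
  for (i in seq_len(n)) A[i, i] <- A[i, i] + loop
  colnorm <- function(M) {
    for (j in seq_len(n)) {
      s <- sum(M[, j])
      if (s == 0) { M[j, j] <- 1; s <- 1 }
      M[, j] <- M[, j] / s
    }
    M
  }
  M <- colnorm(A)
  for (it in seq_len(max_iter)) {
    E <- M
    for (k in seq_len(expansion - 1)) E <- E %*% M
    E <- colnorm(E^inflation)
    E[E < prune] <- 0
    E <- colnorm(E)
    delta <- max(abs(E - M))
    M <- E
    if (delta < tol) break
  }
  nz <- (M > 0) | (t(M) > 0)
  seen <- rep(FALSE, n)
  clusters <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      queue <- c(queue, which(nz[v, ] & !seen))
    }
    clusters[[length(clusters) + 1]] <- sort(rownames(adj)[comp])
  }
  ord <- order(-lengths(clusters),
               vapply(clusters, `[`, character(1), 1))
  clusters[ord]
}

# Canonicalize a clustering for comparison.
canon_clusters <- function(clusters) {
  cl <- lapply(clusters, sort)
  ord <- order(-lengths(cl), vapply(cl, `[`, character(1), 1))
  unname(cl[ord])
}

# Two-group log-rank chi-square from explicit 2x2 tables at each distinct
# event time.
brute_logrank <- function(time, event, group) {
  g1 <- unique(group)[1]
  times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(0)
  (O - E)^2 / V
}

# Hypergeometric upper tail P(X >= obs) by direct pmf summation.
brute_hyper_tail <- function(obs, K, N, n) {
  ks <- max(obs, 0):min(K, n)
  if (!length(ks) || obs > min(K, n)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# AUC as the Mann-Whitney rank statistic (ties give half credit).
rank_auc <- function(labels, d) {
  pos <- d[labels == "case"]; neg <- d[labels == "control"]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
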