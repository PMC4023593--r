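# Independent brute-force oracles. Each is written from the definition of
# the quantity it checks, without reusing package internals.

# Quantile normalization: reference = mean of order statistics across
# columns; each value is replaced by the mean of the reference values at the
# positions its tie block occupies. Plain double loop.
oracle_quantile_normalize <- function(m) {
  n <- nrow(m)
  sorted <- matrix(NA_real_, n, ncol(m))
  for (j in seq_len(ncol(m))) sorted[, j] <- sort(m[, j])
  ref <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    for (i in seq_len(n)) {
      positions <- which(sort(v) == v[i])
      out[i, j] <- mean(ref[positions])
    }
  }
  out
}

# Benjamini-Hochberg step-up from the definition:
# q_i = min over {j : p_j >= p_i} of m * p_j / rank(p_j), clipped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    js <- which(p >= p[i])
    min(1, min(m * p[js] / r[js]))
  }, numeric(1))
}

# Upper-tail hypergeometric by exact enumeration of the pmf.
oracle_hyper_upper <- function(k, K, N, n) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Average-linkage (UPGMA) agglomeration, O(n^3), returning the cophenetic
# distance matrix. Ties merge the lowest-index pair.
oracle_average_linkage_cophenetic <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n + (n - 1))
  clusters <- c(clusters, vector("list", n - 1))
  active[(n + 1):length(active)] <- FALSE
  dmat <- matrix(Inf, length(active), length(active))
  dmat[1:n, 1:n] <- D
  diag(dmat) <- Inf
  coph <- matrix(0, n, n)
  next_id <- n + 1
  for (step in seq_len(n - 1)) {
    ids <- which(active)
    best <- c(NA, NA)
    best_d <- Inf
    for (a in ids) for (b in ids) {
      if (a < b && dmat[a, b] < best_d) {
        best_d <- dmat[a, b]
        best <- c(a, b)
      }
    }
    a <- best[1]; b <- best[2]
    merged <- c(clusters[[a]], clusters[[b]])
    for (i in clusters[[a]]) for (j in clusters[[b]]) {
      coph[i, j] <- best_d
      coph[j, i] <- best_d
    }
    clusters[[next_id]] <- merged
    active[c(a, b)] <- FALSE
    active[next_id] <- TRUE
    for (o in which(active)) {
      if (o == next_id) next
      na <- length(clusters[[a]]); nb <- length(clusters[[b]])
      d_new <- (na * dmat[a, o] + nb * dmat[b, o]) / (na + nb)
      dmat[next_id, o] <- d_new
      dmat[o, next_id] <- d_new
    }
    next_id <- next_id + 1
  }
  coph
}

# Expected noise-free log2 treated/untreated intensity ratio of a strain,
# from the compositional abundance update evaluated directly.
oracle_pool_log2_ratio <- function(f, delta, G, strain_idx) {
  w_u <- 2^(f * G)
  w_t <- 2^((f + delta) * G)
  log2((w_t[strain_idx] / sum(w_t)) / (w_u[strain_idx] / sum(w_u)))
}

# Ordinary two-sample pooled t-statistic and two-sided p-value.
oracle_pooled_t <- function(xt, xu) {
  n_t <- length(xt); n_u <- length(xu)
  d <- n_t + n_u - 2
  sp2 <- (sum((xt - mean(xt))^2) + sum((xu - mean(xu))^2)) / d
  t <- (mean(xt) - mean(xu)) / sqrt(sp2 * (1 / n_t + 1 / n_u))
  list(t = t, p = 2 * pt(-abs(t), d), s_sq = sp2, d = d)
}

# Transitive ancestor closure of a term DAG by depth-first search.
oracle_ancestors <- function(edges) {
  parents <- split(edges$parent, edges$child)
  all_terms <- unique(c(edges$child, edges$parent))
  walk <- function(tm) {
    out <- character()
    stack <- parents[[tm]]
    while (length(stack)) {
      x <- stack[[1]]
      stack <- stack[-1]
      if (!(x %in% out)) {
        out <- c(out, x)
        stack <- c(stack, parents[[x]])
      }
    }
    sort(out)
  }
  setNames(lapply(all_terms, walk), all_terms)
}
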