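# Brute-force oracles and fixture builders used across the suite. Each
# oracle is an independent, naive implementation of the quantity it checks
# (loops and enumeration, no shared code with the package internals).

random_sym_matrix <- function(n, density = 0.7, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < density) {
        w[i, j] <- runif(1, 0.05, 1)
        w[j, i] <- w[i, j]
      }
    }
  }
  w
}

# element-wise mean of two directed entries
oracle_symmetrise <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) out[i, j] <- (m[i, j] + m[j, i]) / 2
    }
  }
  out
}

# all-pairs shortest distances over 1/w lengths, plain triple loop
oracle_floyd_warshall <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && w[i, j] > 0) d[i, j] <- 1 / w[i, j]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_global_efficiency <- function(w) {
  d <- oracle_floyd_warshall(w)
  n <- nrow(w)
  if (n < 2) return(0)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
  }
  tot / (n * (n - 1))
}

oracle_char_path_length <- function(w) {
  d <- oracle_floyd_warshall(w)
  n <- nrow(w)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (is.finite(d[i, j])) vals <- c(vals, d[i, j])
  }
  if (length(vals) == 0) 0 else mean(vals)
}

# Onnela weighted clustering by explicit triple enumeration
oracle_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(rep(0, n))
  wh <- w / mx
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h) {
        s <- s + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
      }
    }
    ci[i] <- s / (k * (k - 1))
  }
  ci
}

oracle_local_efficiency <- function(w) {
  n <- nrow(w)
  el <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) >= 2) el[i] <- oracle_global_efficiency(w[nb, nb])
  }
  mean(el)
}

# enumerate every set partition of n elements (restricted growth strings)
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, mx) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (v in seq_len(mx + 1)) rec(c(prefix, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

oracle_modularity_q <- function(w, membership) {
  tw <- sum(w) / 2
  q <- 0
  for (c in unique(membership)) {
    idx <- which(membership == c)
    ec <- sum(w[idx, idx]) / 2
    dc <- sum(w[idx, ])
    q <- q + ec / tw - (dc / (2 * tw))^2
  }
  q
}

oracle_best_partition <- function(w) {
  parts <- all_set_partitions(nrow(w))
  qs <- vapply(parts, function(p) oracle_modularity_q(w, p), numeric(1))
  list(membership = parts[[which.max(qs)]], Q = max(qs))
}

# information-theoretic NMI: mutual information over arithmetic-mean entropy
oracle_nmi_entropy <- function(a, b) {
  n <- length(a)
  pij <- table(a, b) / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  mi <- 0
  for (i in seq_along(pi_)) for (j in seq_along(pj_)) {
    if (pij[i, j] > 0) mi <- mi + pij[i, j] * log(pij[i, j] / (pi_[i] * pj_[j]))
  }
  h <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  denom <- (h(pi_) + h(pj_)) / 2
  if (denom == 0) return(1)
  as.numeric(mi / denom)
}

# two unit-weight triangles joined by a single bridge edge
two_triangle_matrix <- function() {
  w <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))) {
    w[e[1], e[2]] <- 1
    w[e[2], e[1]] <- 1
  }
  w
}

# trapezoid integral written independently
oracle_trapz <- function(x, y) {
  s <- 0
  for (k in seq_len(length(x) - 1)) {
    s <- s + (x[k + 1] - x[k]) * (y[k] + y[k + 1]) / 2
  }
  s
}

# Mann-Whitney concordance AUC (pairwise counting)
oracle_concordance_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# pairwise U statistic with 0.5 credit for ties
oracle_u_statistic <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
  u
}

# small standard cohort config used by pipeline-level unit tests
small_cohort_config <- function(seed = 1L, n_per_group = 6L) {
  cohort_config(n_nodes = 20L, n_per_group = n_per_group, base_density = 0.4,
                noise_cv = 0.1, planted_nodes = 1:4, planted_effect = 0.6,
                master_seed = seed)
}
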