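#' Nodal strength
#'
#' Strength of node i is the sum of the weights of its incident edges
#' (the weighted degree).
#'
#' @param m A connectivity matrix.
#' @return Numeric vector of per-node strengths, named by node label.
#' @export
nodal_strength <- function(m) {
  rowSums(as.matrix(m))
}

#' Weighted clustering coefficient (Onnela)
#'
#' Per-node weighted clustering in the Onnela form: weights are normalised
#' by the network maximum, and the geometric-mean triangle intensity
#' around node i is divided by the number of possible triangles
#' k_i (k_i - 1), with k_i the binary degree. Nodes with fewer than two
#' neighbours contribute 0. Normalisation by the maximum makes the value
#' invariant under uniform rescaling of all weights.
#'
#' @param m A connectivity matrix.
#' @param per_node If `TRUE` return the per-node vector instead of the mean.
#' @return Mean clustering coefficient (or per-node vector).
#' @export
clustering_coefficient <- function(m, per_node = FALSE) {
  w <- as.matrix(m)
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0 || n < 3) {
    ci <- rep(0, n)
  } else {
    wh <- (w / mx)^(1 / 3)
    tri <- diag(wh %*% wh %*% wh)  # 2 x triangle intensity around each node
    k <- rowSums(w > 0)
    denom <- k * (k - 1)
    ci <- unname(ifelse(denom > 0, tri / denom, 0))
  }
  if (per_node) ci else mean(ci)
}

# igraph handle on the positive-weight edges; distances use the standard
# inverse-weight length transform for probability-weighted connectomes.
.as_igraph <- function(w) {
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# All-pairs shortest distances by vectorised Floyd-Warshall; kept in base R
# because the pipeline calls this on many small neighbourhood subgraphs,
# where per-call graph-construction overhead dominates.
.shortest_dist <- function(w) {
  n <- nrow(w)
  if (n == 0) return(matrix(numeric(0), 0, 0))
  d <- matrix(Inf, n, n)
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  for (k in seq_len(n)) {
    cand <- outer(d[, k], d[k, ], "+")
    d <- matrix(pmin(d, cand), n, n)
  }
  d
}

#' Characteristic path length and global efficiency
#'
#' Edge lengths are inverse weights (1/w for w > 0, infinite otherwise);
#' shortest paths are computed over these lengths. Global efficiency Eg is
#' the mean over ordered node pairs of the inverse shortest distance
#' (disconnected pairs contribute 0). Characteristic path length Lp is the
#' mean shortest distance over connected unordered pairs only.
#'
#' @param m A connectivity matrix.
#' @return List with `Lp`, `Eg` and logical `disconnected` (TRUE when any
#'   node pair has no connecting path). For a graph with no connected pair,
#'   `Lp` is 0 and `Eg` is 0.
#' @export
path_based_metrics <- function(m) {
  w <- as.matrix(m)
  n <- nrow(w)
  if (n < 2) return(list(Lp = 0, Eg = 0, disconnected = FALSE))
  d <- .shortest_dist(w)
  off <- d[upper.tri(d)]
  connected <- is.finite(off)
  eg <- mean(ifelse(connected, 1 / off, 0))  # ordered-pair mean == unordered mean
  lp <- if (any(connected)) mean(off[connected]) else 0
  list(Lp = lp, Eg = eg, disconnected = any(!connected))
}

#' Weighted local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbours, with the same inverse-weight length transform. Nodes
#' with fewer than two neighbours contribute 0.
#'
#' @param m A connectivity matrix.
#' @param per_node If `TRUE` return the per-node vector instead of the mean.
#' @return Mean local efficiency (or per-node vector).
#' @export
local_efficiency <- function(m, per_node = FALSE) {
  w <- as.matrix(m)
  n <- nrow(w)
  el <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    path_based_metrics(w[nb, nb, drop = FALSE])$Eg
  }, numeric(1))
  if (per_node) el else mean(el)
}

#' Louvain modularity with seeded restarts
#'
#' Maximises the weighted Newman modularity
#' Q = sum_c \[ e_c / W - (d_c / 2W)^2 \] by the Louvain algorithm, run
#' `restarts` times from seeded random states; the partition with the
#' highest Q is returned. A single-community partition (Q = 0) is used
#' whenever no split improves on it, so Q is never negative. Deterministic
#' given `seed`.
#'
#' @param m A connectivity matrix with at least one edge.
#' @param seed Integer seed.
#' @param restarts Number of seeded restarts (default 20).
#' @return List with `membership` (integer vector, contiguous labels
#'   starting at 1) and `Q`.
#' @export
modularity_louvain <- function(m, seed = 1L, restarts = 20L) {
  w <- as.matrix(m)
  n <- nrow(w)
  if (sum(w[upper.tri(w)] > 0) == 0) stop("modularity undefined for an edgeless graph")
  g <- .as_igraph(w)
  ew <- igraph::E(g)$weight
  best_q <- -Inf
  best_mem <- NULL
  for (r in seq_len(restarts)) {
    set.seed(.derive_seed(seed, r))
    cl <- igraph::cluster_louvain(g, weights = ew)
    mem <- igraph::membership(cl)
    q <- igraph::modularity(g, mem, weights = ew)
    if (q > best_q + 1e-12) {
      best_q <- q
      best_mem <- as.integer(mem)
    }
  }
  if (best_q < 0) {  # never return a worse-than-trivial split
    best_mem <- rep(1L, n)
    best_q <- 0
  }
  list(membership = .relabel_partition(best_mem), Q = best_q)
}

# canonical contiguous labels 1..C in order of first appearance
.relabel_partition <- function(mem) {
  as.integer(match(mem, unique(mem)))
}

#' Rich-club node assignment and connection-class strengths
#'
#' The rich club is the top `ceiling(rich_fraction * n)` nodes by nodal
#' strength (ties broken by ascending node index). Every existing edge is
#' classified: rich if both endpoints are rich-club nodes, feeder if
#' exactly one is, local if neither. Each class strength is the mean weight
#' of the existing edges in that class (0 for an empty class).
#'
#' @param m A connectivity matrix.
#' @param rich_fraction Fraction of nodes in the rich club, in (0, 1).
#' @return List with `rich_nodes` (integer indices), `edge_classes`
#'   (data frame: i, j, weight, class), `Rich_s`, `Feeder_s`, `Local_s`.
#' @export
rich_club_analysis <- function(m, rich_fraction = 0.15) {
  if (length(rich_fraction) != 1 || !is.finite(rich_fraction) ||
      rich_fraction <= 0 || rich_fraction >= 1) {
    stop("rich_fraction must lie in (0, 1)")
  }
  w <- as.matrix(m)
  n <- nrow(w)
  s <- rowSums(w)
  n_rich <- ceiling(rich_fraction * n)
  rich <- order(-s, seq_len(n))[seq_len(n_rich)]
  is_rich <- seq_len(n) %in% rich
  ut <- which(upper.tri(w) & w > 0)
  i <- ((ut - 1L) %% n) + 1L
  j <- ((ut - 1L) %/% n) + 1L
  n_rich_ends <- is_rich[i] + is_rich[j]
  cls <- c("local", "feeder", "rich")[n_rich_ends + 1L]
  wt <- w[ut]
  mean_or_zero <- function(x) if (length(x) > 0) mean(x) else 0
  list(
    rich_nodes = sort(rich),
    edge_classes = data.frame(i = i, j = j, weight = wt, class = cls,
                              stringsAsFactors = FALSE),
    Rich_s = mean_or_zero(wt[cls == "rich"]),
    Feeder_s = mean_or_zero(wt[cls == "feeder"]),
    Local_s = mean_or_zero(wt[cls == "local"])
  )
}

#' Area under the curve of a metric across the density grid
#'
#' Threshold-free summary of a network property: the trapezoidal integral
#' of the per-density metric values over the density grid.
#'
#' @param values Metric value at each grid density.
#' @param grid A [threshold_grid()] (or increasing numeric vector) of the
#'   same length, with at least two points.
#' @return The trapezoidal AUC.
#' @export
auc_over_densities <- function(values, grid) {
  grid <- as.numeric(grid)
  if (length(grid) < 2) stop("AUC requires a grid of at least two densities")
  if (length(values) != length(grid)) stop("values and grid lengths differ")
  sum(diff(grid) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' The eight AUC-summarised network properties of one connectome
#'
#' Thresholds the matrix at every density of the grid, computes the eight
#' weighted graph properties at each density (clustering coefficient,
#' global efficiency, local efficiency, characteristic path length,
#' Louvain modularity, and rich-club / local / feeder connection
#' strengths), and summarises each as its AUC over the grid. Deterministic
#' given `seed` (the Louvain restarts at each density are seeded).
#'
#' An edgeless thresholded matrix (e.g. an all-zero connectome) yields 0
#' for all properties at that density, with a warning for the undefined
#' modularity.
#'
#' @param m A connectivity matrix.
#' @param grid A [threshold_grid()].
#' @param rich_fraction Rich-club node fraction, see [rich_club_analysis()].
#' @param seed Integer seed for the modularity restarts.
#' @param restarts Louvain restarts per density.
#' @return Named numeric vector: `aCp`, `aEg`, `aEloc`, `aLp`, `aQ`,
#'   `Rich_s`, `Local_s`, `Feeder_s`.
#' @export
network_feature_vector <- function(m, grid = threshold_grid(),
                                   rich_fraction = 0.15, seed = 1L,
                                   restarts = 20L) {
  grid <- threshold_grid(as.numeric(grid))
  per_density <- matrix(0, nrow = length(grid), ncol = 8,
                        dimnames = list(NULL, c("Cp", "Eg", "Eloc", "Lp", "Q",
                                                "Rich_s", "Local_s", "Feeder_s")))
  for (k in seq_along(grid)) {
    mt <- threshold_by_density(m, grid[k])
    w <- as.matrix(mt)
    per_density[k, "Cp"] <- clustering_coefficient(mt)
    pm <- path_based_metrics(mt)
    per_density[k, "Eg"] <- pm$Eg
    per_density[k, "Lp"] <- pm$Lp
    per_density[k, "Eloc"] <- local_efficiency(mt)
    if (sum(w[upper.tri(w)] > 0) == 0) {
      warning("edgeless graph at density ", grid[k], "; modularity set to 0")
      per_density[k, "Q"] <- 0
    } else {
      per_density[k, "Q"] <- modularity_louvain(mt, seed = .derive_seed(seed, k),
                                                restarts = restarts)$Q
    }
    rc <- rich_club_analysis(mt, rich_fraction)
    per_density[k, "Rich_s"] <- rc$Rich_s
    per_density[k, "Local_s"] <- rc$Local_s
    per_density[k, "Feeder_s"] <- rc$Feeder_s
  }
  auc <- apply(per_density, 2, auc_over_densities, grid = grid)
  c(aCp = unname(auc["Cp"]), aEg = unname(auc["Eg"]),
    aEloc = unname(auc["Eloc"]), aLp = unname(auc["Lp"]),
    aQ = unname(auc["Q"]), Rich_s = unname(auc["Rich_s"]),
    Local_s = unname(auc["Local_s"]), Feeder_s = unname(auc["Feeder_s"]))
}

#' Network feature table for a cohort
#'
#' Applies [network_feature_vector()] to each subject and returns one row
#' per subject with the eight AUC metrics plus `subject_id` and `group`.
#'
#' @param matrices Named list of connectivity matrices (names = subject ids).
#' @param groups Character vector of group labels, parallel to `matrices`.
#' @param ... Passed to [network_feature_vector()].
#' @return Data frame with columns subject_id, group and the eight metrics.
#' @export
cohort_feature_table <- function(matrices, groups, ...) {
  stopifnot(length(matrices) == length(groups))
  rows <- lapply(seq_along(matrices), function(s) {
    fv <- network_feature_vector(matrices[[s]], ...)
    cbind(data.frame(subject_id = names(matrices)[s] %||% as.character(s),
                     group = groups[s], stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  do.call(rbind, rows)
}

#' Write a cohort feature table
#'
#' @param features Data frame from [cohort_feature_table()].
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
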