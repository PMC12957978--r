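#' Trimmed-mean reference matrix from control connectomes
#'
#' For each edge, the subject values are pooled across the control group,
#' the `floor(trim * S)` largest and smallest values are removed (S =
#' number of subjects) and the remaining values averaged, yielding the
#' reference ("standard") network of healthy ageing. With the default
#' trim of 0.025 the top and bottom 2.5% of values are removed at each
#' edge.
#'
#' @param hc_matrices List of connectivity matrices over the same node set.
#' @param trim Fraction trimmed from each tail, in \[0, 0.5).
#' @return The reference [connectivity_matrix()].
#' @export
build_reference_matrix <- function(hc_matrices, trim = 0.025) {
  if (length(hc_matrices) < 1) stop("at least one control matrix is required")
  if (trim < 0 || trim >= 0.5) stop("trim must lie in [0, 0.5)")
  labs <- rownames(as.matrix(hc_matrices[[1]]))
  n <- length(labs)
  for (m in hc_matrices) {
    if (!identical(rownames(as.matrix(m)), labs)) {
      stop("control matrices have heterogeneous node sets")
    }
  }
  s <- length(hc_matrices)
  k <- floor(trim * s)
  arr <- vapply(hc_matrices, function(m) as.numeric(as.matrix(m)),
                numeric(n * n))
  arr <- matrix(arr, nrow = n * n)  # one row per cell, one column per subject
  if (k == 0) {
    ref <- rowMeans(arr)
  } else {
    srt <- t(apply(arr, 1, sort))
    ref <- rowMeans(srt[, (k + 1):(s - k), drop = FALSE])
  }
  connectivity_matrix(matrix(ref, n, n), labs)
}

#' Patient-minus-reference difference matrix
#'
#' The element-wise mean of the patient-group matrices minus the reference
#' matrix. Entries may be negative; the diagonal is zero.
#'
#' @param group_matrices List of patient-group connectivity matrices.
#' @param reference The reference matrix from [build_reference_matrix()].
#' @return List with `deltas` (n x n symmetric matrix) and `node_labels`.
#' @export
build_difference_matrix <- function(group_matrices, reference) {
  if (length(group_matrices) < 1) stop("patient group is empty")
  ref <- as.matrix(reference)
  labs <- rownames(ref)
  for (m in group_matrices) {
    if (!identical(rownames(as.matrix(m)), labs)) {
      stop("patient matrices and reference have heterogeneous node sets")
    }
  }
  gm <- Reduce(`+`, lapply(group_matrices, as.matrix)) / length(group_matrices)
  deltas <- gm - ref
  diag(deltas) <- 0
  list(deltas = deltas, node_labels = labs)
}

#' Draw one randomised network from the difference matrix
#'
#' Reverse-correlation perturbation draw: each upper-triangle edge of the
#' difference matrix is independently included with probability
#' `inclusion_p`; the randomised network is the reference plus the masked
#' differences, clipped at zero (connection probabilities cannot be
#' negative) and symmetric by construction.
#'
#' With `mode = "permute"` the included difference values are additionally
#' permuted among the included positions, destroying edge identity while
#' keeping the value distribution.
#'
#' @param deltas Symmetric difference matrix (or result of
#'   [build_difference_matrix()]).
#' @param reference Reference connectivity matrix.
#' @param inclusion_p Per-edge inclusion probability in (0, 1].
#' @param seed Integer seed for the draw.
#' @param mode `"mask"` (default) or `"permute"`.
#' @return List with `weights` (a [connectivity_matrix()]), `mask`
#'   (symmetric logical matrix of included edges) and `seed_state`.
#' @export
sample_randomised_network <- function(deltas, reference, inclusion_p = 0.5,
                                      seed = 1L, mode = c("mask", "permute")) {
  mode <- match.arg(mode)
  if (is.list(deltas)) deltas <- deltas$deltas
  if (inclusion_p <= 0 || inclusion_p > 1) stop("inclusion_p must lie in (0, 1]")
  ref <- as.matrix(reference)
  n <- nrow(ref)
  ut <- which(upper.tri(ref))
  inc <- .with_seed(seed, {
    keep <- stats::runif(length(ut)) < inclusion_p
    if (mode == "permute" && sum(keep) > 1) {
      perm <- sample(which(keep))
      list(keep = keep, perm = perm)
    } else list(keep = keep, perm = which(keep))
  })
  mask <- matrix(FALSE, n, n)
  mask[ut[inc$keep]] <- TRUE
  mask <- mask | t(mask)
  dvals <- numeric(length(ut))
  dvals[inc$keep] <- deltas[ut][inc$perm]
  dmat <- matrix(0, n, n)
  dmat[ut] <- dvals
  dmat <- dmat + t(dmat)
  w <- pmax(ref + dmat, 0)
  diag(w) <- 0
  list(weights = connectivity_matrix(w, rownames(ref)), mask = mask,
       seed_state = as.integer(seed))
}

#' NMI selection of one randomised network
#'
#' Computes the candidate's partition profile and its NMI scores against
#' the patient (LOD) and control (HC) reference profiles, then applies the
#' selection criterion. Under `direction = "printed"` a candidate passes
#' when NMI_LOD < NMI_HC (the criterion as stated); under
#' `direction = "resemble_lod"` it passes when NMI_LOD > NMI_HC
#' (candidates resembling the patient configuration are retained). Ties
#' fail in both modes.
#'
#' @param candidate A randomised network from [sample_randomised_network()]
#'   (or any connectivity matrix).
#' @param lod_profile,hc_profile Reference partition profiles.
#' @param direction `"printed"` or `"resemble_lod"`.
#' @param score Which NMI score enters the criterion: `"combined"`
#'   (default, mean of modular and rich-club NMI), `"modular"` or
#'   `"richclub"`.
#' @param density_ref,rich_fraction,seed,restarts Passed to
#'   [partition_profile()].
#' @return List with logical `pass` and the two [nmi_scores()] results.
#' @export
nmi_select <- function(candidate, lod_profile, hc_profile,
                       direction = c("printed", "resemble_lod"),
                       score = c("combined", "modular", "richclub"),
                       density_ref = 0.225, rich_fraction = 0.15,
                       seed = 1L, restarts = 20L) {
  direction <- match.arg(direction)
  score <- match.arg(score)
  m <- if (is.list(candidate) && !is.null(candidate$weights)) candidate$weights else candidate
  prof <- partition_profile(m, density_ref = density_ref,
                            rich_fraction = rich_fraction, seed = seed,
                            restarts = restarts)
  sc <- score_against_references(prof, lod_profile, hc_profile)
  key <- switch(score, combined = "combined", modular = "nmi_modular",
                richclub = "nmi_richclub")
  s_lod <- sc$lod[[key]]
  s_hc <- sc$hc[[key]]
  pass <- if (direction == "printed") s_lod < s_hc else s_lod > s_hc
  list(pass = pass, lod = sc$lod, hc = sc$hc)
}

#' Aggregate inclusion masks into an edge-frequency map
#'
#' @param masks List of symmetric logical matrices (inclusion masks of the
#'   retained, classified randomised networks).
#' @return List with `counts` (symmetric integer matrix; counts\[i,j\] =
#'   number of masks including edge (i,j)) and `n_matrices`.
#' @export
aggregate_edge_frequencies <- function(masks) {
  if (length(masks) == 0) stop("no masks to aggregate")
  dims <- dim(masks[[1]])
  counts <- matrix(0L, dims[1], dims[2])
  for (mk in masks) {
    if (!identical(dim(mk), dims)) stop("masks have differing shapes")
    counts <- counts + mk
  }
  diag(counts) <- 0L
  list(counts = counts, n_matrices = length(masks))
}

#' Select the most frequently occurring edges of a frequency map
#'
#' Ranks the edges with nonzero counts by count (descending) and selects
#' the top `ceiling(fraction * K)` of the K nonzero-count edges; all edges
#' tied with the count at the cutoff are included and reported separately.
#'
#' @param freq Result of [aggregate_edge_frequencies()].
#' @param fraction Fraction of nonzero-count edges to select, in (0, 1).
#' @return Data frame with columns i, j, count, rank and logical
#'   `at_cutoff_tie` flagging edges added by the tie-extension rule.
#' @export
select_top_edges <- function(freq, fraction = 0.05) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  counts <- freq$counts
  n <- nrow(counts)
  ut <- which(upper.tri(counts) & counts > 0)
  if (length(ut) == 0) stop("frequency map has no nonzero counts")
  i <- ((ut - 1L) %% n) + 1L
  j <- ((ut - 1L) %/% n) + 1L
  cnt <- counts[ut]
  ord <- order(-cnt, i, j)
  k_sel <- ceiling(fraction * length(ut))
  cutoff <- cnt[ord][k_sel]
  sel <- which(cnt >= cutoff)
  if (length(unique(cnt)) == 1) {
    warning("all nonzero counts are equal; returning every nonzero-count edge as ties")
  }
  sel_ord <- sel[order(-cnt[sel], i[sel], j[sel])]
  data.frame(
    i = i[sel_ord], j = j[sel_ord], count = cnt[sel_ord],
    rank = seq_along(sel_ord),
    at_cutoff_tie = seq_along(sel_ord) > k_sel
  )
}

#' Run the reverse-correlation analysis
#'
#' The core engine: for each of `n_cycles` seeded cycles a randomised
#' network is drawn from the difference matrix
#' ([sample_randomised_network()]), screened by the NMI criterion
#' ([nmi_select()]), and — if retained — summarised by its network feature
#' vector and classified by the trained MLP. The inclusion masks of the
#' retained networks are grouped by predicted class, aggregated into
#' per-class edge-frequency maps, and the most frequent edges of each
#' class are selected. The whole run is reproducible from `seed`.
#'
#' @param reference Reference connectivity matrix.
#' @param deltas Difference matrix (matrix, or result of
#'   [build_difference_matrix()]).
#' @param model Trained MLP from [train_scg_mlp()].
#' @param lod_profile,hc_profile Reference partition profiles; computed
#'   from `reference + deltas` (clipped) and `reference` when NULL.
#' @param n_cycles Number of randomisation cycles (default 10000).
#' @param inclusion_p Per-edge inclusion probability.
#' @param direction,score NMI selection mode, see [nmi_select()].
#' @param fraction Top-edge fraction per class (default 0.05).
#' @param grid Density grid for the classifier features.
#' @param density_ref Reference density for partition profiles (default:
#'   median of `grid`).
#' @param rich_fraction Rich-club node fraction.
#' @param restarts Louvain restarts inside the pipeline.
#' @param mode Randomisation mode, see [sample_randomised_network()].
#' @param seed Master seed fixing every draw and restart.
#' @param metric_seed Seed used for the Louvain restarts of every
#'   candidate's partition profile and feature vector. One fixed seed is
#'   used for all cycles so that candidate features are a deterministic
#'   function of the candidate matrix, computed exactly as the training
#'   features were; pass the seed used for the training feature table to
#'   make the two computations identical. Default: derived from `seed`.
#' @return A `reverse_correlation_result`: list with `retained_count`
#'   (named per class, plus `total`), `frequency_maps`, `selected_edges`
#'   (per class, NULL where nothing was retained), `nmi_pass_count` and a
#'   `config` echo including the master seed.
#' @export
run_reverse_correlation <- function(reference, deltas, model,
                                    lod_profile = NULL, hc_profile = NULL,
                                    n_cycles = 10000L, inclusion_p = 0.5,
                                    direction = c("printed", "resemble_lod"),
                                    score = c("combined", "modular", "richclub"),
                                    fraction = 0.05, grid = threshold_grid(),
                                    density_ref = NULL, rich_fraction = 0.15,
                                    restarts = 20L,
                                    mode = c("mask", "permute"), seed = 1L,
                                    metric_seed = NULL) {
  direction <- match.arg(direction)
  score <- match.arg(score)
  mode <- match.arg(mode)
  if (is.list(deltas)) deltas <- deltas$deltas
  grid <- threshold_grid(as.numeric(grid))
  if (is.null(density_ref)) density_ref <- stats::median(as.numeric(grid))
  if (is.null(metric_seed)) metric_seed <- .derive_seed(seed, 3L)
  ref <- as.matrix(reference)
  if (is.null(lod_profile) || is.null(hc_profile)) {
    lod_net <- connectivity_matrix(pmax(ref + deltas, 0), rownames(ref))
    if (is.null(lod_profile)) {
      lod_profile <- partition_profile(lod_net, density_ref, rich_fraction,
                                       seed = .derive_seed(seed, -1L),
                                       restarts = restarts)
    }
    if (is.null(hc_profile)) {
      hc_profile <- partition_profile(reference, density_ref, rich_fraction,
                                      seed = .derive_seed(seed, -2L),
                                      restarts = restarts)
    }
  }
  classes <- model$classes
  masks_by_class <- stats::setNames(vector("list", length(classes)), classes)
  for (cl in classes) masks_by_class[[cl]] <- list()
  nmi_pass <- 0L
  if (n_cycles > 0) {
    for (cyc in seq_len(n_cycles)) {
      s_cyc <- .derive_seed(seed, cyc)
      cand <- sample_randomised_network(deltas, reference, inclusion_p,
                                        seed = s_cyc, mode = mode)
      sel <- nmi_select(cand, lod_profile, hc_profile, direction = direction,
                        score = score, density_ref = density_ref,
                        rich_fraction = rich_fraction,
                        seed = metric_seed, restarts = restarts)
      if (!sel$pass) next
      nmi_pass <- nmi_pass + 1L
      fv <- network_feature_vector(cand$weights, grid = grid,
                                   rich_fraction = rich_fraction,
                                   seed = metric_seed,
                                   restarts = restarts)
      pred <- predict_mlp(model, fv[model$feature_names])
      masks_by_class[[pred$label]] <-
        c(masks_by_class[[pred$label]], list(cand$mask))
    }
  }
  retained <- vapply(masks_by_class, length, integer(1))
  frequency_maps <- stats::setNames(vector("list", length(classes)), classes)
  selected <- stats::setNames(vector("list", length(classes)), classes)
  for (cl in classes) {
    if (retained[[cl]] == 0) {
      warning("no retained matrices for class '", cl, "'")
      next
    }
    frequency_maps[[cl]] <- aggregate_edge_frequencies(masks_by_class[[cl]])
    if (any(frequency_maps[[cl]]$counts > 0)) {
      selected[[cl]] <- select_top_edges(frequency_maps[[cl]], fraction)
    }
  }
  structure(list(
    retained_count = c(as.list(retained), list(total = sum(retained))),
    nmi_pass_count = nmi_pass,
    frequency_maps = frequency_maps,
    selected_edges = selected,
    node_labels = rownames(ref),
    config = list(n_cycles = n_cycles, inclusion_p = inclusion_p,
                  direction = direction, score = score, fraction = fraction,
                  grid = as.numeric(grid), density_ref = density_ref,
                  rich_fraction = rich_fraction, restarts = restarts,
                  mode = mode, seed = as.integer(seed),
                  metric_seed = as.integer(metric_seed))
  ), class = "reverse_correlation_result")
}

#' Write reverse-correlation outputs to a directory
#'
#' Emits, per class, the edge-frequency matrix (same delimited format as
#' connectivity matrices) and the selected-edge table, plus a JSON run
#' summary (retained counts, config echo, master seed).
#'
#' @param result A `reverse_correlation_result`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_reverse_correlation_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labs <- result$node_labels
  for (cl in names(result$frequency_maps)) {
    fm <- result$frequency_maps[[cl]]
    if (is.null(fm)) next
    cm <- connectivity_matrix(fm$counts, labs)
    write_connectivity_matrix(cm, file.path(dir, paste0("frequency_", cl, ".csv")))
    se <- result$selected_edges[[cl]]
    if (!is.null(se)) {
      se$label_i <- labs[se$i]
      se$label_j <- labs[se$j]
      utils::write.table(se[c("i", "j", "label_i", "label_j", "count",
                              "rank", "at_cutoff_tie")],
                         file.path(dir, paste0("selected_edges_", cl, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  summary <- list(retained_count = result$retained_count,
                  nmi_pass_count = result$nmi_pass_count,
                  config = result$config)
  jsonlite::write_json(summary, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
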