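#' Configuration for a synthetic connectome cohort
#'
#' Defines the study conditions emulated by the generator: a shared
#' template connectome, subject-level multiplicative noise, and a planted
#' group effect on the edges inside a node cluster (emulating a regional
#' weakening of connectivity in the patient group).
#'
#' The planted edges are, by default, every node pair inside
#' `planted_nodes`; these edges are guaranteed to exist in the template
#' (an effect can only be planted on present connections). A subset can
#' be specified explicitly via `planted_edges` (two-column matrix of node
#' indices).
#'
#' @param n_nodes Number of network nodes (default 82).
#' @param n_per_group Subjects per group (default 30).
#' @param base_density Fraction of nonzero edges in the template
#'   (default 0.3).
#' @param noise_cv Coefficient of variation of the per-edge lognormal
#'   subject noise (mean 1; default 0.2).
#' @param planted_nodes Node indices of the planted cluster (default the
#'   first 6 nodes).
#' @param planted_effect Multiplicative factor applied to planted-edge
#'   weights in the patient group (default 0.6, i.e. a 40% weakening).
#' @param planted_edges Optional explicit matrix of planted edges
#'   (columns i, j), a subset of the within-cluster pairs.
#' @param master_seed Integer seed fixing the template and every subject.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_nodes = 82L, n_per_group = 30L,
                          base_density = 0.3, noise_cv = 0.2,
                          planted_nodes = 1:6, planted_effect = 0.6,
                          planted_edges = NULL, master_seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be at least 2")
  if (planted_effect <= 0) stop("planted_effect must be positive")
  if (noise_cv < 0) stop("noise_cv must be nonnegative")
  if (any(planted_nodes < 1 | planted_nodes > n_nodes)) {
    stop("planted node outside the node range")
  }
  if (!is.null(planted_edges)) {
    planted_edges <- as.matrix(planted_edges)
    if (!all(planted_edges %in% planted_nodes)) {
      stop("planted_edges must connect planted nodes")
    }
  }
  structure(list(n_nodes = as.integer(n_nodes),
                 n_per_group = as.integer(n_per_group),
                 base_density = base_density, noise_cv = noise_cv,
                 planted_nodes = as.integer(planted_nodes),
                 planted_effect = planted_effect,
                 planted_edges = planted_edges,
                 master_seed = as.integer(master_seed)),
            class = "cohort_config")
}

# planted edge list as a two-column matrix (i < j)
.planted_edge_matrix <- function(config) {
  if (!is.null(config$planted_edges)) {
    pe <- config$planted_edges
    cbind(pmin(pe[, 1], pe[, 2]), pmax(pe[, 1], pe[, 2]))
  } else {
    t(utils::combn(sort(config$planted_nodes), 2))
  }
}

#' Planted edge keys of a cohort configuration
#'
#' @param config A [cohort_config()].
#' @return Character vector of canonical `"i-j"` edge keys.
#' @export
planted_edge_keys <- function(config) {
  pe <- .planted_edge_matrix(config)
  edge_keys(pe[, 1], pe[, 2])
}

#' Generate the template connectome of a synthetic cohort
#'
#' Edges are present independently with probability `base_density`
#' (planted edges always present) and weights are drawn from a Beta(2, 5)
#' distribution, mimicking the nonnegative right-skewed distribution of
#' tract connection probabilities. Deterministic from `master_seed`.
#'
#' @param config A [cohort_config()].
#' @return A [connectivity_matrix()].
#' @export
generate_template <- function(config) {
  n <- config$n_nodes
  .with_seed(.derive_seed(config$master_seed, 0L), {
    w <- matrix(0, n, n)
    ut <- which(upper.tri(w))
    present <- stats::runif(length(ut)) < config$base_density
    wts <- stats::rbeta(length(ut), 2, 5)
    pe <- .planted_edge_matrix(config)
    present[match(pe[, 1] + (pe[, 2] - 1) * n, ut)] <- TRUE
    w[ut[present]] <- wts[present]
    w <- w + t(w)
    connectivity_matrix(w)
  })
}

#' Generate a synthetic two-group cohort of connectomes
#'
#' Control subjects are the template with independent per-edge lognormal
#' multiplicative noise (mean 1, coefficient of variation `noise_cv`);
#' patient subjects additionally have their planted-edge weights
#' multiplied by `planted_effect`. Fully deterministic from
#' `master_seed`, including per-subject sub-seeds.
#'
#' @param config A [cohort_config()].
#' @return List with `matrices` (named list of connectivity matrices),
#'   `manifest` (data frame: subject_id, group, matrix_path — empty paths
#'   until written), `template` and `planted_edges` (key vector).
#' @export
generate_cohort <- function(config) {
  template <- generate_template(config)
  n <- config$n_nodes
  tw <- as.matrix(template)
  ut <- which(upper.tri(tw))
  pe <- .planted_edge_matrix(config)
  planted_idx <- pe[, 1] + (pe[, 2] - 1) * n
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  meanlog <- -sdlog^2 / 2  # keeps the multiplicative noise mean at 1
  make_subject <- function(sub_seed, patient) {
    .with_seed(sub_seed, {
      w <- tw
      if (config$noise_cv > 0) {
        noise <- stats::rlnorm(length(ut), meanlog, sdlog)
        w[ut] <- w[ut] * noise
      }
      if (patient) w[planted_idx] <- w[planted_idx] * config$planted_effect
      w[lower.tri(w)] <- 0
      w <- w + t(w)
      connectivity_matrix(w, rownames(tw))
    })
  }
  s <- config$n_per_group
  ids <- c(paste0("HC", sprintf("%03d", seq_len(s))),
           paste0("PAT", sprintf("%03d", seq_len(s))))
  groups <- rep(c("HC", "PATIENT"), each = s)
  matrices <- lapply(seq_along(ids), function(k) {
    make_subject(.derive_seed(config$master_seed, k), groups[k] == "PATIENT")
  })
  names(matrices) <- ids
  list(matrices = matrices,
       manifest = data.frame(subject_id = ids, group = groups,
                             matrix_path = "", stringsAsFactors = FALSE),
       template = template,
       planted_edges = planted_edge_keys(config))
}

#' Write a generated cohort to a directory
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory.
#' @return The manifest (with `matrix_path` filled in), invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort$manifest
  for (k in seq_len(nrow(manifest))) {
    p <- file.path(dir, paste0(manifest$subject_id[k], ".csv"))
    write_connectivity_matrix(cohort$matrices[[k]], p)
    manifest$matrix_path[k] <- p
  }
  write_cohort_manifest(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

#' Precision and recall of a selected edge set against the planted set
#'
#' @param selected_edges Selected edges: a data frame with columns i, j
#'   (e.g. from [select_top_edges()]) or a character vector of `"i-j"` keys.
#' @param planted_edges Character vector of planted `"i-j"` keys (nonempty).
#' @return List with `precision` and `recall`.
#' @export
recovery_metrics <- function(selected_edges, planted_edges) {
  if (length(planted_edges) == 0) stop("planted edge set is empty")
  if (is.data.frame(selected_edges)) {
    sel <- edge_keys(selected_edges$i, selected_edges$j)
  } else {
    sel <- as.character(selected_edges)
  }
  hit <- length(intersect(sel, planted_edges))
  list(precision = if (length(sel) > 0) hit / length(sel) else 0,
       recall = hit / length(planted_edges))
}

#' End-to-end planted-edge recovery experiment
#'
#' Runs the full pipeline on one synthetic cohort: generate the cohort,
#' compute every subject's network feature vector, train the MLP on a
#' stratified 8:1:1 split (patients labelled `impaired`, controls
#' `normal`), build the trimmed-mean reference from the controls and the
#' patient-minus-reference difference matrix, run the reverse-correlation
#' engine, and score the patient-class selected edges against the planted
#' set.
#'
#' @param config A [cohort_config()].
#' @param n_cycles Randomisation cycles (default 2000).
#' @param grid Density grid for the features (default
#'   `threshold_grid(seq(0.1, 0.4, by = 0.1))`, a coarse grid chosen for
#'   the pipeline's inner loop).
#' @param direction NMI selection mode (default `"resemble_lod"`: the
#'   recovery targets candidates resembling the patient configuration).
#' @param restarts Louvain restarts inside the pipeline (default 3).
#' @param fraction Top-edge fraction (default 0.05).
#' @param inclusion_p Per-edge inclusion probability (default 0.5).
#' @return List with `precision`, `recall`, `result` (the
#'   `reverse_correlation_result`), `model`, `test_accuracy` and
#'   `planted_edges`.
#' @export
run_recovery_experiment <- function(config,
                                    n_cycles = 2000L,
                                    grid = threshold_grid(seq(0.1, 0.4, by = 0.1)),
                                    direction = "resemble_lod",
                                    restarts = 3L, fraction = 0.05,
                                    inclusion_p = 0.5) {
  seed <- config$master_seed
  cohort <- generate_cohort(config)
  groups <- cohort$manifest$group
  features <- cohort_feature_table(cohort$matrices, groups, grid = grid,
                                   seed = .derive_seed(seed, 101L),
                                   restarts = restarts)
  features$label <- ifelse(features$group == "PATIENT", "impaired", "normal")
  split <- stratified_split(features, c(0.8, 0.1, 0.1),
                            seed = .derive_seed(seed, 102L))
  model <- train_scg_mlp(split$train, split$validation,
                         seed = .derive_seed(seed, 103L))
  test_pred <- predict_mlp(model, split$test)
  test_acc <- mean(test_pred$label == split$test$label)
  hc_mats <- cohort$matrices[groups == "HC"]
  pat_mats <- cohort$matrices[groups == "PATIENT"]
  reference <- build_reference_matrix(hc_mats, trim = 0.025)
  diff <- build_difference_matrix(pat_mats, reference)
  result <- run_reverse_correlation(
    reference, diff, model,
    n_cycles = n_cycles, inclusion_p = inclusion_p,
    direction = direction, fraction = fraction, grid = grid,
    rich_fraction = 0.15, restarts = restarts,
    seed = .derive_seed(seed, 104L),
    metric_seed = .derive_seed(seed, 101L)  # same seed as the training features
  )
  sel <- result$selected_edges[["impaired"]]
  rec <- if (is.null(sel)) list(precision = 0, recall = 0)
         else recovery_metrics(sel, cohort$planted_edges)
  list(precision = rec$precision, recall = rec$recall, result = result,
       model = model, test_accuracy = test_acc,
       planted_edges = cohort$planted_edges)
}
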