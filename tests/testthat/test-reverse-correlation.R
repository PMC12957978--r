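make_matrices <- function(n_sub, n = 6, seed = 1) {
  lapply(seq_len(n_sub), function(s) {
    connectivity_matrix(random_sym_matrix(n, density = 0.9, seed = seed + s))
  })
}

test_that("the reference matrix is a per-edge trimmed mean", {
  one <- connectivity_matrix(random_sym_matrix(5, seed = 3))
  mats <- rep(list(one), 90)
  expect_equal(unclass(build_reference_matrix(mats, 0.025)), unclass(one))

  # 40 subjects whose values at one edge are 1..40: trim 0.025 drops one
  # from each tail, leaving mean(2:39) = 20.5
  mats40 <- lapply(1:40, function(v) {
    w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- v
    connectivity_matrix(w)
  })
  ref <- build_reference_matrix(mats40, 0.025)
  expect_equal(unclass(ref)[1, 2], mean(2:39))
  srt <- sort(sapply(1:40, function(v) v))  # sort-and-slice oracle
  expect_equal(unclass(ref)[1, 2], mean(srt[2:39]))

  # 10 subjects: floor(0.025 * 10) = 0 dropped, plain mean
  mats10 <- make_matrices(10, seed = 5)
  ref10 <- build_reference_matrix(mats10, 0.025)
  plain <- Reduce(`+`, lapply(mats10, unclass)) / 10
  expect_equal(unclass(ref10), plain, tolerance = 1e-12)

  bad <- c(mats10, list(connectivity_matrix(matrix(0, 4, 4))))
  expect_error(build_reference_matrix(bad), "heterogeneous")
})

test_that("the difference matrix is the group mean minus the reference", {
  mats <- make_matrices(5, seed = 20)
  ref <- build_reference_matrix(mats)
  d0 <- build_difference_matrix(mats, ref)
  expect_equal(max(abs(d0$deltas)), 0, tolerance = 1e-12)

  single <- make_matrices(1, seed = 31)
  d1 <- build_difference_matrix(single, ref)
  expect_equal(d1$deltas, unclass(single[[1]]) - unclass(ref), tolerance = 1e-12)

  grp <- make_matrices(5, seed = 40)
  d5 <- build_difference_matrix(grp, ref)
  loop <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    if (i != j) {
      loop[i, j] <- mean(sapply(grp, function(m) unclass(m)[i, j])) - unclass(ref)[i, j]
    }
  }
  expect_equal(unname(d5$deltas), loop, tolerance = 1e-12)

  expect_error(build_difference_matrix(list(), ref), "empty")
})

test_that("randomised networks apply Bernoulli edge masks to the differences", {
  ref <- connectivity_matrix(random_sym_matrix(6, density = 1, seed = 50))
  pat <- connectivity_matrix(random_sym_matrix(6, density = 1, seed = 51))
  deltas <- unclass(pat) - unclass(ref)

  full <- sample_randomised_network(deltas, ref, inclusion_p = 1, seed = 1)
  expect_equal(unclass(full$weights), pmax(unclass(ref) + deltas, 0),
               tolerance = 1e-12)

  none <- sample_randomised_network(matrix(0, 6, 6), ref, 0.5, seed = 2)
  expect_equal(unclass(none$weights), unclass(ref), tolerance = 1e-12)

  # per-edge inclusion frequency ~ Binomial(p = 0.5) across many draws
  ref10 <- connectivity_matrix(random_sym_matrix(10, density = 1, seed = 52))
  d10 <- matrix(0.01, 10, 10); diag(d10) <- 0
  n_draws <- 4000
  acc <- matrix(0, 10, 10)
  for (k in seq_len(n_draws)) {
    acc <- acc + sample_randomised_network(d10, ref10, 0.5, seed = k)$mask
  }
  freq <- acc[upper.tri(acc)] / n_draws
  se <- sqrt(0.25 / n_draws)
  expect_true(all(abs(freq - 0.5) < 4 * se))
  expect_lt(abs(mean(freq) - 0.5), 4 * se / sqrt(45))
})

test_that("randomised networks always satisfy the connectivity invariants", {
  ref <- connectivity_matrix(random_sym_matrix(8, density = 0.7, seed = 60))
  deltas <- random_sym_matrix(8, density = 0.9, seed = 61) - 0.5
  deltas <- (deltas + t(deltas)) / 2; diag(deltas) <- 0
  for (k in 1:1000) {
    rn <- sample_randomised_network(deltas, ref, 0.5, seed = k)
    expect_equal(length(validate_matrix(unclass(rn$weights))), 0)
    expect_true(all(rn$mask == t(rn$mask)))
    expect_true(all(!diag(rn$mask)))
  }
})

test_that("the permute randomisation mode keeps the included value multiset", {
  # large reference weights so clipping at zero never triggers
  w <- matrix(10, 7, 7); diag(w) <- 0
  ref <- connectivity_matrix(w)
  deltas <- random_sym_matrix(7, density = 1, seed = 71) - 0.4
  deltas <- (deltas + t(deltas)) / 2; diag(deltas) <- 0
  rn <- sample_randomised_network(deltas, ref, 0.6, seed = 5, mode = "permute")
  sel <- upper.tri(w) & rn$mask
  applied <- (unclass(rn$weights) - w)[sel]
  expect_equal(sort(applied), sort(deltas[sel]), tolerance = 1e-12)
  # mask mode applies each delta at its own edge
  rm_ <- sample_randomised_network(deltas, ref, 0.6, seed = 5, mode = "mask")
  selm <- upper.tri(w) & rm_$mask
  expect_equal((unclass(rm_$weights) - w)[selm], deltas[selm], tolerance = 1e-12)
})

test_that("NMI selection passes and fails as the direction dictates", {
  set.seed(80)
  ref <- connectivity_matrix(random_sym_matrix(12, density = 0.6, seed = 80))
  pat_w <- unclass(ref)
  pat_w[1:4, 1:4] <- pat_w[1:4, 1:4] * 0.2  # strongly weakened cluster
  pat <- connectivity_matrix(pat_w)
  lod_prof <- partition_profile(pat, density_ref = 0.4, seed = 1)
  hc_prof <- partition_profile(ref, density_ref = 0.4, seed = 2)

  cand_lod <- list(weights = pat)
  sel <- nmi_select(cand_lod, lod_prof, hc_prof, direction = "resemble_lod",
                    density_ref = 0.4, seed = 1)
  expect_true(sel$pass)
  expect_equal(sel$lod$combined, 1)

  cand_ref <- list(weights = ref)
  sel2 <- nmi_select(cand_ref, lod_prof, hc_prof, direction = "resemble_lod",
                     density_ref = 0.4, seed = 2)
  expect_false(sel2$pass)
  # the printed direction is the exact complement on non-tied scores
  sel3 <- nmi_select(cand_ref, lod_prof, hc_prof, direction = "printed",
                     density_ref = 0.4, seed = 2)
  expect_true(sel3$pass)

  expect_error(nmi_select(cand_ref, lod_prof, hc_prof, direction = "up"))

  # determinism of the pass set across runs
  deltas <- pat_w - unclass(ref)
  passes <- function() {
    vapply(1:40, function(k) {
      cand <- sample_randomised_network(deltas, ref, 0.5, seed = k)
      nmi_select(cand, lod_prof, hc_prof, direction = "resemble_lod",
                 density_ref = 0.4, seed = k)$pass
    }, logical(1))
  }
  expect_identical(passes(), passes())
})

test_that("edge frequencies aggregate mask counts exactly", {
  m1 <- matrix(FALSE, 4, 4); m1[1, 2] <- m1[2, 1] <- TRUE
  f3 <- aggregate_edge_frequencies(list(m1, m1, m1))
  expect_equal(f3$counts[1, 2], 3)
  expect_equal(f3$n_matrices, 3)
  expect_equal(sum(f3$counts), 6)  # symmetric count matrix

  m2 <- matrix(FALSE, 4, 4); m2[3, 4] <- m2[4, 3] <- TRUE
  fd <- aggregate_edge_frequencies(list(m1, m2))
  expect_true(all(fd$counts <= 1))

  set.seed(90)
  masks <- lapply(1:7, function(k) {
    mk <- matrix(runif(25) < 0.4, 5, 5)
    mk <- mk | t(mk); diag(mk) <- FALSE; mk
  })
  fr <- aggregate_edge_frequencies(masks)
  loop <- matrix(0, 5, 5)
  for (mk in masks) loop <- loop + mk
  diag(loop) <- 0
  expect_equal(unname(fr$counts), unname(loop))

  expect_error(aggregate_edge_frequencies(list()), "no masks")
})

test_that("top-edge selection ranks by count with tie extension at the cutoff", {
  # 100 edges with distinct counts on a 15-node map
  n <- 15
  counts <- matrix(0L, n, n)
  ut <- which(upper.tri(counts))[1:100]
  counts[ut] <- sample(1:100)
  counts <- counts + t(counts)
  sel <- select_top_edges(list(counts = counts, n_matrices = 100), 0.05)
  expect_equal(nrow(sel), 5)
  expect_equal(sort(sel$count, decreasing = TRUE), 100:96)

  # all counts equal: every nonzero edge is returned with a warning
  eq <- matrix(0L, 5, 5); eq[1, 2] <- eq[2, 1] <- 2L; eq[3, 4] <- eq[4, 3] <- 2L
  expect_warning(sel_eq <- select_top_edges(list(counts = eq, n_matrices = 2), 0.5),
                 "ties")
  expect_equal(nrow(sel_eq), 2)

  # ties straddling the cutoff match brute-force sort-cut-extend
  cnt2 <- matrix(0L, 8, 8)
  vals <- c(9L, 7L, 7L, 7L, 3L, 2L, 1L, 1L, 1L, 1L)
  ut2 <- which(upper.tri(cnt2))[1:10]
  cnt2[ut2] <- vals
  cnt2 <- cnt2 + t(cnt2)
  sel2 <- select_top_edges(list(counts = cnt2, n_matrices = 9), 0.2)
  # k = ceiling(0.2 * 10) = 2; cutoff count is 7, so all three 7s join
  expect_equal(sort(sel2$count, decreasing = TRUE), c(9, 7, 7, 7))
  expect_equal(sum(sel2$at_cutoff_tie), 2)

  expect_error(select_top_edges(list(counts = matrix(0L, 3, 3), n_matrices = 1), 0.1),
               "no nonzero")
})

test_that("the reverse-correlation engine is deterministic and conserves masks", {
  cfg <- small_cohort_config(seed = 3)
  cohort <- generate_cohort(cfg)
  grid <- threshold_grid(c(0.2, 0.3, 0.4))
  groups <- cohort$manifest$group
  feats <- cohort_feature_table(cohort$matrices, groups, grid = grid,
                                seed = 7, restarts = 2)
  feats$label <- ifelse(feats$group == "PATIENT", "impaired", "normal")
  model <- train_scg_mlp(feats, feature_names = classifier_features(),
                         max_epochs = 200, seed = 5)
  ref <- build_reference_matrix(cohort$matrices[groups == "HC"])
  diffm <- build_difference_matrix(cohort$matrices[groups == "PATIENT"], ref)

  run <- function() {
    run_reverse_correlation(ref, diffm, model, n_cycles = 60L,
                            grid = grid, restarts = 2,
                            direction = "resemble_lod", seed = 99L)
  }
  r1 <- suppressWarnings(run())
  r2 <- suppressWarnings(run())
  expect_identical(r1$retained_count, r2$retained_count)
  expect_identical(r1$frequency_maps, r2$frequency_maps)
  expect_identical(r1$selected_edges, r2$selected_edges)

  # mask conservation: per-class retained counts sum to the total
  expect_equal(r1$retained_count$impaired + r1$retained_count$normal,
               r1$retained_count$total)
  expect_lte(r1$retained_count$total, 60L)
  expect_equal(r1$retained_count$total, r1$nmi_pass_count)

  # zero cycles: empty result, no throw
  r0 <- suppressWarnings(run_reverse_correlation(ref, diffm, model,
                                                 n_cycles = 0L, grid = grid,
                                                 restarts = 2, seed = 1L))
  expect_equal(r0$retained_count$total, 0L)

  # serialisation is byte-identical across reruns of the same seed
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_reverse_correlation_result(r1, d1)
  write_reverse_correlation_result(r2, d2)
  f1 <- list.files(d1)
  expect_true(length(f1) >= 1)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
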