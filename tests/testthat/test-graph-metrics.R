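unit_triangle <- function() {
  w <- matrix(1, 3, 3); diag(w) <- 0; w
}

test_that("nodal strength equals row sums", {
  expect_equal(unname(nodal_strength(connectivity_matrix(unit_triangle()))),
               c(2, 2, 2))
  expect_equal(unname(nodal_strength(connectivity_matrix(matrix(0, 4, 4)))),
               rep(0, 4))
  w <- random_sym_matrix(6, seed = 11)
  s <- unname(nodal_strength(connectivity_matrix(w)))
  loop <- numeric(6)
  for (i in 1:6) for (j in 1:6) loop[i] <- loop[i] + w[i, j]
  expect_equal(s, loop)
})

test_that("Onnela clustering matches triple enumeration and analytic cases", {
  expect_equal(clustering_coefficient(connectivity_matrix(unit_triangle())), 1)

  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(clustering_coefficient(connectivity_matrix(path3)), 0)

  # triangle with one weak edge: the node joining the two unit edges
  tri <- matrix(0, 3, 3)
  tri[1, 2] <- tri[2, 1] <- 1; tri[1, 3] <- tri[3, 1] <- 1
  tri[2, 3] <- tri[3, 2] <- 0.125
  pn <- clustering_coefficient(connectivity_matrix(tri), per_node = TRUE)
  expect_equal(pn[1], 0.5)
  expect_equal(pn, oracle_clustering(tri))

  for (s in 1:5) {
    w <- random_sym_matrix(7, density = 0.6, seed = s)
    expect_equal(clustering_coefficient(connectivity_matrix(w), per_node = TRUE),
                 oracle_clustering(w), tolerance = 1e-9)
  }
})

test_that("clustering and local efficiency are scale invariant (max normalisation / 1/w paths)", {
  w <- random_sym_matrix(8, density = 0.6, seed = 21)
  cm1 <- connectivity_matrix(w)
  cm2 <- connectivity_matrix(w * 3.7)
  expect_equal(clustering_coefficient(cm1), clustering_coefficient(cm2),
               tolerance = 1e-12)
  expect_equal(local_efficiency(cm2), 3.7 * local_efficiency(cm1),
               tolerance = 1e-9)  # efficiencies scale linearly with weights
})

test_that("path metrics match the Floyd-Warshall oracle", {
  # complete unit-weight graph: every shortest distance is 1
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  pm <- path_based_metrics(connectivity_matrix(k5))
  expect_equal(pm$Eg, 1)
  expect_equal(pm$Lp, 1)
  expect_false(pm$disconnected)

  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  pm3 <- path_based_metrics(connectivity_matrix(path3))
  expect_equal(pm3$Eg, (1 + 1 + 0.5) / 3, tolerance = 1e-12)
  expect_equal(pm3$Lp, 4 / 3, tolerance = 1e-12)

  iso <- matrix(0, 2, 2)
  pmi <- path_based_metrics(connectivity_matrix(iso))
  expect_equal(pmi$Eg, 0)
  expect_true(pmi$disconnected)

  for (s in 1:8) {
    w <- random_sym_matrix(8, density = 0.4, seed = s)
    pm <- path_based_metrics(connectivity_matrix(w))
    expect_equal(pm$Eg, oracle_global_efficiency(w), tolerance = 1e-9)
    expect_equal(pm$Lp, oracle_char_path_length(w), tolerance = 1e-9)
  }
})

test_that("local efficiency equals brute-force neighbourhood-subgraph efficiency", {
  k3 <- unit_triangle()
  expect_equal(local_efficiency(connectivity_matrix(k3)), 1)

  star <- matrix(0, 5, 5)
  star[1, 2:5] <- 1; star[2:5, 1] <- 1
  expect_equal(local_efficiency(connectivity_matrix(star)), 0)

  for (s in 1:5) {
    w <- random_sym_matrix(7, density = 0.5, seed = s + 30)
    expect_equal(local_efficiency(connectivity_matrix(w)),
                 oracle_local_efficiency(w), tolerance = 1e-9)
  }
})

test_that("Louvain modularity finds the exhaustive-search optimum on small graphs", {
  w <- two_triangle_matrix()
  res <- modularity_louvain(connectivity_matrix(w), seed = 5)
  best <- oracle_best_partition(w)
  expect_equal(res$Q, best$Q, tolerance = 1e-9)
  expect_equal(res$Q, 2 * (3 / 7 - (7 / 14)^2), tolerance = 1e-9)
  # the optimal communities are exactly the two triangles
  expect_equal(nmi(res$membership, c(1, 1, 1, 2, 2, 2)), 1)

  # complete graph: no split beats the single community
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  rk <- modularity_louvain(connectivity_matrix(k5), seed = 1)
  expect_gte(rk$Q, 0)
  expect_equal(rk$Q, 0, tolerance = 1e-12)

  r1 <- modularity_louvain(connectivity_matrix(w), seed = 42)
  r2 <- modularity_louvain(connectivity_matrix(w), seed = 42)
  expect_identical(r1, r2)

  expect_error(modularity_louvain(connectivity_matrix(matrix(0, 3, 3))),
               "edgeless")
})

test_that("rich-club analysis classifies edges by endpoint membership", {
  # 4 nodes, rich = the strongest half
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.8
  w[1, 3] <- w[3, 1] <- 0.3
  w[2, 4] <- w[4, 2] <- 0.2
  w[3, 4] <- w[4, 3] <- 0.1
  rc <- rich_club_analysis(connectivity_matrix(w), 0.5)
  expect_equal(rc$rich_nodes, c(1, 2))
  expect_equal(rc$Rich_s, 0.8)
  expect_equal(rc$Feeder_s, mean(c(0.3, 0.2)))
  expect_equal(rc$Local_s, 0.1)

  # star: only the hub is rich, so every edge is a feeder and Rich_s = 0
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- 1; star[2:4, 1] <- 1
  rcs <- rich_club_analysis(connectivity_matrix(star), 0.25)
  expect_equal(rcs$rich_nodes, 1)
  expect_equal(rcs$Rich_s, 0)
  expect_equal(rcs$Local_s, 0)
  expect_true(all(rcs$edge_classes$class == "feeder"))

  # random graph against endpoint-membership brute force
  w8 <- random_sym_matrix(8, density = 0.6, seed = 13)
  rc8 <- rich_club_analysis(connectivity_matrix(w8), 0.3)
  s <- rowSums(w8)
  rich <- order(-s, 1:8)[seq_len(ceiling(0.3 * 8))]
  sums <- c(rich = 0, feeder = 0, local = 0)
  cnts <- c(rich = 0, feeder = 0, local = 0)
  for (i in 1:7) for (j in (i + 1):8) {
    if (w8[i, j] > 0) {
      nr <- (i %in% rich) + (j %in% rich)
      cls <- c("local", "feeder", "rich")[nr + 1]
      sums[cls] <- sums[cls] + w8[i, j]
      cnts[cls] <- cnts[cls] + 1
    }
  }
  expect_equal(rc8$Rich_s, unname(sums["rich"] / max(cnts["rich"], 1)))
  expect_equal(rc8$Feeder_s, unname(sums["feeder"] / max(cnts["feeder"], 1)))
  expect_equal(rc8$Local_s, unname(sums["local"] / max(cnts["local"], 1)))

  expect_error(rich_club_analysis(connectivity_matrix(w8), 1.2), "rich_fraction")
})

test_that("AUC over densities is the trapezoidal integral", {
  expect_equal(auc_over_densities(c(2, 2), c(0.1, 0.4)), 0.3 * 2)
  expect_equal(auc_over_densities(c(1, 2, 3), c(0.1, 0.2, 0.3)), 0.4)
  set.seed(44)
  grid <- sort(runif(7, 0.05, 0.5))
  vals <- runif(7)
  expect_equal(auc_over_densities(vals, grid), oracle_trapz(grid, vals),
               tolerance = 1e-12)
  expect_error(auc_over_densities(1, 0.3), "at least two")
})

test_that("the feature vector composes the standalone metrics per density", {
  w <- random_sym_matrix(10, density = 0.8, seed = 9)
  cm <- connectivity_matrix(w)
  grid <- threshold_grid(c(0.2, 0.4, 0.6))
  fv <- network_feature_vector(cm, grid, rich_fraction = 0.3, seed = 7)
  per <- sapply(as.numeric(grid), function(d) {
    mt <- threshold_by_density(cm, d)
    pm <- path_based_metrics(mt)
    rc <- rich_club_analysis(mt, 0.3)
    c(Cp = clustering_coefficient(mt), Eg = pm$Eg,
      Eloc = local_efficiency(mt), Lp = pm$Lp,
      Rich_s = rc$Rich_s, Local_s = rc$Local_s, Feeder_s = rc$Feeder_s)
  })
  for (nm in c("Cp", "Eg", "Eloc", "Lp", "Rich_s", "Local_s", "Feeder_s")) {
    key <- if (nm %in% c("Rich_s", "Local_s", "Feeder_s")) nm else paste0("a", nm)
    expect_equal(unname(fv[key]),
                 auc_over_densities(per[nm, ], grid), tolerance = 1e-9)
  }

  fv2 <- network_feature_vector(cm, grid, rich_fraction = 0.3, seed = 7)
  expect_identical(fv, fv2)

  z <- connectivity_matrix(matrix(0, 6, 6))
  warns <- testthat::capture_warnings(fz <- network_feature_vector(z, grid))
  expect_true(any(grepl("modularity", warns)))
  expect_equal(unname(fz[c("aCp", "aEg", "aEloc", "aQ")]), rep(0, 4))
})
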