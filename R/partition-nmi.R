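#' Normalised mutual information between two partitions
#'
#' Similarity of two partitions A1, A2 of the same node set, from the
#' contingency counts N_ij (nodes shared by community i of A1 and
#' community j of A2), the marginal community sizes N_i, N_j and the node
#' count N:
#'
#' \deqn{NMI = \frac{-2 \sum_i \sum_j N_{ij} \log(N_{ij} N / (N_i N_j))}
#'   {\sum_i N_i \log(N_i/N) + \sum_j N_j \log(N_j/N)}}
#'
#' with 0 log 0 taken as 0 and natural logarithms (the ratio form is
#' invariant to the log base). 1 means identical partitions, 0 means
#' independent ones. When both partitions are the single trivial
#' community the ratio degenerates to 0/0 and is defined as 1 (the
#' partitions are identical).
#'
#' @param a1,a2 Integer community-membership vectors over the same nodes.
#' @return NMI value in \[0, 1\] for non-degenerate partitions.
#' @export
nmi <- function(a1, a2) {
  if (length(a1) != length(a2)) stop("partitions are over different node sets")
  n <- length(a1)
  if (n < 2) stop("NMI requires at least two nodes")
  if (anyNA(a1) || anyNA(a2)) stop("partitions must label every node")
  tab <- table(a1, a2)
  nij <- as.matrix(tab)
  ni <- rowSums(nij)
  nj <- colSums(nij)
  xlogx <- function(x, y) ifelse(x > 0, x * log(y), 0)
  num <- -2 * sum(xlogx(nij, ifelse(nij > 0, nij * n / outer(ni, nj), 1)))
  den <- sum(ni * log(ni / n)) + sum(nj * log(nj / n))
  if (den == 0) return(1)  # both trivial single communities: identical
  num / den
}

#' Modular and rich-club partition profile of a connectome
#'
#' The two partitions used to compare a randomised network against the
#' patient and control configurations: the Louvain modular partition and
#' the two-community rich-club partition (rich-club nodes vs the rest),
#' both computed on the matrix thresholded at a reference density.
#'
#' @param m A connectivity matrix.
#' @param density_ref Reference density at which to threshold before
#'   partitioning; by convention the median of the analysis grid.
#' @param rich_fraction Rich-club node fraction.
#' @param seed Seed for the Louvain restarts.
#' @param restarts Louvain restarts.
#' @return List with integer membership vectors `modular` and `richclub`.
#' @export
partition_profile <- function(m, density_ref = 0.225, rich_fraction = 0.15,
                              seed = 1L, restarts = 20L) {
  mt <- threshold_by_density(m, density_ref)
  w <- as.matrix(mt)
  n <- nrow(w)
  if (sum(w[upper.tri(w)] > 0) == 0) {
    modular <- rep(1L, n)
  } else {
    modular <- modularity_louvain(mt, seed = seed, restarts = restarts)$membership
  }
  rc <- rich_club_analysis(mt, rich_fraction)
  richclub <- ifelse(seq_len(n) %in% rc$rich_nodes, 1L, 2L)
  list(modular = modular, richclub = .relabel_partition(richclub))
}

#' NMI scores of a candidate profile against one reference profile
#'
#' @param candidate,reference Partition profiles from [partition_profile()].
#' @return List with `nmi_modular`, `nmi_richclub` and `combined`
#'   (their unweighted mean).
#' @export
nmi_scores <- function(candidate, reference) {
  s_mod <- nmi(candidate$modular, reference$modular)
  s_rc <- nmi(candidate$richclub, reference$richclub)
  list(nmi_modular = s_mod, nmi_richclub = s_rc,
       combined = (s_mod + s_rc) / 2)
}

#' Score a candidate profile against patient and control references
#'
#' @param candidate Profile of the candidate network.
#' @param lod_profile,hc_profile Profiles of the patient-group and
#'   control-group configurations.
#' @return List with elements `lod` and `hc`, each an [nmi_scores()] result.
#' @export
score_against_references <- function(candidate, lod_profile, hc_profile) {
  list(lod = nmi_scores(candidate, lod_profile),
       hc = nmi_scores(candidate, hc_profile))
}

#' Write or read a partition as two-column text
#'
#' @param profile A partition profile (list of membership vectors).
#' @param path Output path; one block per partition is not used — each
#'   membership vector is stored as `node,label` rows with a `partition`
#'   column.
#' @return `path` invisibly for write; a profile list for read.
#' @export
write_partition_profile <- function(profile, path) {
  df <- do.call(rbind, lapply(names(profile), function(p) {
    data.frame(partition = p, node = seq_along(profile[[p]]),
               label = profile[[p]])
  }))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition_profile
#' @export
read_partition_profile <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  out <- lapply(split(df, df$partition), function(b) {
    as.integer(b$label[order(b$node)])
  })
  out[unique(df$partition)]
}
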