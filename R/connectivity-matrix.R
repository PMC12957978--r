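#' Construct a connectivity matrix
#'
#' A connectivity matrix is a square, symmetric, nonnegative weighted
#' adjacency matrix over labelled brain regions, with a zero diagonal.
#' Weights are dimensionless connection probabilities from probabilistic
#' tractography (or any nonnegative edge weight).
#'
#' @param weights Square numeric matrix of nonnegative weights.
#' @param node_labels Character vector of unique region names, one per node.
#'   Defaults to existing dimnames, or `"R1"..."Rn"`.
#' @return A `connectivity_matrix`: a numeric matrix with node labels as
#'   dimnames and class `"connectivity_matrix"`.
#' @export
connectivity_matrix <- function(weights, node_labels = NULL) {
  weights <- as.matrix(weights)
  if (is.null(node_labels)) {
    node_labels <- rownames(weights)
    if (is.null(node_labels)) node_labels <- paste0("R", seq_len(nrow(weights)))
  }
  dimnames(weights) <- list(node_labels, node_labels)
  v <- validate_matrix(weights)
  if (length(v) > 0) {
    stop("invalid connectivity matrix: ",
         paste(vapply(v, `[[`, "", "message"), collapse = "; "))
  }
  class(weights) <- c("connectivity_matrix", class(matrix()))
  weights
}

#' Validate connectivity-matrix invariants
#'
#' Checks a square numeric matrix against the connectivity-matrix contract:
#' symmetry, zero diagonal, nonnegative finite entries, unique node labels.
#' The validator never throws; it returns a (possibly empty) list of
#' machine-readable violations.
#'
#' @param m A square numeric matrix.
#' @param tol Absolute symmetry tolerance (default 1e-9).
#' @return A list of violations; each has fields `rule`, `indices`
#'   (matrix of offending (i, j) pairs or NULL) and `message`.
#'   An empty list means all invariants hold.
#' @export
validate_matrix <- function(m, tol = 1e-9) {
  violations <- list()
  add <- function(rule, indices, message) {
    violations[[length(violations) + 1L]] <<-
      list(rule = rule, indices = indices, message = message)
  }
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) {
    add("square", NULL, sprintf("matrix is %d x %d, not square", nrow(m), ncol(m)))
    return(violations)
  }
  if (!is.numeric(m)) {
    add("numeric", NULL, "matrix is not numeric")
    return(violations)
  }
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0) add("finite", bad, sprintf("%d non-finite entries", nrow(bad)))
  neg <- which(is.finite(m) & m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    add("nonnegative", neg,
        sprintf("negative entry at (%d,%d)%s", neg[1, 1], neg[1, 2],
                if (nrow(neg) > 1) sprintf(" and %d more", nrow(neg) - 1) else ""))
  }
  asym <- which(abs(m - t(m)) > tol, arr.ind = TRUE)
  if (nrow(asym) > 0) {
    add("symmetric", asym,
        sprintf("asymmetric at (%d,%d)%s", asym[1, 1], asym[1, 2],
                if (nrow(asym) > 1) sprintf(" and %d more", nrow(asym) - 1) else ""))
  }
  dg <- which(is.finite(diag(m)) & diag(m) != 0)
  if (length(dg) > 0) {
    add("zero_diagonal", cbind(dg, dg),
        sprintf("nonzero diagonal at %d node(s)", length(dg)))
  }
  labs <- rownames(m)
  if (!is.null(labs) && anyDuplicated(labs)) {
    add("unique_labels", NULL, "duplicated node labels")
  }
  violations
}

#' Symmetrise a directed connectivity matrix
#'
#' Probabilistic tractography yields two directed connection probabilities
#' per region pair (seed-to-target and target-to-seed). The undirected
#' connection weight is their arithmetic mean; the diagonal is forced to 0.
#'
#' @param directed Square nonnegative numeric matrix.
#' @param node_labels Optional node labels.
#' @return A [connectivity_matrix()].
#' @export
symmetrise_connectivity <- function(directed, node_labels = NULL) {
  directed <- as.matrix(directed)
  if (nrow(directed) != ncol(directed)) stop("input matrix must be square")
  if (!is.numeric(directed) || any(!is.finite(directed))) {
    stop("input matrix must be finite numeric")
  }
  if (any(directed < 0)) stop("input matrix must be nonnegative")
  w <- (directed + t(directed)) / 2
  diag(w) <- 0
  connectivity_matrix(w, node_labels)
}

#' Build a density grid for thresholded network analysis
#'
#' @param densities Strictly increasing numeric vector of connection
#'   densities in (0, 1]; each is the fraction of the strongest possible
#'   edges retained. Default 0.05 to 0.40 in steps of 0.01.
#' @return A numeric vector with class `"threshold_grid"`.
#' @export
threshold_grid <- function(densities = seq(0.05, 0.40, by = 0.01)) {
  densities <- as.numeric(densities)
  if (length(densities) == 0) stop("density grid must be nonempty")
  if (any(!is.finite(densities)) || any(densities <= 0) || any(densities > 1)) {
    stop("densities must lie in (0, 1]")
  }
  if (any(diff(densities) <= 0)) stop("densities must be strictly increasing")
  structure(densities, class = "threshold_grid")
}

# Upper-triangle edge table ordered by descending weight with lexicographic
# (i, j) tie-break; shared by thresholding and edge selection.
.edge_order <- function(w) {
  n <- nrow(w)
  ut <- which(upper.tri(w))
  i <- ((ut - 1L) %% n) + 1L
  j <- ((ut - 1L) %/% n) + 1L
  ord <- order(-w[ut], i, j)
  list(idx = ut[ord], i = i[ord], j = j[ord], weight = w[ut][ord])
}

#' Threshold a connectivity matrix at a target connection density
#'
#' Retains the `ceiling(density * n(n-1)/2)` strongest undirected edges and
#' zeroes the rest; retained weights are unchanged. Ties at the cutoff
#' weight are broken by ascending (i, j) lexicographic edge index, so the
#' result is deterministic.
#'
#' @param m A connectivity matrix.
#' @param density Target density in (0, 1].
#' @return The thresholded [connectivity_matrix()].
#' @export
threshold_by_density <- function(m, density) {
  if (length(density) != 1 || !is.finite(density) || density <= 0 || density > 1) {
    stop("density must be a single value in (0, 1]")
  }
  w <- unclass(as.matrix(m))
  n <- nrow(w)
  e_max <- n * (n - 1) / 2
  keep <- ceiling(density * e_max)
  eo <- .edge_order(w)
  drop_idx <- eo$idx[-seq_len(keep)]
  if (length(drop_idx) > 0) {
    w[drop_idx] <- 0
    w <- pmin(w, t(w))  # mirror zeros into the lower triangle
  }
  connectivity_matrix(w, rownames(w))
}

#' Read a connectivity matrix from a delimited text file
#'
#' Expects a first row of node labels followed by an n x n numeric body.
#' Comma and tab delimiters are auto-detected. Symmetry is enforced at an
#' absolute tolerance of 1e-9; tiny round-off asymmetry below the tolerance
#' is averaged away.
#'
#' @param path File path.
#' @return A [connectivity_matrix()].
#' @export
read_connectivity_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  labs <- strsplit(first, sep, fixed = TRUE)[[1]]
  labs <- trimws(labs)
  lines <- readLines(path)[-1L]
  lines <- lines[nzchar(trimws(lines))]
  n <- length(labs)
  if (length(lines) != n) {
    stop(sprintf("expected %d data rows for %d labels, found %d",
                 n, n, length(lines)))
  }
  w <- matrix(NA_real_, n, n)
  for (r in seq_len(n)) {
    cells <- strsplit(lines[r], sep, fixed = TRUE)[[1]]
    if (length(cells) != n) {
      stop(sprintf("ragged row %d: %d fields, expected %d", r, length(cells), n))
    }
    vals <- suppressWarnings(as.numeric(cells))
    if (any(is.na(vals))) {
      bad <- which(is.na(vals))[1]
      stop(sprintf("non-numeric cell at row %d, column %d", r, bad))
    }
    w[r, ] <- vals
  }
  asym <- abs(w - t(w))
  if (any(asym > 1e-9)) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("asymmetric matrix: (%d,%d) = %g but (%d,%d) = %g",
                 ij[1], ij[2], w[ij[1], ij[2]], ij[2], ij[1], w[ij[2], ij[1]]))
  }
  w <- (w + t(w)) / 2
  diag(w) <- 0
  connectivity_matrix(w, labs)
}

#' Write a connectivity matrix to a delimited text file
#'
#' Writes the node-label header followed by the numeric body at 15
#' significant digits, so that write-then-read round-trips to at least
#' 12 significant digits.
#'
#' @param m A connectivity matrix.
#' @param path Output file path.
#' @param sep Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_connectivity_matrix <- function(m, path, sep = ",") {
  w <- as.matrix(m)
  labs <- rownames(w)
  body <- apply(w, 1, function(row) {
    paste(formatC(row, digits = 15, format = "g"), collapse = sep)
  })
  writeLines(c(paste(labs, collapse = sep), body), path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a delimited table with columns `subject_id`, `group` and
#' `matrix_path` describing one connectivity-matrix file per subject.
#'
#' @param path Manifest file path.
#' @return A data frame with the three manifest columns.
#' @export
read_cohort_manifest <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "matrix_path")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  df[need]
}

#' Write a cohort manifest
#'
#' @param manifest Data frame with columns `subject_id`, `group`, `matrix_path`.
#' @param path Output path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_cohort_manifest <- function(manifest, path, sep = "\t") {
  utils::write.table(manifest, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
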