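#' Subgraph of enhanced inter-myocyte distances
#'
#' Keeps exactly the edges whose septum width exceeds the reference
#' enhancement threshold (`mu + 2 sd`); the node set is unchanged.
#' Myocytes separated by larger-than-normal endomysial fibrosis thus
#' become connected, and spatially contiguous enhancement shows up as
#' cliques of this subgraph.
#'
#' @param graph A measured [myocyte_graph].
#' @param ref A [reference_stats()].
#' @return A `myocyte_graph` restricted to the enhanced edges.
#' @export
enhanced_subgraph <- function(graph, ref) {
  stopifnot(inherits(graph, "myocyte_graph"))
  if (!"septum_width_um" %in% names(graph$edges)) {
    stop("graph has unmeasured edges; run measure_septa() first", call. = FALSE)
  }
  thr <- enhancement_threshold(ref)
  out <- graph
  out$edges <- graph$edges[graph$edges$septum_width_um > thr, , drop = FALSE]
  out$edges$enhanced <- rep(TRUE, nrow(out$edges))
  out
}

#' Average local clustering coefficient
#'
#' Per node with degree at least 2, the local clustering coefficient is
#' `2 T / (deg (deg - 1))` with `T` the number of triangles through the
#' node; nodes of degree below 2 contribute 0. The average is taken
#' over all nodes of the image.
#'
#' @param graph A [myocyte_graph] (typically from [enhanced_subgraph()]),
#'   or a two-column edge matrix.
#' @param n_nodes Number of nodes when `graph` is an edge matrix
#'   (node ids must then be integers in `1..n_nodes`).
#' @return The average clustering coefficient, in `[0, 1]`.
#' @export
average_clustering <- function(graph, n_nodes = NULL) {
  if (inherits(graph, "myocyte_graph")) {
    ids <- graph$nodes$myocyte_id
    if (length(ids) == 0) stop("empty node set", call. = FALSE)
    em <- cbind(match(graph$edges$id_a, ids), match(graph$edges$id_b, ids))
    n <- length(ids)
  } else {
    em <- as.matrix(graph)
    n <- n_nodes %||% if (nrow(em)) max(em) else 0
    if (n == 0) stop("empty node set", call. = FALSE)
  }
  mean(local_clustering(em, n))
}

# per-node local clustering coefficients of a simple undirected graph
local_clustering <- function(edge_matrix, n) {
  if (nrow(edge_matrix) == 0) return(numeric(n))
  A <- Matrix::sparseMatrix(
    i = c(edge_matrix[, 1], edge_matrix[, 2]),
    j = c(edge_matrix[, 2], edge_matrix[, 1]),
    x = 1, dims = c(n, n)
  )
  deg <- Matrix::rowSums(A)
  tri <- Matrix::rowSums((A %*% A) * A) / 2
  cc <- numeric(n)
  ok <- deg >= 2
  cc[ok] <- 2 * tri[ok] / (deg[ok] * (deg[ok] - 1))
  cc
}

#' Permutation test for spatial clustering of enhanced septa
#'
#' Tests whether enhanced inter-myocyte distances cluster spatially.
#' The observed statistic is the average local clustering coefficient
#' of the enhanced subgraph. The null holds the tissue geometry (the
#' neighbour graph) fixed and shuffles the multiset of measured septum
#' widths uniformly over its edges; each permutation re-derives the
#' enhanced subgraph and its average clustering coefficient. The mean
#' over permutations is the expected clustering coefficient, and the
#' p-score is the proportion of permuted coefficients strictly smaller
#' than the observed one (large p-score = more clustering than expected
#' by chance).
#'
#' @param graph A measured [myocyte_graph].
#' @param ref A [reference_stats()].
#' @param n_permutations Number of permutations.
#' @param seed Integer seed making the test reproducible.
#' @return An object of class `clustering_result` with fields
#'   `observed_cc`, `expected_cc`, `p_score`, `relative_deviation`,
#'   `n_permutations`, `seed`, `n_enhanced`, `degenerate` and the
#'   vector `permuted_cc`.
#' @export
permutation_test <- function(graph, ref, n_permutations = 1000L, seed = 1L) {
  stopifnot(inherits(graph, "myocyte_graph"), n_permutations >= 1)
  if (!"septum_width_um" %in% names(graph$edges)) {
    stop("graph has unmeasured edges; run measure_septa() first", call. = FALSE)
  }
  ids <- graph$nodes$myocyte_id
  n <- length(ids)
  em <- cbind(match(graph$edges$id_a, ids), match(graph$edges$id_b, ids))
  w <- graph$edges$septum_width_um
  thr <- enhancement_threshold(ref)
  obs_on <- w > thr
  k <- sum(obs_on)

  if (k == 0) {
    return(structure(list(observed_cc = 0, expected_cc = 0, p_score = NA_real_,
                          relative_deviation = NA_real_,
                          n_permutations = as.integer(n_permutations),
                          seed = as.integer(seed), n_enhanced = 0L,
                          degenerate = TRUE, permuted_cc = numeric(0)),
                     class = "clustering_result"))
  }

  E <- nrow(em)
  tri <- enumerate_triangles(em, n)

  cc_of <- function(on_mat) {
    # on_mat: E x P logical; returns average clustering per column
    deg <- edge_node_incidence(em, n) %*% on_mat           # n x P
    if (nrow(tri$edges) > 0) {
      present <- on_mat[tri$edges[, 1], , drop = FALSE] &
        on_mat[tri$edges[, 2], , drop = FALSE] &
        on_mat[tri$edges[, 3], , drop = FALSE]
      tcount <- tri$node_incidence %*% (present + 0)       # n x P
    } else {
      tcount <- matrix(0, n, ncol(on_mat))
    }
    deg <- as.matrix(deg)
    tcount <- as.matrix(tcount)
    denom <- deg * (deg - 1)
    cc <- ifelse(denom > 0, 2 * tcount / denom, 0)
    colMeans(cc)
  }

  observed_cc <- cc_of(matrix(obs_on, ncol = 1))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  perm_on <- matrix(FALSE, E, n_permutations)
  for (j in seq_len(n_permutations)) {
    perm_on[cbind(sample.int(E, k), j)] <- TRUE
  }
  permuted_cc <- cc_of(perm_on)

  expected_cc <- mean(permuted_cc)
  structure(list(
    observed_cc = observed_cc,
    expected_cc = expected_cc,
    p_score = mean(permuted_cc < observed_cc),
    relative_deviation = if (expected_cc > 0) (observed_cc - expected_cc) / expected_cc else NA_real_,
    n_permutations = as.integer(n_permutations),
    seed = as.integer(seed),
    n_enhanced = as.integer(k),
    degenerate = FALSE,
    permuted_cc = permuted_cc
  ), class = "clustering_result")
}

# all triangles of a simple graph given as 1-based edge matrix;
# returns per-triangle edge indices and a node x triangle incidence
enumerate_triangles <- function(em, n) {
  E <- nrow(em)
  eid <- Matrix::sparseMatrix(
    i = c(em[, 1], em[, 2]), j = c(em[, 2], em[, 1]),
    x = c(seq_len(E), seq_len(E)), dims = c(n, n)
  )
  adj <- vector("list", n)
  for (e in seq_len(E)) {
    adj[[em[e, 1]]] <- c(adj[[em[e, 1]]], em[e, 2])
    adj[[em[e, 2]]] <- c(adj[[em[e, 2]]], em[e, 1])
  }
  tri_nodes <- list(); tri_edges <- list(); m <- 0L
  for (e in seq_len(E)) {
    a <- min(em[e, ]); b <- max(em[e, ])
    common <- intersect(adj[[a]], adj[[b]])
    common <- common[common > b]
    for (cc in common) {
      m <- m + 1L
      tri_nodes[[m]] <- c(a, b, cc)
      tri_edges[[m]] <- c(eid[a, b], eid[a, cc], eid[b, cc])
    }
  }
  if (m == 0) {
    return(list(edges = matrix(integer(), 0, 3),
                node_incidence = Matrix::sparseMatrix(i = integer(), j = integer(),
                                                      dims = c(n, 0))))
  }
  nodes_m <- do.call(rbind, tri_nodes)
  list(
    edges = do.call(rbind, tri_edges),
    node_incidence = Matrix::sparseMatrix(
      i = as.vector(nodes_m), j = rep(seq_len(m), times = 3), x = 1,
      dims = c(n, m)
    )
  )
}

edge_node_incidence <- function(em, n) {
  Matrix::sparseMatrix(
    i = c(em[, 1], em[, 2]), j = c(seq_len(nrow(em)), seq_len(nrow(em))),
    x = 1, dims = c(n, nrow(em))
  )
}

#' @export
print.clustering_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<clustering_result> degenerate: no enhanced edges\n")
  } else {
    cat(sprintf(
      "<clustering_result> observed CC %.4f, expected %.4f (%+.1f%%), p-score %.3f (%d permutations)\n",
      x$observed_cc, x$expected_cc, 100 * x$relative_deviation, x$p_score, x$n_permutations
    ))
  }
  invisible(x)
}

#' @export
tidy.clustering_result <- function(x, ...) {
  tibble::tibble(permutation = seq_along(x$permuted_cc), cc = x$permuted_cc)
}

#' @export
glance.clustering_result <- function(x, ...) {
  tibble::tibble(
    observed_cc = x$observed_cc, expected_cc = x$expected_cc,
    relative_deviation = x$relative_deviation, p_score = x$p_score,
    n_enhanced = x$n_enhanced, n_permutations = x$n_permutations,
    seed = x$seed, degenerate = x$degenerate
  )
}

#' @export
autoplot.clustering_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cc)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_cc, colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "average clustering coefficient (permutations)", y = "count",
      title = sprintf("observed CC %.3f vs expected %.3f (p-score %.3f)",
                      object$observed_cc, object$expected_cc, object$p_score)
    ) +
    ggplot2::theme_minimal()
}
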