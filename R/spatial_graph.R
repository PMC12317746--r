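# Exact k-nearest-neighbour search, blockwise to bound memory, with a
# deterministic tie-break by (distance, point index).
knn_index <- function(x, k, block = 512L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k >= n) stop("k must be below the number of points")
  sq <- rowSums(x * x)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- sq[idx] - 2 * tcrossprod(x[idx, , drop = FALSE], x) +
      rep(sq, each = length(idx))
    d2 <- pmax(d2, 0)
    for (r in seq_along(idx)) {
      dv <- d2[r, ]
      dv[idx[r]] <- Inf
      ord <- order(dv, seq_len(n))
      out[idx[r], ] <- ord[seq_len(k)]
    }
  }
  out
}

#' Build a per-sample spatial kNN graph
#'
#' Connects each unit to its `k` nearest neighbours under Euclidean
#' distance on the spatial coordinates, then symmetrizes by union: an
#' undirected edge exists if either endpoint lists the other, so every
#' node keeps its own k neighbours. Ties are broken deterministically by
#' (distance, unit index).
#'
#' @param coords Numeric matrix of 2D positions, one row per unit.
#' @param k Neighbourhood size (default 6).
#' @param sample_id Optional sample identifier carried on the graph.
#' @return List of class `spatial_graph`: `edges` (m x 2 integer matrix
#'   with `u < v`), `knn` (n x k neighbour index matrix), `coords`, `k`,
#'   `n`, `sample_id`, and `weights` (`NULL` until assigned).
#' @export
build_spatial_knn <- function(coords, k = 6L, sample_id = "") {
  coords <- as.matrix(coords)
  if (any(!is.finite(coords))) stop("coords has non-finite entries")
  if (k >= nrow(coords)) stop("k must be below the number of units")
  nn <- knn_index(coords, k)
  u <- rep(seq_len(nrow(coords)), k)
  v <- as.integer(nn)
  e <- cbind(pmin(u, v), pmax(u, v))
  e <- unique(e)
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  structure(list(sample_id = sample_id, n = nrow(coords), coords = coords,
                 edges = e, weights = NULL, k = as.integer(k), knn = nn),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat("spatial_graph: ", x$n, " nodes, ", nrow(x$edges), " edges (k = ",
      x$k, ")\n", sep = "")
  invisible(x)
}

# Pearson correlation between rows u and v of Y for many (u, v) pairs at
# once; rows with zero variance yield weight 0 (degenerate, warned).
pearson_rows <- function(Y, u, v) {
  N <- ncol(Y)
  z <- Y - rowMeans(Y)
  s <- sqrt(rowSums(z * z) / (N - 1L))
  w <- rowSums(z[u, , drop = FALSE] * z[v, , drop = FALSE]) /
    ((N - 1L) * s[u] * s[v])
  bad <- !is.finite(w)
  if (any(bad)) {
    warning(sum(bad), " edge weight(s) involve a constant PC row; set to 0")
    w[bad] <- 0
  }
  pmin(pmax(w, -1), 1)
}

#' Pairwise Pearson edge weight
#'
#' Correlation across the PC components of two units' embedding rows, the
#' default edge weight of the spatial graph.
#'
#' @param Y Embedding matrix (units x PCs) or a `reduced_matrix`.
#' @param u,v Row indices.
#' @return A number in `[-1, 1]`; 0 (with a warning) if a row is constant.
#' @export
edge_weight_pearson <- function(Y, u, v) {
  if (inherits(Y, "reduced_matrix")) Y <- Y$values
  pearson_rows(Y, u, v)[1L]
}

#' Shared-nearest-neighbour edge weight
#'
#' The fraction of shared members between the two units'
#' `k_snn`-nearest-neighbour sets in embedding space, in `[0, 1]`. Each
#' set contains the unit itself plus its `k_snn - 1` nearest others (the
#' usual self-inclusive SNN convention), so two units with identical
#' embedding rows score exactly 1. Useful for sparse, zero-inflated data
#' where correlations are unstable; normalized by `k_snn` so the same
#' pruning threshold scale applies as for correlations.
#'
#' @param Y Embedding matrix (units x PCs) or a `reduced_matrix`.
#' @param u,v Row indices.
#' @param k_snn Neighbourhood size (default 20; must be below the number
#'   of units).
#' @param knn Optional precomputed self-inclusive neighbour matrix
#'   (n x k_snn, first column the point index itself).
#' @return `|kNN(u) intersect kNN(v)| / k_snn`.
#' @export
edge_weight_snn <- function(Y, u, v, k_snn = 20L, knn = NULL) {
  if (inherits(Y, "reduced_matrix")) Y <- Y$values
  if (is.null(knn)) knn <- snn_sets(Y, k_snn)
  length(intersect(knn[u, ], knn[v, ])) / k_snn
}

snn_sets <- function(Y, k_snn) {
  if (k_snn < 2L) return(matrix(seq_len(nrow(Y)), ncol = 1L))
  cbind(seq_len(nrow(Y)), knn_index(Y, k_snn - 1L))
}

#' Attach expression-based weights to a spatial graph
#'
#' @param graph A `spatial_graph`.
#' @param Y Embedding of the same sample (`reduced_matrix` or matrix).
#' @param mode `"pearson"` or `"snn"`.
#' @param k_snn SNN neighbourhood size (default 20).
#' @return The graph with `weights` filled for every edge.
#' @export
weight_edges <- function(graph, Y, mode = c("pearson", "snn"), k_snn = 20L) {
  mode <- match.arg(mode)
  if (inherits(Y, "reduced_matrix")) Y <- Y$values
  if (nrow(Y) != graph$n) stop("embedding rows do not match graph nodes")
  e <- graph$edges
  if (mode == "pearson") {
    graph$weights <- pearson_rows(Y, e[, 1L], e[, 2L])
  } else {
    knn <- snn_sets(Y, k_snn)
    graph$weights <- vapply(seq_len(nrow(e)), function(i)
      edge_weight_snn(Y, e[i, 1L], e[i, 2L], k_snn, knn), 0)
  }
  graph$weight_mode <- mode
  graph
}

#' Smoothed edge weights
#'
#' Replaces each edge's pairwise weight by the correlation of
#' neighbourhood-averaged embeddings, damping spot/cell-level noise when
#' deciding which edges cross a domain boundary. For an edge `(u, v)` with
#' spatially `q`-nearest neighbour sets `Vu`, `Vv`, the shared neighbours
#' `Vu intersect Vv` are excluded from both sides, each endpoint is added
#' to its own side, and the weight is the Pearson correlation between the
#' component-wise means of `Y` over the two sides. With `q = 0` this
#' reduces exactly to the pairwise Pearson weight.
#'
#' @param graph A `spatial_graph`.
#' @param Y Embedding (`reduced_matrix` or matrix) aligned with the graph.
#' @param q Spatial neighbourhood size (default `graph$k`).
#' @return Numeric vector of weights, one per edge of `graph`.
#' @export
smoothed_edge_weights <- function(graph, Y, q = graph$k) {
  if (inherits(Y, "reduced_matrix")) Y <- Y$values
  if (nrow(Y) != graph$n) stop("embedding rows do not match graph nodes")
  e <- graph$edges
  if (q == 0L) return(pearson_rows(Y, e[, 1L], e[, 2L]))
  nbr <- if (q <= graph$k) graph$knn[, seq_len(q), drop = FALSE]
         else knn_index(graph$coords, q)
  w <- numeric(nrow(e))
  n_bad <- 0L
  for (i in seq_len(nrow(e))) {
    u <- e[i, 1L]; v <- e[i, 2L]
    Vu <- nbr[u, ]; Vv <- nbr[v, ]
    su <- c(Vu[!(Vu %in% Vv)], u)
    sv <- c(Vv[!(Vv %in% Vu)], v)
    mu <- colMeans(Y[su, , drop = FALSE])
    mv <- colMeans(Y[sv, , drop = FALSE])
    wi <- suppressWarnings(stats::cor(mu, mv))
    if (!is.finite(wi)) { wi <- 0; n_bad <- n_bad + 1L }
    w[i] <- wi
  }
  if (n_bad > 0L)
    warning(n_bad, " smoothed weight(s) had a constant mean vector; set to 0")
  w
}

#' Prune low-weight edges
#'
#' Retains exactly the edges whose weight is at or above `threshold`
#' (weights strictly below are pruned); nodes are never removed, so pruning
#' may isolate nodes. A pruning report (number removed and a 20-bin weight
#' histogram, useful for choosing the threshold from the weight
#' distribution) is attached as attribute `"prune_report"`.
#'
#' @param graph A `spatial_graph` with `weights` set (or pass `weights`).
#' @param threshold Minimum retained weight (default 0.6).
#' @param weights Optional weight vector overriding `graph$weights` (e.g.
#'   from [smoothed_edge_weights()]).
#' @return The pruned `spatial_graph`.
#' @export
prune_edges <- function(graph, threshold = 0.6, weights = graph$weights) {
  if (is.null(weights)) stop("graph has no weights; call weight_edges() first")
  if (length(weights) != nrow(graph$edges))
    stop("one weight per edge required")
  keep <- weights >= threshold
  report <- list(n_removed = sum(!keep), n_kept = sum(keep),
                 threshold = threshold,
                 histogram = graphics::hist(weights, breaks = 20L,
                                            plot = FALSE))
  graph$edges <- graph$edges[keep, , drop = FALSE]
  graph$weights <- weights[keep]
  attr(graph, "prune_report") <- report
  graph
}

#' Export a graph as an edge-list CSV
#'
#' @param graph A weighted `spatial_graph`.
#' @param path Output CSV with columns `sample_id,u,v,weight`.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  df <- data.frame(sample_id = graph$sample_id,
                   u = graph$edges[, 1L], v = graph$edges[, 2L],
                   weight = if (is.null(graph$weights)) NA_real_
                            else as.double(graph$weights))
  write_csv_exact(df, path)
  invisible(path)
}
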