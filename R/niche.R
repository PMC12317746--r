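#' Louvain partition of a spatial graph
#'
#' Community detection by modularity optimization (Louvain) with a
#' resolution parameter; at high resolution (~10) on a pruned spatial graph
#' this yields many small, spatially coherent niches. Modularity assumes
#' non-negative weights, so any negative retained weight (possible only
#' with low custom pruning thresholds on correlation weights) is clamped to
#' 0 for community detection, with a warning. Isolated nodes become
#' singleton communities.
#'
#' @param graph A `spatial_graph` (weights optional; missing weights count
#'   as 1).
#' @param resolution Louvain resolution parameter (default 10).
#' @param seed Integer seed making the partition deterministic.
#' @return Integer vector of community labels, one per node.
#' @export
louvain_partition <- function(graph, resolution = 10, seed = 1L) {
  if (graph$n < 1L) stop("empty graph")
  if (nrow(graph$edges) == 0L) return(seq_len(graph$n))
  w <- graph$weights
  if (is.null(w)) w <- rep(1, nrow(graph$edges))
  if (any(w < 0)) {
    warning(sum(w < 0), " negative edge weight(s) clamped to 0 for Louvain")
    w <- pmax(w, 0)
  }
  g <- igraph::make_empty_graph(graph$n, directed = FALSE)
  g <- igraph::add_edges(g, t(graph$edges))
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = w, resolution = resolution)
  as.integer(igraph::membership(cl))
}

#' Merge undersized niches into their spatial surroundings
#'
#' Iteratively dissolves every niche smaller than `min_size`: each member
#' unit is reassigned to the modal niche label among its spatial-graph
#' neighbours (co-members of the dissolving niche do not vote; ties are
#' broken toward the larger niche, then the smaller label id), with all of
#' a niche's reassignments applied simultaneously. Undersized niches are
#' processed smallest first and the sweep repeats until no niche is
#' undersized or no reassignment is possible. Units with no outside
#' neighbours (isolated undersized components) keep their label; such
#' niche ids are returned in the `"unmergeable"` attribute.
#'
#' @param labels Integer niche labels, one per graph node.
#' @param graph The `spatial_graph` the labels were computed on (typically
#'   the pruned graph).
#' @param min_size Minimum niche size (default 5).
#' @return Relabelled integer vector; never more distinct labels than the
#'   input.
#' @export
merge_small_niches <- function(labels, graph, min_size = 5L) {
  labels <- as.integer(labels)
  n <- graph$n
  if (length(labels) != n) stop("one label per node required")
  adj <- vector("list", n)
  e <- graph$edges
  if (nrow(e) > 0L) {
    both <- rbind(e, e[, 2:1, drop = FALSE])
    sp <- split(both[, 2L], both[, 1L])
    adj[as.integer(names(sp))] <- sp
  }
  repeat {
    sz <- table(labels)
    small <- as.integer(names(sz)[sz < min_size])
    if (length(small) == 0L) break
    ord <- small[order(sz[as.character(small)], small)]
    changed <- FALSE
    for (nid in ord) {
      members <- which(labels == nid)
      if (length(members) == 0L || length(members) >= min_size) next
      cur_sz <- table(labels)
      prop <- labels[members]
      for (j in seq_along(members)) {
        nb <- adj[[members[j]]]
        cand <- labels[nb]
        cand <- cand[cand != nid]
        if (length(cand) == 0L) next
        tab <- table(cand)
        ids <- as.integer(names(tab))
        best <- ids[order(-as.integer(tab),
                          -as.integer(cur_sz[as.character(ids)]), ids)][1L]
        prop[j] <- best
      }
      if (any(prop != labels[members])) changed <- TRUE
      labels[members] <- prop
    }
    if (!changed) break
  }
  sz <- table(labels)
  stuck <- as.integer(names(sz)[sz < min_size])
  attr(labels, "unmergeable") <- stuck
  labels
}

#' Pseudobulk counts per niche
#'
#' Aggregates a sample into its niche partition: per-niche gene-wise sums
#' of raw counts (conserving totals exactly), niche sizes and spatial
#' centroids. The niches act as anchor points, shrinking thousands of
#' units to hundreds of profiles for cross-sample integration.
#'
#' @param sample The source [srt_sample()].
#' @param labels Final (post-merge) niche labels over the retained units.
#' @param retained Row indices of `sample` the labels refer to (default all
#'   rows).
#' @param aggregate `"sum"` (default) or `"mean"` per-niche aggregation.
#' @return List of class `niche_partition`: `sample_id`, `niche_of` (named
#'   by unit id), `niche_ids`, `pseudobulk` (niches x genes), `sizes`,
#'   `centroids`, `gene_ids`, `retained`.
#' @export
pseudobulk_niches <- function(sample, labels, retained = seq_len(nrow(sample$counts)),
                              aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  labels <- as.integer(labels)
  if (length(labels) != length(retained))
    stop("one label per retained unit required")
  counts <- sample$counts[retained, , drop = FALSE]
  coords <- sample$coords[retained, , drop = FALSE]
  pb <- rowsum(counts, labels)
  sizes <- as.integer(table(labels))
  niche_ids <- sort(unique(labels))
  if (aggregate == "mean") pb <- pb / sizes
  centroids <- rowsum(coords, labels) / sizes
  structure(list(sample_id = sample$sample_id,
                 niche_of = stats::setNames(labels,
                                            sample$unit_ids[retained]),
                 niche_ids = niche_ids, pseudobulk = pb,
                 sizes = stats::setNames(sizes, niche_ids),
                 centroids = centroids, gene_ids = sample$gene_ids,
                 retained = retained),
            class = "niche_partition")
}

#' @export
print.niche_partition <- function(x, ...) {
  cat("niche_partition '", x$sample_id, "': ", length(x$niche_ids),
      " niches over ", length(x$niche_of), " units\n", sep = "")
  invisible(x)
}

#' Stage 1: reduce one sample to pseudobulked niches
#'
#' Runs the full per-sample chain: dimensionality reduction
#' ([reduce_dims()]), spatial kNN graph ([build_spatial_knn()]), edge
#' weighting (pairwise [weight_edges()] for fixed pruning, or
#' [smoothed_edge_weights()] -- the default -- which is correlation-based
#' by construction), pruning ([prune_edges()]), high-resolution Louvain
#' ([louvain_partition()]), small-niche merging ([merge_small_niches()])
#' and pseudobulking ([pseudobulk_niches()]). Samples are fully
#' independent at this stage, so stage 1 parallelizes across samples; the
#' Louvain seed is set per sample from `config$seed` alone, so results do
#' not depend on worker count or processing order, and identical samples
#' yield identical partitions.
#'
#' @param sample An [srt_sample()].
#' @param config A [run_config()].
#' @return A `niche_partition` with a `report` element (niche/edge counts,
#'   seed, config echo).
#' @export
run_stage1 <- function(sample, config = run_config()) {
  validate_srt_sample(sample)
  seed <- config$seed
  res <- tryCatch({
    red <- reduce_dims(sample, config)
    g <- build_spatial_knn(sample$coords[red$retained, , drop = FALSE],
                           config$k_spatial, sample$sample_id)
    w <- if (config$prune_mode == "smoothed")
      smoothed_edge_weights(g, red, config$q_smooth)
    else weight_edges(g, red, config$weight_mode, config$k_snn)$weights
    n_edges_raw <- nrow(g$edges)
    pruned <- prune_edges(g, config$prune_threshold, weights = w)
    raw_labels <- louvain_partition(pruned, config$resolution_stage1, seed)
    labels <- merge_small_niches(raw_labels, pruned, config$min_niche_size)
    np <- pseudobulk_niches(sample, labels, retained = red$retained)
    np$report <- list(
      sample_id = sample$sample_id, seed = seed,
      n_units = nrow(sample$counts), n_retained = length(red$retained),
      n_edges_raw = n_edges_raw, n_edges_pruned = nrow(pruned$edges),
      n_niches_raw = length(unique(raw_labels)),
      n_niches = length(np$niche_ids),
      unmergeable = attr(labels, "unmergeable"))
    np
  }, error = function(e) {
    stop("stage 1 failed for sample '", sample$sample_id, "': ",
         conditionMessage(e), call. = FALSE)
  })
  res
}
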