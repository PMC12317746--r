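#' Jointly embed the niches of all samples
#'
#' Stacks every sample's niche pseudobulk profiles on the (sorted)
#' intersection of their gene universes, applies Pearson null residuals --
#' which partially absorb sample-wise shifts, helping with batch effects --
#' and computes one shared centered PCA, so distances between niches of
#' different samples are comparable.
#'
#' @param partitions List of `niche_partition` objects (one per sample).
#' @param n_pcs Number of principal components (default 30; reduced with a
#'   warning if the stacked matrix has lower rank).
#' @param residuals `"pearson"` (default) or `"deviance"` null-residual
#'   kind applied before PCA.
#' @return List of class `mnn_embedding`: `values` (total niches x PCs),
#'   `nodes` (data frame `sample_id`, `niche` aligned with the rows),
#'   `genes` (common gene set).
#' @export
joint_embed_niches <- function(partitions, n_pcs = 30L,
                               residuals = c("pearson", "deviance")) {
  residuals <- match.arg(residuals)
  if (length(partitions) < 1L) stop("no partitions")
  genes <- sort(Reduce(intersect, lapply(partitions, `[[`, "gene_ids")))
  if (length(genes) == 0L) stop("empty gene intersection across samples")
  mats <- lapply(partitions, function(p) p$pseudobulk[, genes, drop = FALSE])
  x <- do.call(rbind, mats)
  nodes <- do.call(rbind, lapply(partitions, function(p)
    data.frame(sample_id = p$sample_id, niche = p$niche_ids)))
  rownames(x) <- NULL
  if (any(rowSums(x) == 0))
    stop("a niche has zero total counts on the common gene set")
  r <- null_residuals(x, residuals)
  k <- min(n_pcs, min(dim(r)) - 1L)
  p <- pca_scores(r, k)
  if (ncol(p$scores) < n_pcs)
    warning("joint embedding limited to ", ncol(p$scores), " PCs")
  structure(list(values = p$scores, nodes = nodes, genes = genes),
            class = "mnn_embedding")
}

#' Build the cross-sample mutual nearest-neighbor graph over niches
#'
#' For every niche `u` and every sample `s` other than its own (or
#' including its own when `include_self_sample = TRUE`, which allows
#' sample-specific domains to group), the `k_mnn` nearest niches of `s` in
#' embedding space (Euclidean) form the set `Vu(s)`. Two niches are
#' connected iff the relation is mutual: `u` is in `Vv` and `v` is in
#' `Vu`. Samples holding fewer than `k_mnn` niches contribute their full
#' niche set (flagged in the result).
#'
#' @param embedding An `mnn_embedding` from [joint_embed_niches()].
#' @param k_mnn Neighbours per target sample (default 15).
#' @param include_self_sample Also search within a niche's own sample,
#'   excluding the niche itself (default `FALSE`).
#' @return List of class `mnn_graph`: `nodes`, `embedding`, `edges`
#'   (m x 2 node indices, `u < v`), `knn_sets` (list: node -> target
#'   sample -> neighbour indices), `flagged_samples`.
#' @export
build_mnn_graph <- function(embedding, k_mnn = 15L,
                            include_self_sample = FALSE) {
  nodes <- embedding$nodes
  Y <- embedding$values
  n <- nrow(Y)
  samples <- unique(nodes$sample_id)
  if (length(samples) < 2L && !include_self_sample)
    stop("no cross-sample pairs: a single sample requires ",
         "include_self_sample = TRUE")
  sq <- rowSums(Y * Y)
  d2 <- pmax(outer(sq, sq, `+`) - 2 * tcrossprod(Y), 0)
  by_sample <- split(seq_len(n), nodes$sample_id)
  flagged <- character(0)
  knn_sets <- vector("list", n)
  for (u in seq_len(n)) {
    own <- nodes$sample_id[u]
    targets <- if (include_self_sample) samples else setdiff(samples, own)
    sets <- list()
    for (s in targets) {
      cand <- setdiff(by_sample[[s]], u)
      if (length(cand) == 0L) next
      kk <- min(k_mnn, length(cand))
      if (kk < k_mnn) flagged <- union(flagged, s)
      ord <- cand[order(d2[u, cand], cand)]
      sets[[s]] <- ord[seq_len(kk)]
    }
    knn_sets[[u]] <- sets
  }
  pairs <- matrix(integer(0), 0L, 2L)
  el <- list()
  for (u in seq_len(n)) {
    for (v in unlist(knn_sets[[u]], use.names = FALSE)) {
      if (v > u && u %in% knn_sets[[v]][[nodes$sample_id[u]]])
        el[[length(el) + 1L]] <- c(u, v)
    }
  }
  if (length(el) > 0L) {
    pairs <- do.call(rbind, el)
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  }
  structure(list(nodes = nodes, embedding = Y, edges = pairs,
                 knn_sets = knn_sets, k_mnn = as.integer(k_mnn),
                 include_self_sample = include_self_sample,
                 flagged_samples = flagged),
            class = "mnn_graph")
}

#' Cluster the MNN graph into spatial domains
#'
#' Louvain modularity partitioning of the mutual nearest-neighbor graph at
#' low resolution (default 1), with unit edge weights (mutuality is
#' binary). Domain ids are renumbered by descending niche count. Niches
#' left isolated by the MNN construction (e.g. sample-specific niches when
#' `include_self_sample = FALSE`) inherit the domain of their nearest
#' domain-labelled niche in embedding space, unless
#' `keep_unassigned = TRUE`, in which case they are labelled `-1`.
#'
#' @param graph An `mnn_graph`.
#' @param resolution Louvain resolution (default 1).
#' @param seed Integer seed.
#' @param keep_unassigned Label isolated niches `-1` instead of the
#'   nearest-niche fallback (default `FALSE`).
#' @return Integer domain label per node of `graph`.
#' @export
cluster_mnn_graph <- function(graph, resolution = 1, seed = 1L,
                              keep_unassigned = FALSE) {
  n <- nrow(graph$nodes)
  if (n == 0L) stop("empty MNN graph")
  deg <- tabulate(as.integer(graph$edges), n)
  isolated <- which(deg == 0L)
  if (nrow(graph$edges) == 0L) {
    if (keep_unassigned) return(rep(-1L, n))
    return(rep(1L, n))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(graph$edges))
  set.seed(seed)
  mem <- as.integer(igraph::membership(
    igraph::cluster_louvain(g, resolution = resolution)))
  mem[isolated] <- NA_integer_
  if (length(isolated) > 0L) {
    if (keep_unassigned) {
      mem[isolated] <- -1L
    } else {
      labelled <- which(!is.na(mem))
      Y <- graph$embedding
      for (u in isolated) {
        dd <- colSums((t(Y[labelled, , drop = FALSE]) - Y[u, ])^2)
        mem[u] <- mem[labelled[order(dd, labelled)[1L]]]
      }
    }
  }
  pos <- mem > 0
  counts <- table(mem[pos])
  new_id <- stats::setNames(rank(-as.integer(counts), ties.method = "first"),
                            names(counts))
  mem[pos] <- as.integer(new_id[as.character(mem[pos])])
  mem
}

#' Propagate niche domains to every spot/cell
#'
#' Each unit receives the domain of its niche, giving one shared domain
#' label space across all samples (no per-sample relabelling needed).
#'
#' @param partitions List of `niche_partition` objects.
#' @param nodes Node data frame aligned with `domains` (from the
#'   `mnn_graph`).
#' @param domains Integer domain per node ([cluster_mnn_graph()] output).
#' @return List of class `domain_assignment`: `niche_domain` (data frame
#'   `sample_id`, `niche`, `domain`), `unit_domain` (per-sample named
#'   vectors unit -> domain), `n_domains`, `unassigned` (niches labelled
#'   -1, if any).
#' @export
propagate_labels <- function(partitions, nodes, domains) {
  if (length(domains) != nrow(nodes)) stop("one domain per node required")
  if (anyNA(domains)) stop("niche without a domain after fallback")
  nd <- cbind(nodes, domain = as.integer(domains))
  unit_domain <- lapply(partitions, function(p) {
    rows <- nd[nd$sample_id == p$sample_id, ]
    lut <- stats::setNames(rows$domain, rows$niche)
    dom <- lut[as.character(p$niche_of)]
    if (anyNA(dom)) stop("sample '", p$sample_id,
                         "': niche without a domain")
    stats::setNames(as.integer(dom), names(p$niche_of))
  })
  names(unit_domain) <- vapply(partitions, `[[`, "", "sample_id")
  structure(list(niche_domain = nd, unit_domain = unit_domain,
                 n_domains = length(unique(nd$domain[nd$domain > 0])),
                 unassigned = nd[nd$domain == -1L, , drop = FALSE]),
            class = "domain_assignment")
}

#' @export
print.domain_assignment <- function(x, ...) {
  cat("domain_assignment: ", x$n_domains, " domains across ",
      length(x$unit_domain), " sample(s)\n", sep = "")
  invisible(x)
}

#' Run the full two-stage pipeline
#'
#' Stage 1 ([run_stage1()]) runs independently per sample -- optionally in
#' parallel across `workers` forked processes -- and stage 2
#' ([joint_embed_niches()], [build_mnn_graph()], [cluster_mnn_graph()],
#' [propagate_labels()]) integrates the niches and emits per-unit spatial
#' domain labels shared across samples. Per-sample seeds derived from
#' `config$seed` make the output identical for any worker count or sample
#' order.
#'
#' @param samples List of [srt_sample()] objects.
#' @param config A [run_config()].
#' @param workers Number of stage-1 worker processes (default 1).
#' @param keep_unassigned Passed to [cluster_mnn_graph()].
#' @return List of class `pipeline_result`: `assignment`
#'   (`domain_assignment`), `partitions`, `mnn_graph`, `report`.
#' @export
run_pipeline <- function(samples, config = run_config(), workers = 1L,
                         keep_unassigned = FALSE) {
  if (length(samples) < 1L) stop("no samples")
  ids <- vapply(samples, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  partitions <- if (workers > 1L)
    parallel::mclapply(samples, run_stage1, config = config,
                       mc.cores = workers)
  else lapply(samples, run_stage1, config = config)
  errs <- vapply(partitions, inherits, TRUE, "try-error")
  if (any(errs))
    stop("stage 1 failed for sample(s): ", paste(ids[errs], collapse = ", "))
  emb <- joint_embed_niches(partitions, config$n_pcs,
                            config$residuals_stage2)
  mg <- build_mnn_graph(emb, config$k_mnn, config$include_self_sample)
  domains <- cluster_mnn_graph(mg, config$resolution_stage2,
                               seed = config$seed,
                               keep_unassigned = keep_unassigned)
  assignment <- propagate_labels(partitions, mg$nodes, domains)
  report <- list(
    config = unclass(config),
    samples = ids,
    niches_per_sample = vapply(partitions, function(p)
      length(p$niche_ids), 0L),
    stage1 = lapply(partitions, `[[`, "report"),
    n_mnn_edges = nrow(mg$edges),
    n_domains = assignment$n_domains,
    n_unassigned = nrow(assignment$unassigned))
  structure(list(assignment = assignment, partitions = partitions,
                 mnn_graph = mg, report = report),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result: ", length(x$partitions), " sample(s), ",
      sum(x$report$niches_per_sample), " niches, ",
      x$report$n_mnn_edges, " MNN edges, ", x$report$n_domains,
      " domains\n", sep = "")
  invisible(x)
}
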