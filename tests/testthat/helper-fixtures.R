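# Shared fixtures and independent oracles for the test suite.

# Small Poisson sample on a grid, used where the content of the counts
# does not matter.
tiny_sample <- function(n_row = 5L, n_col = 5L, n_genes = 8L, seed = 7L,
                        sample_id = "tiny") {
  set.seed(seed)
  n <- n_row * n_col
  g <- expand.grid(x = seq_len(n_col) - 1L, y = seq_len(n_row) - 1L)
  counts <- matrix(rpois(n * n_genes, lambda = 4) + 1, n, n_genes,
                   dimnames = list(sprintf("u%03d", seq_len(n)),
                                   sprintf("g%02d", seq_len(n_genes))))
  srt_sample(sample_id, counts, cbind(x = g$x, y = g$y))
}

# Scaled-down simulator configuration for fast end-to-end tests.
small_sim <- function(n_samples = 2L, seed = 11L, ...) {
  sim_config(n_samples = n_samples, grid_shape = c(16L, 20L),
             markers_per_type = 25L, seed = seed, ...)
}

small_run <- function(seed = 11L, ...) {
  run_config(n_pcs = 15L, seed = seed, ...)
}

# O(n^2) kNN oracle: full distance sort per point, ties by index.
brute_knn <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  t(vapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(x) - x[i, ])^2))
    d[i] <- Inf
    order(d, seq_len(n))[seq_len(k)]
  }, integer(k)))
}

# Hand contingency-formula ARI (hypergeometric adjustment), independent of
# mclust.
ari_contingency <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  sn <- choose(sum(tab), 2)
  exp_idx <- sa * sb / sn
  (sij - exp_idx) / ((sa + sb) / 2 - exp_idx)
}

# All set partitions of n items into at most max_b blocks, in canonical
# (restricted growth) form.
all_partitions <- function(n, max_b) {
  out <- list()
  recurse <- function(labels) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    top <- if (i == 1L) 0L else max(labels)
    for (lab in seq_len(min(top + 1L, max_b))) recurse(c(labels, lab))
  }
  recurse(integer(0))
  out
}

# Literal re-evaluation of the smoothed-weight rule for one edge:
# spatial q-nearest sets, shared-neighbour exclusion, endpoint inclusion,
# Pearson correlation of the two mean vectors.
smoothed_weight_oracle <- function(coords, Y, u, v, q) {
  nn <- brute_knn(coords, q)
  Vu <- nn[u, ]; Vv <- nn[v, ]
  shared <- intersect(Vu, Vv)
  Su <- union(setdiff(Vu, shared), u)
  Sv <- union(setdiff(Vv, shared), v)
  stats::cor(colMeans(Y[Su, , drop = FALSE]),
             colMeans(Y[Sv, , drop = FALSE]))
}

# Brute-force mutual-kNN oracle over all cross-sample node pairs.
mnn_edges_oracle <- function(Y, sample_of, k) {
  n <- nrow(Y)
  knn_in <- function(u, s) {
    cand <- setdiff(which(sample_of == s), u)
    d <- sqrt(colSums((t(Y[cand, , drop = FALSE]) - Y[u, ])^2))
    cand[order(d, cand)][seq_len(min(k, length(cand)))]
  }
  el <- list()
  for (u in seq_len(n - 1L)) for (v in (u + 1L):n) {
    if (sample_of[u] == sample_of[v]) next
    if (u %in% knn_in(v, sample_of[u]) && v %in% knn_in(u, sample_of[v]))
      el[[length(el) + 1L]] <- c(u, v)
  }
  if (length(el) == 0L) matrix(integer(0), 0L, 2L) else do.call(rbind, el)
}

# Step-by-step replay of the documented small-niche merge rule, written
# with plain loops.
replay_merge <- function(labels, edges, n, min_size) {
  nbrs <- lapply(seq_len(n), function(i)
    c(edges[edges[, 1L] == i, 2L], edges[edges[, 2L] == i, 1L]))
  repeat {
    sz <- table(labels)
    small <- as.integer(names(sz)[sz < min_size])
    if (!length(small)) break
    small <- small[order(sz[as.character(small)], small)]
    changed <- FALSE
    for (nid in small) {
      members <- which(labels == nid)
      if (!length(members) || length(members) >= min_size) next
      cur_sz <- table(labels)
      prop <- labels[members]
      for (j in seq_along(members)) {
        cand <- labels[nbrs[[members[j]]]]
        cand <- cand[cand != nid]
        if (!length(cand)) next
        tab <- sort(table(cand), decreasing = TRUE)
        top <- as.integer(names(tab)[tab == max(tab)])
        top_sz <- cur_sz[as.character(top)]
        top <- top[top_sz == max(top_sz)]
        prop[j] <- min(top)
      }
      if (any(prop != labels[members])) changed <- TRUE
      labels[members] <- prop
    }
    if (!changed) break
  }
  labels
}

# Pool per-unit predictions of a domain assignment in truth order.
pooled_pred <- function(assignment, samples) {
  unlist(lapply(names(assignment$unit_domain), function(sid)
    assignment$unit_domain[[sid]][samples[[sid]]$unit_ids]),
    use.names = FALSE)
}

pooled_truth <- function(samples) {
  unlist(lapply(samples, function(s) s$truth$region), use.names = FALSE)
}
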