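#' Null-model residuals of a count matrix
#'
#' Residuals of counts under the null multinomial/Poisson model in which
#' every unit expresses every gene in proportion to the gene's overall
#' abundance: the expectation is \eqn{\mu_{ij} = n_i \pi_j} with
#' \eqn{n_i} the unit's total count and \eqn{\pi_j} the gene's share of the
#' grand total. Pearson residuals are \eqn{(y - \mu)/\sqrt{\mu}}; deviance
#' residuals are
#' \eqn{\mathrm{sign}(y-\mu)\sqrt{2[y \ln(y/\mu) - (y-\mu)]}} with
#' \eqn{y\ln(y/\mu) = 0} when \eqn{y = 0}. Deviations from the null capture
#' biological structure without log-transforming sparse counts. Residuals
#' are clipped at \eqn{\pm\sqrt{M}} (M = number of units) to bound the
#' leverage of extreme entries; set `clip = FALSE` to disable.
#'
#' @param counts Non-negative numeric matrix, units x genes, at least 2x2,
#'   with no all-zero unit rows (drop them first).
#' @param kind `"deviance"` or `"pearson"`.
#' @param clip Clip residuals at plus/minus sqrt(number of units)
#'   (default `TRUE`).
#' @return Numeric matrix of residuals, same dimensions as `counts`.
#'   Columns with zero total (genes never observed) get residual 0.
#' @export
null_residuals <- function(counts, kind = c("deviance", "pearson"),
                           clip = TRUE) {
  kind <- match.arg(kind)
  counts <- as.matrix(counts)
  if (anyNA(counts) || min(counts) < 0) stop("counts must be non-negative")
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least 2 units and 2 genes")
  n_i <- rowSums(counts)
  if (any(n_i == 0))
    stop("all-zero unit rows present; drop them before computing residuals")
  total <- sum(n_i)
  if (total <= 0) stop("zero grand total")
  pi_j <- colSums(counts) / total
  mu <- outer(n_i, pi_j)
  if (kind == "pearson") {
    r <- (counts - mu) / sqrt(mu)
    r[mu == 0] <- 0
  } else {
    term <- counts * log(ifelse(counts > 0, counts / ifelse(mu > 0, mu, 1), 1))
    term[counts == 0] <- 0
    dev <- 2 * (term - (counts - mu))
    r <- sign(counts - mu) * sqrt(pmax(dev, 0))
    r[mu == 0] <- 0
  }
  if (clip) {
    bound <- sqrt(nrow(counts))
    r <- pmin(pmax(r, -bound), bound)
  }
  dimnames(r) <- dimnames(counts)
  r
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their log1p counts-per-10k expression and
#' returns the indices of the top `n_top`, with a stable tie-break by gene
#' id. Used by the `hvg_pca` reduction mode.
#'
#' @param counts Units x genes matrix of non-negative values.
#' @param n_top Number of genes to keep (default 2000, capped at the number
#'   of genes).
#' @param gene_ids Gene identifiers used for the tie-break; defaults to
#'   column names, else column index.
#' @return Integer vector of column indices, in decreasing variance order.
#' @export
select_hvg <- function(counts, n_top = 2000L, gene_ids = colnames(counts)) {
  if (n_top <= 0) stop("n_top must be positive")
  counts <- as.matrix(counts)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%09d", seq_len(ncol(counts)))
  if (n_top > ncol(counts)) n_top <- ncol(counts)
  lib <- rowSums(counts)
  lib[lib == 0] <- 1
  ln <- log1p(counts / lib * 1e4)
  v <- apply(ln, 2L, stats::var)
  ord <- order(-v, gene_ids)
  ord[seq_len(n_top)]
}

# Centered PCA via SVD with a deterministic sign convention: each
# component's largest-magnitude loading is made positive.
pca_scores <- function(x, n_pcs) {
  x <- sweep(x, 2L, colMeans(x))
  sv <- svd(x, nu = min(n_pcs, min(dim(x))), nv = min(n_pcs, min(dim(x))))
  tol <- max(sv$d) * 1e-8
  rank <- sum(sv$d > tol)
  k <- min(n_pcs, rank)
  rank_limited <- k < n_pcs
  d <- sv$d[seq_len(k)]
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    l <- v[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 0)
  scores <- u %*% diag(d * flip, k)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, loadings = sweep(v, 2L, flip, `*`),
       sdev = d / sqrt(max(nrow(x) - 1L, 1L)), rank_limited = rank_limited)
}

#' Reduce one sample to a PC embedding
#'
#' Computes the unit x PC matrix used by all graph stages. The default
#' pipeline applies [null_residuals()] to the counts and takes the top
#' `n_pcs` principal components (centered PCA via SVD); the `hvg_pca`
#' method instead log-normalizes, selects highly variable genes with
#' [select_hvg()] and applies standard PCA. All-zero unit rows are dropped
#' with a warning before residual computation; `retained` records the
#' surviving row indices.
#'
#' @param sample An [srt_sample()].
#' @param config A [run_config()]; `n_pcs` and `residuals_stage1` are used.
#' @param method `"deviance_pca"`, `"pearson_pca"` or `"hvg_pca"`;
#'   defaults to the residual kind named by the config.
#' @param n_hvg Number of variable genes for `hvg_pca` (default 2000).
#' @return List of class `reduced_matrix`: `values` (retained units x PCs,
#'   deterministic up to nothing -- component signs are fixed), `sample_id`,
#'   `method`, `retained` (row indices into the sample), `rank_limited`.
#' @export
reduce_dims <- function(sample, config = run_config(), method = NULL,
                        n_hvg = 2000L) {
  validate_srt_sample(sample)
  if (is.null(method))
    method <- paste0(config$residuals_stage1, "_pca")
  method <- match.arg(method, c("deviance_pca", "pearson_pca", "hvg_pca"))
  keep <- which(rowSums(sample$counts) > 0)
  if (length(keep) < nrow(sample$counts))
    warning("sample '", sample$sample_id, "': dropped ",
            nrow(sample$counts) - length(keep), " all-zero units")
  counts <- sample$counts[keep, , drop = FALSE]
  if (config$n_pcs >= min(nrow(counts), ncol(counts)))
    stop("n_pcs must be below min(units, genes)")
  x <- switch(method,
    deviance_pca = null_residuals(counts, "deviance"),
    pearson_pca = null_residuals(counts, "pearson"),
    hvg_pca = {
      lib <- rowSums(counts)
      ln <- log1p(counts / lib * 1e4)
      ln[, select_hvg(counts, n_hvg, sample$gene_ids), drop = FALSE]
    })
  p <- pca_scores(x, config$n_pcs)
  if (p$rank_limited)
    warning("sample '", sample$sample_id, "': rank below n_pcs, returning ",
            ncol(p$scores), " PCs")
  structure(list(values = p$scores, sample_id = sample$sample_id,
                 method = method, retained = keep,
                 sdev = p$sdev, rank_limited = p$rank_limited),
            class = "reduced_matrix")
}
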