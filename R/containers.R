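#' Construct an SRT sample container
#'
#' Bundles one sample's expression matrix, 2D spatial coordinates and
#' identifiers into a validated `srt_sample` object, the unit of input for
#' the whole pipeline.
#'
#' @param sample_id Single string identifying the sample.
#' @param counts Numeric matrix, units (spots/cells) in rows, genes in
#'   columns. Entries must be non-negative (raw counts or simulated values).
#' @param coords Numeric matrix with one row per unit and two columns
#'   (x, y), in platform units (micrometres or array indices).
#' @param gene_ids Character vector of gene identifiers, one per column of
#'   `counts`. Defaults to `colnames(counts)`.
#' @param unit_ids Character vector of unit identifiers, one per row of
#'   `counts`. Defaults to `rownames(counts)`.
#' @param annotations Optional vector of per-unit labels (ground truth),
#'   length `nrow(counts)`.
#' @param landmarks Optional numeric matrix of 2D landmark positions (e.g.
#'   amyloid-plaque centroids) in the same length units as `coords`.
#'
#' @return An object of class `srt_sample`: a list with elements
#'   `sample_id`, `counts`, `coords`, `gene_ids`, `unit_ids`,
#'   `annotations`, `landmarks`.
#' @export
#' @examples
#' counts <- matrix(rpois(12, 5), nrow = 4,
#'                  dimnames = list(paste0("u", 1:4), paste0("g", 1:3)))
#' coords <- cbind(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
#' s <- srt_sample("demo", counts, coords)
srt_sample <- function(sample_id, counts, coords, gene_ids = colnames(counts),
                       unit_ids = rownames(counts), annotations = NULL,
                       landmarks = NULL) {
  counts <- as.matrix(counts)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(counts)))
  if (is.null(unit_ids)) unit_ids <- paste0("unit_", seq_len(nrow(counts)))
  obj <- structure(
    list(sample_id = as.character(sample_id)[1],
         counts = counts, coords = coords,
         gene_ids = as.character(gene_ids),
         unit_ids = as.character(unit_ids),
         annotations = annotations, landmarks = landmarks),
    class = "srt_sample")
  dimnames(obj$counts) <- list(obj$unit_ids, obj$gene_ids)
  colnames(obj$coords) <- c("x", "y")
  rownames(obj$coords) <- obj$unit_ids
  validate_srt_sample(obj)
  obj
}

#' Validate an SRT sample container
#'
#' Checks the structural invariants every pipeline stage relies on: matching
#' unit counts between `counts`, `coords` and `unit_ids`; matching gene
#' counts; non-negative expression; finite coordinates.
#'
#' @param x An `srt_sample` object.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_srt_sample <- function(x) {
  if (!inherits(x, "srt_sample")) stop("not an 'srt_sample' object")
  n <- nrow(x$counts)
  if (n < 1L) stop("sample '", x$sample_id, "': no units")
  if (nrow(x$coords) != n)
    stop("sample '", x$sample_id, "': counts has ", n,
         " units but coords has ", nrow(x$coords))
  if (ncol(x$coords) != 2L)
    stop("sample '", x$sample_id, "': coords must have 2 columns")
  if (length(x$unit_ids) != n)
    stop("sample '", x$sample_id, "': unit_ids length mismatch")
  if (length(x$gene_ids) != ncol(x$counts))
    stop("sample '", x$sample_id, "': gene_ids length mismatch")
  if (anyNA(x$counts) || min(x$counts) < 0)
    stop("sample '", x$sample_id, "': counts has negative or missing entries")
  if (any(!is.finite(x$coords)))
    stop("sample '", x$sample_id, "': coords has non-finite entries")
  if (!is.null(x$annotations) && length(x$annotations) != n)
    stop("sample '", x$sample_id, "': annotations length mismatch")
  invisible(x)
}

#' @export
print.srt_sample <- function(x, ...) {
  cat("srt_sample '", x$sample_id, "': ", nrow(x$counts), " units x ",
      ncol(x$counts), " genes", sep = "")
  if (!is.null(x$annotations)) cat(" (annotated)")
  cat("\n")
  invisible(x)
}

#' Pipeline run configuration
#'
#' Collects every tunable parameter of the two-stage pipeline with the
#' package defaults. Stage 1 (per sample): dimensionality reduction on
#' `n_pcs` principal components of null-model residuals, a spatial kNN
#' graph with `k_spatial` neighbours, `weight_mode` edge weights, pruning
#' (`prune_mode`, `prune_threshold`, smoothing neighbourhood `q_smooth`),
#' Louvain at `resolution_stage1`, and merging of niches smaller than
#' `min_niche_size`. Stage 2: a cross-sample mutual nearest-neighbor graph
#' with `k_mnn` neighbours per target sample, Louvain at
#' `resolution_stage2`.
#'
#' @param n_pcs Number of principal components (default 30).
#' @param k_spatial Spatial kNN neighbourhood size (default 6; choose from
#'   the platform geometry or cell density).
#' @param weight_mode `"pearson"` (correlation of PC rows, default) or
#'   `"snn"` (shared-nearest-neighbor overlap, useful for sparse data).
#' @param prune_mode `"smoothed"` (neighbourhood-averaged weights, default)
#'   or `"fixed"` (pairwise weights).
#' @param prune_threshold Edges with weight below this are removed
#'   (default 0.6; inspect the edge-weight histogram to adapt it).
#' @param q_smooth Spatial neighbourhood size used by smoothed weighting;
#'   defaults to `k_spatial`.
#' @param resolution_stage1 Louvain resolution for niche detection
#'   (default 10, yielding on the order of 100-200 niches per ~5000-unit
#'   sample).
#' @param resolution_stage2 Louvain resolution for domain detection on the
#'   MNN graph (default 1).
#' @param min_niche_size Niches smaller than this are merged into
#'   neighbouring niches (default 5).
#' @param k_mnn Neighbours per target sample in the MNN search (default 15;
#'   on the order of a tenth of the expected niches per sample, so that
#'   same-domain niches stay connected across samples).
#' @param include_self_sample If `TRUE`, MNN edges are also sought within a
#'   niche's own sample, enabling detection of sample-specific domains
#'   (default `FALSE`).
#' @param residuals_stage1,residuals_stage2 Null-residual kind used before
#'   PCA in each stage: `"deviance"` (stage 1 default) or `"pearson"`
#'   (stage 2 default, partially absorbing batch shifts).
#' @param k_snn Neighbourhood size for SNN weights (default 20).
#' @param seed Integer seed controlling all stochastic steps.
#'
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_pcs = 30L, k_spatial = 6L,
                       weight_mode = c("pearson", "snn"),
                       prune_mode = c("smoothed", "fixed"),
                       prune_threshold = 0.6, q_smooth = k_spatial,
                       resolution_stage1 = 10, resolution_stage2 = 1,
                       min_niche_size = 5L, k_mnn = 15L,
                       include_self_sample = FALSE,
                       residuals_stage1 = c("deviance", "pearson"),
                       residuals_stage2 = c("pearson", "deviance"),
                       k_snn = 20L, seed = 1L) {
  cfg <- list(
    n_pcs = as.integer(n_pcs), k_spatial = as.integer(k_spatial),
    weight_mode = match.arg(weight_mode),
    prune_mode = match.arg(prune_mode),
    prune_threshold = prune_threshold, q_smooth = as.integer(q_smooth),
    resolution_stage1 = resolution_stage1,
    resolution_stage2 = resolution_stage2,
    min_niche_size = as.integer(min_niche_size), k_mnn = as.integer(k_mnn),
    include_self_sample = isTRUE(include_self_sample),
    residuals_stage1 = match.arg(residuals_stage1),
    residuals_stage2 = match.arg(residuals_stage2),
    k_snn = as.integer(k_snn), seed = as.integer(seed))
  stopifnot(cfg$k_spatial >= 1L, cfg$n_pcs >= 2L,
            cfg$resolution_stage1 > 0, cfg$resolution_stage2 > 0,
            cfg$min_niche_size >= 1L, is.finite(cfg$prune_threshold),
            cfg$k_mnn >= 1L, cfg$q_smooth >= 0L)
  class(cfg) <- "run_config"
  cfg
}

# Deterministic per-sample seed derived from the global seed and the
# sample id, so results do not depend on worker count or sample order.
sample_seed <- function(seed, sample_id) {
  h <- sum(utf8ToInt(sample_id) * seq_along(utf8ToInt(sample_id)))
  as.integer((as.double(seed) + 1009 * h) %% 2147483647)
}
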