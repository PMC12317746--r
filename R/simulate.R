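#' Default tissue-to-cell-type probability matrix
#'
#' Row-stochastic 4x4 matrix giving the cell-type mixture of each simulated
#' tissue group: group 1 is dominated by type 1 (0.90), group 2 by type 2
#' (0.60), group 3 by type 3 (0.50) and group 4 by type 4 (0.70), with the
#' remaining mass spread over the other types. A tissue is a region
#' containing multiple cell types, so domains are mixtures, not single
#' types.
#'
#' @return A 4x4 numeric matrix, rows = tissue groups, columns = cell types.
#' @export
default_prob_matrix <- function() {
  m <- rbind(c(0.90, 0.03, 0.04, 0.03),
             c(0.20, 0.60, 0.05, 0.15),
             c(0.25, 0.15, 0.50, 0.10),
             c(0.10, 0.10, 0.10, 0.70))
  dimnames(m) <- list(paste0("group", 1:4), paste0("type", 1:4))
  m
}

#' Simulator configuration
#'
#' Parameters of the two-phase multi-sample SRT simulator. Phase 1 lays
#' units on a regular grid, assigns tissue-region labels by a spatial
#' pattern and draws each unit's cells' types from the region's row of
#' `prob_matrix`. Phase 2 generates expression: marker gene `g` of cell
#' type `Lg` in unit `i` holding cells `k = 1..Ni` takes value
#' \deqn{X_{ij} = \frac{1}{N_i}\sum_k \delta(L_k, L_g)\,E_g + E_s +
#'   \epsilon,\qquad \epsilon \sim N(0, \sigma^2 + \sigma_s^2),}
#' where \eqn{\delta} is the Kronecker delta, \eqn{E_g} the marker
#' expression level and \eqn{E_s, \sigma_s^2} sample-wise batch shift and
#' extra variance. Noisy genes take low-level expression
#' \eqn{E_g/2 \cdot U(0,1)} (plus shift and noise) independent of cell
#' type. Negative values are clipped at 0 by default so the output is a
#' valid non-negative expression matrix.
#'
#' @param n_samples Number of samples (default 4).
#' @param grid_shape Integer `(rows, cols)` of the unit grid (default
#'   `c(64, 78)`, i.e. 4992 units).
#' @param n_cell_types Number of cell types (default 4).
#' @param prob_matrix Tissue x cell-type row-stochastic matrix (default
#'   [default_prob_matrix()]); its row count sets the number of tissue
#'   regions.
#' @param markers_per_type Marker genes per cell type (default 200).
#' @param noise_gene_frac Fraction of all genes that are noisy (default
#'   0.10); the total gene count is
#'   `ceiling(markers_per_type * n_cell_types / (1 - noise_gene_frac))`
#'   (889 with defaults).
#' @param Eg Marker expression level (default 10).
#' @param sigma2 Base Gaussian noise variance (default 1).
#' @param batch_shift_frac Maximum sample shift `Es` as a fraction of `Eg`
#'   (default 0; the extreme preset uses 5, a 500% shift). Sample `s` of
#'   `N` receives `Es = Eg * batch_shift_frac * (s-1)/(N-1)`.
#' @param batch_var_frac Maximum extra sample variance as a fraction of
#'   `sigma2` (default 0; extreme preset 1.25), spread over samples like
#'   the shift.
#' @param cells_per_unit `list(kind = "fixed", n = 1)` (cell-based
#'   default: one cell per unit) or `list(kind = "dunif", min, max)`
#'   (spot-based preset: `min = 1, max = 6`).
#' @param pattern Spatial pattern of the tissue regions: `"h_layers"`,
#'   `"d_layers"`, `"rings"` or `"quadrants"`.
#' @param clip_negative Floor expression at 0 (default `TRUE`).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 4L, grid_shape = c(64L, 78L),
                       n_cell_types = 4L,
                       prob_matrix = default_prob_matrix(),
                       markers_per_type = 200L, noise_gene_frac = 0.10,
                       Eg = 10, sigma2 = 1, batch_shift_frac = 0,
                       batch_var_frac = 0,
                       cells_per_unit = list(kind = "fixed", n = 1L),
                       pattern = c("h_layers", "d_layers", "rings",
                                   "quadrants"),
                       clip_negative = TRUE, seed = 1L) {
  pattern <- match.arg(pattern)
  prob_matrix <- as.matrix(prob_matrix)
  if (ncol(prob_matrix) != n_cell_types)
    stop("prob_matrix must have one column per cell type")
  if (any(abs(rowSums(prob_matrix) - 1) > 1e-12))
    stop("prob_matrix rows must sum to 1")
  if (noise_gene_frac < 0 || noise_gene_frac >= 1)
    stop("noise_gene_frac must be in [0, 1)")
  n_markers <- markers_per_type * n_cell_types
  n_genes <- as.integer(ceiling(n_markers / (1 - noise_gene_frac)))
  structure(list(
    n_samples = as.integer(n_samples), grid_shape = as.integer(grid_shape),
    n_cell_types = as.integer(n_cell_types), prob_matrix = prob_matrix,
    n_tissues = nrow(prob_matrix),
    markers_per_type = as.integer(markers_per_type),
    noise_gene_frac = noise_gene_frac, n_genes = n_genes,
    n_noise_genes = n_genes - n_markers,
    Eg = Eg, sigma2 = sigma2, batch_shift_frac = batch_shift_frac,
    batch_var_frac = batch_var_frac, cells_per_unit = cells_per_unit,
    pattern = pattern, clip_negative = isTRUE(clip_negative),
    seed = as.integer(seed)), class = "sim_config")
}

#' Spatial region pattern on a regular grid
#'
#' Deterministically assigns each grid unit to one of `n_tissues` regions:
#' `"h_layers"` -- equal-height horizontal bands; `"d_layers"` -- diagonal
#' bands by quantiles of row+col; `"rings"` -- concentric annuli by
#' quantiles of the distance to the grid centre; `"quadrants"` -- 2x2
#' blocks (requires `n_tissues = 4`). Coordinates are integer grid
#' positions `(x = column, y = row)`, zero-based.
#'
#' @param pattern One of `"h_layers"`, `"d_layers"`, `"rings"`,
#'   `"quadrants"`.
#' @param grid_shape Integer `(rows, cols)`.
#' @param n_tissues Number of regions (>= 2).
#' @return List with `coords` (units x 2 matrix) and `region` (integer
#'   labels in `1..n_tissues`); every region is non-empty.
#' @export
make_pattern <- function(pattern, grid_shape = c(64L, 78L), n_tissues = 4L) {
  if (n_tissues < 2L) stop("need at least 2 tissues")
  rows <- grid_shape[1L]; cols <- grid_shape[2L]
  if (rows * cols < n_tissues) stop("grid too small for n_tissues")
  g <- expand.grid(row = seq_len(rows) - 1L, col = seq_len(cols) - 1L)
  coords <- cbind(x = g$col, y = g$row)
  region <- switch(pattern,
    h_layers = pmin(floor(g$row * n_tissues / rows), n_tissues - 1L) + 1L,
    d_layers = quantile_bins(g$row + g$col, n_tissues),
    rings = {
      cy <- (rows - 1) / 2; cx <- (cols - 1) / 2
      quantile_bins(sqrt((g$row - cy)^2 + (g$col - cx)^2), n_tissues)
    },
    quadrants = {
      if (n_tissues != 4L) stop("quadrants requires n_tissues = 4")
      as.integer(2L * (g$row >= rows / 2) + (g$col >= cols / 2) + 1L)
    },
    stop("unknown pattern: ", pattern))
  region <- as.integer(region)
  if (length(unique(region)) != n_tissues)
    stop("grid too small for n_tissues: some region is empty")
  list(coords = coords, region = region)
}

# Bins a value vector into n near-equal groups; a pure (non-decreasing)
# function of the value, so equal values share a label.
quantile_bins <- function(v, n) {
  br <- stats::quantile(v, probs = seq(0, 1, length.out = n + 1L), type = 1L)
  br <- unique(br)
  as.integer(cut(v, breaks = br, labels = FALSE, include.lowest = TRUE))
}

#' Draw cells and cell types for each unit
#'
#' Phase-2 sampling step: the number of cells per unit `Ni` comes from the
#' configured distribution (one cell per unit for cell-based platforms;
#' discrete-uniform for spot-based), and each cell's type is drawn i.i.d.
#' from the unit's region row of the probability matrix.
#'
#' @param region Integer region label per unit.
#' @param prob_matrix Tissue x cell-type row-stochastic matrix.
#' @param cells_per_unit Distribution spec, see [sim_config()].
#' @param seed Integer seed.
#' @return List with `ni` (integer cells per unit) and `types` (list of
#'   per-unit integer cell-type vectors).
#' @export
assign_cells <- function(region, prob_matrix,
                         cells_per_unit = list(kind = "fixed", n = 1L),
                         seed = 1L) {
  set.seed(seed)
  n_units <- length(region)
  n_types <- ncol(prob_matrix)
  ni <- switch(cells_per_unit$kind,
    fixed = rep(as.integer(cells_per_unit$n), n_units),
    dunif = sample(seq(cells_per_unit$min, cells_per_unit$max), n_units,
                   replace = TRUE),
    stop("unknown cells_per_unit kind"))
  types <- lapply(seq_len(n_units), function(i)
    sample.int(n_types, ni[i], replace = TRUE,
               prob = prob_matrix[region[i], ]))
  list(ni = ni, types = types)
}

#' Generate the expression matrix of one sample
#'
#' Applies the generative model (see [sim_config()]) to drawn cells: each
#' marker gene of type `t` takes the unit's fraction of type-`t` cells
#' times `Eg`, noisy genes take `Eg/2 * U(0,1)`, and every entry receives
#' the sample shift `Es` plus Gaussian noise of variance
#' `sigma2 + sigma_s2`.
#'
#' @param cells Output of [assign_cells()].
#' @param config A [sim_config()].
#' @param Es Sample-wise shift added to every entry.
#' @param sigma_s2 Sample-wise extra noise variance.
#' @return Units x genes numeric matrix; genes are ordered as
#'   `markers_per_type` blocks per cell type followed by the noisy genes,
#'   named `mk_t<type>_<i>` and `noise_<i>`.
#' @export
generate_expression <- function(cells, config, Es = 0, sigma_s2 = 0) {
  n_units <- length(cells$ni)
  n_types <- config$n_cell_types
  frac <- matrix(0, n_units, n_types)
  for (i in seq_len(n_units))
    frac[i, ] <- tabulate(cells$types[[i]], n_types) / cells$ni[i]
  mpt <- config$markers_per_type
  marker_means <- frac[, rep(seq_len(n_types), each = mpt)] * config$Eg
  noise_block <- matrix(
    stats::runif(n_units * config$n_noise_genes) * config$Eg / 2,
    n_units, config$n_noise_genes)
  x <- cbind(marker_means, noise_block) + Es +
    matrix(stats::rnorm(n_units * config$n_genes,
                        sd = sqrt(config$sigma2 + sigma_s2)),
           n_units, config$n_genes)
  if (config$clip_negative) x[x < 0] <- 0
  colnames(x) <- c(sprintf("mk_t%d_%03d", rep(seq_len(n_types), each = mpt),
                           rep(seq_len(mpt), n_types)),
                   sprintf("noise_%03d", seq_len(config$n_noise_genes)))
  x
}

#' Gene role table of a simulator configuration
#'
#' @param config A [sim_config()].
#' @return Data frame with `gene_id` and `role`
#'   (`"marker_t<type>"` or `"noisy"`), in the gene order of
#'   [generate_expression()].
#' @export
gene_roles <- function(config) {
  n_types <- config$n_cell_types; mpt <- config$markers_per_type
  data.frame(
    gene_id = c(sprintf("mk_t%d_%03d", rep(seq_len(n_types), each = mpt),
                        rep(seq_len(mpt), n_types)),
                sprintf("noise_%03d", seq_len(config$n_noise_genes))),
    role = c(paste0("marker_t", rep(seq_len(n_types), each = mpt)),
             rep("noisy", config$n_noise_genes)))
}

#' Simulate a multi-sample SRT dataset with ground truth
#'
#' Produces `n_samples` samples sharing one gene universe, grid geometry
#' and probability matrix, each with independent cell draws and noise and
#' its own batch shift/variance (evenly spaced from 0 up to the configured
#' maxima, so "up to" the extreme preset is realized by the last sample).
#' Ground truth is attached to each sample: region labels as
#' `annotations`, per-unit dominant cell type, cell draws and batch
#' parameters.
#'
#' @param config A [sim_config()].
#' @return List of [srt_sample()] objects named `sample_1 ...`, each with
#'   extra fields `truth` (list: `region`, `cells`, `Es`, `sigma_s2`);
#'   the gene role table is attached as attribute `"gene_roles"`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  pat <- make_pattern(config$pattern, config$grid_shape, config$n_tissues)
  N <- config$n_samples
  spread <- if (N > 1L) (seq_len(N) - 1L) / (N - 1L) else 0
  shifts <- config$Eg * config$batch_shift_frac * spread
  vars <- config$sigma2 * config$batch_var_frac * spread
  samples <- vector("list", N)
  for (s in seq_len(N)) {
    sid <- paste0("sample_", s)
    cells <- assign_cells(pat$region, config$prob_matrix,
                          config$cells_per_unit,
                          seed = sample_seed(config$seed, sid))
    x <- generate_expression(cells, config, Es = shifts[s],
                             sigma_s2 = vars[s])
    rownames(x) <- sprintf("%s_u%05d", sid, seq_len(nrow(x)))
    smp <- srt_sample(sid, x, pat$coords,
                      annotations = as.character(pat$region))
    smp$truth <- list(region = pat$region, cells = cells,
                      Es = shifts[s], sigma_s2 = vars[s])
    samples[[s]] <- smp
  }
  names(samples) <- vapply(samples, `[[`, "", "sample_id")
  attr(samples, "gene_roles") <- gene_roles(config)
  attr(samples, "config") <- config
  samples
}
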