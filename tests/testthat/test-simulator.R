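test_that("patterns tile the grid deterministically", {
  hp <- make_pattern("h_layers", c(8L, 8L), 4L)
  expect_equal(hp$region, rep(rep(1:4, each = 2), 8))
  expect_equal(as.integer(table(hp$region)), rep(16L, 4))

  # rings: label non-decreasing in distance to the grid centre
  rp <- make_pattern("rings", c(20L, 20L), 4L)
  ctr <- c((20 - 1) / 2, (20 - 1) / 2)
  d <- sqrt((rp$coords[, 1] - ctr[1])^2 + (rp$coords[, 2] - ctr[2])^2)
  expect_true(all(diff(rp$region[order(d)]) >= 0))
  expect_equal(length(unique(rp$region)), 4L)

  dp <- make_pattern("d_layers", c(10L, 12L), 3L)
  ssum <- rp$coords[, 1] + rp$coords[, 2]
  expect_true(all(diff(dp$region[order(dp$coords[, 1] + dp$coords[, 2])])
                  >= 0))

  qp <- make_pattern("quadrants", c(6L, 6L), 4L)
  expect_equal(as.integer(table(qp$region)), rep(9L, 4))
  expect_error(make_pattern("quadrants", c(6L, 6L), 3L), "requires")
  expect_error(make_pattern("h_layers", c(1L, 2L), 4L), "too small")

  # geometry is deterministic
  expect_identical(make_pattern("rings", c(20L, 20L), 4L), rp)
})

test_that("cell-type draws follow the probability matrix", {
  # degenerate row: every cell in that region is type 1
  pm <- rbind(c(1, 0, 0, 0), c(0.25, 0.25, 0.25, 0.25))
  cells <- assign_cells(rep(1:2, each = 500), pm, seed = 5)
  t1 <- unlist(cells$types[1:500])
  expect_true(all(t1 == 1L))

  # binomial 3-sigma bands at ~1200 cells per region
  pat <- make_pattern("h_layers", c(64L, 78L), 4L)
  dc <- assign_cells(pat$region, default_prob_matrix(), seed = 6)
  for (r in 1:4) {
    draws <- unlist(dc$types[pat$region == r])
    n <- length(draws)
    for (ct in 1:4) {
      p <- default_prob_matrix()[r, ct]
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(mean(draws == ct) - p), 3 * se + 1e-9)
    }
  }

  # spot-based preset draws 1..6 cells per unit
  sc <- assign_cells(rep(1L, 300), pm[1, , drop = FALSE],
                     cells_per_unit = list(kind = "dunif", min = 1, max = 6),
                     seed = 7)
  expect_true(all(sc$ni >= 1 & sc$ni <= 6))
  expect_equal(lengths(sc$types), sc$ni)
})

test_that("expression follows the generative model in the noiseless limit", {
  cfg <- sim_config(markers_per_type = 3L, noise_gene_frac = 0.25,
                    sigma2 = 0, Eg = 10)
  # one unit of pure type 2, one spot with one cell each of types 1 and 2
  cells <- list(ni = c(1L, 2L), types = list(2L, c(1L, 2L)))
  x <- generate_expression(cells, cfg, Es = 0, sigma_s2 = 0)
  expect_equal(unname(x[1, 4:6]), rep(10, 3))     # type-2 markers at Eg
  expect_equal(unname(x[1, c(1:3, 7:12)]), rep(0, 9))
  expect_equal(unname(x[2, 1:6]), rep(5, 6))      # Eg/2 from the 1/Ni average
  # noisy genes are uniform below Eg/2, independent of type
  expect_true(all(x[, 13:16] >= 0 & x[, 13:16] <= 5))

  # CLT check: marker mean over pure units ~ Eg + Es
  cfg2 <- sim_config(markers_per_type = 2L, sigma2 = 1, Eg = 10,
                     clip_negative = FALSE)
  set.seed(8)
  cellsn <- list(ni = rep(1L, 2000), types = as.list(rep(1L, 2000)))
  xn <- generate_expression(cellsn, cfg2, Es = 3, sigma_s2 = 0)
  expect_lt(abs(mean(xn[, 1]) - 13), 3 / sqrt(2000))
})

test_that("datasets have the configured geometry and reproduce exactly", {
  cfg <- small_sim(n_samples = 2, seed = 9)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1[[1]]$counts, d2[[1]]$counts)
  expect_identical(d1[[2]]$counts, d2[[2]]$counts)
  expect_equal(nrow(d1[[1]]$counts), 320L)
  expect_equal(ncol(d1[[1]]$counts),
               ceiling(25 * 4 / 0.9))

  # zero noise, cell-based: marker rows take exactly n_cell_types patterns
  cfg0 <- sim_config(n_samples = 1, grid_shape = c(8L, 10L),
                     markers_per_type = 5L, sigma2 = 0, seed = 10)
  d0 <- simulate_dataset(cfg0)
  marker_part <- d0[[1]]$counts[, 1:20]
  pats <- unique(apply(marker_part > 0, 1, paste, collapse = ""))
  expect_equal(length(pats), 4L)

  # batch monotonicity: a larger shift widens the cross-sample mean gap
  gap <- function(frac) {
    dd <- simulate_dataset(small_sim(n_samples = 2, seed = 11,
                                     batch_shift_frac = frac))
    mean(dd[[2]]$counts) - mean(dd[[1]]$counts)
  }
  expect_gt(gap(2), gap(0.5))
  expect_gt(gap(0.5), gap(0))
})
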