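# Builds a niche_partition directly from a pseudobulk matrix.
fake_partition <- function(sample_id, pb, gene_ids = colnames(pb)) {
  structure(list(sample_id = sample_id,
                 niche_of = stats::setNames(integer(0), character(0)),
                 niche_ids = seq_len(nrow(pb)),
                 pseudobulk = `colnames<-`(pb, gene_ids),
                 sizes = rep(1L, nrow(pb)), centroids = NULL,
                 gene_ids = gene_ids, retained = integer(0)),
            class = "niche_partition")
}

test_that("joint embedding is symmetric and matches an eigen oracle", {
  set.seed(31)
  pb <- matrix(rpois(10 * 40, 20) + 1, 10, 40,
               dimnames = list(NULL, sprintf("g%02d", 1:40)))
  pa <- fake_partition("a", pb)
  pc <- fake_partition("b", pb)
  emb <- joint_embed_niches(list(pa, pc), n_pcs = 5)
  expect_equal(emb$values[1:10, ], emb$values[11:20, ])

  # eigen-oracle on the stacked residuals
  r <- null_residuals(rbind(pb, pb), "pearson")
  ev <- eigen(stats::cov(r), symmetric = TRUE)$values[1:5]
  expect_equal(unname(apply(emb$values, 2, stats::var)), ev,
               tolerance = 1e-8)

  # sample-order permutation only reorders rows
  emb2 <- joint_embed_niches(list(pc, pa), n_pcs = 5)
  expect_equal(emb2$values[11:20, ], emb$values[1:10, ])

  bad <- fake_partition("c", matrix(1, 3, 2), gene_ids = c("zz1", "zz2"))
  expect_error(joint_embed_niches(list(pa, bad)), "intersection")
})

test_that("MNN edges equal the brute-force mutual pairs", {
  set.seed(32)
  pbs <- lapply(1:3, function(i)
    fake_partition(paste0("s", i),
                   matrix(rpois(5 * 30, 15) + 1, 5, 30,
                          dimnames = list(NULL, sprintf("g%02d", 1:30)))))
  emb <- joint_embed_niches(pbs, n_pcs = 4)
  mg <- build_mnn_graph(emb, k_mnn = 2)
  oracle <- mnn_edges_oracle(emb$values, emb$nodes$sample_id, 2)
  expect_equal(mg$edges, oracle[order(oracle[, 1], oracle[, 2]), ,
                                drop = FALSE],
               ignore_attr = TRUE)
  # multipartite constraint: no within-sample edges
  expect_true(all(emb$nodes$sample_id[mg$edges[, 1]] !=
                  emb$nodes$sample_id[mg$edges[, 2]]))

  # 2 samples x 1 niche each: the unique pair is mutual
  one <- lapply(1:2, function(i)
    fake_partition(paste0("o", i),
                   matrix(rpois(20, 10) + i, 1, 20,
                          dimnames = list(NULL, sprintf("g%02d", 1:20)))))
  embo <- suppressWarnings(joint_embed_niches(one, n_pcs = 2))
  mgo <- build_mnn_graph(embo, k_mnn = 1)
  expect_equal(mgo$edges, rbind(c(1L, 2L)), ignore_attr = TRUE)

  expect_error(build_mnn_graph(joint_embed_niches(pbs[1], n_pcs = 3),
                               k_mnn = 2), "cross-sample")
})

test_that("domain clustering handles components, cliques and isolates", {
  nodes <- data.frame(sample_id = rep(c("a", "b"), each = 4), niche = 1:4)
  emb <- matrix(c(rep(0, 4), rep(10, 4)), 8, 2)
  emb[, 2] <- rep(c(1, 2, 50, 51), 2)
  # two disconnected components (cross-sample pairs)
  g2 <- structure(list(nodes = nodes, embedding = emb,
                       edges = rbind(c(1, 5), c(2, 6), c(3, 7), c(4, 8),
                                     c(1, 6), c(3, 8)),
                       knn_sets = NULL), class = "mnn_graph")
  dom <- cluster_mnn_graph(g2, resolution = 1, seed = 5)
  expect_equal(length(unique(dom)), 2L)
  expect_equal(length(unique(dom[c(1, 2, 5, 6)])), 1L)

  # a clique collapses to one domain
  gc <- g2
  gc$edges <- t(utils::combn(8, 2))
  expect_equal(unique(cluster_mnn_graph(gc, 1, 6)), 1L)

  # isolated niche inherits its nearest labelled niche's domain
  gi <- g2
  gi$edges <- rbind(c(1, 5), c(2, 6), c(3, 7))  # node 4 and 8 mostly apart
  gi$edges <- rbind(gi$edges, c(4, 8))
  gi$edges <- gi$edges[-4, , drop = FALSE]      # leave 4, 8 isolated
  domi <- cluster_mnn_graph(gi, 1, 7)
  expect_equal(domi[4], domi[3])  # embedding row 4 is closest to row 3
  domk <- cluster_mnn_graph(gi, 1, 7, keep_unassigned = TRUE)
  expect_equal(domk[c(4, 8)], c(-1L, -1L))

  # tiny-graph modularity not below the exhaustive optimum
  ig <- igraph::make_empty_graph(8, directed = FALSE)
  ig <- igraph::add_edges(ig, t(g2$edges))
  q_found <- igraph::modularity(ig, dom)
  best <- max(vapply(all_partitions(8, 4), function(p)
    igraph::modularity(ig, p), 0))
  expect_gte(q_found + 1e-12, best)
})

test_that("label propagation is a pure lookup with conserved counts", {
  s <- tiny_sample(3, 4, n_genes = 5, sample_id = "p1")
  lab <- rep(1:3, each = 4)
  part <- pseudobulk_niches(s, lab)
  nodes <- data.frame(sample_id = "p1", niche = 1:3)
  da <- propagate_labels(list(part), nodes, c(2L, 2L, 1L))
  expect_equal(unname(da$unit_domain$p1),
               c(2L, 2L, 1L)[lab])
  tab <- table(da$unit_domain$p1)
  expect_equal(as.integer(tab[c("1", "2")]), c(4L, 8L))
  expect_equal(da$n_domains, 2L)
  expect_error(propagate_labels(list(part), nodes, c(1L, NA, 2L)),
               "without a domain")
})

test_that("pipeline is worker-invariant and exchangeable on identical copies", {
  sims <- simulate_dataset(small_sim(n_samples = 2, seed = 33))
  cfg <- small_run(seed = 33, k_mnn = 8)
  r1 <- run_pipeline(sims, cfg, workers = 1)
  r2 <- run_pipeline(sims, cfg, workers = 2)
  expect_identical(r1$assignment$unit_domain, r2$assignment$unit_domain)
  expect_identical(r1$assignment$niche_domain, r2$assignment$niche_domain)

  # two identical copies of one sample: same per-unit domains
  a <- sims[[1]]
  b <- a
  b$sample_id <- "copy"
  b$unit_ids <- paste0("c_", a$unit_ids)
  rownames(b$counts) <- b$unit_ids
  rownames(b$coords) <- b$unit_ids
  names(b$annotations) <- NULL
  rc <- run_pipeline(list(a, b), cfg)
  expect_identical(unname(rc$assignment$unit_domain[[a$sample_id]]),
                   unname(rc$assignment$unit_domain[["copy"]]))
})
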