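test_that("coarse and fine networks hold pairwise Pearson correlations with zero diagonal", {
  # two identical region means, one anti-correlated, plus a hand-checked pair
  t1 <- c(1, 2, 3, 4, 2)
  t3 <- c(2, 1, 4, 3, 5)
  d <- cbind(t1, t1, -t1, -t1, t3, t3)
  parc <- parcellation(c(0, 0, 1, 1, 2, 2))
  ts <- timeseries_matrix(d, 1, 1)
  net <- coarse_network(ts, parc)
  expect_equal(diag(net$weights), rep(0, 3))
  expect_equal(net$weights[1, 2], -1)
  expect_equal(net$weights[1, 3], cor(t1, t3))
  expect_equal(net$weights, t(net$weights))

  fine <- fine_network(ts, parc, 0L)
  expect_equal(fine$weights[1, 2], 1) # identical vertex pair, diag removed
  expect_equal(diag(fine$weights), c(0, 0))
  fine2 <- fine_network(ts, parc, 1L)
  expect_equal(fine2$weights[1, 2], 1)
})

test_that("density thresholding keeps the strongest links deterministically", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- 0.9; w[1, 3] <- 0.5; w[1, 4] <- 0.1
  w[2, 3] <- 0.7; w[2, 4] <- -0.2; w[3, 4] <- 0.3
  w <- w + t(w)
  net <- structure(list(weights = w, node_ids = 0:3), class = "WeightedNet")

  # top-2 of 6 pairs by signed weight
  g <- threshold_density(net, 2 / 6 + 1e-9)
  expect_equal(sum(g$adjacency) / 2, 2)
  expect_equal(g$adjacency[1, 2], 1L)
  expect_equal(g$adjacency[2, 3], 1L)

  # sort oracle at a higher density: kept edges are exactly the top-k
  g5 <- threshold_density(net, 5 / 6 + 1e-9)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  kept <- order(-w[ut])[1:5]
  expect_equal(sum(g5$adjacency) / 2, 5)
  for (k in kept) expect_equal(g5$adjacency[ut[k, 1], ut[k, 2]], 1L)

  # total tie: first index-ordered pairs, reproducibly
  tie <- structure(list(weights = matrix(1, 4, 4) - diag(4), node_ids = 0:3),
                   class = "WeightedNet")
  gt1 <- threshold_density(tie, 0.5)
  gt2 <- threshold_density(tie, 0.5)
  expect_identical(gt1$adjacency, gt2$adjacency)
  expect_equal(gt1$adjacency[1, 2], 1L) # (1,2),(1,3),(1,4) first in order
  expect_equal(gt1$adjacency[1, 3], 1L)
  expect_equal(gt1$adjacency[1, 4], 1L)

  expect_error(threshold_density(net, 1.2), "density")
  expect_error(threshold_density(net, 0.01), "zero edges")
})

test_that("threshold_density is monotone in density (nested edge sets)", {
  with_seed(21, {
    w <- matrix(rnorm(100), 10, 10); w <- (w + t(w)) / 2; diag(w) <- 0
  })
  net <- structure(list(weights = w, node_ids = 0:9), class = "WeightedNet")
  prev <- NULL
  for (d in c(0.1, 0.2, 0.3, 0.5)) {
    g <- threshold_density(net, d)
    if (!is.null(prev)) expect_true(all(g$adjacency[prev == 1] == 1))
    prev <- g$adjacency
  }
})

test_that("global metrics match closed forms on canonical graphs", {
  k3 <- as_binary_graph(matrix(1, 3, 3) - diag(3))
  gm <- global_metrics(k3, null_rewires = 0)
  expect_equal(gm$path_length, 1)
  expect_equal(gm$clustering, 1)
  expect_equal(gm$global_efficiency, 1)

  # 4-node path graph: L = (1*3 + 2*2 + 3*1) * 2 / 12 = 5/3
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 3] <- A[3, 4] <- 1; A <- A + t(A)
  gp <- global_metrics(as_binary_graph(A), null_rewires = 0)
  expect_equal(gp$path_length, 5 / 3)
  D <- oracle_distances(A); inv <- 1 / D; diag(inv) <- 0
  expect_equal(gp$global_efficiency, sum(inv) / 12)

  # two K4 cliques plus one bridge: Louvain finds the cliques and the
  # reported Q matches the Newman formula evaluated directly
  B <- matrix(0, 8, 8); B[1:4, 1:4] <- 1; B[5:8, 5:8] <- 1
  diag(B) <- 0; B[4, 5] <- B[5, 4] <- 1
  gq <- global_metrics(as_binary_graph(B), null_rewires = 0, seed = 1)
  expect_equal(gq$modularity_q, oracle_newman_q(B, rep(1:2, each = 4)),
               tolerance = 1e-12)
})

test_that("small-worldness exceeds 1 for a ring lattice and is seed-reproducible", {
  # 16-node ring lattice, each node tied to its 2 nearest neighbours per side
  N <- 16
  A <- matrix(0, N, N)
  for (i in seq_len(N)) for (s in 1:2) {
    j <- ((i - 1 + s) %% N) + 1
    A[i, j] <- A[j, i] <- 1
  }
  g <- as_binary_graph(A)
  s1 <- global_metrics(g, null_rewires = 5, seed = 3)$small_worldness
  s2 <- global_metrics(g, null_rewires = 5, seed = 3)$small_worldness
  expect_gt(s1, 1)
  expect_identical(s1, s2)
})

test_that("local metrics match closed forms on star and cycle graphs", {
  N <- 6
  star <- matrix(0, N, N); star[1, 2:N] <- 1; star <- star + t(star)
  lm <- local_metrics(as_binary_graph(star), modules = rep(0, N))
  expect_equal(lm$degree[1], N - 1)
  expect_equal(lm$closeness[1], 1)
  expect_equal(lm$clustcoef[1], 0)
  expect_equal(lm$eigencentrality[1], 1)
  expect_equal(lm$participation, rep(0, N)) # single module

  c5 <- matrix(0, 5, 5)
  for (i in 1:5) { j <- (i %% 5) + 1; c5[i, j] <- c5[j, i] <- 1 }
  lc <- local_metrics(as_binary_graph(c5))
  expect_equal(lc$degree, rep(2, 5))
  expect_equal(lc$kcore, rep(2, 5))
})

test_that("participation coefficient matches the direct-sum oracle on a planted toy", {
  A <- matrix(0, 6, 6)
  A[1, 2] <- A[2, 3] <- A[1, 3] <- 1 # module 0 triangle
  A[4, 5] <- A[5, 6] <- 1            # module 1 path
  A[3, 4] <- 1                       # bridge
  A <- A + t(A)
  mods <- c(0, 0, 0, 1, 1, 1)
  lm <- local_metrics(as_binary_graph(A), modules = mods)
  expect_equal(lm$participation, oracle_participation(A, mods), tolerance = 1e-12)
  expect_equal(lm$participation[1], 0)       # all edges within module
  expect_gt(lm$participation[3], 0)          # bridge endpoint
})

test_that("metrics are invariant under node relabeling", {
  A <- random_graph(7, 0.4, seed = 31)
  with_seed(32, p <- sample(7))
  Ap <- A[p, p]
  g1 <- suppressWarnings(global_metrics(as_binary_graph(A), null_rewires = 0))
  g2 <- suppressWarnings(global_metrics(as_binary_graph(Ap), null_rewires = 0))
  expect_equal(g1$path_length, g2$path_length)
  expect_equal(g1$clustering, g2$clustering)
  expect_equal(g1$global_efficiency, g2$global_efficiency)
  l1 <- local_metrics(as_binary_graph(A))
  l2 <- local_metrics(as_binary_graph(Ap))
  expect_equal(l1$degree[p], l2$degree)
  expect_equal(l1$closeness[p], l2$closeness, tolerance = 1e-12)
  expect_equal(l1$kcore[p], l2$kcore)
})

test_that("metric patterns have the documented shapes and are reproducible", {
  co <- generate_cohort(synth_config(
    n_subjects = 3, n_timepoints = 60, n_runs = 1, n_regions = 3,
    vertices_per_region = 10, noise_sd = 0.3, trait_effect_size = 0, seed = 41))
  ts <- lapply(co$timeseries, `[[`, 1)
  pat <- metric_pattern(ts, co$parcellation, "coarse_global_pattern",
                        "clustering", density = 0.3)
  expect_equal(dim(pat), c(3, 3))
  # identical subjects give identical rows
  pat2 <- metric_pattern(ts[c(1, 1)], co$parcellation, "coarse_global_pattern",
                         "clustering", density = 0.3)
  expect_equal(pat2[1, ], pat2[2, ])
  # fine local: single region, metric = degree equals the degree sequence
  fl <- metric_pattern(ts, co$parcellation, "fine_local", "degree",
                       density = 0.3, region = 1L)
  expect_equal(dim(fl), c(3, 10))
  g <- threshold_density(fine_network(ts[[2]], co$parcellation, 1L), 0.3)
  expect_equal(fl[2, ], local_metrics(g)$degree)
  # determinism replay
  expect_identical(pat, metric_pattern(ts, co$parcellation,
                                       "coarse_global_pattern", "clustering",
                                       density = 0.3))
})
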