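noise_free_cohort <- function(seed = 1, subjects = 4, regions = 3, vpr = 12,
                              scope = "region", n_timepoints = 80) {
  generate_cohort(synth_config(
    n_subjects = subjects, n_timepoints = n_timepoints, n_runs = 2,
    n_regions = regions, vertices_per_region = vpr, noise_sd = 0,
    rotation_scope = scope, trait_effect_size = 0, seed = seed))
}

cohort_connectomes <- function(co, run = 1) {
  lapply(co$timeseries, function(x) {
    ts <- x[[run]]
    make_connectome(ts, make_targets(ts, co$parcellation), zscore = TRUE)
  })
}

test_that("procrustes solves the orthogonal alignment problem", {
  with_seed(1, X <- matrix(rnorm(30 * 5), 30, 5))
  expect_equal(procrustes(X, X), diag(5), tolerance = 1e-10)

  R0 <- with_seed(2, random_orthogonal(5))
  expect_equal(procrustes(X, X %*% R0), R0, tolerance = 1e-8)

  # 1-D reflection
  x <- matrix(c(1, -2, 3), 3, 1)
  expect_equal(procrustes(x, -x), matrix(-1, 1, 1))

  expect_error(procrustes(X, X[, 1:3]), "mismatch")

  # residual invariant under a common right-rotation of both inputs
  Y <- with_seed(3, matrix(rnorm(30 * 5), 30, 5))
  G <- with_seed(4, random_orthogonal(5))
  r1 <- norm(X %*% procrustes(X, Y) - Y, "F")
  r2 <- norm((X %*% G) %*% procrustes(X %*% G, Y %*% G) - Y %*% G, "F")
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("fit_template recovers the shared space from rotated copies", {
  # identical subjects: template equals the (normalized) common matrix
  with_seed(5, X <- matrix(rnorm(40 * 6), 40, 6))
  tmpl <- fit_template(list(X, X, X))
  Xn <- sweep(X, 2, colMeans(X), "-")
  Xn <- Xn / sqrt(mean(Xn^2))
  expect_equal(tmpl, Xn, tolerance = 1e-10)

  # subjects = template %*% R_s exactly (noise-free time-series blocks):
  # every subject aligns back onto the template
  co <- noise_free_cohort(seed = 6, subjects = 5, regions = 4, vpr = 20)
  idx <- which(co$parcellation$labels == 0)
  stack <- lapply(co$timeseries, function(x) x[[1]]$data[, idx])
  tm <- fit_template(stack)
  for (s in seq_along(stack)) {
    al <- stack[[s]] %*% procrustes(stack[[s]], tm)
    al <- sweep(al, 2, colMeans(al), "-")
    al <- al / sqrt(mean(al^2))
    expect_lt(norm(al - tm, "F") / norm(tm, "F"), 0.05)
  }
})

test_that("fit_template is gauge-invariant to subject order on noise-free input", {
  co <- noise_free_cohort(seed = 7, subjects = 5, regions = 4, vpr = 20)
  idx <- which(co$parcellation$labels == 1)
  stack <- lapply(co$timeseries, function(x) x[[1]]$data[, idx])
  t1 <- fit_template(stack)
  t2 <- fit_template(stack[c(4, 2, 5, 1, 3)])
  G <- procrustes(t1, t2)
  expect_lt(norm(t1 %*% G - t2, "F") / norm(t2, "F"), 1e-6)
})

test_that("rCHA mappers are block-diagonal, identity for duplicated subjects, and improve ISC", {
  # full-rank configuration (n_latents = vertices_per_region) so that the
  # Procrustes solution is unique and the duplicated-subject mapper is
  # exactly the identity
  co_fr <- generate_cohort(synth_config(
    n_subjects = 3, n_timepoints = 60, n_runs = 2, n_regions = 6,
    vertices_per_region = 4, n_latents = 4, noise_sd = 0,
    trait_effect_size = 0, seed = 8))
  conns_fr <- cohort_connectomes(co_fr)
  mdup <- fit_rcha(rep(conns_fr[1], 3), co_fr$parcellation)
  V <- length(co_fr$parcellation$labels)
  expect_equal(as.matrix(mdup[[2]]$matrix), diag(V), tolerance = 1e-8)

  co <- noise_free_cohort(seed = 8)
  parc <- co$parcellation
  conns <- cohort_connectomes(co)
  maps <- fit_rcha(conns, parc)
  # block-diagonal: no nonzeros across regions
  M <- as.matrix(maps[[1]]$matrix)
  for (r in 0:2) {
    idx <- which(parc$labels == r)
    off <- M[idx, -idx]
    expect_equal(max(abs(off)), 0)
  }

  # rotation recovery: mapped connectomes agree across subjects far better
  # than unaligned ones.  (Agreement cannot reach 1 even noise-free: the
  # region-mean targets are themselves rotated per subject, so profiles are
  # only approximately shared.)
  mapped <- lapply(seq_along(conns), function(s) apply_mapper(maps[[s]], conns[[s]]))
  for (s in 2:length(mapped)) {
    pre <- cor(as.vector(conns[[1]]$matrix), as.vector(conns[[s]]$matrix))
    post <- cor(as.vector(mapped[[1]]$matrix), as.vector(mapped[[s]]$matrix))
    expect_gt(post, 0.85)
    expect_gt(post, pre + 0.3)
  }

  # ISC strictly increases relative to unaligned training connectomes
  expect_gt(isc_profiles(mapped)$mean, isc_profiles(conns)$mean)
})

test_that("searchlight membership follows Euclidean distance", {
  geom <- data.frame(vertex = 0:4, x = 0:4, y = 0, z = 0)
  # radius below spacing: singletons
  sl <- build_searchlights(geom, 0.5)
  expect_true(all(vapply(sl, function(s) identical(s$members, s$center), logical(1))))
  # radius covering the cloud: everything
  sl <- build_searchlights(geom, 10)
  expect_true(all(vapply(sl, function(s) length(s$members) == 5, logical(1))))
  # unit chain, radius 1.5: interior searchlights have exactly 3 members
  sl <- build_searchlights(geom, 1.5)
  expect_equal(lengths(lapply(sl, `[[`, "members")), c(2, 3, 3, 3, 2))
  expect_equal(sl[[3]]$members, 1:3)
  expect_error(build_searchlights(geom, 0), "radius")
})

test_that("searchlights that tile regions reproduce rCHA mappers", {
  co <- noise_free_cohort(seed = 9, subjects = 3, regions = 2, vpr = 9)
  parc <- co$parcellation
  conns <- cohort_connectomes(co)
  # region blocks are 3x3 grids with diameter sqrt(8) < inter-region gap
  sls <- build_searchlights(co$geometry, sqrt(8) + 1e-6)
  for (sl in sls) # confirm the construction: members = whole region
    expect_equal(sl$members + 1L, which(parc$labels == parc$labels[sl$center + 1]))
  rmap <- fit_rcha(conns, parc)
  smap <- fit_scha(conns, sls)
  for (s in seq_along(conns)) {
    Ms <- as.matrix(smap[[s]]$matrix)
    Mr <- as.matrix(rmap[[s]]$matrix)
    # each region's block is summed over its 9 identical searchlights
    for (r in 0:1) {
      idx <- which(parc$labels == r)
      expect_lt(max(abs(Ms[idx, idx] / length(idx) - Mr[idx, idx])), 1e-6)
    }
  }
})

test_that("a duplicated subject's searchlight mapper acts as identity after re-z-scoring", {
  co <- noise_free_cohort(seed = 10, subjects = 3, regions = 2, vpr = 9)
  conns <- cohort_connectomes(co)
  sls <- build_searchlights(co$geometry, 1.5)
  dup <- rep(conns[1], 3)
  smap <- fit_scha(dup, sls)
  mapped <- apply_mapper(smap[[2]], conns[[1]]$matrix, rezscore = TRUE)
  expect_equal(mapped, zscore_cols(conns[[1]]$matrix, warn = FALSE),
               tolerance = 1e-6)
})

test_that("sCHA raises ISC above the unaligned level on misaligned cohorts", {
  co <- noise_free_cohort(seed = 11, subjects = 4, regions = 2, vpr = 9,
                          scope = "searchlight")
  conns <- cohort_connectomes(co)
  sls <- build_searchlights(co$geometry, 2)
  smap <- fit_scha(conns, sls)
  mapped <- lapply(seq_along(conns), function(s)
    apply_mapper(smap[[s]], conns[[s]]))
  expect_gt(isc_profiles(mapped)$mean, isc_profiles(conns)$mean)
})

test_that("apply_mapper performs the sparse product and validates shapes", {
  V <- 6
  ident <- structure(list(subject_id = 1,
                          matrix = Matrix::Diagonal(V), kind = "roi"),
                     class = "Mapper")
  with_seed(12, X <- matrix(rnorm(4 * V), 4, V))
  expect_equal(apply_mapper(ident, X, rezscore = FALSE), X)

  # block-diagonal product equals per-block dense products
  R1 <- with_seed(13, random_orthogonal(3))
  R2 <- with_seed(14, random_orthogonal(3))
  M <- Matrix::bdiag(R1, R2)
  mp <- structure(list(subject_id = 1, matrix = M, kind = "roi"), class = "Mapper")
  got <- apply_mapper(mp, X, rezscore = FALSE)
  expect_equal(got, cbind(X[, 1:3] %*% R1, X[, 4:6] %*% R2), tolerance = 1e-12)

  expect_error(apply_mapper(mp, X[, 1:4]), "columns")
})

test_that("mapping time series then recomputing equals mapping the connectome", {
  # Convention under which the two routes coincide: the time series is
  # column-standardized before mapping, targets are taken from the unmapped
  # data, and both resulting connectomes are profile-z-scored.
  co <- noise_free_cohort(seed = 15, subjects = 3, regions = 2, vpr = 8)
  parc <- co$parcellation
  ts <- co$timeseries[[2]][[1]]
  targets <- make_targets(ts, parc)
  conn <- make_connectome(ts, targets, zscore = TRUE)
  maps <- fit_rcha(cohort_connectomes(co), parc)
  m <- maps[[2]]

  route_conn <- apply_mapper(m, conn$matrix, rezscore = TRUE)
  ts_std <- timeseries_matrix(zscore_cols(ts$data), 2, 1)
  mapped_ts <- apply_mapper(m, ts_std, rezscore = FALSE)
  route_ts <- make_connectome(mapped_ts, targets, zscore = TRUE)
  expect_equal(route_ts$matrix, route_conn, tolerance = 1e-6)
})

test_that("mappers fit on run 1 generalize to the held-out run", {
  co <- generate_cohort(synth_config(
    n_subjects = 5, n_timepoints = 100, n_runs = 2, n_regions = 3,
    vertices_per_region = 12, noise_sd = 0.5, trait_effect_size = 0, seed = 16))
  maps <- fit_rcha(cohort_connectomes(co, run = 1), co$parcellation)
  conn2 <- cohort_connectomes(co, run = 2)
  mapped2 <- lapply(seq_along(conn2), function(s) apply_mapper(maps[[s]], conn2[[s]]))
  expect_gt(isc_profiles(mapped2)$mean, isc_profiles(conn2)$mean)
})
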