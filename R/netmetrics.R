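#' Weighted functional network between regions (coarse scale)
#'
#' Region-mean time series, pairwise Pearson correlation, zero diagonal.
#'
#' @param ts a [timeseries_matrix()].
#' @param parc a [parcellation()].
#' @return a `WeightedNet` (symmetric weights matrix, zero diagonal).
#' @export
coarse_network <- function(ts, parc) {
  targets <- make_targets(ts, parc)
  weighted_net(cor_guarded(targets$matrix), node_ids = seq_len(parc$n_regions) - 1L)
}

#' Weighted functional network among one region's vertices (fine scale)
#'
#' Pairwise Pearson correlation between the region's vertex time series,
#' diagonal (self-connections) set to 0.
#'
#' @param ts a [timeseries_matrix()].
#' @param parc a [parcellation()].
#' @param region 0-based region id.
#' @return a `WeightedNet` over the region's vertices.
#' @export
fine_network <- function(ts, parc, region) {
  idx <- region_cols(parc, region)
  if (length(idx) == 0) stop("region ", region, " has no vertices")
  weighted_net(cor_guarded(ts$data[, idx, drop = FALSE]),
               node_ids = ts$vertex_ids[idx])
}

# internal constructor enforcing symmetry and zero diagonal
weighted_net <- function(w, node_ids = seq_len(ncol(w)) - 1L) {
  w <- as.matrix(w)
  dimnames(w) <- NULL
  if (max(abs(w - t(w))) > 1e-10) stop("weights must be symmetric")
  diag(w) <- 0
  structure(list(weights = w, node_ids = node_ids), class = "WeightedNet")
}

#' Density-threshold a weighted network into a binary graph
#'
#' Keeps the `floor(density * N(N-1)/2)` strongest links by signed weight
#' (so negative correlations are effectively excluded at realistic
#' densities).  Ties at the cutoff are broken deterministically by (smaller
#' i, smaller j) index order, which also makes the kept edge set nested
#' across densities.
#'
#' @param net a `WeightedNet`.
#' @param density requested edge fraction in (0, 1).
#' @return a `BinaryGraph` with fields `adjacency`, `density` (achieved),
#'   `node_ids`.
#' @export
threshold_density <- function(net, density) {
  stopifnot(inherits(net, "WeightedNet"))
  if (!(density > 0 && density < 1)) stop("density must be in (0, 1)")
  N <- ncol(net$weights)
  ut <- which(upper.tri(net$weights), arr.ind = TRUE)
  w <- net$weights[ut]
  k <- floor(density * N * (N - 1) / 2)
  if (k < 1) stop("requested density keeps zero edges")
  keep <- order(-w, ut[, 1], ut[, 2])[seq_len(k)]
  A <- matrix(0L, N, N)
  A[ut[keep, , drop = FALSE]] <- 1L
  A <- A + t(A)
  structure(list(adjacency = A, density = 2 * k / (N * (N - 1)),
                 node_ids = net$node_ids), class = "BinaryGraph")
}

# internal: igraph handle for a BinaryGraph
bg_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
}

#' Global graph metrics on a binary network
#'
#' Characteristic path length (mean finite shortest-path length over ordered
#' reachable pairs; computed on reachable pairs with a warning if the graph
#' is disconnected), mean nodal clustering coefficient (nodes of degree < 2
#' contribute 0), global efficiency (mean inverse shortest-path length over
#' ordered pairs, disconnected pairs contributing 0), degree assortativity,
#' single-layer modularity (seeded Louvain at resolution 1, best of
#' `n_restarts`), and small-worldness sigma = (C/C_rand)/(L/L_rand) against
#' degree-preserving rewired nulls.
#'
#' @param g a `BinaryGraph`.
#' @param null_rewires number of rewired null graphs for sigma (0 skips it).
#' @param seed integer seed for Louvain restarts and rewiring.
#' @param n_restarts Louvain restarts.
#' @return a `GlobalMetrics` list.
#' @export
global_metrics <- function(g, null_rewires = 10, seed = 1, n_restarts = 20) {
  ig <- bg_igraph(g)
  if (!igraph::is_connected(ig))
    warning("graph is disconnected; path length computed over reachable pairs")
  L <- suppressWarnings(igraph::mean_distance(ig, unconnected = TRUE))
  C <- graph_clustering(g)
  eff <- graph_efficiency(g)
  assort <- suppressWarnings(igraph::assortativity_degree(ig))
  q <- best_louvain(ig, seed = seed, n_restarts = n_restarts)$q
  sigma <- NA_real_
  if (null_rewires > 0 && igraph::ecount(ig) > 1) {
    Cr <- Lr <- numeric(null_rewires)
    for (b in seq_len(null_rewires)) {
      rg <- with_seed(substream_seed(seed, 7L, b),
                      igraph::rewire(ig, igraph::keeping_degseq(
                        niter = 10 * igraph::ecount(ig))))
      rga <- structure(list(adjacency = as.matrix(igraph::as_adjacency_matrix(rg))),
                       class = "BinaryGraph")
      Cr[b] <- graph_clustering(rga)
      Lr[b] <- suppressWarnings(igraph::mean_distance(rg, unconnected = TRUE))
    }
    if (mean(Cr) > 0 && mean(Lr) > 0 && L > 0)
      sigma <- (C / mean(Cr)) / (L / mean(Lr))
  }
  structure(list(path_length = L, clustering = C, global_efficiency = eff,
                 assortativity = assort, modularity_q = q,
                 small_worldness = sigma),
            class = "GlobalMetrics")
}

# mean nodal clustering coefficient; degree < 2 counts as 0
graph_clustering <- function(g) {
  ig <- bg_igraph(g)
  lc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  mean(lc)
}

# mean of inverse shortest-path lengths over ordered pairs (0 if unreachable)
graph_efficiency <- function(g) {
  ig <- bg_igraph(g)
  N <- igraph::vcount(ig)
  if (N < 2) return(0)
  d <- igraph::distances(ig)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (N * (N - 1))
}

# seeded Louvain, best modularity over restarts
best_louvain <- function(ig, seed, n_restarts = 20, resolution = 1) {
  best <- NULL
  for (b in seq_len(n_restarts)) {
    cl <- with_seed(substream_seed(seed, 8L, b),
                    igraph::cluster_louvain(ig, resolution = resolution))
    q <- igraph::modularity(cl)
    if (!is.finite(q)) q <- 0 # edgeless graph

    if (is.null(best) || q > best$q)
      best <- list(q = q, membership = igraph::membership(cl))
  }
  best
}

#' Local (per-node) graph metrics on a binary network
#'
#' Degree; eigenvector centrality (principal eigenvector of the adjacency,
#' scaled to maximum 1); closeness centrality with the reachable-fraction
#' scaling `(r/(N-1)) * (r / sum of finite distances)` where r counts
#' reachable others (isolated nodes get 0); nodal clustering coefficient;
#' k-core score; and, when `modules` is given, the participation coefficient
#' `1 - sum_m (k_im/k_i)^2` (0 for isolated nodes).
#'
#' @param g a `BinaryGraph`.
#' @param modules optional 0-based module id per node (for participation).
#' @return a `LocalMetrics` data.frame, one row per node.
#' @export
local_metrics <- function(g, modules = NULL) {
  ig <- bg_igraph(g)
  A <- g$adjacency
  N <- ncol(A)
  deg <- rowSums(A)
  # principal eigenvector via symmetric eigendecomposition; deterministic
  if (sum(A) == 0) {
    eig <- rep(0, N)
  } else {
    ev <- eigen(A, symmetric = TRUE)
    v <- abs(ev$vectors[, 1])
    eig <- if (max(v) > 0) v / max(v) else v
  }
  d <- igraph::distances(ig)
  clo <- vapply(seq_len(N), function(i) {
    di <- d[i, -i]
    fin <- di[is.finite(di)]
    r <- length(fin)
    if (r == 0 || sum(fin) == 0) return(0)
    (r / (N - 1)) * (r / sum(fin))
  }, numeric(1))
  cc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  kc <- igraph::coreness(ig)
  part <- rep(NA_real_, N)
  if (!is.null(modules)) {
    modules <- as.integer(modules)
    part <- vapply(seq_len(N), function(i) {
      if (deg[i] == 0) return(0)
      km <- tapply(A[i, ], modules, sum)
      1 - sum((km / deg[i])^2)
    }, numeric(1))
  }
  structure(data.frame(node_id = g$node_ids %||% (seq_len(N) - 1L),
                       degree = deg, eigencentrality = eig, closeness = clo,
                       clustcoef = cc, kcore = kc, participation = part),
            class = c("LocalMetrics", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subject x feature matrices of topological patterns
#'
#' `scale = "coarse_global_pattern"`: for each subject, a global measure is
#' recomputed region-by-region on each region's fine (vertex-level) graph,
#' giving an S x P matrix — the fine-grained topological signature of that
#' measure across regions.  `scale = "fine_local"`: for one region, the S x
#' n_vertices matrix of a local metric.
#'
#' @param ts_list list over subjects of `TimeseriesMatrix` (one run).
#' @param parc a [parcellation()].
#' @param scale `"coarse_global_pattern"` or `"fine_local"`.
#' @param metric metric name: one of `path_length`, `clustering`,
#'   `global_efficiency`, `assortativity`, `modularity_q` (global scale), or
#'   `degree`, `eigencentrality`, `closeness`, `clustcoef`, `kcore` (local).
#' @param density edge density for thresholding.
#' @param region 0-based region id (required for `fine_local`).
#' @param seed seed for seeded metrics (modularity).
#' @return numeric subject x feature matrix.
#' @export
metric_pattern <- function(ts_list, parc,
                           scale = c("coarse_global_pattern", "fine_local"),
                           metric, density = 0.15, region = NULL, seed = 1) {
  scale <- match.arg(scale)
  S <- length(ts_list)
  if (S == 0) stop("no subjects provided")
  if (scale == "coarse_global_pattern") {
    P <- parc$n_regions
    out <- matrix(NA_real_, S, P)
    for (s in seq_len(S)) {
      for (r in seq_len(P) - 1L) {
        gg <- suppressWarnings(
          threshold_density(fine_network(ts_list[[s]], parc, r), density))
        out[s, r + 1L] <- suppressWarnings(
          global_metric_value(gg, metric, seed = substream_seed(seed, 9L, s, r)))
      }
    }
  } else {
    if (is.null(region)) stop("fine_local scale requires a region")
    idx <- region_cols(parc, region)
    out <- matrix(NA_real_, S, length(idx))
    for (s in seq_len(S)) {
      gg <- suppressWarnings(
        threshold_density(fine_network(ts_list[[s]], parc, region), density))
      lm <- local_metrics(gg)
      if (!metric %in% names(lm)) stop("unknown local metric: ", metric)
      out[s, ] <- lm[[metric]]
    }
  }
  out
}

# internal: single named global metric (cheap path; sigma not offered here)
global_metric_value <- function(g, metric, seed = 1) {
  ig <- bg_igraph(g)
  switch(metric,
    path_length = igraph::mean_distance(ig, unconnected = TRUE),
    clustering = graph_clustering(g),
    global_efficiency = graph_efficiency(g),
    assortativity = igraph::assortativity_degree(ig),
    modularity_q = best_louvain(ig, seed = seed, n_restarts = 5)$q,
    stop("unknown global metric: ", metric)
  )
}
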