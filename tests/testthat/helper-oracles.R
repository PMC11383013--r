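# Brute-force oracles, deliberately independent of the package's
# implementation paths: plain BFS, explicit triangle counting, exhaustive
# k-core peeling, direct formula evaluations, and exhaustive partition
# enumeration.  They are only ever run on tiny inputs.

# all-pairs shortest paths by breadth-first search
oracle_distances <- function(A) {
  N <- nrow(A)
  D <- matrix(Inf, N, N)
  for (s in seq_len(N)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (u in frontier) {
        nb <- which(A[u, ] > 0)
        new <- nb[D[s, nb] == Inf]
        D[s, new] <- d
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
  }
  D
}

# nodal clustering coefficient by explicit triangle enumeration
oracle_clustcoef <- function(A) {
  N <- nrow(A)
  vapply(seq_len(N), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (A[nb[a], nb[b]] > 0) tri <- tri + 1
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

# k-core scores by exhaustive peeling
oracle_kcore <- function(A) {
  N <- nrow(A)
  core <- integer(N)
  alive <- rep(TRUE, N)
  k <- 0
  while (any(alive)) {
    repeat {
      deg <- rowSums(A[, alive, drop = FALSE])
      peel <- which(alive & deg <= k)
      if (!length(peel)) break
      core[peel] <- k
      alive[peel] <- FALSE
    }
    k <- k + 1
  }
  core
}

# Newman modularity by direct double-sum over all ordered pairs (incl. i=j)
oracle_newman_q <- function(A, memb) {
  twom <- sum(A)
  if (twom == 0) return(0)
  k <- rowSums(A)
  q <- 0
  N <- nrow(A)
  for (i in seq_len(N)) for (j in seq_len(N))
    if (memb[i] == memb[j]) q <- q + A[i, j] - k[i] * k[j] / twom
  q / twom
}

# closeness with reachable-fraction scaling, straight from the definition
oracle_closeness <- function(A) {
  D <- oracle_distances(A)
  N <- nrow(A)
  vapply(seq_len(N), function(i) {
    di <- D[i, -i]
    fin <- di[is.finite(di)]
    r <- length(fin)
    if (r == 0 || sum(fin) == 0) return(0)
    (r / (N - 1)) * (r / sum(fin))
  }, numeric(1))
}

# participation coefficient by a hand loop over modules
oracle_participation <- function(A, modules) {
  N <- nrow(A)
  vapply(seq_len(N), function(i) {
    k <- sum(A[i, ])
    if (k == 0) return(0)
    s <- 0
    for (m in unique(modules)) s <- s + (sum(A[i, modules == m]) / k)^2
    1 - s
  }, numeric(1))
}

# principal-eigenvector centrality by power iteration (max scaled to 1).
# Iterates on A + I, which shares A's eigenvectors but shifts the spectrum
# so the dominant eigenvalue is strictly largest in magnitude even for
# bipartite graphs (where -lambda_1 is also an eigenvalue of A).
oracle_eigencentrality <- function(A, iters = 5000) {
  M <- A + diag(nrow(A))
  v <- rowSums(A) + 1
  for (it in seq_len(iters)) {
    w <- M %*% v
    nv <- sqrt(sum(w^2))
    if (nv == 0) return(rep(0, nrow(A)))
    v <- as.numeric(w) / nv
  }
  v <- abs(v)
  v / max(v)
}

# all set partitions of n elements as restricted-growth label vectors
oracle_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, k) {
    i <- length(labels) + 1
    if (i > n) { out[[length(out) + 1]] <<- labels; return() }
    for (c in seq_len(k + 1)) recurse(c(labels, c), max(k, c))
  }
  recurse(integer(0), 0L)
  out
}

# multilayer quality from the definition: intralayer modularity terms over
# all ordered pairs (incl. i=j) plus categorical all-to-all coupling,
# normalized by total edge weight plus coupling weight
oracle_ml_quality <- function(layers, labmat, gamma, omega) {
  N <- nrow(labmat); L <- ncol(labmat)
  num <- 0; twomu <- 0
  for (l in seq_len(L)) {
    A <- if (inherits(layers[[l]], "WeightedNet")) layers[[l]]$weights else layers[[l]]
    A <- pmax(A, 0)
    k <- rowSums(A); twom <- sum(k)
    twomu <- twomu + twom
    for (i in seq_len(N)) for (j in seq_len(N)) {
      if (labmat[i, l] == labmat[j, l]) {
        null <- if (twom > 0) gamma * k[i] * k[j] / twom else 0
        num <- num + A[i, j] - null
      }
    }
  }
  for (i in seq_len(N))
    for (l in seq_len(L)) for (lp in seq_len(L))
      if (l != lp && labmat[i, l] == labmat[i, lp]) num <- num + omega
  twomu <- twomu + omega * N * L * (L - 1)
  num / twomu
}

# random binary graph on n nodes with edge probability p
random_graph <- function(n, p, seed) {
  with_seed(seed, {
    A <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (stats::runif(1) < p) A[i, j] <- A[j, i] <- 1L
    A
  })
}

as_binary_graph <- function(A) {
  structure(list(adjacency = A, density = sum(A) / (nrow(A) * (nrow(A) - 1)),
                 node_ids = seq_len(nrow(A)) - 1L), class = "BinaryGraph")
}
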