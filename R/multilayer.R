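#' Multi-subject (multilayer) modularity with categorical coupling
#'
#' Maximizes the multilayer quality function
#' \deqn{Q = \frac{1}{2\mu}\Big[\sum_l \sum_{ij} \big(A^l_{ij} - \gamma
#'   \frac{k^l_i k^l_j}{2m_l}\big)\,\delta(c_{il}, c_{jl}) + \omega
#'   \sum_i \sum_{l \ne l'} \delta(c_{il}, c_{il'})\Big]}
#' where layers (here: subjects) are coupled categorically — every node is
#' linked to its own copy in every other layer with weight `omega` — and
#' \eqn{2\mu} is the total intralayer edge weight plus the total coupling
#' weight, so Q is comparable across layer counts.  Optimization is a
#' Louvain-style greedy over node-layer elements (seeded shuffled sweep
#' order) followed by community-merge passes, iterated to convergence; the
#' best of `n_restarts` seeded restarts is kept.  Community labels are
#' canonicalized by first appearance (layer by layer, nodes in order).
#'
#' @param layers list of `WeightedNet`s (or N x N matrices) on the same node
#'   set, one per layer.
#' @param gamma structural resolution (> 0); larger gives smaller modules.
#' @param omega categorical interlayer coupling (>= 0).
#' @param seed integer seed.
#' @param n_restarts restarts of the greedy optimizer.
#' @param negative `"zero"` clips negative weights to 0 before forming the
#'   modularity matrix (the null model assumes nonnegative weights);
#'   `"keep"` uses them as-is.
#' @return a `MultilayerPartition`: `labels` (N x L integer matrix, 0-based,
#'   consecutive), `q`, `gamma`, `omega`, `n_communities`.
#' @export
multilayer_modularity <- function(layers, gamma, omega, seed = 1,
                                  n_restarts = 20,
                                  negative = c("zero", "keep")) {
  negative <- match.arg(negative)
  if (gamma <= 0) stop("gamma must be > 0")
  if (omega < 0) stop("omega must be >= 0")
  sup <- supra_modularity(layers, gamma, omega, negative)
  NL <- nrow(sup$B)
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    lab <- with_seed(substream_seed(seed, 10L, rs),
                     greedy_multilayer(sup$B, sample.int(NL)))
    q <- partition_quality(sup, lab)
    if (is.null(best) || q > best$q + 1e-12) best <- list(q = q, lab = lab)
  }
  labmat <- matrix(best$lab, sup$N, sup$L) # node-layer index = (l-1)N + i
  labmat <- canonicalize_labels(labmat)
  structure(list(labels = labmat, q = best$q, gamma = gamma, omega = omega,
                 n_communities = length(unique(as.vector(labmat)))),
            class = "MultilayerPartition")
}

# internal: dense supra-modularity matrix.  Node-layer x = (l-1)*N + i.
# Intralayer blocks hold A - gamma*k k'/(2m) (including the diagonal null
# term); interlayer entries hold omega between copies of the same node.
supra_modularity <- function(layers, gamma, omega, negative = "zero") {
  As <- lapply(layers, function(l) {
    a <- if (inherits(l, "WeightedNet")) l$weights else as.matrix(l)
    if (length(a) == 0 || nrow(a) == 0) stop("empty layer")
    if (negative == "zero") a[a < 0] <- 0
    a
  })
  N <- nrow(As[[1]])
  if (any(vapply(As, nrow, 0L) != N)) stop("all layers must share the node set")
  L <- length(As)
  B <- matrix(0, N * L, N * L)
  twom_total <- 0
  for (l in seq_len(L)) {
    A <- As[[l]]
    k <- rowSums(A)
    twom <- sum(k)
    Bl <- if (twom > 0) A - gamma * tcrossprod(k) / twom else A
    idx <- (l - 1) * N + seq_len(N)
    B[idx, idx] <- Bl
    twom_total <- twom_total + twom
  }
  if (L > 1 && omega > 0) {
    for (l in seq_len(L - 1)) for (lp in (l + 1):L) {
      for (i in seq_len(N)) {
        x <- (l - 1) * N + i; y <- (lp - 1) * N + i
        B[x, y] <- B[y, x] <- omega
      }
    }
  }
  twomu <- twom_total + omega * N * L * (L - 1)
  if (twomu <= 0) twomu <- 1
  list(B = B, twomu = twomu, N = N, L = L)
}

# internal: quality of a labeling under a supra-modularity structure
partition_quality <- function(sup, lab) {
  q <- 0
  for (c in unique(lab)) {
    m <- which(lab == c)
    q <- q + sum(sup$B[m, m])
  }
  q / sup$twomu
}

# internal: greedy optimizer — local node-layer moves (each accepted move
# strictly increases the quality) alternated with community merges until no
# improving move exists.  `order0` fixes the first sweep order.
greedy_multilayer <- function(B, order0) {
  NL <- nrow(B)
  lab <- seq_len(NL)
  eps <- 1e-12
  repeat {
    moved_any <- FALSE
    repeat {
      moved <- FALSE
      for (x in order0) {
        row <- B[x, ]
        s <- rowsum(row, lab) # community sums including y = x
        comms <- as.integer(rownames(s))
        own <- lab[x]
        s_own <- s[match(own, comms)] - B[x, x]
        gains <- s[, 1]
        gains[match(own, comms)] <- s_own
        bi <- which.max(gains)
        if (comms[bi] != own && gains[bi] > s_own + eps) {
          lab[x] <- comms[bi]
          moved <- TRUE
        }
      }
      if (!moved) break
      moved_any <- TRUE
      order0 <- sample.int(NL) # reshuffle between sweeps
    }
    # merge pass: best positive community-pair merge
    comms <- unique(lab)
    merged <- FALSE
    if (length(comms) > 1) {
      members <- split(seq_len(NL), lab)
      nm <- names(members)
      bestgain <- eps; bi <- bj <- 0
      for (a in seq_along(members)) {
        for (b in seq_along(members)) {
          if (b <= a) next
          g <- 2 * sum(B[members[[a]], members[[b]], drop = FALSE])
          if (g > bestgain) { bestgain <- g; bi <- a; bj <- b }
        }
      }
      if (bi > 0) {
        lab[lab == as.integer(nm[bj])] <- as.integer(nm[bi])
        merged <- TRUE
      }
    }
    if (!moved_any && !merged) break
  }
  lab
}

# internal: renumber community labels 0,1,2,... by first appearance,
# scanning layer by layer with nodes in ascending order within a layer
canonicalize_labels <- function(labmat) {
  seen <- unique(as.vector(labmat)) # column-major scan = layer-major
  matrix(match(as.vector(labmat), seen) - 1L,
         nrow(labmat), ncol(labmat))
}

#' Sweep the (gamma, omega) parameter plane
#'
#' Evaluates [multilayer_modularity()] on every grid combination for every
#' network (a network = one list of layers), with seeds shared across
#' combinations so the comparison is paired.  The selected combination is
#' the one attaining the maximum Q on the largest number of networks, ties
#' broken by higher mean Q.
#'
#' @param problems one layer-list, or a list of layer-lists (networks).
#' @param gammas,omegas numeric grids.
#' @param seed integer seed.
#' @param n_restarts restarts per evaluation.
#' @return list with `table` (data.frame: network, gamma, omega, q,
#'   n_communities) and `selected` (named vector gamma, omega).
#' @export
sweep_gamma_omega <- function(problems, gammas, omegas, seed = 1,
                              n_restarts = 10) {
  if (length(gammas) == 0 || length(omegas) == 0) stop("empty grid")
  if (inherits(problems[[1]], "WeightedNet") || is.matrix(problems[[1]]))
    problems <- list(problems)
  rows <- list()
  for (p in seq_along(problems)) {
    for (g in gammas) for (o in omegas) {
      fit <- multilayer_modularity(problems[[p]], gamma = g, omega = o,
                                   seed = seed, n_restarts = n_restarts)
      rows[[length(rows) + 1]] <- data.frame(
        network = p, gamma = g, omega = o, q = fit$q,
        n_communities = fit$n_communities)
    }
  }
  tab <- do.call(rbind, rows)
  # count, per (gamma, omega), how many networks it is optimal for
  key <- paste(tab$gamma, tab$omega)
  wins <- integer(0)
  for (p in seq_along(problems)) {
    sub <- tab[tab$network == p, ]
    top <- sub$q >= max(sub$q) - 1e-12
    k <- paste(sub$gamma, sub$omega)[top]
    wins <- c(wins, stats::setNames(rep(1L, sum(top)), k))
  }
  agg <- tapply(wins, names(wins), sum)
  meanq <- tapply(tab$q, key, mean)
  cand <- names(agg)[agg == max(agg)]
  sel <- cand[which.max(meanq[cand])]
  gv <- as.numeric(strsplit(sel, " ")[[1]])
  list(table = tab, selected = c(gamma = gv[1], omega = gv[2]))
}

#' Module allegiance matrix
#'
#' Node x node probability of sharing a community label across layers: the
#' mean over layers of the per-layer co-occurrence indicator.  Entries are
#' exact multiples of 1/n_layers; the diagonal is 1.
#'
#' @param p a `MultilayerPartition` (or a node x layer label matrix).
#' @return an `Allegiance`: `matrix` (N x N in \[0, 1\]) and `n_layers`.
#' @export
allegiance_matrix <- function(p) {
  labs <- if (inherits(p, "MultilayerPartition")) p$labels else as.matrix(p)
  N <- nrow(labs); L <- ncol(labs)
  A <- matrix(0, N, N)
  for (l in seq_len(L))
    A <- A + outer(labs[, l], labs[, l], "==")
  structure(list(matrix = A / L, n_layers = L), class = "Allegiance")
}

#' Recruitment and integration coefficients
#'
#' Recruitment of node i is its mean allegiance with the other nodes of its
#' own predefined region (how well it is recruited to its region; 1 for a
#' singleton region).  Integration is its mean allegiance with nodes of all
#' other regions (how much it is integrated with the rest of the system; 0
#' when there are no other regions).  Self-pairs are excluded.
#'
#' @param a an `Allegiance`.
#' @param parc_labels 0-based predefined region id per node.
#' @return a `RecruitIntegrate` data.frame with columns `node`,
#'   `recruitment`, `integration`.
#' @export
recruit_integrate <- function(a, parc_labels) {
  A <- if (inherits(a, "Allegiance")) a$matrix else as.matrix(a)
  N <- nrow(A)
  parc_labels <- as.integer(parc_labels)
  if (length(parc_labels) != N) stop("every node must be labeled")
  rec <- int <- numeric(N)
  for (i in seq_len(N)) {
    same <- which(parc_labels == parc_labels[i]); same <- setdiff(same, i)
    other <- which(parc_labels != parc_labels[i])
    rec[i] <- if (length(same)) mean(A[i, same]) else 1
    int[i] <- if (length(other)) mean(A[i, other]) else 0
  }
  structure(data.frame(node = seq_len(N) - 1L, recruitment = rec,
                       integration = int),
            class = c("RecruitIntegrate", "data.frame"))
}
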