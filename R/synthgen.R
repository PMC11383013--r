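#' Configuration for a synthetic multi-subject cohort
#'
#' The generator emulates the statistical structure the alignment analysis
#' assumes: a shared group-level signal whose fine-grained vertex topography
#' differs across subjects by unknown orthogonal transformations local to
#' regions (or sub-region patches), additive subject noise, planted modular
#' structure within regions, and an individual trait linearly coupled to each
#' subject's fine-scale topology perturbation.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_timepoints frames per run (>= n_latents).
#' @param n_runs number of runs (>= 2; run 1 is the training run).
#' @param n_regions number of parcellation regions.
#' @param vertices_per_region vertices in each region (scalar or per-region).
#' @param n_latents shared latent sources per region.
#' @param noise_sd standard deviation of additive subject noise (>= 0).
#' @param rotation_scope `"region"` (one rotation per subject x region) or
#'   `"searchlight"` (one rotation per subject x sub-region spatial patch of
#'   extent ~`searchlight_radius`).
#' @param searchlight_radius spatial patch extent for searchlight-scope
#'   rotations, in grid units (grid spacing is 1).
#' @param planted_modules_per_region planted modules within each region (>= 1).
#' @param trait_effect_size coupling strength between the subject topology
#'   perturbation and the trait; 0 disables the perturbation entirely, giving
#'   a pure alignment benchmark with exactly shared representational geometry.
#' @param rotation_strength amount of misalignment. `Inf` (default) draws
#'   rotations uniformly from the orthogonal group; a finite value `tau`
#'   draws partial rotations (Cayley transform of a skew-symmetric matrix
#'   with entry sd `tau`), approaching the identity as `tau -> 0`.  Finite
#'   values emulate the residual local misalignment left after anatomical
#'   surface registration, which is the baseline condition alignment is
#'   compared against.
#' @param seed master seed; all streams are derived from it.
#' @return a `SynthConfig` object.
#' @export
synth_config <- function(n_subjects = 8, n_timepoints = 200, n_runs = 2,
                         n_regions = 4, vertices_per_region = 20,
                         n_latents = 6, noise_sd = 0.5,
                         rotation_scope = c("region", "searchlight"),
                         searchlight_radius = 2,
                         planted_modules_per_region = 2,
                         trait_effect_size = 1, rotation_strength = Inf,
                         seed = 1) {
  rotation_scope <- match.arg(rotation_scope)
  vpr <- rep_len(as.integer(vertices_per_region), n_regions)
  stopifnot(n_subjects >= 2, n_runs >= 1, n_regions >= 1,
            all(vpr >= 1), planted_modules_per_region >= 1,
            searchlight_radius > 0)
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (n_latents > min(vpr)) stop("n_latents must not exceed vertices_per_region")
  if (n_timepoints < n_latents) stop("n_timepoints must be >= n_latents")
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_timepoints = as.integer(n_timepoints),
    n_runs = as.integer(n_runs),
    n_regions = as.integer(n_regions),
    vertices_per_region = vpr,
    n_latents = as.integer(n_latents),
    noise_sd = noise_sd,
    rotation_scope = rotation_scope,
    searchlight_radius = searchlight_radius,
    planted_modules_per_region = as.integer(planted_modules_per_region),
    trait_effect_size = trait_effect_size,
    rotation_strength = rotation_strength,
    seed = as.integer(seed)
  ), class = "SynthConfig")
}

#' Random orthogonal matrix (Haar measure)
#'
#' QR decomposition of a Gaussian matrix with the sign of R's diagonal fixed,
#' giving a draw uniform over the full orthogonal group O(k); reflections are
#' allowed (the Procrustes solver handles them).
#'
#' @param k dimension.
#' @return k x k orthogonal matrix.
#' @export
random_orthogonal <- function(k) {
  if (k == 1) return(matrix(sample(c(-1, 1), 1), 1, 1))
  qrd <- qr(matrix(stats::rnorm(k * k), k, k))
  Q <- qr.Q(qrd)
  d <- sign(diag(qr.R(qrd)))
  d[d == 0] <- 1
  Q %*% diag(d)
}

#' Random partial rotation (Cayley transform)
#'
#' `R = (I - S/2)^-1 (I + S/2)` for a skew-symmetric `S` with Gaussian
#' entries of sd `tau`: exactly orthogonal (no reflections), approaching the
#' identity as `tau -> 0` and broad rotations as `tau` grows.
#'
#' @param k dimension.
#' @param tau misalignment strength (> 0); `Inf` falls back to
#'   [random_orthogonal()].
#' @return k x k orthogonal matrix.
#' @export
random_partial_rotation <- function(k, tau) {
  if (!is.finite(tau)) return(random_orthogonal(k))
  if (k == 1) return(matrix(1, 1, 1))
  G <- matrix(stats::rnorm(k * k, sd = tau), k, k)
  S <- (G - t(G)) / 2
  solve(diag(k) - S / 2, diag(k) + S / 2)
}

# internal: vertex layout on a unit-spaced planar grid, regions spatially
# contiguous and separated by wide gaps so Euclidean searchlights never span
# region boundaries at realistic radii.
synth_geometry <- function(vpr, gap = 50) {
  coords <- NULL
  offset <- 0
  for (r in seq_along(vpr)) {
    v <- vpr[r]
    ncols <- ceiling(sqrt(v))
    j <- seq_len(v) - 1
    coords <- rbind(coords, cbind(offset + (j %% ncols), j %/% ncols, 0))
    offset <- offset + ncols + gap
  }
  data.frame(vertex = seq_len(nrow(coords)) - 1L,
             x = coords[, 1], y = coords[, 2], z = coords[, 3])
}

# internal: partition a region's vertices (local indices) into spatial patches
# of x-extent <= radius, used as rotation scope units for scope="searchlight".
synth_patches <- function(v, radius) {
  ncols <- ceiling(sqrt(v))
  j <- seq_len(v) - 1
  col <- j %% ncols
  width <- max(1, floor(radius))
  split(seq_len(v), col %/% width)
}

#' Generate a synthetic multi-subject cohort with known ground truth
#'
#' For each region a block of `n_latents` unit-variance latent sources is
#' mixed into vertex patterns whose block structure follows the planted module
#' labels; subject `s` observes `template %*% R_s + noise` where `R_s` is a
#' random orthogonal matrix drawn per scope unit (region or spatial patch).
#' Runs share rotations but redraw latent series and noise.  When
#' `trait_effect_size != 0`, each subject's within-module mixing weights are
#' modulated by a subject-specific factor and the trait is a noisy linear
#' readout of those factors, so fine-scale topology is genuinely predictive.
#' Fully deterministic given `cfg$seed`; each (subject, run, purpose) draws
#' from its own derived stream, so extending the cohort never perturbs
#' existing subjects.
#'
#' @param cfg a [synth_config()].
#' @param identity_rotations debug flag: force every rotation to the identity.
#' @return a list with elements `timeseries` (list over subjects of lists over
#'   runs of `TimeseriesMatrix`), `parcellation`, `geometry`, and `truth`
#'   (rotations, planted labels, trait, template time series, module
#'   multipliers).
#' @export
generate_cohort <- function(cfg, identity_rotations = FALSE) {
  stopifnot(inherits(cfg, "SynthConfig"))
  vpr <- cfg$vertices_per_region
  P <- cfg$n_regions
  V <- sum(vpr)
  Tt <- cfg$n_timepoints
  K <- cfg$n_latents
  M <- cfg$planted_modules_per_region
  S <- cfg$n_subjects
  seed <- cfg$seed
  perturb_sd <- 0.3 # multiplier sd of the subject topology perturbation

  region_of <- rep.int(seq_len(P) - 1L, vpr) # 0-based region labels
  col_start <- c(0L, cumsum(vpr))            # global column offsets

  geometry <- synth_geometry(vpr)

  # planted modules: contiguous near-equal groups within each region,
  # globally unique 0-based ids
  planted_labels <- integer(V)
  module_verts <- vector("list", P) # [[r]] = list of local index vectors
  for (r in seq_len(P)) {
    grp <- sort(rep_len(seq_len(M), vpr[r]))
    planted_labels[col_start[r] + seq_len(vpr[r])] <- (r - 1L) * M + grp - 1L
    module_verts[[r]] <- split(seq_len(vpr[r]), grp)
  }

  # cohort-level mixing weights and trait loadings (shared by all subjects)
  W <- vector("list", P)
  lambda <- numeric(P)
  for (r in seq_len(P)) {
    with_seed(substream_seed(seed, 4L, r), {
      w <- matrix(stats::rnorm(K * vpr[r], sd = 0.3), K, vpr[r])
      for (m in seq_len(M)) {
        lat <- ((m - 1L) %% K) + 1L
        w[lat, module_verts[[r]][[m]]] <- w[lat, module_verts[[r]][[m]]] + 1
      }
      W[[r]] <- w
      lambda[r] <- stats::rnorm(1)
    })
  }

  # rotation scope units per region
  scope_units <- lapply(seq_len(P), function(r) {
    if (cfg$rotation_scope == "region") list(seq_len(vpr[r]))
    else synth_patches(vpr[r], cfg$searchlight_radius)
  })

  # per-subject rotations and topology perturbations
  rotations <- vector("list", S)
  mult <- vector("list", S) # [[s]] P x M multiplier matrix
  trait <- numeric(S)
  for (s in seq_len(S)) {
    rotations[[s]] <- vector("list", P)
    for (r in seq_len(P)) {
      units <- scope_units[[r]]
      rotations[[s]][[r]] <- lapply(seq_along(units), function(u) {
        k <- length(units[[u]])
        if (identity_rotations) diag(k)
        else with_seed(substream_seed(seed, 2L, s, r, u),
                       random_partial_rotation(k, cfg$rotation_strength))
      })
    }
    # antisymmetric within-region modulation: module m scaled by
    # 1 + delta_r * sign_m with alternating signs, so the unordered spectrum
    # of a region's data carries no trait sign — only the spatial (vertex-
    # identified) topography does, which is what alignment restores
    dm <- matrix(1, P, M)
    delta <- numeric(P)
    if (cfg$trait_effect_size != 0) {
      for (r in seq_len(P)) {
        delta[r] <- with_seed(substream_seed(seed, 5L, s, r),
                              stats::rnorm(1, sd = perturb_sd))
        sgn <- rep_len(c(1, -1), M)
        dm[r, ] <- pmax(0.1, 1 + delta[r] * sgn)
      }
    }
    mult[[s]] <- dm
    raw <- sum(delta * lambda)
    sd_theory <- perturb_sd * sqrt(sum(lambda^2))
    noise_t <- with_seed(substream_seed(seed, 6L, s), stats::rnorm(1))
    trait[s] <- cfg$trait_effect_size * raw / sd_theory + noise_t
  }

  # latent series per (region, run), shared across subjects
  latents <- lapply(seq_len(cfg$n_runs), function(run) {
    lapply(seq_len(P), function(r) {
      with_seed(substream_seed(seed, 1L, r, run),
                matrix(stats::rnorm(Tt * K), Tt, K))
    })
  })

  template_ts <- lapply(seq_len(cfg$n_runs), function(run) {
    do.call(cbind, lapply(seq_len(P), function(r) latents[[run]][[r]] %*% W[[r]]))
  })

  timeseries <- vector("list", S)
  for (s in seq_len(S)) {
    timeseries[[s]] <- vector("list", cfg$n_runs)
    for (run in seq_len(cfg$n_runs)) {
      D <- matrix(0, Tt, V)
      for (r in seq_len(P)) {
        Ws <- W[[r]]
        for (m in seq_len(M)) {
          vm <- module_verts[[r]][[m]]
          Ws[, vm] <- Ws[, vm] * mult[[s]][r, m]
        }
        block <- latents[[run]][[r]] %*% Ws
        units <- scope_units[[r]]
        for (u in seq_along(units)) {
          idx <- units[[u]]
          block[, idx] <- block[, idx] %*% rotations[[s]][[r]][[u]]
        }
        D[, col_start[r] + seq_len(vpr[r])] <- block
      }
      if (cfg$noise_sd > 0) {
        D <- D + with_seed(substream_seed(seed, 3L, s, run),
                           matrix(stats::rnorm(Tt * V, sd = cfg$noise_sd), Tt, V))
      }
      timeseries[[s]][[run]] <- timeseries_matrix(D, subject_id = s, run_id = run)
    }
  }

  parc <- parcellation(labels = region_of,
                       region_names = paste0("R", seq_len(P) - 1L))

  list(
    timeseries = timeseries,
    parcellation = parc,
    geometry = geometry,
    truth = structure(list(
      rotations = rotations,
      planted_labels = planted_labels,
      trait = trait,
      template_timeseries = template_ts,
      module_multipliers = mult,
      trait_loadings = lambda,
      scope_units = scope_units
    ), class = "SynthTruth")
  )
}

#' Planted-partition random graph
#'
#' Symmetric 0/1 adjacency with zero diagonal; an edge is present within a
#' module with probability `p_in` and between modules with probability
#' `p_out`.  Modules are contiguous, near-equal blocks of node indices.
#'
#' @param n_nodes number of nodes.
#' @param n_modules number of planted modules.
#' @param p_in,p_out within/between edge probabilities, `0 <= p_out < p_in <= 1`.
#' @param seed integer seed.
#' @return a `BinaryGraph` (see [threshold_density()]) with an extra
#'   `modules` field holding the planted labels (0-based).
#' @export
planted_partition_graph <- function(n_nodes, n_modules, p_in, p_out, seed) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1))
    stop("require 0 <= p_out < p_in <= 1")
  labels <- sort(rep_len(seq_len(n_modules), n_nodes)) - 1L
  A <- matrix(0L, n_nodes, n_nodes)
  with_seed(seed, {
    for (i in seq_len(n_nodes - 1)) {
      for (j in (i + 1):n_nodes) {
        p <- if (labels[i] == labels[j]) p_in else p_out
        if (stats::runif(1) < p) A[i, j] <- A[j, i] <- 1L
      }
    }
  })
  structure(list(
    adjacency = A,
    density = sum(A) / (n_nodes * (n_nodes - 1)),
    node_ids = seq_len(n_nodes) - 1L,
    modules = labels
  ), class = "BinaryGraph")
}
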