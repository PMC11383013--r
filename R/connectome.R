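#' Construct a TimeseriesMatrix
#'
#' One subject/run's time x vertex data matrix, the raw input to everything
#' downstream.
#'
#' @param data numeric time x vertex matrix without missing values.
#' @param subject_id,run_id identifiers.
#' @param vertex_ids ordered 0-based vertex ids (default `0:(V-1)`).
#' @return a `TimeseriesMatrix`.
#' @export
timeseries_matrix <- function(data, subject_id, run_id,
                              vertex_ids = seq_len(ncol(data)) - 1L) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("time series contains missing values")
  vertex_ids <- as.integer(vertex_ids)
  if (anyDuplicated(vertex_ids) || is.unsorted(vertex_ids))
    stop("vertex_ids must be unique and sorted ascending")
  if (length(vertex_ids) != ncol(data))
    stop("vertex_ids length must match data columns")
  structure(list(data = data, subject_id = subject_id, run_id = run_id,
                 vertex_ids = vertex_ids),
            class = "TimeseriesMatrix")
}

#' Construct a Parcellation
#'
#' @param labels 0-based region id per vertex.
#' @param region_names optional region names.
#' @param network_of_region optional region -> network id map (for grouping
#'   analyses such as network-level participation).
#' @return a `Parcellation`.
#' @export
parcellation <- function(labels, region_names = NULL, network_of_region = NULL) {
  labels <- as.integer(labels)
  P <- max(labels) + 1L
  counts <- tabulate(labels + 1L, nbins = P)
  if (any(counts == 0))
    stop("empty region(s): ", paste(which(counts == 0) - 1L, collapse = ", "))
  if (is.null(region_names)) region_names <- paste0("R", seq_len(P) - 1L)
  structure(list(labels = labels, region_names = region_names,
                 network_of_region = network_of_region, n_regions = P),
            class = "Parcellation")
}

# internal: local (1-based) column indices of region r (0-based id)
region_cols <- function(parc, r) which(parc$labels == r)

#' Parcel-averaged connectivity targets
#'
#' The target matrix holds, per region, the average time series over that
#' region's vertices.
#'
#' @param ts a [timeseries_matrix()].
#' @param parc a [parcellation()].
#' @return a `ConnectivityTargets` with a time x P `matrix` field.
#' @export
make_targets <- function(ts, parc) {
  stopifnot(inherits(ts, "TimeseriesMatrix"), inherits(parc, "Parcellation"))
  if (length(parc$labels) != ncol(ts$data))
    stop("parcellation covers ", length(parc$labels),
         " vertices but time series has ", ncol(ts$data))
  P <- parc$n_regions
  Tm <- matrix(0, nrow(ts$data), P)
  for (r in seq_len(P) - 1L) {
    idx <- region_cols(parc, r)
    if (length(idx) == 0) stop("region ", r, " has no vertices in the time series")
    Tm[, r + 1L] <- rowMeans(ts$data[, idx, drop = FALSE])
  }
  structure(list(matrix = Tm), class = "ConnectivityTargets")
}

#' Per-subject connectome against connectivity targets
#'
#' Entry (r, v) is the Pearson correlation between target column r and vertex
#' column v.  Each column of the result is a vertex's "connectivity profile"
#' (length P), each row a target's "connectivity pattern".  With
#' `zscore = TRUE` each profile is standardized to mean 0 and unit
#' (population) variance, the form the hyperalignment stage consumes.
#' Zero-variance series give correlation 0 with a warning.
#'
#' @param ts a [timeseries_matrix()].
#' @param targets a [make_targets()] result (time dimension must match).
#' @param zscore standardize connectivity profiles.
#' @return a `Connectome`.
#' @export
make_connectome <- function(ts, targets, zscore = TRUE) {
  stopifnot(inherits(ts, "TimeseriesMatrix"))
  Tm <- if (inherits(targets, "ConnectivityTargets")) targets$matrix else as.matrix(targets)
  if (nrow(Tm) != nrow(ts$data))
    stop("targets and time series have different numbers of timepoints")
  C <- cor_guarded(Tm, ts$data)
  if (zscore) C <- zscore_cols(C, warn = FALSE)
  structure(list(matrix = C, profiles_zscored = zscore,
                 subject_id = ts$subject_id, run_id = ts$run_id),
            class = "Connectome")
}

#' Inter-subject correlation (ISC) of connectivity profiles
#'
#' For every vertex, the Pearson correlation between that vertex's P-length
#' connectivity profiles is averaged over all S(S-1)/2 subject pairs.  Higher
#' values reflect lower inter-subject variability; the quantity the alignment
#' stage is validated on.  Also returns, per subject, the mean ISC of that
#' subject against all others averaged over vertices (for subject-level
#' scatter analyses).
#'
#' @param connectomes list of `Connectome`s of identical shape (>= 2).
#' @return list with `per_vertex` (numeric V), `per_subject` (numeric S) and
#'   `mean` (scalar).
#' @export
isc_profiles <- function(connectomes) {
  if (length(connectomes) < 2) stop("need at least 2 subjects")
  mats <- lapply(connectomes, function(cc)
    if (inherits(cc, "Connectome")) cc$matrix else as.matrix(cc))
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("connectomes must have identical shapes")
  S <- length(mats)
  V <- ncol(mats[[1]])
  P <- nrow(mats[[1]])
  # standardize each profile once; pairwise correlation is then a dot product
  zs <- lapply(mats, function(m) zscore_cols(m, warn = FALSE))
  per_vertex <- numeric(V)
  pair_subject <- matrix(0, S, V) # row s: sum over pairs involving s
  for (a in seq_len(S - 1)) {
    for (b in (a + 1):S) {
      rv <- colSums(zs[[a]] * zs[[b]]) / P
      per_vertex <- per_vertex + rv
      pair_subject[a, ] <- pair_subject[a, ] + rv
      pair_subject[b, ] <- pair_subject[b, ] + rv
    }
  }
  n_pairs <- S * (S - 1) / 2
  list(per_vertex = per_vertex / n_pairs,
       per_subject = rowMeans(pair_subject) / (S - 1),
       mean = mean(per_vertex) / n_pairs)
}
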