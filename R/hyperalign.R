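#' Orthogonal Procrustes solution
#'
#' Returns the orthogonal matrix R minimizing ||source R - target||_F, via the
#' singular value decomposition of source' target (R = U V').  Reflections are
#' permitted; no scaling or translation is applied (scale is handled by the
#' surrounding z-scoring conventions).
#'
#' @param source,target n x k matrices of equal shape.
#' @return k x k orthogonal matrix.
#' @export
procrustes <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (!all(dim(source) == dim(target))) stop("source/target shape mismatch")
  s <- svd(crossprod(source, target))
  s$u %*% t(s$v)
}

#' Fit a common template across subjects
#'
#' Three-pass scheme (standard two-level hyperalignment ordering): pass 1
#' initializes with subject 1 and, for s = 2..S, aligns subject s to the
#' running mean of aligned predecessors and updates the mean; pass 2 realigns
#' every subject to the pass-1 mean and averages; pass 3 repeats pass 2 on
#' the refined mean.  The template is column-centered and scaled to unit
#' root-mean-square as a whole; this normalization is equivariant under the
#' template's orthogonal gauge freedom, so templates fit under different
#' subject orders agree up to an orthogonal transform.
#'
#' @param stack list of n x k matrices, one per subject (>= 2).
#' @return n x k template matrix.
#' @export
fit_template <- function(stack) {
  S <- length(stack)
  if (S < 2) stop("need at least 2 subjects")
  stack <- lapply(stack, as.matrix)
  d <- dim(stack[[1]])
  if (!all(vapply(stack, function(x) all(dim(x) == d), logical(1))))
    stop("all subjects must have equal shapes")

  tmpl <- stack[[1]]
  for (s in 2:S) {
    aligned <- stack[[s]] %*% procrustes(stack[[s]], tmpl)
    tmpl <- (tmpl * (s - 1) + aligned) / s
  }
  for (pass in 2:3) {
    aligned <- lapply(stack, function(x) x %*% procrustes(x, tmpl))
    tmpl <- Reduce(`+`, aligned) / S
  }
  tmpl <- sweep(tmpl, 2, colMeans(tmpl), "-")
  rms <- sqrt(mean(tmpl^2))
  if (rms > 0) tmpl <- tmpl / rms
  tmpl
}

#' ROI-wise connectivity hyperalignment (rCHA)
#'
#' For each region independently, fits a common template over the region's
#' connectivity-profile columns across subjects, solves one Procrustes
#' transform per subject, and assembles the per-region transforms into a
#' block-diagonal whole-cortex mapper per subject.  Mappers never mix
#' vertices across regions.
#'
#' @param connectomes list of z-scored `Connectome`s (one per subject).
#' @param parc a [parcellation()].
#' @return list of `Mapper`s (sparse V x V matrix, kind `"roi"`), one per
#'   subject, in input order.
#' @export
fit_rcha <- function(connectomes, parc) {
  stopifnot(inherits(parc, "Parcellation"))
  mats <- lapply(connectomes, function(cc) cc$matrix)
  S <- length(mats)
  V <- ncol(mats[[1]])
  trip <- lapply(seq_len(S), function(s) list(i = integer(0), j = integer(0), x = numeric(0)))
  for (r in seq_len(parc$n_regions) - 1L) {
    idx <- region_cols(parc, r)
    stack <- lapply(mats, function(m) m[, idx, drop = FALSE])
    tmpl <- fit_template(stack)
    ij <- expand.grid(i = idx, j = idx)
    for (s in seq_len(S)) {
      R <- procrustes(stack[[s]], tmpl)
      trip[[s]]$i <- c(trip[[s]]$i, ij$i)
      trip[[s]]$j <- c(trip[[s]]$j, ij$j)
      trip[[s]]$x <- c(trip[[s]]$x, as.numeric(R))
    }
  }
  lapply(seq_len(S), function(s) {
    structure(list(
      subject_id = connectomes[[s]]$subject_id,
      matrix = Matrix::sparseMatrix(i = trip[[s]]$i, j = trip[[s]]$j,
                                    x = trip[[s]]$x, dims = c(V, V)),
      kind = "roi"
    ), class = "Mapper")
  })
}

#' Build Euclidean searchlights
#'
#' One searchlight per vertex; members are all vertices within `radius` of
#' the center (Euclidean distance over the supplied coordinates), in
#' ascending vertex order.
#'
#' @param geom data.frame with columns `vertex` (0-based), `x`, `y`, `z`.
#' @param radius searchlight radius (> 0), same units as the coordinates.
#' @return list of searchlights, each `list(center =, members =)` with 0-based
#'   vertex ids.
#' @export
build_searchlights <- function(geom, radius) {
  if (radius <= 0) stop("radius must be > 0")
  xyz <- as.matrix(geom[, c("x", "y", "z")])
  V <- nrow(xyz)
  lapply(seq_len(V), function(v) {
    d2 <- (xyz[, 1] - xyz[v, 1])^2 + (xyz[, 2] - xyz[v, 2])^2 + (xyz[, 3] - xyz[v, 3])^2
    list(center = geom$vertex[v],
         members = geom$vertex[which(d2 <= radius^2)])
  })
}

#' Searchlight connectivity hyperalignment (sCHA)
#'
#' Per searchlight, fits a template and per-subject Procrustes transform on
#' the member columns of the z-scored connectomes; each local transform's
#' entries are added into the subject's whole-cortex sparse mapper at the
#' member vertex pairs (overlapping searchlights sum).  Because the plain sum
#' scales columns by their overlap count, mapped data must be re-z-scored per
#' vertex after application ([apply_mapper()] with `rezscore = TRUE`).
#'
#' @param connectomes list of z-scored `Connectome`s.
#' @param searchlights from [build_searchlights()].
#' @return list of `Mapper`s (kind `"searchlight"`), one per subject.
#' @export
fit_scha <- function(connectomes, searchlights) {
  mats <- lapply(connectomes, function(cc) cc$matrix)
  S <- length(mats)
  V <- ncol(mats[[1]])
  trip <- lapply(seq_len(S), function(s) list(i = list(), j = list(), x = list()))
  for (sl in searchlights) {
    idx <- sl$members + 1L # to 1-based columns
    stack <- lapply(mats, function(m) m[, idx, drop = FALSE])
    tmpl <- fit_template(stack)
    ij <- expand.grid(i = idx, j = idx)
    for (s in seq_len(S)) {
      R <- procrustes(stack[[s]], tmpl)
      n <- length(trip[[s]]$i)
      trip[[s]]$i[[n + 1]] <- ij$i
      trip[[s]]$j[[n + 1]] <- ij$j
      trip[[s]]$x[[n + 1]] <- as.numeric(R)
    }
  }
  lapply(seq_len(S), function(s) {
    structure(list(
      subject_id = connectomes[[s]]$subject_id,
      matrix = Matrix::sparseMatrix(i = unlist(trip[[s]]$i),
                                    j = unlist(trip[[s]]$j),
                                    x = unlist(trip[[s]]$x),
                                    dims = c(V, V)), # repeated entries sum
      kind = "searchlight"
    ), class = "Mapper")
  })
}

#' Apply a mapper to data in vertex space
#'
#' Projects `data` (any matrix with V columns: a time series, or a connectome
#' with targets as rows) into the common space as `data %*% mapper`.  With
#' `rezscore = TRUE` columns are standardized afterwards, which removes the
#' overlap-count scaling of searchlight mappers.
#'
#' @param m a `Mapper`.
#' @param data matrix with V columns (or a `TimeseriesMatrix` / `Connectome`,
#'   returned with the mapped matrix in place).
#' @param rezscore standardize columns after mapping.
#' @return object of the same kind as `data`.
#' @export
apply_mapper <- function(m, data, rezscore = TRUE) {
  stopifnot(inherits(m, "Mapper"))
  if (inherits(data, "TimeseriesMatrix")) {
    data$data <- apply_mapper(m, data$data, rezscore)
    return(data)
  }
  if (inherits(data, "Connectome")) {
    data$matrix <- apply_mapper(m, data$matrix, rezscore)
    data$profiles_zscored <- rezscore
    return(data)
  }
  data <- as.matrix(data)
  if (ncol(data) != nrow(m$matrix))
    stop("data has ", ncol(data), " columns but mapper expects ", nrow(m$matrix))
  out <- as.matrix(data %*% m$matrix)
  if (rezscore) out <- zscore_cols(out, warn = FALSE)
  out
}
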