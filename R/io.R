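#' Write named dense matrices to a text container
#'
#' Plain-text container holding one or more named arrays.  Each array starts
#' with a header line `@array <name> <nrow> <ncol>` followed by `nrow` lines
#' of tab-separated values printed with 17 significant digits, which
#' round-trips IEEE doubles bit-identically.  All indices in companion files
#' are 0-based.
#'
#' @param x named list of numeric matrices (a bare matrix is wrapped as
#'   `list(matrix = x)`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dense <- function(x, path) {
  if (is.matrix(x)) x <- list(matrix = x)
  stopifnot(is.list(x), length(names(x)) == length(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# chanet dense-matrix container v1",
               paste("# arrays:", length(x))), con)
  for (nm in names(x)) {
    m <- as.matrix(x[[nm]])
    writeLines(sprintf("@array %s %d %d", nm, nrow(m), ncol(m)), con)
    writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t")), con)
  }
  invisible(path)
}

#' Read a dense-matrix container written by [write_dense()]
#'
#' @param path input file.
#' @return named list of matrices.
#' @export
read_dense <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "# chanet dense-matrix container"))
    stop("malformed header in ", path)
  heads <- grep("^@array ", lines)
  if (length(heads) == 0) stop("no arrays in ", path)
  out <- list()
  for (h in heads) {
    parts <- strsplit(lines[h], " ")[[1]]
    if (length(parts) != 4) stop("malformed array header: ", lines[h])
    nr <- as.integer(parts[3]); nc <- as.integer(parts[4])
    body <- lines[h + seq_len(nr)]
    vals <- scan(text = body, quiet = TRUE)
    if (length(vals) != nr * nc)
      stop("dimension mismatch for array ", parts[2], ": expected ",
           nr * nc, " values, got ", length(vals))
    out[[parts[2]]] <- matrix(vals, nr, nc, byrow = TRUE)
  }
  out
}

#' Write / read a parcellation label file
#'
#' Tab-separated `vertex_index<TAB>region_id`, both 0-based, one line per
#' vertex, vertices consecutive from 0.
#'
#' @param parc a [parcellation()].
#' @param path file path.
#' @return `path` invisibly (write); a `Parcellation` (read).
#' @export
write_parcellation <- function(parc, path) {
  utils::write.table(
    data.frame(vertex = seq_along(parc$labels) - 1L, region = parc$labels),
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  tab <- utils::read.table(path, sep = "\t",
                           col.names = c("vertex", "region"))
  expect <- seq_len(nrow(tab)) - 1L
  gap <- which(tab$vertex != expect)
  if (length(gap))
    stop("parcellation file has a gap at vertex ", expect[gap[1]])
  parcellation(tab$region)
}

#' Write / read a vertex coordinate file
#'
#' Tab-separated `vertex_index<TAB>x<TAB>y<TAB>z`, vertex 0-based.
#'
#' @param geom data.frame with columns vertex, x, y, z.
#' @param path file path.
#' @return `path` invisibly (write); the geometry data.frame (read).
#' @export
write_coordinates <- function(geom, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d\t%.17g\t%.17g\t%.17g",
                     geom$vertex, geom$x, geom$y, geom$z), con)
  invisible(path)
}

#' @rdname write_coordinates
#' @export
read_coordinates <- function(path) {
  utils::read.table(path, sep = "\t", col.names = c("vertex", "x", "y", "z"))
}

#' Write / read a mapper as sparse triplets
#'
#' Header comments name the subject and mapper kind; body lines are
#' `row<TAB>col<TAB>value` with 0-based indices.
#'
#' @param m a `Mapper`.
#' @param path file path.
#' @param radius optional searchlight radius recorded in the header.
#' @return `path` invisibly (write); a `Mapper` (read).
#' @export
write_mapper <- function(m, path, radius = NA) {
  tm <- methods::as(m$matrix, "TsparseMatrix")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# chanet mapper subject=%s kind=%s radius=%s dim=%d",
                       m$subject_id, m$kind, radius, nrow(m$matrix))), con)
  writeLines(sprintf("%d\t%d\t%.17g", tm@i, tm@j, tm@x), con)
  invisible(path)
}

#' @rdname write_mapper
#' @export
read_mapper <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# chanet mapper ", lines[1])) stop("malformed mapper header")
  fields <- regmatches(lines[1], gregexpr("[a-z]+=[^ ]+", lines[1]))[[1]]
  kv <- do.call(rbind, strsplit(fields, "="))
  meta <- stats::setNames(kv[, 2], kv[, 1])
  V <- as.integer(meta["dim"])
  body <- lines[-1]
  trip <- utils::read.table(text = body, sep = "\t",
                            col.names = c("i", "j", "x"))
  structure(list(
    subject_id = meta[["subject"]],
    matrix = Matrix::sparseMatrix(i = trip$i + 1L, j = trip$j + 1L,
                                  x = trip$x, dims = c(V, V)),
    kind = meta[["kind"]]
  ), class = "Mapper")
}

#' Adapter stub for real dense-timeseries neuroimaging files
#'
#' The pipeline consumes plain time x vertex matrices; an adapter for real
#' surface-sampled neuroimaging containers is specified here as an interface
#' point but is not shipped.
#'
#' @param path ignored.
#' @export
read_neuroimaging_timeseries <- function(path) {
  stop("adapter not installed: supply time x vertex matrices via ",
       "timeseries_matrix() or the dense-matrix container")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates the study design end to end: generate (or accept) a cohort,
#' build run-1 connectomes, fit mappers per condition (unaligned / ROI CHA /
#' searchlight CHA), project the held-out runs, and compute the validation
#' ISC, multilayer modularity of one region's fine networks, and the ridge
#' prediction MSE per condition.  All artifacts are written under `out_dir`
#' together with a manifest of files, stages and checksums; rerunning the
#' same config reproduces the checksums.
#'
#' @param cfg a [synth_config()] (or a list with element `synth` holding
#'   one), plus optional elements `radius` (searchlight radius, default 6),
#'   `density` (default 0.15), `gamma` (default 1), `omega` (default 0.1),
#'   `alpha` (default 1), `conditions` (default all three).
#' @param out_dir output directory (created).
#' @param cohort optionally, a pre-generated [generate_cohort()] result.
#' @return list with `manifest` (data.frame: file, stage, md5) and `results`
#'   (named list of stage outputs).
#' @export
run_pipeline <- function(cfg, out_dir, cohort = NULL) {
  if (inherits(cfg, "SynthConfig")) cfg <- list(synth = cfg)
  synth <- cfg$synth
  radius <- cfg$radius %||% 6
  density <- cfg$density %||% 0.15
  gamma <- cfg$gamma %||% 1
  omega <- cfg$omega %||% 0.1
  alpha <- cfg$alpha %||% 1
  conditions <- cfg$conditions %||% c("unaligned", "roi_cha", "searchlight_cha")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0); stages <- character(0)
  emit <- function(path, stage) {
    files <<- c(files, path); stages <<- c(stages, stage)
  }

  if (is.null(cohort)) cohort <- generate_cohort(synth)
  parc <- cohort$parcellation
  S <- length(cohort$timeseries)
  n_runs <- length(cohort$timeseries[[1]])
  if (n_runs < 2) stop("pipeline requires at least 2 runs (train + test)")

  f <- file.path(out_dir, "parcellation.tsv")
  write_parcellation(parc, f); emit(f, "synth")
  f <- file.path(out_dir, "coordinates.tsv")
  write_coordinates(cohort$geometry, f); emit(f, "synth")

  train <- lapply(cohort$timeseries, `[[`, 1)
  conn_train <- lapply(train, function(ts)
    make_connectome(ts, make_targets(ts, parc), zscore = TRUE))

  mappers <- list(unaligned = NULL)
  if ("roi_cha" %in% conditions)
    mappers$roi_cha <- fit_rcha(conn_train, parc)
  if ("searchlight_cha" %in% conditions) {
    sls <- build_searchlights(cohort$geometry, radius)
    mappers$searchlight_cha <- fit_scha(conn_train, sls)
  }
  for (cond in setdiff(names(mappers), "unaligned")) {
    for (s in seq_len(S)) {
      f <- file.path(out_dir, sprintf("mapper_%s_s%02d.tsv", cond, s))
      write_mapper(mappers[[cond]][[s]], f, radius = radius)
      emit(f, "hyperalign")
    }
  }

  # validation ISC on held-out run 2 connectomes
  test_ts <- lapply(cohort$timeseries, `[[`, 2)
  conn_test <- lapply(test_ts, function(ts)
    make_connectome(ts, make_targets(ts, parc), zscore = TRUE))
  isc <- list()
  for (cond in conditions) {
    cs <- if (cond == "unaligned") conn_test
          else lapply(seq_len(S), function(s)
            apply_mapper(mappers[[cond]][[s]], conn_test[[s]]))
    isc[[cond]] <- isc_profiles(cs)
  }
  f <- file.path(out_dir, "isc.tsv")
  utils::write.table(
    data.frame(condition = names(isc),
               mean_isc = vapply(isc, `[[`, 0, "mean")),
    f, sep = "\t", row.names = FALSE, quote = FALSE)
  emit(f, "connectome")

  # fine-scale networks of region 0 across subjects -> multilayer Q
  mapped_test <- lapply(conditions, function(cond) {
    if (cond == "unaligned") test_ts
    else lapply(seq_len(S), function(s)
      apply_mapper(mappers[[cond]][[s]], test_ts[[s]]))
  })
  names(mapped_test) <- conditions
  mlq <- vapply(conditions, function(cond) {
    layers <- lapply(mapped_test[[cond]], function(ts)
      suppressWarnings(fine_network(ts, parc, 0L)))
    multilayer_modularity(layers, gamma = gamma, omega = omega,
                          seed = synth$seed, n_restarts = 10)$q
  }, numeric(1))
  f <- file.path(out_dir, "multilayer_q.tsv")
  utils::write.table(data.frame(condition = conditions, q = mlq),
                     f, sep = "\t", row.names = FALSE, quote = FALSE)
  emit(f, "multilayer")

  # prediction: fine local-metric patterns, train run 1, test runs 2..n
  pred <- list()
  for (cond in conditions) {
    ftrain <- pipeline_features(
      if (cond == "unaligned") train
      else lapply(seq_len(S), function(s)
        apply_mapper(mappers[[cond]][[s]], train[[s]])),
      parc, density, seed = synth$seed)
    mses <- numeric(0)
    fit <- suppressWarnings(fit_ridge(ftrain, cohort$truth$trait, alpha = alpha))
    for (run in 2:n_runs) {
      run_ts <- lapply(cohort$timeseries, `[[`, run)
      ftest <- pipeline_features(
        if (cond == "unaligned") run_ts
        else lapply(seq_len(S), function(s)
          apply_mapper(mappers[[cond]][[s]], run_ts[[s]])),
        parc, density, seed = synth$seed)
      mses[as.character(run)] <- evaluate(fit, ftest, cohort$truth$trait)$mse
    }
    pred[[cond]] <- mean(mses)
  }
  f <- file.path(out_dir, "prediction_mse.tsv")
  utils::write.table(data.frame(condition = names(pred),
                                mse = unlist(pred)),
                     f, sep = "\t", row.names = FALSE, quote = FALSE)
  emit(f, "predict")

  manifest <- data.frame(file = basename(files), stage = stages,
                         md5 = unname(tools::md5sum(files)))
  f <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, f, sep = "\t", row.names = FALSE, quote = FALSE)
  list(manifest = manifest,
       results = list(isc = isc, multilayer_q = mlq, prediction_mse = pred,
                      mappers = mappers))
}

# internal: concatenated fine-scale local-metric patterns (degree and nodal
# clustering per vertex, all regions) used as prediction features
pipeline_features <- function(ts_list, parc, density, seed = 1) {
  feats <- lapply(seq_len(parc$n_regions) - 1L, function(r) {
    cbind(metric_pattern(ts_list, parc, "fine_local", "degree",
                         density = density, region = r, seed = seed),
          metric_pattern(ts_list, parc, "fine_local", "clustcoef",
                         density = density, region = r, seed = seed))
  })
  do.call(cbind, feats)
}
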