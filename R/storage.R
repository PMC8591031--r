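# Storage manager: one folder per experiment under Data/, one run_<k>
# sub-folder per run holding arrays (HDF5), parameters and free-form results
# (JSON). Run indices are allocated atomically via dir.create, so concurrent
# callers never collide.

#' Allocate the next run folder of an experiment
#'
#' Creates `Data/<experiment>/run_<k>/` with the smallest free index `k`
#' (starting at 0). Allocation relies on the atomicity of directory
#' creation: if two processes race for the same index, one of them fails and
#' retries with the next, so indices are unique and a run folder is never
#' overwritten.
#'
#' @param experiment experiment name (one folder per experiment).
#' @param root data root (default "Data", the conventional project folder).
#' @return a `run_folder` with fields `experiment`, `index`, `path`.
#' @export
create_run <- function(experiment, root = "Data") {
  exp_dir <- file.path(root, experiment)
  dir.create(exp_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(exp_dir)) stop(sprintf("cannot create '%s'", exp_dir))
  existing <- list.dirs(exp_dir, recursive = FALSE, full.names = FALSE)
  idx <- suppressWarnings(as.integer(sub("^run_", "", existing[grepl("^run_\\d+$", existing)])))
  k <- if (length(idx) == 0) 0L else max(idx) + 1L
  repeat {
    path <- file.path(exp_dir, sprintf("run_%d", k))
    if (!dir.exists(path) && dir.create(path, showWarnings = FALSE)) break
    k <- k + 1L
    if (k > 1e6) stop("run index allocation failed")
  }
  structure(list(experiment = experiment, index = k, path = path, root = root),
            class = "run_folder")
}

#' Open an existing run folder
#'
#' @param experiment experiment name.
#' @param index run index.
#' @param root data root.
#' @return a `run_folder`.
#' @export
open_run <- function(experiment, index, root = "Data") {
  path <- file.path(root, experiment, sprintf("run_%d", index))
  if (!dir.exists(path)) stop(sprintf("run folder '%s' does not exist", path))
  structure(list(experiment = experiment, index = as.integer(index),
                 path = path, root = root),
            class = "run_folder")
}

#' @export
print.run_folder <- function(x, ...) {
  cat(sprintf("<run %s/run_%d at %s>\n", x$experiment, x$index, x$path))
  invisible(x)
}

run_h5 <- function(run) file.path(run$path, "arrays.h5")

#' Save an array into a run folder
#'
#' Vectors and matrices are stored in the run's HDF5 container
#' (`arrays.h5`); [load_array()] returns them bitwise-equal. A
#' `recorder_trace` may be passed directly: vector traces are stacked into a
#' time x neuron matrix, scalar traces into a vector.
#'
#' @param run a `run_folder`.
#' @param name dataset name (filesystem-safe string).
#' @param data numeric vector, matrix, or `recorder_trace`.
#' @export
save_array <- function(run, name, data) {
  stopifnot(inherits(run, "run_folder"))
  if (!grepl("^[A-Za-z0-9._-]+$", name)) {
    stop(sprintf("array name '%s' is not filesystem-safe", name))
  }
  if (inherits(data, "recorder_trace")) {
    data <- if (length(data$values) > 0 && length(data$values[[1]]) > 1) {
      as.matrix(data)
    } else {
      as.numeric(data)
    }
  }
  f <- run_h5(run)
  if (!file.exists(f)) rhdf5::h5createFile(f)
  if (name %in% list_arrays(run)) rhdf5::h5delete(f, name)
  if (length(data) == 0) {
    # zero-length datasets are awkward in HDF5; store a tagged placeholder
    rhdf5::h5write(NA_real_, f, name)
    fid <- rhdf5::H5Fopen(f)
    did <- rhdf5::H5Dopen(fid, name)
    rhdf5::h5writeAttribute(1L, did, "empty")
    rhdf5::H5Dclose(did)
    rhdf5::H5Fclose(fid)
  } else {
    rhdf5::h5write(data, f, name)
  }
  rhdf5::h5closeAll()
  invisible(run)
}

#' Load an array from a run folder
#'
#' @param run a `run_folder`.
#' @param name dataset name.
#' @return the stored vector/matrix, bitwise-equal to what was saved.
#' @export
load_array <- function(run, name) {
  f <- run_h5(run)
  avail <- list_arrays(run)
  if (!name %in% avail) {
    stop(sprintf("run has no array '%s' (available: %s)",
                 name, if (length(avail)) paste(avail, collapse = ", ") else "none"))
  }
  out <- rhdf5::h5read(f, name, read.attributes = TRUE)
  if (isTRUE(attr(out, "empty") == 1)) return(numeric(0))
  d <- dim(out)
  attributes(out) <- NULL
  if (length(d) > 1) dim(out) <- d   # 1-d datasets come back as plain vectors
  out
}

#' List arrays stored in a run
#'
#' @param run a `run_folder`.
#' @return character vector of dataset names.
#' @export
list_arrays <- function(run) {
  f <- run_h5(run)
  if (!file.exists(f)) return(character(0))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5ls(f)$name
}

#' Save run parameters (key -> scalar/string)
#'
#' Parameters round-trip losslessly through JSON (numbers written at full
#' precision).
#'
#' @param run a `run_folder`.
#' @param params named list of scalars/strings.
#' @export
save_parameters <- function(run, params) {
  stopifnot(is.list(params), !is.null(names(params)))
  existing <- load_parameters(run)
  merged <- utils::modifyList(existing, params)
  jsonlite::write_json(merged, file.path(run$path, "parameters.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(run)
}

#' Load run parameters
#'
#' @param run a `run_folder`.
#' @return named list (empty if none saved).
#' @export
load_parameters <- function(run) {
  f <- file.path(run$path, "parameters.json")
  if (!file.exists(f)) return(list())
  jsonlite::read_json(f, simplifyVector = TRUE)
}

#' Save free-form results (key -> scalar)
#'
#' @param run a `run_folder`.
#' @param results named list.
#' @export
save_results <- function(run, results) {
  f <- file.path(run$path, "results.json")
  existing <- if (file.exists(f)) jsonlite::read_json(f, simplifyVector = TRUE) else list()
  merged <- utils::modifyList(existing, results)
  jsonlite::write_json(merged, f, auto_unbox = TRUE, digits = NA)
  invisible(run)
}

#' Load free-form results
#'
#' @param run a `run_folder`.
#' @return named list (empty if none saved).
#' @export
load_results <- function(run) {
  f <- file.path(run$path, "results.json")
  if (!file.exists(f)) return(list())
  jsonlite::read_json(f, simplifyVector = TRUE)
}

#' Compare the runs of an experiment
#'
#' Builds a table with one row per run and one column per requested
#' parameter/result name. Values missing in a run are `NA`, never an error.
#' The table is sorted by the first requested column (runs sort by index when
#' none is given).
#'
#' @param experiment experiment name.
#' @param parameters character vector of parameter/result names to include.
#' @param root data root.
#' @param sort_by column to sort by (default: the first of `parameters`).
#' @return data.frame with a `run` column plus the requested columns.
#' @export
compare_runs <- function(experiment, parameters = character(0),
                         root = "Data", sort_by = NULL) {
  exp_dir <- file.path(root, experiment)
  if (!dir.exists(exp_dir)) stop(sprintf("experiment '%s' has no runs", experiment))
  dirs <- list.dirs(exp_dir, recursive = FALSE, full.names = FALSE)
  idx <- sort(as.integer(sub("^run_", "", dirs[grepl("^run_\\d+$", dirs)])))
  if (length(idx) == 0) stop(sprintf("experiment '%s' has no runs", experiment))
  rows <- lapply(idx, function(k) {
    run <- open_run(experiment, k, root)
    vals <- c(load_parameters(run), load_results(run))
    row <- list(run = k)
    for (p in parameters) {
      v <- vals[[p]]
      row[[p]] <- if (is.null(v)) NA else v
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(sort_by) && length(parameters) > 0) sort_by <- parameters[1]
  if (!is.null(sort_by) && sort_by %in% names(tab)) {
    tab <- tab[order(tab[[sort_by]]), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Export a histogram of a diversified parameter (";plot" hook)
#'
#' The core parses and ignores the ";plot" suffix of diversification
#' strings; this helper realizes it on demand by saving a histogram of a
#' sampled vector as a CSV of bin counts.
#'
#' @param run a `run_folder`.
#' @param name output name.
#' @param values numeric vector.
#' @param breaks passed to [hist()].
#' @export
save_histogram <- function(run, name, values, breaks = 30) {
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  utils::write.csv(data.frame(mid = h$mids, count = h$counts),
                   file.path(run$path, paste0(name, "_hist.csv")),
                   row.names = FALSE)
  invisible(run)
}
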