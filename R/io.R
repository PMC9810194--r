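#' Downsample a time series by an integer factor
#'
#' Keeps every `factor`-th sample starting from the first, so the output
#' length is `ceiling(T / factor)` (e.g. 801 steps at factor 2 give 401).
#'
#' @param series Numeric vector or T x M matrix.
#' @param factor Integer >= 1.
#' @return The downsampled series of the same type.
#' @export
downsample_series <- function(series, factor) {
  check_that(length(factor) == 1L && factor >= 1 && factor == round(factor),
             sprintf("factor must be an integer >= 1, got %s",
                     paste(factor, collapse = ",")))
  factor <- as.integer(factor)
  if (is.matrix(series)) {
    series[seq(1L, nrow(series), by = factor), , drop = FALSE]
  } else {
    series[seq(1L, length(series), by = factor)]
  }
}

#' Downsample every series in a task
#'
#' @param task A [task_data()].
#' @param factor Integer >= 1; the time step is scaled by the same factor.
#' @return The downsampled [task_data()].
#' @export
downsample_task <- function(task, factor) {
  if (factor == 1L) return(task)
  task_data(f_in = downsample_series(task$f_in, factor),
            f_out = downsample_series(task$f_out, factor),
            hint = if (!is.null(task$hint)) downsample_series(task$hint, factor),
            dt = task$dt * factor,
            metadata = c(task$metadata, list(downsample = factor)))
}

#' Write a task to CSV with a JSON sidecar
#'
#' One CSV per series (`f_in.csv`, `f_out.csv`, `hint.csv`; comma-separated,
#' header row, '.' decimal) plus `task.json` carrying dt, seed and the
#' generator parameters.
#'
#' @param task A [task_data()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_task <- function(task, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mat <- function(m, name) {
    df <- as.data.frame(m)
    names(df) <- paste0("ch", seq_len(ncol(m)) - 1L)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  write_mat(task$f_in, "f_in.csv")
  write_mat(task$f_out, "f_out.csv")
  if (!is.null(task$hint)) write_mat(task$hint, "hint.csv")
  jsonlite::write_json(list(dt = task$dt, metadata = task$metadata),
                       file.path(dir, "task.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a task written by [save_task()]
#'
#' @param dir Task directory.
#' @return A [task_data()].
#' @export
load_task <- function(dir) {
  read_mat <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) return(NULL)
    as.matrix(utils::read.csv(p, check.names = FALSE))
  }
  side <- jsonlite::read_json(file.path(dir, "task.json"), simplifyVector = TRUE)
  f_in <- read_mat("f_in.csv")
  if (is.null(f_in)) f_in <- matrix(0, nrow(read_mat("f_out.csv")), 0L)
  task_data(f_in = f_in, f_out = read_mat("f_out.csv"),
            hint = read_mat("hint.csv"), dt = side$dt,
            metadata = as.list(side$metadata))
}

weight_slots <- function(layer) {
  if (inherits(layer, "spiking_layer")) {
    list(w_in = layer$params$w_in, omega0 = layer$params$omega0,
         eta = layer$params$eta, phi = layer$params$phi)
  } else {
    list(w_in = layer$params$w_in, w_R = layer$params$w_R,
         w_out = layer$params$w_out, w_F = layer$params$w_F,
         mask = layer$params$mask * 1)
  }
}

#' Serialize a layer's weight matrices
#'
#' `format = "csv"` writes one dense CSV per matrix plus a `weights.json`
#' manifest; `format = "h5"` writes a single HDF5 container with datasets
#' named after the matrices (`w_in`, `w_R`, `w_out`, `w_F`, `mask`; spiking
#' layers: `w_in`, `omega0`, `eta`, `phi`).
#'
#' @param layer A `rate_layer` or `spiking_layer`.
#' @param path Directory (csv) or file path (h5).
#' @param format `"csv"` or `"h5"` (the latter requires the rhdf5 package).
#' @return `path`, invisibly.
#' @export
save_weights <- function(layer, path, format = c("csv", "h5")) {
  format <- match.arg(format)
  slots <- weight_slots(layer)
  if (format == "csv") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(slots)) {
      utils::write.table(slots[[nm]], file.path(path, paste0(nm, ".csv")),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
    meta <- layer$params[setdiff(names(layer$params),
                                 c(names(slots), "act", "filt", "constants"))]
    meta$constants <- layer$params$constants
    jsonlite::write_json(list(class = class(layer)[1], params = meta),
                         file.path(path, "weights.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    check_that(requireNamespace("rhdf5", quietly = TRUE),
               "the h5 format requires the rhdf5 package")
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    for (nm in names(slots)) rhdf5::h5write(slots[[nm]], path, nm)
    rhdf5::H5close()
  }
  invisible(path)
}

#' Read weight matrices written by [save_weights()]
#'
#' @param path Directory (csv bundle) or .h5 file.
#' @return Named list of matrices.
#' @export
load_weights <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.csv$")
    out <- lapply(files, function(f) {
      as.matrix(utils::read.table(file.path(path, f), sep = ","))
    })
    names(out) <- sub("\\.csv$", "", files)
    out <- lapply(out, unname)
  } else {
    check_that(requireNamespace("rhdf5", quietly = TRUE),
               "reading .h5 requires the rhdf5 package")
    nms <- rhdf5::h5ls(path)$name
    out <- lapply(nms, function(nm) rhdf5::h5read(path, nm))
    names(out) <- nms
    rhdf5::H5close()
  }
  out
}

#' Write a connectivity mask in Matrix Market format
#'
#' Coordinate-format MTX with 1-based indices per that standard.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param path Output .mtx path.
#' @return `path`, invisibly.
#' @export
write_mask_mtx <- function(mask, path) {
  m <- Matrix::Matrix(mask * 1, sparse = TRUE)
  Matrix::writeMM(methods::as(m, "generalMatrix"), path)
  invisible(path)
}

#' Read a connectivity mask from Matrix Market format
#'
#' @param path .mtx path (1-based indices per the MTX standard).
#' @return Logical dense matrix.
#' @export
read_mask_mtx <- function(path) {
  m <- Matrix::readMM(path)
  as.matrix(m) != 0
}

#' Write a training history as CSV
#'
#' Columns: epoch, train_mae, val_mae, n_updates. Wall times are kept only
#' in memory (as an attribute) so re-runs with the same seed produce
#' byte-identical files.
#'
#' @param history History data.frame from a trainer.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_history <- function(history, path) {
  utils::write.csv(history[, c("epoch", "train_mae", "val_mae", "n_updates")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a spike raster as two-column CSV
#'
#' @param spikes data.frame with `time_s` and 0-based `neuron_index`
#'   (as produced by [run_spiking_network()] with `record = "spikes"`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_spikes <- function(spikes, path) {
  utils::write.csv(spikes[, c("time_s", "neuron_index")], path,
                   row.names = FALSE)
  invisible(path)
}
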