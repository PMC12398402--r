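# Trial-set file I/O.  Two container formats are supported, selected by file
# extension: HDF5 (.h5/.hdf5) and NPZ (.npz).  Both hold the same keys:
#   X  [trials, time, channels]  float32
#   y  [trials]                  int8 (1 = behavior, 0 = control)
#   sampling_rate (scalar, Hz), t_zero_index (scalar, 0-based on disk)
# The on-disk axis order of X is the one a numpy/h5py consumer sees;
# the R <-> HDF5 axis reversal is handled internally.

io_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("h5", "hdf5")) return("h5")
  if (ext == "npz") return("npz")
  stop("unrecognised trial-set extension '.", ext, "' (use .h5 or .npz)",
       call. = FALSE)
}

#' Write a trial set to HDF5 or NPZ
#'
#' @param x A [trial_set()].
#' @param path Output path; the extension (`.h5`/`.hdf5` or `.npz`) selects
#'   the container.
#' @return `path`, invisibly.
#' @details Data are stored in single precision with the trial axis first as
#'   seen from numpy/h5py.  `t_zero_index` is stored 0-based on disk and
#'   converted back on read.  Channel names and generator metadata are kept
#'   in the HDF5 container only.
#' @export
write_trials <- function(x, path) {
  stopifnot(inherits(x, "trial_set"))
  fmt <- io_format(path)
  if (file.exists(path)) unlink(path)
  if (fmt == "h5") {
    rhdf5::h5createFile(path)
    # aperm so the on-disk (C-order) shape is [trials, time, channels]
    rhdf5::h5createDataset(path, "X", dims = rev(dim(x$data)),
                           H5type = "H5T_IEEE_F32LE")
    rhdf5::h5write(aperm(x$data, c(3, 2, 1)), path, "X")
    rhdf5::h5createDataset(path, "y", dims = length(x$labels),
                           H5type = "H5T_STD_I8LE")
    rhdf5::h5write(x$labels, path, "y")
    if (!is.null(x$channel_names))
      rhdf5::h5write(x$channel_names, path, "channel_names")
    fid <- rhdf5::H5Fopen(path)
    rhdf5::h5writeAttribute(x$sampling_rate, fid, "sampling_rate")
    rhdf5::h5writeAttribute(x$t_zero_index - 1L, fid, "t_zero_index")
    if (length(x$meta))
      rhdf5::h5writeAttribute(
        as.character(jsonlite::toJSON(x$meta, auto_unbox = TRUE,
                                      digits = NA, force = TRUE)),
        fid, "meta")
    rhdf5::H5Fclose(fid)
    rhdf5::h5closeAll()
  } else {
    write_npz(
      list(X = x$data, y = x$labels,
           sampling_rate = x$sampling_rate,
           t_zero_index = x$t_zero_index - 1L),
      path,
      dtypes = c(X = "float32", y = "int8",
                 sampling_rate = "float64", t_zero_index = "int64"))
  }
  invisible(path)
}

#' Read a trial set from HDF5 or NPZ
#'
#' @param path Path to a `.h5`/`.hdf5` or `.npz` file with keys `X` and `y`
#'   (see [write_trials()] for the layout).
#' @return A validated [trial_set()].
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  fmt <- io_format(path)
  if (fmt == "h5") {
    on.exit(rhdf5::h5closeAll())
    keys <- rhdf5::h5ls(path)$name
    for (k in c("X", "y"))
      if (!k %in% keys)
        stop("HDF5 file is missing required dataset '", k, "'", call. = FALSE)
    X <- aperm(rhdf5::h5read(path, "X"), c(3, 2, 1))
    y <- as.integer(rhdf5::h5read(path, "y"))
    at <- rhdf5::h5readAttributes(path, "/")
    cn <- if ("channel_names" %in% keys)
      as.character(rhdf5::h5read(path, "channel_names")) else NULL
    meta <- if (!is.null(at$meta))
      jsonlite::fromJSON(as.character(at$meta)) else list()
    sr <- as.numeric(at$sampling_rate %||% 30)
    tz <- as.integer(at$t_zero_index %||% (dim(X)[2] - 1L)) + 1L
  } else {
    arrs <- read_npz(path)
    for (k in c("X", "y"))
      if (!k %in% names(arrs))
        stop("NPZ file is missing required array '", k, "'", call. = FALSE)
    X <- arrs$X
    y <- as.integer(arrs$y)
    cn <- NULL
    meta <- list()
    sr <- as.numeric(arrs$sampling_rate %||% 30)
    tz <- as.integer(arrs$t_zero_index %||% (dim(X)[2] - 1L)) + 1L
  }
  if (anyNA(X) || !all(is.finite(X)))
    stop("trial data in '", path, "' contain non-finite values", call. = FALSE)
  trial_set(X, y, sampling_rate = sr, t_zero_index = tz,
            channel_names = cn, meta = meta)
}
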