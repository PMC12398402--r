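# Minimal NPY / NPZ serialisation.  NPY files are written with
# fortran_order=True so R's column-major memory layout goes to disk verbatim;
# NPZ is a zip container with stored (uncompressed) entries, the layout numpy
# itself uses for savez().  Readers accept both C- and Fortran-ordered NPY
# and stored NPZ entries.

npy_descr <- function(x, dtype) {
  switch(dtype,
         float32 = "<f4", float64 = "<f8",
         int8 = "|i1", int32 = "<i4", int64 = "<i8",
         stop("unsupported dtype: ", dtype, call. = FALSE))
}

npy_bytes <- function(x, dtype = if (is.integer(x)) "int32" else "float64") {
  shape <- if (is.null(dim(x))) {
    if (length(x) == 1L) integer(0) else length(x)  # scalars go 0-d
  } else dim(x)
  header <- sprintf(
    "{'descr': '%s', 'fortran_order': True, 'shape': (%s), }",
    npy_descr(x, dtype),
    if (length(shape) == 1L) paste0(shape, ",")
    else paste(shape, collapse = ", "))
  # total header block (magic 6 + version 2 + len 2 + dict) padded to 64
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- rawConnection(raw(0L), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59, 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  vals <- as.vector(x)
  if (dtype %in% c("float32", "float64")) {
    writeBin(as.double(vals), con, size = if (dtype == "float32") 4L else 8L,
             endian = "little")
  } else if (dtype == "int64") {
    # values are limited to the int32 range; low word + sign extension
    for (v in as.integer(vals)) {
      writeBin(v, con, size = 4L, endian = "little")
      writeBin(if (v < 0L) -1L else 0L, con, size = 4L, endian = "little")
    }
  } else {
    writeBin(as.integer(vals), con,
             size = switch(dtype, int8 = 1L, int32 = 4L),
             endian = "little")
  }
  rawConnectionValue(con)
}

npy_parse <- function(bytes) {
  stopifnot(length(bytes) > 10L,
            identical(bytes[1:6], as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59))))
  major <- as.integer(bytes[7])
  hlen_bytes <- if (major >= 2L) 4L else 2L
  hlen <- sum(as.integer(bytes[9:(8L + hlen_bytes)]) * 256^(0:(hlen_bytes - 1L)))
  hdr <- rawToChar(bytes[(9L + hlen_bytes):(8L + hlen_bytes + hlen)])
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", hdr)
  fortran <- grepl("'fortran_order':\\s*True", hdr)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", hdr)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  if (length(shape) == 0L) shape <- integer(0)  # 0-d scalar
  data0 <- bytes[(9L + hlen_bytes + hlen):length(bytes)]
  n <- if (length(shape)) prod(shape) else 1L
  code <- sub("^[<>|=]", "", descr)
  endian <- if (substr(descr, 1, 1) == ">") "big" else "little"
  vals <- switch(code,
    f4 = readBin(data0, "double", n = n, size = 4L, endian = endian),
    f8 = readBin(data0, "double", n = n, size = 8L, endian = endian),
    i1 = readBin(data0, "integer", n = n, size = 1L, signed = TRUE, endian = endian),
    i2 = readBin(data0, "integer", n = n, size = 2L, endian = endian),
    i4 = readBin(data0, "integer", n = n, size = 4L, endian = endian),
    i8 = {  # int64: low/high 4-byte words (little-endian only)
      if (endian != "little") stop("big-endian int64 not supported")
      w <- readBin(data0, "integer", n = 2L * n, size = 4L, endian = endian)
      lo <- w[seq(1L, 2L * n, 2L)]; hi <- w[seq(2L, 2L * n, 2L)]
      hi * 2^32 + ifelse(lo < 0, lo + 2^32, lo)
    },
    b1 = as.integer(readBin(data0, "integer", n = n, size = 1L,
                            signed = FALSE, endian = endian)),
    stop("unsupported NPY dtype: ", descr, call. = FALSE))
  if (length(shape) <= 1L) return(vals)
  if (fortran) array(vals, dim = shape)
  else aperm(array(vals, dim = rev(shape)), rev(seq_along(shape)))
}

u16_raw <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))
u32_raw <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                                (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

#' Write arrays to an NPZ container
#'
#' Writes a named list of numeric/integer arrays as an uncompressed NPZ
#' (zip-of-NPY) file readable by numpy.
#'
#' @param arrays Named list of arrays/vectors.
#' @param path Output path (conventionally `.npz`).
#' @param dtypes Optional named character vector of dtypes per entry
#'   (`"float32"`, `"float64"`, `"int8"`, `"int32"`, `"int64"`).
#' @return `path`, invisibly.
#' @export
write_npz <- function(arrays, path, dtypes = NULL) {
  stopifnot(is.list(arrays), !is.null(names(arrays)), all(nzchar(names(arrays))))
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(0); crcs <- numeric(0); sizes <- integer(0)
  names_npy <- paste0(names(arrays), ".npy")
  pos <- 0L
  for (j in seq_along(arrays)) {
    dtype <- if (!is.null(dtypes) && names(arrays)[j] %in% names(dtypes))
      dtypes[[names(arrays)[j]]]
    else if (is.integer(arrays[[j]])) "int32" else "float64"
    payload <- npy_bytes(arrays[[j]], dtype)
    crc <- .cpp_crc32(payload)
    nm <- names_npy[j]
    offsets <- c(offsets, pos); crcs <- c(crcs, crc)
    sizes <- c(sizes, length(payload))
    hdr <- c(u32_raw(0x04034b50), u16_raw(20), u16_raw(0), u16_raw(0),
             u16_raw(0), u16_raw(0), u32_raw(crc),
             u32_raw(length(payload)), u32_raw(length(payload)),
             u16_raw(nchar(nm)), u16_raw(0), charToRaw(nm))
    writeBin(hdr, con); writeBin(payload, con)
    pos <- pos + length(hdr) + length(payload)
  }
  cd_start <- pos
  for (j in seq_along(arrays)) {
    nm <- names_npy[j]
    cd <- c(u32_raw(0x02014b50), u16_raw(20), u16_raw(20), u16_raw(0),
            u16_raw(0), u16_raw(0), u16_raw(0), u32_raw(crcs[j]),
            u32_raw(sizes[j]), u32_raw(sizes[j]), u16_raw(nchar(nm)),
            u16_raw(0), u16_raw(0), u16_raw(0), u16_raw(0), u32_raw(0),
            u32_raw(offsets[j]), charToRaw(nm))
    writeBin(cd, con)
    pos <- pos + length(cd)
  }
  writeBin(c(u32_raw(0x06054b50), u16_raw(0), u16_raw(0),
             u16_raw(length(arrays)), u16_raw(length(arrays)),
             u32_raw(pos - cd_start), u32_raw(cd_start), u16_raw(0)), con)
  invisible(path)
}

#' Read arrays from an NPZ container
#'
#' Reads stored (uncompressed) NPZ files, as written by [write_npz()] or
#' numpy's `savez()`.  Deflated entries (`savez_compressed`) are not
#' supported.
#'
#' @param path Path to an `.npz` file.
#' @return Named list of arrays.
#' @export
read_npz <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(i) sum(as.integer(bytes[i + 0:1]) * c(1, 256))
  u32 <- function(i) sum(as.integer(bytes[i + 0:3]) * 256^(0:3))
  out <- list()
  pos <- 1L
  repeat {
    if (pos + 3L > length(bytes) || u32(pos) != 0x04034b50) break
    method <- u16(pos + 8L)
    csize <- u32(pos + 18L)
    nmlen <- u16(pos + 26L); exlen <- u16(pos + 28L)
    nm <- rawToChar(bytes[(pos + 30L):(pos + 29L + nmlen)])
    data_start <- pos + 30L + nmlen + exlen
    payload <- bytes[data_start:(data_start + csize - 1L)]
    if (method != 0L)
      stop("NPZ entry '", nm, "' is compressed; only stored entries are supported",
           call. = FALSE)
    out[[sub("\\.npy$", "", nm)]] <- npy_parse(payload)
    pos <- data_start + csize
  }
  out
}
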