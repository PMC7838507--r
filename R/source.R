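# Source volume providers: a uniform "read this (x, y, z) box" interface over
# in-memory arrays, multi-page TIFF stacks, directories of 2D TIFF slices and
# headerless raw binary. The reformatter streams z-slabs through this
# interface so it never needs the whole level-1 volume in memory.

#' Source volume providers
#'
#' A source volume is a list with fields `dims` (x, y, z), `bit_depth` and
#' `read_box(x0, x1, y0, y1, z0, z1)` returning the requested half-open,
#' 0-based box as a 3D integer array indexed `[x, y, z]`.
#'
#' `vol_source_array()` wraps an in-memory array. `vol_source_tiff()` reads a
#' multi-page grayscale TIFF (one page per z slice). `vol_source_dir()` reads
#' a directory of 2D TIFF slices in lexicographic filename order.
#' `vol_source_raw()` reads headerless binary, voxels x-fastest then y then z,
#' 8-bit unsigned or 16-bit little-endian unsigned.
#'
#' @param a 3D integer array indexed `[x, y, z]`.
#' @param bit_depth Bits per voxel (8 or 16).
#' @return A list of class `bitvox_source`.
#' @export
vol_source_array <- function(a, bit_depth = 8L) {
  bit_depth <- check_bit_depth(bit_depth)
  d <- dim(a)
  if (is.null(d) || length(d) != 3L) stop("`a` must be a 3D array", call. = FALSE)
  storage.mode(a) <- "integer"
  new_source(as.integer(d), bit_depth, function(x0, x1, y0, y1, z0, z1) {
    a[(x0 + 1):x1, (y0 + 1):y1, (z0 + 1):z1, drop = FALSE]
  })
}

#' @rdname vol_source_array
#' @param path File (TIFF stack, raw binary) or directory of slices.
#' @export
vol_source_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  slices_source(pages, path)
}

#' @rdname vol_source_array
#' @export
vol_source_dir <- function(path) {
  files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                           ignore.case = TRUE))
  if (!length(files)) stop("no TIFF slices found in ", path, call. = FALSE)
  pages <- lapply(files, tiff::readTIFF, as.is = TRUE)
  slices_source(pages, path)
}

#' @rdname vol_source_array
#' @param dims Integer triple for the raw volume.
#' @export
vol_source_raw <- function(path, dims, bit_depth = 8L) {
  dims <- check_dims(dims)
  bit_depth <- check_bit_depth(bit_depth)
  expected <- prod(as.double(dims)) * (bit_depth / 8)
  if (!file.exists(path)) stop("raw volume not found: ", path, call. = FALSE)
  if (file.size(path) < expected) {
    stop(sprintf("raw volume %s is %d bytes; dims imply %.0f",
                 path, file.size(path), expected), call. = FALSE)
  }
  nx <- dims[1]; ny <- dims[2]
  bytes_per <- bit_depth / 8
  new_source(dims, bit_depth, function(x0, x1, y0, y1, z0, z1) {
    con <- file(path, "rb")
    on.exit(close(con))
    out <- array(0L, dim = c(x1 - x0, y1 - y0, z1 - z0))
    plane_vox <- as.double(nx) * ny
    for (z in z0:(z1 - 1)) {
      seek(con, (plane_vox * z + as.double(nx) * y0) * bytes_per)
      slab <- readBin(con, "integer", n = nx * (y1 - y0),
                      size = bytes_per, signed = FALSE, endian = "little")
      m <- matrix(slab, nrow = nx)
      out[, , z - z0 + 1] <- m[(x0 + 1):x1, , drop = FALSE]
    }
    out
  })
}

# pages: list of 2D matrices [row = y, col = x] as returned by readTIFF as.is
slices_source <- function(pages, what) {
  first <- pages[[1]]
  if (is.null(dim(first)) || length(dim(first)) != 2L) {
    stop("expected single-channel grayscale slices in ", what, call. = FALSE)
  }
  maxv <- max(vapply(pages, max, 0))
  bit_depth <- if (maxv > 255) 16L else 8L
  ny <- nrow(first); nx <- ncol(first)
  ok <- vapply(pages, function(p) identical(dim(p), c(ny, nx)), FALSE)
  if (!all(ok)) stop("slices in ", what, " differ in shape", call. = FALSE)
  dims <- c(nx, ny, length(pages))
  new_source(as.integer(dims), bit_depth, function(x0, x1, y0, y1, z0, z1) {
    out <- array(0L, dim = c(x1 - x0, y1 - y0, z1 - z0))
    for (z in z0:(z1 - 1)) {
      # TIFF pages are [y, x]; transpose to [x, y]
      out[, , z - z0 + 1] <- t(pages[[z + 1]][(y0 + 1):y1, (x0 + 1):x1, drop = FALSE])
    }
    out
  })
}

new_source <- function(dims, bit_depth, read_fn) {
  dims <- check_dims(dims)
  reader <- function(x0, x1, y0, y1, z0, z1) {
    if (x0 < 0 || y0 < 0 || z0 < 0 || x1 > dims[1] || y1 > dims[2] ||
        z1 > dims[3] || x0 >= x1 || y0 >= y1 || z0 >= z1) {
      stop(sprintf("box [%d,%d)x[%d,%d)x[%d,%d) outside volume %dx%dx%d",
                   x0, x1, y0, y1, z0, z1, dims[1], dims[2], dims[3]),
           call. = FALSE)
    }
    out <- read_fn(x0, x1, y0, y1, z0, z1)
    storage.mode(out) <- "integer"
    out
  }
  structure(list(dims = dims, bit_depth = bit_depth, read_box = reader),
            class = "bitvox_source")
}

#' @export
print.bitvox_source <- function(x, ...) {
  cat(sprintf("bitvox source volume %d x %d x %d, %d-bit\n",
              x$dims[1], x$dims[2], x$dims[3], x$bit_depth))
  invisible(x)
}
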