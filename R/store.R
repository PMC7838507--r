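# On-disk store: four-level folder hierarchy level{r}_data/z{i}/y{j}/x{k}
# with one file per bit-plane, named {b}.tif. Each bitBlock is the packed
# binary payload of one plane of one block, wrapped in a single-image 8-bit
# grayscale TIFF of width block_size/8 and height block_size^2, compressed
# with LZW and no predictor. The TIFF geometry is a declared dialect recorded
# in the metadata; payload bytes are laid out row-major.

#' Store locations
#'
#' A store location is either a local directory root or a base URL; exactly
#' one of the two. All store operations ([write_bitblock()],
#' [read_bitblock()], [read_metadata()], ...) accept either kind where
#' reading is concerned; writing requires a local store.
#'
#' @param root Local directory holding (or to hold) a dataset tree.
#' @param base_url Base URL of a served dataset tree.
#' @return A list of class `bitvox_store`.
#' @export
store_local <- function(root) {
  structure(list(root = root, url = NULL), class = "bitvox_store")
}

#' @rdname store_local
#' @export
store_url <- function(base_url) {
  structure(list(root = NULL, url = sub("/+$", "", base_url)),
            class = "bitvox_store")
}

as_store <- function(location) {
  if (inherits(location, "bitvox_store")) return(location)
  if (is.character(location) && length(location) == 1L) {
    if (grepl("^https?://", location)) store_url(location) else store_local(location)
  } else {
    stop("`location` must be a path, URL or bitvox_store", call. = FALSE)
  }
}

#' Relative path of a bitBlock file
#'
#' Maps an address to `level{r}_data/z{i}/y{j}/x{k}/{b}.tif`. The mapping is
#' bijective; [parse_bitblock_relpath()] is its inverse.
#'
#' @param ref A [bitplane_ref()].
#' @return Relative path string.
#' @examples
#' bitblock_relpath(bitplane_ref(1, 0, 0, 0, 1))
#' @export
bitblock_relpath <- function(ref) {
  stopifnot(inherits(ref, "bitvox_ref"))
  sprintf("level%d_data/z%d/y%d/x%d/%d.tif", ref$r, ref$i, ref$j, ref$k, ref$b)
}

#' @rdname bitblock_relpath
#' @param relpath A relative path produced by `bitblock_relpath()`.
#' @export
parse_bitblock_relpath <- function(relpath) {
  m <- regmatches(relpath, regexec(
    "^level([0-9]+)_data/z([0-9]+)/y([0-9]+)/x([0-9]+)/([0-9]+)\\.tif$",
    relpath))[[1]]
  if (length(m) != 6L) {
    stop("not a bitBlock path: ", relpath, call. = FALSE)
  }
  v <- as.integer(m[-1])
  bitplane_ref(r = v[1], i = v[2], j = v[3], k = v[4], b = v[5])
}

#' Write and read bitBlock files
#'
#' `write_bitblock()` serializes one packed bit-plane payload as a
#' single-image 8-bit grayscale TIFF (width `block_size / 8`, height
#' `block_size^2`, LZW, no predictor) at the path given by
#' [bitblock_relpath()]. `read_bitblock()` is its byte-exact inverse and
#' also decodes payloads fetched over HTTP when the location is a URL store.
#'
#' @param location Local root path, base URL, or a `bitvox_store`.
#' @param ref A [bitplane_ref()].
#' @param plane A `bitvox_bitplane` (from [split_planes()] or a previous
#'   read).
#' @return `read_bitblock()` returns a `bitvox_bitplane`.
#' @export
write_bitblock <- function(location, ref, plane) {
  loc <- as_store(location)
  if (is.null(loc$root)) stop("cannot write to a URL store", call. = FALSE)
  stopifnot(inherits(plane, "bitvox_bitplane"))
  bs <- plane$block_size
  if (length(plane$payload) != bs^3 / 8) {
    stop(sprintf("payload must be %d bytes for block %d, got %d",
                 bs^3 / 8, bs, length(plane$payload)), call. = FALSE)
  }
  path <- file.path(loc$root, bitblock_relpath(ref))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  img <- matrix(as.integer(plane$payload), nrow = bs^2, ncol = bs / 8,
                byrow = TRUE)
  tiff::writeTIFF(img / 255, path, bits.per.sample = 8L, compression = "LZW")
  invisible(path)
}

#' @rdname write_bitblock
#' @export
read_bitblock <- function(location, ref) {
  loc <- as_store(location)
  if (!is.null(loc$url)) return(fetch_bitblock(loc$url, ref))
  relpath <- bitblock_relpath(ref)
  path <- file.path(loc$root, relpath)
  if (!file.exists(path)) {
    stop(errorCondition(paste0("bitBlock not found: ", relpath),
                        relpath = relpath,
                        class = c("bitvox_not_found", "error")))
  }
  decode_bitblock_tiff(tiff::readTIFF(path, as.is = TRUE), ref, relpath)
}

# img: integer matrix [height, width] from readTIFF(as.is = TRUE)
decode_bitblock_tiff <- function(img, ref, relpath) {
  if (is.null(dim(img)) || length(dim(img)) != 2L) {
    stop(errorCondition(paste0("bitBlock TIFF is not single-channel: ", relpath),
                        class = c("bitvox_format_error", "error")))
  }
  w <- ncol(img); h <- nrow(img)
  bs <- 8L * w
  if (h != bs^2) {
    stop(errorCondition(sprintf(
      "bitBlock TIFF %s has shape %dx%d; expected height = (8*width)^2",
      relpath, h, w), class = c("bitvox_format_error", "error")))
  }
  payload <- as.raw(as.integer(t(img)))   # row-major byte order
  new_bitplane(ref$b, payload, bs)
}

#' Write and read dataset metadata
#'
#' `metadata.json` at the store root records every [dataset_meta()] field,
#' including the codec conventions. Reads are schema-validated: bit depth
#' must be 8 or 16 and the recorded level count must equal
#' `num_levels(dims, block_size)`.
#'
#' @inheritParams write_bitblock
#' @param meta A [dataset_meta()] object.
#' @return `read_metadata()` returns a validated `bitvox_meta`.
#' @export
write_metadata <- function(location, meta) {
  loc <- as_store(location)
  if (is.null(loc$root)) stop("cannot write to a URL store", call. = FALSE)
  validate_meta(meta)
  dir.create(loc$root, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(meta), file.path(loc$root, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(loc$root, "metadata.json"))
}

#' @rdname write_metadata
#' @export
read_metadata <- function(location) {
  loc <- as_store(location)
  txt <- if (!is.null(loc$url)) {
    res <- fetch_url(paste0(loc$url, "/metadata.json"))
    rawToChar(res)
  } else {
    path <- file.path(loc$root, "metadata.json")
    if (!file.exists(path)) {
      stop(errorCondition(paste0("metadata.json not found under ", loc$root),
                          class = c("bitvox_format_error", "error")))
    }
    paste(readLines(path, warn = FALSE), collapse = "\n")
  }
  raw <- tryCatch(jsonlite::fromJSON(txt),
                  error = function(e) {
                    stop(errorCondition(
                      paste0("invalid metadata.json: ", conditionMessage(e)),
                      class = c("bitvox_format_error", "error")))
                  })
  meta <- structure(raw, class = "bitvox_meta")
  tryCatch(validate_meta(meta), error = function(e) {
    stop(errorCondition(paste0("invalid metadata.json: ", conditionMessage(e)),
                        class = c("bitvox_format_error", "error")))
  })
  meta$dims <- as.integer(meta$dims)
  meta$bit_depth <- as.integer(meta$bit_depth)
  meta$block_size <- as.integer(meta$block_size)
  meta$levels <- as.integer(meta$levels)
  meta
}

#' Compressed size per bit-plane
#'
#' Sums the on-disk (LZW-compressed) bytes of every bitBlock file, grouped by
#' bit-plane index, over all levels and blocks of a converted dataset. On a
#' high-contrast fluorescence volume the most significant planes are nearly
#' empty and compress far better than the noisy least significant planes, so
#' their fraction of total storage is small — the property that makes
#' top-planes-first streaming cheap.
#'
#' @param location Local root of a complete dataset tree.
#' @param meta Optional [dataset_meta()]; read from the store when missing.
#' @return A tibble of class `bitvox_plane_report` with columns `b`,
#'   `bytes` and `fraction` (fractions sum to 1).
#' @export
plane_size_report <- function(location, meta = NULL) {
  loc <- as_store(location)
  if (is.null(loc$root)) stop("plane_size_report needs a local store", call. = FALSE)
  if (is.null(meta)) meta <- read_metadata(loc)
  plan <- plan_pyramid(meta)
  B <- meta$bit_depth
  bytes <- numeric(B)
  for (r in plan$r) {
    row <- plan[plan$r == r, ]
    for (i in 0:(row$gz - 1L)) for (j in 0:(row$gy - 1L)) for (k in 0:(row$gx - 1L)) {
      for (b in seq_len(B)) {
        path <- file.path(loc$root,
                          bitblock_relpath(bitplane_ref(r, i, j, k, b)))
        sz <- file.size(path)
        if (is.na(sz)) {
          stop(errorCondition(paste0("incomplete tree; missing ", path),
                              class = c("bitvox_not_found", "error")))
        }
        bytes[b] <- bytes[b] + sz
      }
    }
  }
  out <- tibble::tibble(b = seq_len(B), bytes = bytes,
                        fraction = bytes / sum(bytes))
  class(out) <- c("bitvox_plane_report", class(out))
  out
}

#' Plot a plane-size report
#'
#' @param object A `bitvox_plane_report` from [plane_size_report()].
#' @param ... Ignored.
#' @return A ggplot bar chart of compressed bytes per bit-plane.
#' @method autoplot bitvox_plane_report
#' @export
autoplot.bitvox_plane_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(b), y = bytes)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "bit-plane (1 = most significant)",
                  y = "compressed bytes",
                  title = "Storage per bit-plane")
}
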