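#' Dataset metadata
#'
#' Global description of a converted dataset: the level-1 voxel dimensions,
#' physical voxel size, bit depth, block edge length and the derived level
#' count, plus the codec conventions (voxel scan order, bit packing order,
#' pad value, downsampling operator) that a conforming reader needs. The
#' level count is always recomputed from `dims` and `block_size`; it is not
#' a free field.
#'
#' @param name Dataset name (used in messages and file naming only).
#' @param dims Integer triple: x, y, z voxel counts at level 1.
#' @param voxel_size Numeric triple, micrometres per voxel along x, y, z.
#' @param bit_depth Bits per voxel, 8 or 16.
#' @param block_size Block edge length in voxels; must be a multiple of 8
#'   (bit-plane payloads pack 8 voxels per byte). Default 128.
#' @param downsample Downsampling operator recorded for provenance:
#'   `"mean"` (2x2x2 arithmetic mean, rounded half-up) or `"stride"`.
#' @return A list of class `bitvox_meta`.
#' @examples
#' dataset_meta("brain", c(13913, 18000, 5115), c(0.32, 0.32, 2), 8)
#' @export
dataset_meta <- function(name, dims, voxel_size = c(1, 1, 1), bit_depth = 8L,
                         block_size = 128L, downsample = c("mean", "stride")) {
  dims <- check_dims(dims)
  bit_depth <- check_bit_depth(bit_depth)
  block_size <- check_block_size(block_size)
  downsample <- match.arg(downsample)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 3L ||
      any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("`voxel_size` must be three positive numbers (um/voxel)", call. = FALSE)
  }
  structure(list(
    name = name,
    dims = dims,
    voxel_size = as.numeric(voxel_size),
    bit_depth = bit_depth,
    block_size = block_size,
    levels = num_levels(dims, block_size),
    compression = "LZW",
    format_version = "1.0",
    # codec dialect, fixed so independent readers can interoperate
    scan_order = "x-fastest",        # voxel traversal: x, then y, then z
    bit_order = "msb-first",         # first voxel of a byte -> bit 7
    pad_value = 0L,                  # edge blocks padded with background 0
    downsample = downsample          # mean = 2x2x2 mean, rounded half-up
  ), class = "bitvox_meta")
}

validate_meta <- function(meta) {
  required <- c("name", "dims", "voxel_size", "bit_depth", "block_size",
                "levels", "compression", "format_version")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("metadata is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dims <- check_dims(meta$dims)
  bit_depth <- check_bit_depth(meta$bit_depth)
  block_size <- check_block_size(meta$block_size)
  expected <- num_levels(dims, block_size)
  if (!identical(as.integer(meta$levels), expected)) {
    stop(sprintf(
      "metadata `levels` is %s but num_levels(dims, block_size) gives %d",
      meta$levels, expected), call. = FALSE)
  }
  invisible(meta)
}

#' @export
print.bitvox_meta <- function(x, ...) {
  cat(sprintf("bitvox dataset '%s'\n", x$name))
  cat(sprintf("  dims:       %d x %d x %d voxels (%g x %g x %g um/voxel)\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  bit depth:  %d   block: %d^3   levels: %d   compression: %s\n",
              x$bit_depth, x$block_size, x$levels, x$compression))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy dataset metadata
#'
#' @param x A `bitvox_meta` object.
#' @param ... Ignored.
#' @return A two-column tibble of field names and (character) values.
#' @method tidy bitvox_meta
#' @export
tidy.bitvox_meta <- function(x, ...) {
  tibble::tibble(
    field = names(x),
    value = vapply(x, function(v) paste(format(v), collapse = " x "), "")
  )
}

#' One-row summary of a dataset
#'
#' @param x A `bitvox_meta` object.
#' @param ... Ignored.
#' @return A one-row tibble with voxel counts, level count, total blocks,
#'   total bitBlock files and the uncompressed size in bytes.
#' @method glance bitvox_meta
#' @export
glance.bitvox_meta <- function(x, ...) {
  plan <- plan_pyramid(x)
  tibble::tibble(
    name = x$name,
    voxels = prod(as.double(x$dims)),
    bit_depth = x$bit_depth,
    block_size = x$block_size,
    levels = x$levels,
    total_blocks = sum(plan$blocks),
    total_files = count_files(plan, x$bit_depth),
    raw_bytes = raw_size_bytes(x$dims, x$bit_depth)
  )
}
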