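#' Dimensions of a pyramid level
#'
#' The multiresolution pyramid halves each axis per level with a ceiling, so
#' level `r` of a volume with level-1 dimensions `dims` has
#' `ceiling(dims / 2^(r - 1))` voxels per axis. Level 1 is the original
#' resolution.
#'
#' @param dims Integer vector of length 3: x, y, z voxel counts at level 1.
#' @param r Level index (1 = original resolution).
#' @return Integer vector of length 3 with the level-`r` dimensions.
#' @examples
#' level_dims(c(13913, 18000, 5115), 2)
#' @export
level_dims <- function(dims, r) {
  dims <- check_dims(dims)
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 1 || r != floor(r)) {
    stop("`r` must be a single integer >= 1", call. = FALSE)
  }
  # exact for all d <= 2^52: d / 2^(r-1) is a dyadic division of an integer
  as.integer(ceiling(dims / 2^(r - 1)))
}

#' Number of pyramid levels
#'
#' Downsampling is applied until every axis of the coarsest level is strictly
#' below the block edge length. A volume already smaller than one block has a
#' single level.
#'
#' @inheritParams level_dims
#' @param block_size Block edge length in voxels (default 128).
#' @return Integer level count (>= 1).
#' @examples
#' num_levels(c(13913, 18000, 5115), 128) # 9
#' num_levels(c(13913, 18000, 5115), 512) # 7
#' @export
num_levels <- function(dims, block_size = 128L) {
  dims <- check_dims(dims)
  block_size <- check_block_size(block_size, require_mult8 = FALSE)
  L <- 1L
  while (any(level_dims(dims, L) >= block_size)) L <- L + 1L
  L
}

#' Plan the full block pyramid
#'
#' Enumerates every level of the pyramid for a dataset, with per-level voxel
#' dimensions and the ceil-grid of blocks covering them. Edge blocks are
#' counted as full blocks; they are zero-padded when written.
#'
#' @param meta A [dataset_meta()] object, or an integer dims triple (in which
#'   case `block_size` is used).
#' @param block_size Block edge length, used only when `meta` is a dims triple.
#' @return A tibble of class `bitvox_plan` with one row per level and columns
#'   `r`, `nx`, `ny`, `nz` (level dims), `gx`, `gy`, `gz` (block grid) and
#'   `blocks` (= gx * gy * gz).
#' @examples
#' plan_pyramid(c(13913, 18000, 5115), block_size = 128)
#' @export
plan_pyramid <- function(meta, block_size = 128L) {
  if (inherits(meta, "bitvox_meta")) {
    dims <- meta$dims
    block_size <- meta$block_size
  } else {
    dims <- check_dims(meta)
    block_size <- check_block_size(block_size, require_mult8 = FALSE)
  }
  L <- num_levels(dims, block_size)
  rows <- lapply(seq_len(L), function(r) {
    d <- level_dims(dims, r)
    g <- as.integer(ceiling(d / block_size))
    tibble::tibble(
      r = r, nx = d[1], ny = d[2], nz = d[3],
      gx = g[1], gy = g[2], gz = g[3],
      blocks = prod(as.double(g))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bitvox_plan", class(out))
  attr(out, "block_size") <- as.integer(block_size)
  attr(out, "dims") <- dims
  out
}

#' Count bitBlock files in a pyramid
#'
#' Total file count is the number of blocks over all levels times the number
#' of files written per block: `bit_depth` for the bit-plane-separated layout
#' (one file per bit-plane) or 1 for a conventional one-file-per-block layout.
#'
#' @param plan A `bitvox_plan` tibble from [plan_pyramid()].
#' @param planes_per_block Files per block (e.g. 8 for an 8-bit bit-plane
#'   layout, 1 for one file per block).
#' @return File count as a double (counts can exceed `.Machine$integer.max`
#'   territory for teravoxel datasets only in principle; doubles are exact
#'   well past any realistic count).
#' @examples
#' count_files(plan_pyramid(c(13913, 18000, 5115), 128), 8) # 5635504
#' @export
count_files <- function(plan, planes_per_block) {
  stopifnot(inherits(plan, "bitvox_plan"))
  if (!is.numeric(planes_per_block) || length(planes_per_block) != 1L ||
      planes_per_block < 1 || planes_per_block != floor(planes_per_block)) {
    stop("`planes_per_block` must be a single integer >= 1", call. = FALSE)
  }
  sum(plan$blocks) * planes_per_block
}

#' Uncompressed size of a raw volume
#'
#' @inheritParams level_dims
#' @param bit_depth Bits per voxel, 8 or 16.
#' @return Size in bytes (double).
#' @examples
#' raw_size_bytes(c(13913, 18000, 5115), 8) / 2^40 # ~1.17 TiB
#' @export
raw_size_bytes <- function(dims, bit_depth) {
  dims <- check_dims(dims)
  bit_depth <- check_bit_depth(bit_depth)
  prod(as.double(dims)) * (bit_depth / 8)
}

#' @export
print.bitvox_plan <- function(x, ...) {
  d <- attr(x, "dims")
  cat(sprintf("# Block pyramid: %d x %d x %d voxels, block %d, %d level%s\n",
              d[1], d[2], d[3], attr(x, "block_size"), nrow(x),
              if (nrow(x) > 1) "s" else ""))
  NextMethod()
  invisible(x)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a pyramid plan
#'
#' Bar chart of block counts per level (log scale), a quick visual check that
#' the pyramid shrinks roughly 8x per level until the single root block.
#'
#' @param object A `bitvox_plan`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot bitvox_plan
#' @export
autoplot.bitvox_plan <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(r), y = blocks)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "pyramid level (1 = full resolution)",
                  y = "blocks (log scale)",
                  title = "Blocks per pyramid level")
}

# ---- shared argument checks ----

check_dims <- function(dims) {
  if (!is.numeric(dims) || length(dims) != 3L || anyNA(dims) ||
      any(dims < 1) || any(dims != floor(dims))) {
    stop("`dims` must be three integers >= 1 (x, y, z)", call. = FALSE)
  }
  as.integer(dims)
}

check_bit_depth <- function(bit_depth) {
  if (!is.numeric(bit_depth) || length(bit_depth) != 1L ||
      !(bit_depth %in% c(8, 16))) {
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  }
  as.integer(bit_depth)
}

check_block_size <- function(block_size, require_mult8 = TRUE) {
  if (!is.numeric(block_size) || length(block_size) != 1L ||
      is.na(block_size) || block_size < (if (require_mult8) 8 else 1) ||
      block_size != floor(block_size)) {
    stop("`block_size` must be a single integer >= 8", call. = FALSE)
  }
  if (require_mult8 && block_size %% 8 != 0) {
    stop("`block_size` must be divisible by 8", call. = FALSE)
  }
  as.integer(block_size)
}
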