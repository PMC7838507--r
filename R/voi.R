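# VOI loader: pick a resolution level for a navigation window, enumerate the
# covering blocks at that level, and deliver the VOI progressively one
# bit-plane at a time (most significant first), optionally stopping at the
# top half of the planes (half-bit mode).

#' Axis-aligned volume of interest
#'
#' A half-open box `[x_min, x_max) x [y_min, y_max) x [z_min, z_max)` in
#' level-1 (full resolution) voxel coordinates, 0-based.
#'
#' @param x_min,x_max,y_min,y_max,z_min,z_max Integer box bounds, min < max.
#' @return A list of class `bitvox_box`.
#' @export
voi_box <- function(x_min, x_max, y_min, y_max, z_min, z_max) {
  v <- c(x_min, x_max, y_min, y_max, z_min, z_max)
  if (anyNA(v) || any(v != floor(v))) {
    stop("box bounds must be integers", call. = FALSE)
  }
  if (x_min >= x_max || y_min >= y_max || z_min >= z_max) {
    stop("degenerate box: need min < max on every axis", call. = FALSE)
  }
  structure(list(x_min = as.integer(x_min), x_max = as.integer(x_max),
                 y_min = as.integer(y_min), y_max = as.integer(y_max),
                 z_min = as.integer(z_min), z_max = as.integer(z_max)),
            class = "bitvox_box")
}

box_extents <- function(box) {
  c(box$x_max - box$x_min, box$y_max - box$y_min, box$z_max - box$z_min)
}

#' Resolution level for a navigation window
#'
#' The level at which a window is loaded is driven by its voxel volume `V`
#' against a per-request cap of `M` mebivoxels (2^20 voxels):
#'
#'   `R = floor(log_base(V / (1024 * 1024 * M)))`,
#'
#' clamped to the valid level range `[1, meta$levels]`. Larger windows map
#' monotonically to coarser levels. `M` defaults to 20; the log base defaults
#' to 2 (see the package vignette for the base-2 vs base-8 discussion).
#'
#' @param box A [voi_box()] in level-1 voxel coordinates.
#' @param meta A [dataset_meta()].
#' @param M VOI size cap in mebivoxels per request.
#' @param log_base Base of the logarithm in the level formula.
#' @return Integer level in `1..meta$levels`.
#' @examples
#' meta <- dataset_meta("d1", c(13913, 18000, 5115), bit_depth = 8)
#' resolution_level(voi_box(0, 1024, 0, 1024, 0, 160), meta)  # 3
#' @export
resolution_level <- function(box, meta, M = 20, log_base = 2) {
  stopifnot(inherits(box, "bitvox_box"))
  if (!is.numeric(M) || length(M) != 1L || M < 1) {
    stop("`M` must be a number >= 1", call. = FALSE)
  }
  V <- prod(as.double(box_extents(box)))
  r_raw <- floor(log(V / (1024 * 1024 * M), base = log_base))
  as.integer(min(max(r_raw, 1), meta$levels))
}

#' Blocks covering a box at a level
#'
#' Maps a level-1 box to level-`r` coordinates (`floor(min / 2^(r-1))`,
#' `ceiling(max / 2^(r-1))`), clips it to the level extent, and returns the
#' minimal set of 0-based block coordinates covering it.
#'
#' @inheritParams resolution_level
#' @param r Pyramid level.
#' @return A tibble with columns `r`, `i`, `j`, `k`, ordered i-major (z
#'   slowest), matching the reformatter's write order. Empty when the box
#'   misses the dataset entirely.
#' @export
blocks_for_box <- function(box, r, meta) {
  stopifnot(inherits(box, "bitvox_box"))
  if (r < 1 || r > meta$levels) stop("level out of range", call. = FALSE)
  lev <- level_box(box, r)
  d <- level_dims(meta$dims, r)
  lo <- pmax(lev$lo, 0L)
  hi <- pmin(lev$hi, d)
  if (any(lo >= hi)) {
    return(tibble::tibble(r = integer(), i = integer(), j = integer(),
                          k = integer()))
  }
  bs <- meta$block_size
  kb <- (lo[1] %/% bs):((hi[1] - 1L) %/% bs)
  jb <- (lo[2] %/% bs):((hi[2] - 1L) %/% bs)
  ib <- (lo[3] %/% bs):((hi[3] - 1L) %/% bs)
  grid <- expand.grid(k = kb, j = jb, i = ib)   # k fastest
  tibble::tibble(r = as.integer(r), i = as.integer(grid$i),
                 j = as.integer(grid$j), k = as.integer(grid$k))
}

# level-r half-open box of a level-1 box (unclipped)
level_box <- function(box, r) {
  s <- 2^(r - 1)
  list(lo = as.integer(floor(c(box$x_min, box$y_min, box$z_min) / s)),
       hi = as.integer(ceiling(c(box$x_max, box$y_max, box$z_max) / s)))
}

#' Stitch blocks into a VOI array
#'
#' Places decoded blocks into the level-`r` crop of the box, dropping block
#' padding and anything outside the box or the dataset extent.
#'
#' @param blocks Named list mapping `"i_j_k"` to cubic block arrays.
#' @param box A [voi_box()] in level-1 coordinates.
#' @param r Level the blocks belong to.
#' @param meta A [dataset_meta()].
#' @return 3D integer array with the level-`r` box extents (clipped to the
#'   dataset).
#' @export
assemble <- function(blocks, box, r, meta) {
  lev <- level_box(box, r)
  d <- level_dims(meta$dims, r)
  lo <- pmax(lev$lo, 0L)
  hi <- pmin(lev$hi, d)
  if (any(lo >= hi)) stop("box does not intersect the dataset", call. = FALSE)
  bs <- meta$block_size
  out <- array(0L, dim = hi - lo)
  cover <- blocks_for_box(box, r, meta)
  for (n in seq_len(nrow(cover))) {
    i <- cover$i[n]; j <- cover$j[n]; k <- cover$k[n]
    key <- paste(i, j, k, sep = "_")
    blk <- blocks[[key]]
    if (is.null(blk)) stop("missing block ", key, " for assembly", call. = FALSE)
    b0 <- c(k, j, i) * bs                       # block origin, level coords
    src_lo <- pmax(lo, b0)
    src_hi <- pmin(hi, b0 + bs, d)              # clip padding at volume edge
    if (any(src_lo >= src_hi)) next
    bx <- (src_lo[1] - b0[1] + 1L):(src_hi[1] - b0[1])
    by <- (src_lo[2] - b0[2] + 1L):(src_hi[2] - b0[2])
    bz <- (src_lo[3] - b0[3] + 1L):(src_hi[3] - b0[3])
    ox <- (src_lo[1] - lo[1] + 1L):(src_hi[1] - lo[1])
    oy <- (src_lo[2] - lo[2] + 1L):(src_hi[2] - lo[2])
    oz <- (src_lo[3] - lo[3] + 1L):(src_hi[3] - lo[3])
    out[ox, oy, oz] <- blk[bx, by, bz, drop = FALSE]
  }
  out
}

#' Load a VOI progressively, one bit-plane at a time
#'
#' Transfers the bitBlocks covering `box` plane-major: all plane-1 files
#' first, then plane 2, and so on, emitting a refined VOI after each plane.
#' Refinement `m` equals the top-m-bit quantization of the fully-loaded VOI
#' ([quantize_top()]), so per-voxel error is bounded by
#' [max_error_bound()]`(m, B)` and shrinks monotonically. In half-bit mode
#' only the top `B / 2` planes are transferred — half the files — which on
#' high-contrast data changes the image very little.
#'
#' @param box A [voi_box()] in level-1 voxel coordinates.
#' @param location Local root, base URL or `bitvox_store` of a converted
#'   dataset.
#' @param meta Optional [dataset_meta()]; read from the store when missing.
#' @param level Pyramid level to load; defaults to
#'   [resolution_level()] of the box.
#' @param half_bit Transfer only the most significant half of the planes.
#' @param M,log_base Passed to [resolution_level()] when `level` is missing.
#' @param callback Optional `function(voi)` invoked with each refinement as
#'   soon as its plane has fully arrived, before the next plane is fetched
#'   (the hook a renderer would attach to).
#' @return A list of refinements; each element has fields `m` (planes merged),
#'   `level`, `data` (3D integer array) and `complete`. The last refinement is
#'   the full image in full-bit mode. The attribute `"transferred"` records
#'   every bitBlock file fetched, in transfer order.
#' @export
load_progressive <- function(box, location, meta = NULL, level = NULL,
                             half_bit = FALSE, M = 20, log_base = 2,
                             callback = NULL) {
  stopifnot(inherits(box, "bitvox_box"))
  loc <- as_store(location)
  if (is.null(meta)) meta <- read_metadata(loc)
  r <- if (is.null(level)) resolution_level(box, meta, M, log_base) else as.integer(level)
  B <- meta$bit_depth
  P <- if (half_bit) B %/% 2L else B
  cover <- blocks_for_box(box, r, meta)
  if (!nrow(cover)) stop("box does not intersect the dataset", call. = FALSE)
  bs <- meta$block_size
  accum <- list()
  for (n in seq_len(nrow(cover))) {
    accum[[paste(cover$i[n], cover$j[n], cover$k[n], sep = "_")]] <-
      array(0L, dim = rep(bs, 3L))
  }
  out <- vector("list", P)
  log <- vector("list", P * nrow(cover))
  nlog <- 0L
  for (m in seq_len(P)) {
    # transfer phase: all plane-m files of the covering set
    for (n in seq_len(nrow(cover))) {
      key <- paste(cover$i[n], cover$j[n], cover$k[n], sep = "_")
      ref <- bitplane_ref(r, cover$i[n], cover$j[n], cover$k[n], m)
      plane <- read_bitblock(loc, ref)
      nlog <- nlog + 1L
      log[[nlog]] <- bitblock_relpath(ref)
      bits <- unpack_bits_msb(plane$payload)
      accum[[key]] <- accum[[key]] + array(bits * bitwShiftL(1L, B - m),
                                           dim = rep(bs, 3L))
    }
    # merge phase: refinement m is available before plane m+1 is requested
    voi <- structure(list(m = m, level = r,
                          data = assemble(accum, box, r, meta),
                          complete = (m == P)),
                     class = "bitvox_voi")
    out[[m]] <- voi
    if (!is.null(callback)) callback(voi)
  }
  attr(out, "transferred") <- unlist(log)
  out
}

#' Load a VOI in one shot
#'
#' Convenience wrapper: the final refinement of [load_progressive()].
#'
#' @inheritParams load_progressive
#' @param planes Planes to merge, default all (`1:B`).
#' @return 3D integer array.
#' @export
load_voi <- function(box, location, meta = NULL, level = NULL, planes = NULL,
                     M = 20, log_base = 2) {
  loc <- as_store(location)
  if (is.null(meta)) meta <- read_metadata(loc)
  r <- if (is.null(level)) resolution_level(box, meta, M, log_base) else as.integer(level)
  B <- meta$bit_depth
  if (is.null(planes)) planes <- seq_len(B)
  cover <- blocks_for_box(box, r, meta)
  if (!nrow(cover)) stop("box does not intersect the dataset", call. = FALSE)
  blocks <- list()
  for (n in seq_len(nrow(cover))) {
    refs <- lapply(planes, function(b)
      bitplane_ref(r, cover$i[n], cover$j[n], cover$k[n], b))
    pls <- lapply(refs, function(ref) read_bitblock(loc, ref))
    blocks[[paste(cover$i[n], cover$j[n], cover$k[n], sep = "_")]] <-
      merge_planes(pls, B)
  }
  assemble(blocks, box, r, meta)
}

#' @export
print.bitvox_voi <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bitvox VOI refinement m=%d, level %d, %d x %d x %d%s\n",
              x$m, x$level, d[1], d[2], d[3],
              if (x$complete) " (complete)" else ""))
  invisible(x)
}
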