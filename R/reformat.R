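# Reformatter: raw volume -> on-disk bitBlock tree. Builds the pyramid level
# by level, dices each level into blocks, splits every block into bit-plane
# payloads and writes them through the store. Memory stays bounded by
# streaming one z-slab of block_size depth at a time; the downsampled slab is
# appended to a temporary raw file that becomes the next level's source.

#' Downsample a volume by 2x per axis
#'
#' Each output voxel is the arithmetic mean of its up-to-2x2x2 source
#' neighborhood (fewer voxels at odd edges), rounded half-up. Output
#' dimensions are `ceiling(dim / 2)` per axis. `method = "stride"` instead
#' keeps every second voxel (the one at the even 0-based index).
#'
#' @param a 3D integer array indexed `[x, y, z]`.
#' @param method `"mean"` (default) or `"stride"`.
#' @return 3D integer array with ceil-halved dimensions.
#' @examples
#' downsample2x(array(c(10L, 20L, 30L), dim = c(3, 1, 1)))  # 15, 30
#' @export
downsample2x <- function(a, method = c("mean", "stride")) {
  method <- match.arg(method)
  d <- dim(a)
  if (is.null(d) || length(d) != 3L) stop("`a` must be a 3D array", call. = FALSE)
  if (method == "stride") {
    out <- a[seq(1, d[1], by = 2), seq(1, d[2], by = 2), seq(1, d[3], by = 2),
             drop = FALSE]
    storage.mode(out) <- "integer"
    return(out)
  }
  s <- a
  storage.mode(s) <- "double"
  cnt <- array(1, dim = d)
  for (axis in 1:3) {
    s <- halve_axis_sum(s, axis)
    cnt <- halve_axis_sum(cnt, axis)
  }
  out <- floor(s / cnt + 0.5)   # mean, rounded half-up
  storage.mode(out) <- "integer"
  out
}

# Pairwise sum along one axis; a lone trailing element passes through.
halve_axis_sum <- function(a, axis) {
  d <- dim(a)
  n <- d[axis]
  if (n == 1L) return(a)
  odd <- seq(1, n, by = 2)
  even <- seq(2, n, by = 2)
  idx <- function(i) {
    args <- list(a)
    ii <- rep(list(quote(expr = )), 3)
    ii[[axis]] <- i
    do.call(`[`, c(args, ii, list(drop = FALSE)))
  }
  if (n %% 2L == 0L) {
    idx(odd) + idx(even)
  } else {
    lead <- if (n > 1) idx(odd[-length(odd)]) + idx(even) else NULL
    tail <- idx(n)
    if (is.null(lead)) tail else {
      dd <- d; dd[axis] <- ceiling(n / 2)
      out <- array(0, dim = dd)
      args_head <- rep(list(quote(expr = )), 3)
      args_head[[axis]] <- seq_len(dd[axis] - 1L)
      out <- do.call(`[<-`, c(list(out), args_head, list(lead)))
      args_tail <- rep(list(quote(expr = )), 3)
      args_tail[[axis]] <- dd[axis]
      do.call(`[<-`, c(list(out), args_tail, list(tail)))
    }
  }
}

#' Dice a volume into fixed-size blocks
#'
#' Splits a level volume into a ceil-grid of non-overlapping cubes of edge
#' `block_size`, zero-padding edge blocks to full size. Blocks are returned
#' in (i, j, k) lexicographic order (z index slowest-changing first, then y,
#' then x — i.e. k varies fastest).
#'
#' @param a 3D integer array indexed `[x, y, z]`.
#' @param block_size Block edge length.
#' @return A list of elements `list(i, j, k, data)` where `data` is the
#'   zero-padded cubic block and i, j, k are 0-based block indices along
#'   z, y, x respectively.
#' @export
dice <- function(a, block_size) {
  block_size <- check_block_size(block_size)
  d <- dim(a)
  if (is.null(d) || length(d) != 3L) stop("`a` must be a 3D array", call. = FALSE)
  g <- as.integer(ceiling(d / block_size))
  out <- vector("list", prod(g))
  n <- 0L
  for (i in 0:(g[3] - 1L)) for (j in 0:(g[2] - 1L)) for (k in 0:(g[1] - 1L)) {
    x0 <- k * block_size; y0 <- j * block_size; z0 <- i * block_size
    x1 <- min(x0 + block_size, d[1])
    y1 <- min(y0 + block_size, d[2])
    z1 <- min(z0 + block_size, d[3])
    blk <- array(0L, dim = rep(block_size, 3L))
    blk[seq_len(x1 - x0), seq_len(y1 - y0), seq_len(z1 - z0)] <-
      a[(x0 + 1):x1, (y0 + 1):y1, (z0 + 1):z1, drop = FALSE]
    n <- n + 1L
    out[[n]] <- list(i = i, j = j, k = k, data = blk)
  }
  out
}

#' Convert a source volume into a bitBlock tree
#'
#' Runs the full reformatting pipeline: plans the pyramid, streams each level
#' in z-slabs of `block_size` depth, dices each slab into blocks, splits every
#' block into bit-plane payloads and writes one LZW-compressed TIFF per plane
#' under `out_root`, then writes `metadata.json`. The downsampled copy of each
#' slab is spooled to a temporary raw file that serves as the next level's
#' input, so peak memory is bounded by a couple of z-slabs, never a whole
#' level.
#'
#' While conversion is running an `.incomplete` sentinel file sits in
#' `out_root`; it is removed on success, so its presence flags a partial tree.
#'
#' @param source A `bitvox_source` (see [vol_source_array()] and friends).
#' @param out_root Output directory (created if needed).
#' @param block_size Block edge length, a multiple of 8. Default 128.
#' @param name Dataset name recorded in the metadata.
#' @param voxel_size Physical voxel size (um) recorded in the metadata.
#' @param downsample `"mean"` or `"stride"`, see [downsample2x()].
#' @param force Overwrite an existing complete tree. Default `FALSE`: refusing
#'   to clobber a finished conversion.
#' @return The [dataset_meta()] of the converted dataset, invisibly.
#' @export
reformat <- function(source, out_root, block_size = 128L, name = "dataset",
                     voxel_size = c(1, 1, 1),
                     downsample = c("mean", "stride"), force = FALSE) {
  stopifnot(inherits(source, "bitvox_source"))
  downsample <- match.arg(downsample)
  meta <- dataset_meta(name, source$dims, voxel_size, source$bit_depth,
                       block_size, downsample)
  if (file.exists(file.path(out_root, "metadata.json")) &&
      !file.exists(file.path(out_root, ".incomplete")) && !force) {
    stop("out_root already holds a complete dataset; use force = TRUE",
         call. = FALSE)
  }
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_root)) stop("cannot create ", out_root, call. = FALSE)
  sentinel <- file.path(out_root, ".incomplete")
  file.create(sentinel)

  plan <- plan_pyramid(meta)
  bs <- meta$block_size
  B <- meta$bit_depth
  loc <- store_local(out_root)
  cur <- source
  tmp_files <- character(0)
  con <- NULL
  on.exit({
    if (!is.null(con)) tryCatch(close(con), error = function(e) NULL)
    unlink(tmp_files)
  }, add = TRUE)

  for (r in seq_len(meta$levels)) {
    d <- level_dims(meta$dims, r)
    next_d <- as.integer(ceiling(d / 2))
    want_next <- r < meta$levels
    next_file <- NULL
    if (want_next) {
      next_file <- tempfile(fileext = ".raw")
      tmp_files <- c(tmp_files, next_file)
      con <- file(next_file, "wb")
    }
    gz <- as.integer(ceiling(d[3] / bs))
    for (i in 0:(gz - 1L)) {
      z0 <- i * bs
      z1 <- min(z0 + bs, d[3])
      slab <- cur$read_box(0L, d[1], 0L, d[2], z0, z1)
      write_slab_blocks(loc, slab, r, i, bs, B)
      if (want_next) {
        down <- downsample2x(slab, method = downsample)
        writeBin(as.integer(down), con, size = B / 8, endian = "little")
      }
    }
    if (want_next) {
      close(con)
      con <- NULL
      cur <- vol_source_raw(next_file, next_d, B)
    }
  }
  write_metadata(loc, meta)
  unlink(sentinel)
  invisible(meta)
}

# Dice one z-slab (block row i of level r) and write all bit-plane files.
write_slab_blocks <- function(loc, slab, r, i, bs, B) {
  d <- dim(slab)
  gx <- as.integer(ceiling(d[1] / bs))
  gy <- as.integer(ceiling(d[2] / bs))
  for (j in 0:(gy - 1L)) for (k in 0:(gx - 1L)) {
    x0 <- k * bs; y0 <- j * bs
    x1 <- min(x0 + bs, d[1]); y1 <- min(y0 + bs, d[2])
    blk <- array(0L, dim = rep(bs, 3L))
    blk[seq_len(x1 - x0), seq_len(y1 - y0), seq_len(d[3])] <-
      slab[(x0 + 1):x1, (y0 + 1):y1, , drop = FALSE]
    planes <- split_planes(blk, B)
    for (p in planes) {
      write_bitblock(loc, bitplane_ref(r, i, j, k, p$b), p)
    }
  }
}

#' Address of one bit-plane file
#'
#' @param r Pyramid level (1 = full resolution).
#' @param i,j,k 0-based block indices along z, y, x.
#' @param b Bit-plane index, 1 = most significant.
#' @return A list of class `bitvox_ref`.
#' @export
bitplane_ref <- function(r, i, j, k, b) {
  v <- c(r = r, i = i, j = j, k = k, b = b)
  if (anyNA(v) || any(v != floor(v)) || r < 1 || b < 1 || i < 0 || j < 0 || k < 0) {
    stop("invalid bitBlock address", call. = FALSE)
  }
  structure(list(r = as.integer(r), i = as.integer(i), j = as.integer(j),
                 k = as.integer(k), b = as.integer(b)),
            class = "bitvox_ref")
}

#' @export
print.bitvox_ref <- function(x, ...) {
  cat(sprintf("bitBlock ref %s\n", bitblock_relpath(x)))
  invisible(x)
}
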