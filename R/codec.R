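# Bit-plane codec: lossless decomposition of a voxel block into per-plane
# packed payloads and exact partial/full reconstruction.
#
# Conventions (recorded in dataset metadata):
#   * plane index b runs 1..B with b = 1 the MOST significant bit;
#   * voxels are traversed x-fastest, then y, then z — R's native
#     column-major order for an array indexed [x, y, z];
#   * 8 consecutive voxels pack into one byte MSB-first (the first voxel
#     lands in bit 7). R's packBits()/rawToBits() are LSB-first, so each
#     group of 8 is reversed around them.

#' Split a voxel block into bit-plane payloads
#'
#' Decomposes a cubic block of B-bit voxels into B packed binary payloads,
#' one per bit significance position. Plane 1 carries the most significant
#' bit of every voxel; plane B the least. The decomposition is lossless:
#' [merge_planes()] over all B planes reproduces the block exactly.
#'
#' @param block 3D integer array, cubic, indexed `[x, y, z]`, values in
#'   `[0, 2^bit_depth - 1]`.
#' @param bit_depth Bits per voxel (8 or 16).
#' @return A list of `bit_depth` objects of class `bitvox_bitplane`, each with
#'   fields `b` (plane index), `payload` (raw vector, `block_size^3 / 8`
#'   bytes) and `block_size`.
#' @examples
#' blk <- array(171L, dim = c(8, 8, 8))
#' planes <- split_planes(blk, 8)
#' identical(merge_planes(planes, 8), blk)
#' @export
split_planes <- function(block, bit_depth) {
  bit_depth <- check_bit_depth(bit_depth)
  bs <- check_cubic_block(block)
  v <- as.integer(block)
  if (anyNA(v) || any(v < 0L) || any(v > bitwShiftL(1L, bit_depth) - 1L)) {
    stop(sprintf("block values must lie in [0, %d]",
                 bitwShiftL(1L, bit_depth) - 1L), call. = FALSE)
  }
  lapply(seq_len(bit_depth), function(b) {
    bits <- bitwAnd(bitwShiftR(v, bit_depth - b), 1L)
    new_bitplane(b, pack_bits_msb(bits), bs)
  })
}

#' Merge bit-plane payloads into a voxel block
#'
#' Reconstructs a block from any subset of its bit-planes; absent planes
#' contribute zero. Merging planes `1..m` yields the top-m-bit quantization
#' `(v %/% 2^(B - m)) * 2^(B - m)` of the original value `v`.
#'
#' @param planes List of `bitvox_bitplane` objects with distinct indices.
#' @param bit_depth Bits per voxel of the full decomposition.
#' @return 3D integer array indexed `[x, y, z]`.
#' @export
merge_planes <- function(planes, bit_depth) {
  bit_depth <- check_bit_depth(bit_depth)
  if (!is.list(planes)) stop("`planes` must be a list", call. = FALSE)
  idx <- vapply(planes, function(p) as.integer(p$b), 0L)
  if (anyDuplicated(idx)) {
    stop("duplicate bit-plane index in `planes`", call. = FALSE)
  }
  if (length(idx) && (any(idx < 1L) || any(idx > bit_depth))) {
    stop(sprintf("plane indices must lie in 1..%d", bit_depth), call. = FALSE)
  }
  if (!length(planes)) {
    stop("cannot infer block size from an empty plane list; ",
         "use array(0L, dim = rep(bs, 3)) directly", call. = FALSE)
  }
  bs <- unique(vapply(planes, function(p) as.integer(p$block_size), 0L))
  if (length(bs) != 1L) stop("planes disagree on block_size", call. = FALSE)
  v <- integer(bs^3)
  for (p in planes) {
    bits <- unpack_bits_msb(p$payload)
    v <- v + bits * bitwShiftL(1L, bit_depth - as.integer(p$b))
  }
  array(as.integer(v), dim = rep(bs, 3L))
}

#' Quantize a block to its top m bits
#'
#' Voxelwise `(v %/% 2^(B - m)) * 2^(B - m)`: the value reconstructed from
#' the m most significant bit-planes alone. The reference operation for
#' progressive-refinement checks.
#'
#' @inheritParams split_planes
#' @param m Number of most-significant planes kept, `1 <= m <= bit_depth`.
#' @return 3D integer array of the same shape.
#' @export
quantize_top <- function(block, m, bit_depth) {
  bit_depth <- check_bit_depth(bit_depth)
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1 ||
      m > bit_depth || m != floor(m)) {
    stop(sprintf("`m` must be an integer in 1..%d", bit_depth), call. = FALSE)
  }
  shift <- bit_depth - as.integer(m)
  out <- bitwShiftL(bitwShiftR(as.integer(block), shift), shift)
  array(out, dim = dim(block))
}

#' Worst-case error after m bit-planes
#'
#' The largest possible absolute difference between a B-bit value and its
#' top-m-bit quantization: `2^(B - m) - 1`, achieved by values whose low
#' `B - m` bits are all ones.
#'
#' @param m Number of most-significant planes merged.
#' @param bit_depth Bits per voxel.
#' @return Integer bound.
#' @export
max_error_bound <- function(m, bit_depth) {
  bit_depth <- check_bit_depth(bit_depth)
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1 ||
      m > bit_depth || m != floor(m)) {
    stop(sprintf("`m` must be an integer in 1..%d", bit_depth), call. = FALSE)
  }
  bitwShiftL(1L, bit_depth - as.integer(m)) - 1L
}

# ---- packing primitives ----

# bits: integer vector of 0/1, length a multiple of 8, in voxel scan order.
# Packs MSB-first: bits[1] -> bit 7 of byte 1. packBits() is LSB-first, so
# reverse each group of 8 first.
pack_bits_msb <- function(bits) {
  n <- length(bits)
  stopifnot(n %% 8L == 0L)
  m <- matrix(bits, nrow = 8L)
  packBits(as.logical(m[8:1, , drop = FALSE]), type = "raw")
}

# Inverse of pack_bits_msb: raw vector -> integer 0/1 vector, scan order.
unpack_bits_msb <- function(payload) {
  m <- matrix(as.integer(rawToBits(payload)), nrow = 8L)
  as.integer(m[8:1, , drop = FALSE])
}

new_bitplane <- function(b, payload, block_size) {
  structure(list(b = as.integer(b), payload = payload,
                 block_size = as.integer(block_size)),
            class = "bitvox_bitplane")
}

check_cubic_block <- function(block) {
  d <- dim(block)
  if (is.null(d) || length(d) != 3L || length(unique(d)) != 1L) {
    stop("`block` must be a cubic 3D array", call. = FALSE)
  }
  if (d[1] %% 8L != 0L) {
    stop("block edge must be a multiple of 8", call. = FALSE)
  }
  as.integer(d[1])
}

#' @export
print.bitvox_bitplane <- function(x, ...) {
  cat(sprintf("bitvox bit-plane b=%d, block %d^3, payload %d bytes\n",
              x$b, x$block_size, length(x$payload)))
  invisible(x)
}
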