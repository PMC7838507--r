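# Shared fixtures, built once per test run and cached in this environment.
# Everything is generated in code; nothing is read from disk fixtures.

.fixture_cache <- new.env(parent = emptyenv())

# Small random 8-bit volume with awkward (non-block-multiple) dims, plus its
# reformatted tree. Used across store/voi/reformat tests.
small_tree <- function() {
  if (is.null(.fixture_cache$small)) {
    set.seed(401)
    vol <- array(sample(0:255, 40 * 33 * 20, replace = TRUE),
                 dim = c(40, 33, 20))
    root <- file.path(tempdir(), "bitvox-small-tree")
    unlink(root, recursive = TRUE)
    meta <- reformat(vol_source_array(vol, 8), root, block_size = 16,
                     name = "small")
    .fixture_cache$small <- list(vol = vol, root = root, meta = meta)
  }
  .fixture_cache$small
}

# Small deterministic phantom (scaled-down spec) for synth/view tests.
small_phantom <- function() {
  if (is.null(.fixture_cache$phantom)) {
    spec <- phantom_spec(dims = c(64, 48, 40), n_somas = 4,
                         soma_radius = c(3, 5), n_fibers = 2,
                         fiber_steps = 20, seed = 7)
    .fixture_cache$phantom <- c(make_phantom(spec), list(spec = spec))
  }
  .fixture_cache$phantom
}

# --- independent oracles ---

# Brute-force mean-downsample: loop over output voxels, average the
# <=2x2x2 neighborhood, round half-up.
oracle_downsample_mean <- function(a) {
  d <- dim(a)
  nd <- ceiling(d / 2)
  out <- array(0L, dim = nd)
  for (i in seq_len(nd[1])) for (j in seq_len(nd[2])) for (k in seq_len(nd[3])) {
    xs <- (2 * i - 1):min(2 * i, d[1])
    ys <- (2 * j - 1):min(2 * j, d[2])
    zs <- (2 * k - 1):min(2 * k, d[3])
    out[i, j, k] <- as.integer(floor(mean(a[xs, ys, zs]) + 0.5))
  }
  out
}

# Brute-force even-odd point-in-polygon for a single point (ray casting,
# written independently of the package's vectorized version).
oracle_point_in_poly <- function(px, py, v) {
  n <- nrow(v)
  crossings <- 0L
  for (e in seq_len(n)) {
    x1 <- v[e, 1]; y1 <- v[e, 2]
    f <- if (e == n) 1L else e + 1L
    x2 <- v[f, 1]; y2 <- v[f, 2]
    if ((y1 > py) != (y2 > py)) {
      xint <- (x2 - x1) * (py - y1) / (y2 - y1) + x1
      if (px < xint) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# 6-connected component count of a logical 3D array (iterative flood fill).
oracle_n_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  ncomp <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    ncomp <- ncomp + 1L
    stack <- start
    lab[start] <- ncomp
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pos <- arrayInd(cur, d)
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        nb <- pos
        nb[ax] <- nb[ax] + s
        if (nb[ax] < 1L || nb[ax] > d[ax]) next
        lin <- nb[1] + d[1] * (nb[2] - 1L) + d[1] * d[2] * (nb[3] - 1L)
        if (mask[lin] && lab[lin] == 0L) {
          lab[lin] <- ncomp
          stack <- c(stack, lin)
        }
      }
    }
  }
  ncomp
}
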