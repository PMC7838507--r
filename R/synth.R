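# Synthetic fluorescence-like phantoms: sparse bright somas (Gaussian blobs)
# and fibers (random-walk tubes) on a dark background, blurred and corrupted
# with additive Gaussian noise, then clipped and quantized to bit depth.
# Deterministic given the seed: a single RNG stream drives, in order, soma
# centers and radii, then per-fiber start points, directions and step
# perturbations, then the noise field.

#' Phantom specification
#'
#' Defaults describe a high-contrast, sparsely labelled volume of the kind
#' produced by fMOST/light-sheet imaging of GFP-labelled mouse brain: a
#' handful of bright somas and thin fibers over a dark, mildly noisy
#' background.
#'
#' @param dims Integer triple, >= 32 per axis. Default 300 x 256 x 200.
#' @param n_somas Number of somas (Gaussian blobs).
#' @param soma_radius Length-2 range of soma radii in voxels.
#' @param n_fibers Number of fibers (random-walk tubes).
#' @param fiber_radius Tube radius in voxels.
#' @param fiber_steps Steps per fiber walk.
#' @param amplitude Peak structure intensity above background.
#' @param background Background intensity.
#' @param blur_sigma Gaussian blur sigma in voxels (0 disables).
#' @param noise_sigma Additive Gaussian noise sigma (0 disables).
#' @param bit_depth 8 or 16.
#' @param seed RNG seed; the whole phantom is a pure function of the spec.
#' @return A list of class `bitvox_phantom_spec`.
#' @export
phantom_spec <- function(dims = c(300L, 256L, 200L), n_somas = 12L,
                         soma_radius = c(4, 8), n_fibers = 6L,
                         fiber_radius = 1.5, fiber_steps = 60L,
                         amplitude = 200L, background = 10L,
                         blur_sigma = 1.5, noise_sigma = 4,
                         bit_depth = 8L, seed = 42L) {
  dims <- check_dims(dims)
  bit_depth <- check_bit_depth(bit_depth)
  if (any(dims < 32L)) stop("phantom dims must be >= 32 per axis", call. = FALSE)
  maxv <- 2^bit_depth - 1
  if (amplitude > maxv) stop("amplitude exceeds bit depth", call. = FALSE)
  if (background >= amplitude) stop("background must be < amplitude", call. = FALSE)
  structure(list(dims = dims, n_somas = as.integer(n_somas),
                 soma_radius = as.numeric(soma_radius),
                 n_fibers = as.integer(n_fibers),
                 fiber_radius = as.numeric(fiber_radius),
                 fiber_steps = as.integer(fiber_steps),
                 amplitude = as.integer(amplitude),
                 background = as.integer(background),
                 blur_sigma = as.numeric(blur_sigma),
                 noise_sigma = as.numeric(noise_sigma),
                 bit_depth = bit_depth, seed = as.integer(seed)),
            class = "bitvox_phantom_spec")
}

#' Generate a phantom volume with ground truth
#'
#' Somas are spherical Gaussian blobs at uniformly random, mutually separated
#' centers; fibers are random-walk polylines rasterized as tubes of constant
#' radius. The intensity field is
#' `background + structures`, Gaussian-blurred, plus Gaussian noise, clipped
#' to `[0, 2^B - 1]` and quantized. Ground truth lists soma centers as
#' [ann_point()] and fiber polylines as [ann_line()].
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (3D integer array `[x, y, z]`) and `truth`
#'   (list of annotations).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "bitvox_phantom_spec"))
  d <- spec$dims
  set.seed(spec$seed)
  field <- array(0, dim = d)
  truth <- list()

  # --- somas ---
  centers <- matrix(0, nrow = 0, ncol = 3)
  radii <- numeric(0)
  if (spec$n_somas > 0) {
    max_r <- max(spec$soma_radius)
    margin <- 2 * max_r
    if (any(d - 2 * margin < 1)) {
      stop("volume too small for requested soma radii", call. = FALSE)
    }
    tries <- 0L
    while (nrow(centers) < spec$n_somas) {
      tries <- tries + 1L
      if (tries > 500L * spec$n_somas) {
        stop("infeasible packing: could not place ", spec$n_somas,
             " somas after ", tries, " attempts", call. = FALSE)
      }
      cand <- margin + stats::runif(3) * (d - 2 * margin)
      r <- stats::runif(1, spec$soma_radius[1], spec$soma_radius[2])
      # blobs fall below half-amplitude ~1.7 r from center; 2.5 r plus a blur
      # allowance keeps thresholded components disjoint
      min_sep <- 2.5 * pmax(r, radii) + 4 + 2 * spec$blur_sigma
      if (nrow(centers) == 0 ||
          all(sqrt(colSums((t(centers) - cand)^2)) >= min_sep)) {
        centers <- rbind(centers, cand)
        radii <- c(radii, r)
      }
    }
    for (s in seq_len(nrow(centers))) {
      field <- add_blob(field, centers[s, ], radii[s], spec$amplitude)
      truth[[length(truth) + 1L]] <-
        ann_point(centers[s, ] - 1, label = sprintf("soma_%d", s))
    }
  }

  # --- fibers ---
  if (spec$n_fibers > 0) {
    for (f in seq_len(spec$n_fibers)) {
      start <- stats::runif(3) * (d - 1)
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      pts <- matrix(0, nrow = spec$fiber_steps + 1L, ncol = 3)
      pts[1, ] <- start
      step_len <- 2
      for (s in seq_len(spec$fiber_steps)) {
        dir <- dir + stats::rnorm(3, sd = 0.25)
        dir <- dir / sqrt(sum(dir^2))
        nxt <- pts[s, ] + step_len * dir
        nxt <- pmin(pmax(nxt, 0), d - 1)
        pts[s + 1L, ] <- nxt
      }
      field <- add_tube(field, pts, spec$fiber_radius, spec$amplitude)
      truth[[length(truth) + 1L]] <-
        ann_line(pts, radius = spec$fiber_radius, label = sprintf("fiber_%d", f))
    }
  }

  img <- spec$background + field
  if (spec$blur_sigma > 0) img <- gaussian_blur3d(img, spec$blur_sigma)
  if (spec$noise_sigma > 0) {
    img <- img + stats::rnorm(length(img), sd = spec$noise_sigma)
  }
  maxv <- 2^spec$bit_depth - 1
  vol <- array(as.integer(pmin(pmax(round(img), 0), maxv)), dim = d)
  list(volume = vol, truth = truth)
}

# Add a spherical Gaussian blob; values capped at `amplitude` when blobs and
# tubes overlap so structure intensity never exceeds the nominal peak.
add_blob <- function(field, center, r, amplitude) {
  d <- dim(field)
  w <- ceiling(3 * r)
  lo <- pmax(floor(center - w), 1)
  hi <- pmin(ceiling(center + w), d)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- (xs - center[1])^2
  dy2 <- (ys - center[2])^2
  dz2 <- (zs - center[3])^2
  g <- amplitude * exp(-outer(outer(dx2, dy2, `+`), dz2, `+`) / (2 * (r / 2)^2))
  field[xs, ys, zs] <- pmin(field[xs, ys, zs] + g, amplitude)
  field
}

# Rasterize a polyline as a constant-intensity tube of given radius.
add_tube <- function(field, pts, radius, amplitude) {
  d <- dim(field)
  rr <- radius
  for (s in seq_len(nrow(pts) - 1L)) {
    a <- pts[s, ]; b <- pts[s + 1L, ]
    lo <- pmax(floor(pmin(a, b) - rr), 1)
    hi <- pmin(ceiling(pmax(a, b) + rr), d)
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    grid <- expand.grid(x = xs, y = ys, z = zs)
    ab <- b - a
    len2 <- sum(ab^2)
    ap <- cbind(grid$x - a[1], grid$y - a[2], grid$z - a[3])
    t <- if (len2 > 0) pmin(pmax(ap %*% ab / len2, 0), 1) else numeric(nrow(ap))
    closest <- cbind(a[1] + t * ab[1], a[2] + t * ab[2], a[3] + t * ab[3])
    dist2 <- rowSums((cbind(grid$x, grid$y, grid$z) - closest)^2)
    hit <- dist2 <= rr^2
    if (any(hit)) {
      idx <- cbind(grid$x[hit], grid$y[hit], grid$z[hit])
      field[idx] <- amplitude
    }
  }
  field
}

# Separable 3D Gaussian blur with a truncated (3 sigma), renormalized kernel.
# Edges are handled by kernel renormalization over the in-bounds support.
gaussian_blur3d <- function(a, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-rad:rad, sd = sigma)
  k <- k / sum(k)
  for (axis in 1:3) a <- convolve_axis(a, k, axis)
  a
}

# 1D convolution along one axis as a banded-matrix multiply; rows of the
# kernel matrix are renormalized so edge voxels average only in-bounds taps.
convolve_axis <- function(a, k, axis) {
  d <- dim(a)
  n <- d[axis]
  rad <- (length(k) - 1L) / 2
  K <- matrix(0, n, n)
  for (off in -rad:rad) {
    idx <- seq_len(n - abs(off))
    rows <- idx + max(0L, -off)
    cols <- idx + max(0L, off)
    K[cbind(rows, cols)] <- k[off + rad + 1L]
  }
  K <- K / rowSums(K)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  res <- K %*% matrix(ap, nrow = n)
  aperm(array(res, dim = d[perm]), order(perm))
}

#' Build a complete fixture dataset
#'
#' Generates a phantom, reformats it into a bitBlock tree under `out_root`,
#' and writes the ground-truth annotations alongside as `truth.json`.
#'
#' @param out_root Output directory.
#' @param spec A [phantom_spec()]; the default is the package's standard
#'   soma-fiber fixture.
#' @param block_size Block edge length for the tree. Default 32 (a desk-scale
#'   stand-in for the full-scale 128).
#' @param force Passed to [reformat()].
#' @return The dataset's [dataset_meta()], invisibly.
#' @export
make_fixture_dataset <- function(out_root, spec = phantom_spec(),
                                 block_size = 32L, force = FALSE) {
  ph <- make_phantom(spec)
  meta <- reformat(vol_source_array(ph$volume, spec$bit_depth), out_root,
                   block_size = block_size, name = "phantom",
                   force = force)
  save_annotations(file.path(out_root, "truth.json"), ph$truth)
  invisible(meta)
}
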