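# 2D presentation and vector annotation. Projections operate on VOI arrays
# indexed [x, y, z]; annotations live in global level-1 voxel coordinates so
# they survive VOI changes, with the physical voxel size recorded alongside
# for micrometre conversion.

#' Maximum intensity projection with thickness
#'
#' Projects a slab of the VOI along one axis by per-pixel maximum. The slab
#' is the half-open index range `[center - floor(t/2), center + ceiling(t/2))`
#' (1-based indices), clipped to the volume.
#'
#' @param voi 3D integer array indexed `[x, y, z]`.
#' @param axis `"x"`, `"y"` or `"z"` — the projection direction.
#' @param center 1-based index of the slab center along `axis`.
#' @param thickness Slab thickness in voxels (>= 1).
#' @return 2D matrix over the two remaining axes in x-before-y-before-z
#'   order (e.g. `axis = "z"` gives an `[x, y]` image).
#' @export
mip <- function(voi, axis = c("z", "y", "x"), center = NULL, thickness = 1L) {
  axis <- match.arg(axis)
  d <- dim(voi)
  if (is.null(d) || length(d) != 3L) stop("`voi` must be a 3D array", call. = FALSE)
  ax <- match(axis, c("x", "y", "z"))
  n <- d[ax]
  if (is.null(center)) center <- (n + 1L) %/% 2L
  if (thickness < 1) stop("`thickness` must be >= 1", call. = FALSE)
  lo <- center - floor(thickness / 2)
  hi <- lo + thickness            # half-open
  lo <- max(lo, 1L); hi <- min(hi, n + 1L)
  if (lo >= hi) {
    stop("projection slab does not intersect the volume", call. = FALSE)
  }
  idx <- rep(list(quote(expr = )), 3)
  idx[[ax]] <- lo:(hi - 1L)
  slab <- do.call(`[`, c(list(voi), idx, list(drop = FALSE)))
  apply(slab, setdiff(1:3, ax), max)
}

#' Orthogonal slices through a point
#'
#' @param voi 3D integer array indexed `[x, y, z]`.
#' @param point Integer triple of 1-based indices inside the VOI.
#' @return List with matrices `xy` (slice at z = point\[3\]), `yz` (at x) and
#'   `xz` (at y).
#' @export
ortho_slices <- function(voi, point) {
  d <- dim(voi)
  if (is.null(d) || length(d) != 3L) stop("`voi` must be a 3D array", call. = FALSE)
  p <- as.integer(point)
  if (length(p) != 3L || anyNA(p) || any(p < 1L) || any(p > d)) {
    stop("`point` must be a 1-based index triple inside the VOI", call. = FALSE)
  }
  list(xy = voi[, , p[3], drop = TRUE],
       yz = voi[p[1], , , drop = TRUE],
       xz = voi[, p[2], , drop = TRUE])
}

#' Annotation constructors
#'
#' Three vector annotation types, all in global level-1 voxel coordinates:
#' a labelled point (e.g. a soma), a polyline with optional tube radius
#' (e.g. a neuron fiber) and a closed planar contour on one slice (e.g. a
#' brain outline). Contours are implicitly closed: the first vertex is not
#' repeated.
#'
#' @param position Numeric triple (x, y, z).
#' @param label Text label.
#' @return An object of class `bitvox_ann_point`, `bitvox_ann_line` or
#'   `bitvox_ann_contour` (all also `bitvox_ann`).
#' @export
ann_point <- function(position, label = "") {
  position <- as.numeric(position)
  if (length(position) != 3L || any(!is.finite(position))) {
    stop("`position` must be three finite numbers", call. = FALSE)
  }
  structure(list(type = "point", position = position, label = label),
            class = c("bitvox_ann_point", "bitvox_ann"))
}

#' @rdname ann_point
#' @param vertices Numeric matrix, one row per vertex: 3 columns for lines,
#'   2 (in-plane) for contours.
#' @param radius Tube radius in micrometres (optional, default 1).
#' @export
ann_line <- function(vertices, radius = 1, label = "") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3L || nrow(vertices) < 2L || any(!is.finite(vertices))) {
    stop("`vertices` must be a finite matrix with >= 2 rows and 3 columns",
         call. = FALSE)
  }
  structure(list(type = "line", vertices = unname(vertices),
                 radius = as.numeric(radius), label = label),
            class = c("bitvox_ann_line", "bitvox_ann"))
}

#' @rdname ann_point
#' @param axis Slice normal of the contour plane: `"x"`, `"y"` or `"z"`.
#' @param slice_index 0-based index of the slice along `axis`.
#' @export
ann_contour <- function(axis, slice_index, vertices, label = "") {
  axis <- match.arg(axis, c("x", "y", "z"))
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L || any(!is.finite(vertices))) {
    stop("`vertices` must be a finite matrix with >= 3 rows and 2 columns",
         call. = FALSE)
  }
  if (isTRUE(all(vertices[1, ] == vertices[nrow(vertices), ]))) {
    stop("contours are implicitly closed; do not repeat the first vertex",
         call. = FALSE)
  }
  structure(list(type = "contour", axis = axis,
                 slice_index = as.integer(slice_index),
                 vertices = unname(vertices), closed = TRUE, label = label),
            class = c("bitvox_ann_contour", "bitvox_ann"))
}

#' Rasterize a closed contour to a binary mask
#'
#' A pixel is set iff its center lies inside the closed polygon under the
#' even-odd rule. Pixel centers sit at integer coordinates: mask entry
#' `[px + 1, py + 1]` corresponds to the point `(px, py)`, 0-based. This
#' half-open convention makes an axis-aligned square with corners on pixel
#' centers `(10,10)...(20,20)` cover exactly the 10 x 10 pixels `[10, 20)^2`.
#'
#' @param contour A [ann_contour()].
#' @param slice_dims Integer pair: mask extent (nx, ny) in pixels.
#' @return Integer 0/1 matrix of dimension `slice_dims`.
#' @export
contour_to_mask <- function(contour, slice_dims) {
  stopifnot(inherits(contour, "bitvox_ann_contour"))
  slice_dims <- as.integer(slice_dims)
  if (length(slice_dims) != 2L || any(slice_dims < 1L)) {
    stop("`slice_dims` must be two positive integers", call. = FALSE)
  }
  v <- contour$vertices
  if (polygon_area(v) == 0) {
    warning("degenerate (zero-area) contour; returning empty mask")
    return(matrix(0L, slice_dims[1], slice_dims[2]))
  }
  px <- rep(0:(slice_dims[1] - 1L), times = slice_dims[2])
  py <- rep(0:(slice_dims[2] - 1L), each = slice_dims[1])
  inside <- point_in_polygon_evenodd(px, py, v)
  matrix(as.integer(inside), slice_dims[1], slice_dims[2])
}

# Vectorized even-odd crossing test. Points exactly on a lower/left boundary
# count as inside, upper/right as outside (the standard half-open rule).
point_in_polygon_evenodd <- function(px, py, vertices) {
  n <- nrow(vertices)
  inside <- logical(length(px))
  xi <- vertices[, 1]; yi <- vertices[, 2]
  xj <- vertices[c(n, seq_len(n - 1)), 1]
  yj <- vertices[c(n, seq_len(n - 1)), 2]
  for (e in seq_len(n)) {
    crosses <- (yi[e] > py) != (yj[e] > py)
    if (!any(crosses)) next
    xint <- (xj[e] - xi[e]) * (py - yi[e]) / (yj[e] - yi[e]) + xi[e]
    inside <- xor(inside, crosses & (px < xint))
  }
  inside
}

polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(n, seq_len(n - 1))
  abs(sum(v[j, 1] * v[, 2] - v[, 1] * v[j, 2])) / 2
}

#' Annotation file I/O
#'
#' Annotations are stored as a JSON document: a list of typed records plus
#' the voxel size (um) for physical-unit conversion. Coordinates are kept in
#' level-1 voxel space at double precision; the round trip is lossless.
#'
#' @param path JSON file path.
#' @param annotations List of [ann_point()] / [ann_line()] / [ann_contour()]
#'   objects.
#' @param voxel_size Numeric triple recorded in the file (um per voxel).
#' @return `load_annotations()` returns the list of annotation objects, with
#'   the voxel size attached as attribute `voxel_size`.
#' @export
save_annotations <- function(path, annotations, voxel_size = c(1, 1, 1)) {
  if (!all(vapply(annotations, inherits, TRUE, what = "bitvox_ann"))) {
    stop("`annotations` must all be bitvox_ann objects", call. = FALSE)
  }
  doc <- list(
    format = "bitvox-annotations",
    version = "1.0",
    voxel_size_um = as.numeric(voxel_size),
    annotations = lapply(annotations, unclass)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_annotations
#' @export
load_annotations <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  if (!identical(doc$format, "bitvox-annotations")) {
    stop(errorCondition("not a bitvox annotation file",
                        class = c("bitvox_format_error", "error")))
  }
  anns <- lapply(doc$annotations, function(a) {
    switch(a$type,
      point = ann_point(unlist(a$position), a$label),
      line = ann_line(matrix(unlist(a$vertices), ncol = 3, byrow = !is.matrix(a$vertices)),
                      a$radius, a$label),
      contour = ann_contour(a$axis, a$slice_index,
                            matrix(unlist(a$vertices), ncol = 2,
                                   byrow = !is.matrix(a$vertices)),
                            a$label),
      stop(errorCondition(paste0("unknown annotation type tag: ", a$type),
                          class = c("bitvox_format_error", "error")))
    )
  })
  attr(anns, "voxel_size") <- as.numeric(doc$voxel_size_um)
  anns
}

#' Export line annotations as SWC
#'
#' Writes one SWC node per polyline vertex: parent of the first vertex of
#' each line is -1, every later vertex parents its predecessor. The SWC
#' radius column carries the line's tube radius (default 1.0). Structure
#' type is 0 (undefined).
#'
#' @param lines Non-empty list of [ann_line()] objects.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
export_swc <- function(lines, path) {
  if (!length(lines)) stop("`lines` must be non-empty", call. = FALSE)
  if (!all(vapply(lines, inherits, TRUE, what = "bitvox_ann_line"))) {
    stop("`lines` must all be ann_line objects", call. = FALSE)
  }
  rows <- list()
  id <- 0L
  for (ln in lines) {
    first <- id + 1L
    for (v in seq_len(nrow(ln$vertices))) {
      id <- id + 1L
      parent <- if (v == 1L) -1L else id - 1L
      rows[[id]] <- sprintf("%d 0 %.6g %.6g %.6g %.6g %d",
                            id, ln$vertices[v, 1], ln$vertices[v, 2],
                            ln$vertices[v, 3],
                            if (is.null(ln$radius) || is.na(ln$radius)) 1
                            else ln$radius,
                            parent)
    }
  }
  writeLines(c("# SWC export (bitvox); coordinates in level-1 voxels",
               unlist(rows)), path)
  invisible(path)
}

#' @rdname export_swc
#' @export
read_swc <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  lines <- list()
  starts <- which(tab$parent == -1)
  bounds <- c(starts, nrow(tab) + 1L)
  for (s in seq_along(starts)) {
    seg <- tab[bounds[s]:(bounds[s + 1] - 1L), ]
    lines[[s]] <- ann_line(as.matrix(seg[, c("x", "y", "z")]),
                           radius = seg$radius[1])
  }
  lines
}

#' @export
print.bitvox_ann <- function(x, ...) {
  extra <- switch(x$type,
    point = sprintf("at (%g, %g, %g)", x$position[1], x$position[2], x$position[3]),
    line = sprintf("%d vertices, radius %g", nrow(x$vertices), x$radius),
    contour = sprintf("%d vertices on %s-slice %d", nrow(x$vertices), x$axis,
                      x$slice_index))
  cat(sprintf("bitvox %s annotation%s %s\n", x$type,
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "", extra))
  invisible(x)
}
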