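test_that("MIP over a slab equals the brute-force maximum", {
  ph <- small_phantom()
  voi <- ph$volume

  # thickness 1 is the slice itself
  expect_identical(mip(voi, "z", center = 10, thickness = 1), voi[, , 10])
  # full-depth slab is the whole-axis max
  expect_identical(mip(voi, "z", center = 20, thickness = 1000),
                   apply(voi, c(1, 2), max))
  expect_identical(mip(voi, "x", center = 30, thickness = 1000),
                   apply(voi, c(2, 3), max))

  # arbitrary slabs against a direct max oracle
  set.seed(61)
  for (case in 1:10) {
    ax <- sample(c("x", "y", "z"), 1)
    nax <- dim(voi)[match(ax, c("x", "y", "z"))]
    ctr <- sample(1:nax, 1)
    t <- sample(1:nax, 1)
    got <- mip(voi, ax, center = ctr, thickness = t)
    lo <- max(ctr - floor(t / 2), 1)
    hi <- min(ctr - floor(t / 2) + t - 1, nax)
    idx <- rep(list(quote(expr = )), 3)
    idx[[match(ax, c("x", "y", "z"))]] <- lo:hi
    slab <- do.call(`[`, c(list(voi), idx, list(drop = FALSE)))
    expect_identical(got, apply(slab, setdiff(1:3, match(ax, c("x", "y", "z"))),
                                max))
  }

  # a single bright voxel appears at its (row, col)
  v <- array(0L, dim = c(10, 12, 8))
  v[3, 7, 5] <- 99L
  expect_identical(mip(v, "z", 5, 3)[3, 7], 99L)
  expect_error(mip(v, "z", center = 100, thickness = 2), "slab")

  # MIP values always come from the input value set
  expect_true(all(mip(voi, "y", 20, 7) %in% as.vector(voi)))
})

test_that("orthogonal slices equal direct array indexing", {
  ph <- small_phantom()
  voi <- ph$volume
  sl <- ortho_slices(voi, c(10, 20, 30))
  expect_identical(sl$xy, voi[, , 30])
  expect_identical(sl$yz, voi[10, , ])
  expect_identical(sl$xz, voi[, 20, ])

  cst <- array(5L, dim = c(8, 8, 8))
  slc <- ortho_slices(cst, c(4, 4, 4))
  expect_true(all(slc$xy == 5L) && all(slc$yz == 5L) && all(slc$xz == 5L))

  expect_error(ortho_slices(voi, c(0, 1, 1)), "inside")
  expect_error(ortho_slices(voi, c(1, 1, 999)), "inside")
})

test_that("contour masks follow the even-odd pixel-center rule exactly", {
  # axis-aligned square with corners on pixel centers: half-open 10x10 fill
  sq <- ann_contour("z", 0, rbind(c(10, 10), c(20, 10), c(20, 20), c(10, 20)))
  mask <- contour_to_mask(sq, c(32, 32))
  expect_identical(sum(mask), 100L)
  expect_identical(unname(which(mask == 1L, arr.ind = TRUE)[1, ]),
                   c(11L, 11L))  # pixel (10, 10), 0-based
  expect_identical(mask[21, 15], 0L)  # pixel (20, 14): right edge excluded

  # random simple polygons vs the brute-force oracle on every pixel
  set.seed(62)
  for (case in 1:12) {
    nv <- sample(3:7, 1)
    ang <- sort(stats::runif(nv, 0, 2 * pi))
    rad <- stats::runif(nv, 3, 14)
    v <- cbind(16 + rad * cos(ang), 16 + rad * sin(ang))  # star-shaped: simple
    cont <- ann_contour("z", 0, v)
    mask <- contour_to_mask(cont, c(32, 32))
    for (px in 0:31) for (py in 0:31) {
      expect_identical(mask[px + 1, py + 1],
                       as.integer(oracle_point_in_poly(px, py, v)))
    }
  }

  # fully-outside polygon yields an empty mask
  far <- ann_contour("z", 0, rbind(c(100, 100), c(110, 100), c(110, 110)))
  expect_identical(sum(contour_to_mask(far, c(32, 32))), 0L)

  # degenerate polygon: empty mask with a warning
  flat <- ann_contour("z", 0, rbind(c(1, 1), c(5, 1), c(9, 1)))
  expect_warning(m0 <- contour_to_mask(flat, c(16, 16)), "degenerate")
  expect_identical(sum(m0), 0L)
})

test_that("annotation JSON round-trips losslessly and rejects unknown tags", {
  anns <- list(
    ann_point(c(10.25, 20.5, 30.75), label = "soma_1"),
    ann_line(rbind(c(0, 0, 0), c(1.5, 2.5, 3.5), c(10, 10, 10)),
             radius = 2.25, label = "fiber"),
    ann_contour("z", 15, rbind(c(1.1, 2.2), c(30.3, 2.2), c(15.5, 28.8)),
                label = "outline")
  )
  path <- tempfile(fileext = ".json")
  save_annotations(path, anns, voxel_size = c(0.32, 0.32, 2))
  back <- load_annotations(path)
  expect_length(back, 3L)
  expect_identical(back[[1]]$position, anns[[1]]$position)
  expect_identical(back[[2]]$vertices, anns[[2]]$vertices)
  expect_identical(back[[2]]$radius, 2.25)
  expect_identical(back[[3]]$vertices, anns[[3]]$vertices)
  expect_identical(back[[3]]$axis, "z")
  expect_identical(attr(back, "voxel_size"), c(0.32, 0.32, 2))

  # empty list round trip
  save_annotations(path, list())
  expect_length(load_annotations(path), 0L)

  # unknown type tag is a format error naming the tag
  bad <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  bad$annotations <- list(list(type = "blob", position = c(1, 2, 3)))
  jsonlite::write_json(bad, path, auto_unbox = TRUE)
  err <- tryCatch(load_annotations(path), error = function(e) e)
  expect_s3_class(err, "bitvox_format_error")
  expect_match(conditionMessage(err), "blob")
})

test_that("SWC export writes parented chains and re-imports faithfully", {
  two <- ann_line(rbind(c(0, 1, 2), c(3, 4, 5)), radius = 1.5)
  path <- tempfile(fileext = ".swc")
  export_swc(list(two), path)
  tab <- read.table(path, comment.char = "#")
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$V7, c(-1L, 1L))
  expect_equal(tab$V6, c(1.5, 1.5))

  lines <- list(
    ann_line(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)), radius = 2),
    ann_line(rbind(c(9, 9, 9), c(8, 8, 8)), radius = 0.5)
  )
  export_swc(lines, path)
  back <- read_swc(path)
  expect_length(back, 2L)
  for (s in 1:2) {
    expect_equal(back[[s]]$vertices, lines[[s]]$vertices)
    expect_equal(back[[s]]$radius, lines[[s]]$radius)
  }
  expect_error(export_swc(list(), path), "non-empty")
})
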