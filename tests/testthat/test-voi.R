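test_that("window volume maps to the level given by the size-cap formula", {
  meta <- dataset_meta("d1", c(13913, 18000, 5115), c(0.32, 0.32, 2), 8)

  # 1024 x 1024 x 160 voxels at M = 20: V / (2^20 * 20) = 8 -> floor(log2 8) = 3
  expect_identical(resolution_level(voi_box(0, 1024, 0, 1024, 0, 160), meta),
                   3L)
  # small windows clamp up to level 1
  expect_identical(resolution_level(voi_box(0, 64, 0, 64, 0, 64), meta), 1L)
  # the full extent clamps down to the coarsest level:
  # floor(log2(1,280,969,910,000 / 20,971,520)) = 15 -> 9
  full <- voi_box(0, 13913, 0, 18000, 0, 5115)
  expect_identical(resolution_level(full, meta), meta$levels)

  # monotone: larger windows never map to finer levels
  set.seed(51)
  vols <- sort(round(10^stats::runif(30, 4, 12)))
  levels <- vapply(vols, function(V) {
    e <- max(1, round(V^(1 / 3)))
    resolution_level(voi_box(0, e, 0, e, 0, e), meta)
  }, 0L)
  expect_true(all(diff(levels) >= 0))

  expect_error(voi_box(0, 0, 0, 10, 0, 10), "degenerate")
})

test_that("the size cap holds exactly on power-of-eight window volumes", {
  meta <- dataset_meta("d1", c(13913, 18000, 5115), c(0.32, 0.32, 2), 8)
  M <- 20
  for (t in 1:3) {
    # V = 8^t * 2^20 * M  -> unclamped R = 3t; loaded level-R voxels <= 2^20 M
    ext <- c(1024 * 2^t, 1024 * 2^t, 20 * 2^t)
    stopifnot(prod(ext) == 8^t * 2^20 * M)   # oracle arithmetic
    box <- do.call(voi_box, as.list(c(0, ext[1], 0, ext[2], 0, ext[3])))
    R <- resolution_level(box, meta, M = M)
    expect_identical(R, 3L * t)
    loaded <- prod(ceiling(ext / 2^(R - 1)))
    expect_lte(loaded, 2^20 * M)
  }
})

test_that("block covers match an interval-arithmetic oracle", {
  meta <- dataset_meta("cov", c(300, 256, 200), bit_depth = 8, block_size = 32)

  cover <- blocks_for_box(voi_box(0, 130, 0, 10, 0, 32), 1, meta)
  expect_identical(nrow(cover), 5L)   # ceil(130/32) x 1 x 1
  expect_identical(sort(unique(cover$k)), 0:4)
  expect_identical(unique(cover$j), 0L)
  expect_identical(unique(cover$i), 0L)

  expect_identical(nrow(blocks_for_box(voi_box(0, 32, 0, 32, 0, 32), 1, meta)),
                   1L)
  # level-2 coordinates halve: [0, 64)^3 at r = 2 -> [0, 32)^3 -> 1 block
  expect_identical(nrow(blocks_for_box(voi_box(0, 64, 0, 64, 0, 64), 2, meta)),
                   1L)

  # every covering block intersects the box; every box voxel is covered
  set.seed(52)
  for (case in 1:20) {
    lo <- sapply(c(300, 256, 200), function(n) sample(0:(n - 2), 1))
    hi <- pmin(lo + sapply(c(300, 256, 200), function(n) sample(1:n, 1)),
               c(300, 256, 200))
    box <- voi_box(lo[1], hi[1], lo[2], hi[2], lo[3], hi[3])
    r <- sample(1:meta$levels, 1)
    cover <- blocks_for_box(box, r, meta)
    s <- 2^(r - 1)
    llo <- floor(lo / s); lhi <- pmin(ceiling(hi / s), level_dims(meta$dims, r))
    bs <- meta$block_size
    # oracle: enumerate blocks whose extent intersects the level box
    g <- ceiling(level_dims(meta$dims, r) / bs)
    want <- 0L
    for (i in 0:(g[3] - 1)) for (j in 0:(g[2] - 1)) for (k in 0:(g[1] - 1)) {
      b0 <- c(k, j, i) * bs
      if (all(pmax(llo, b0) < pmin(lhi, b0 + bs))) want <- want + 1L
    }
    expect_identical(nrow(cover), want)
  }

  # a box fully outside the dataset covers nothing
  expect_identical(nrow(blocks_for_box(voi_box(400, 500, 0, 10, 0, 10), 1,
                                       meta)), 0L)
})

test_that("assembly stitches multi-block VOIs and crops padding exactly", {
  fx <- small_tree()

  # single-block box: identity crop
  expect_identical(load_voi(voi_box(2, 14, 3, 9, 1, 8), fx$root, level = 1),
                   fx$vol[3:14, 4:9, 2:8])

  # x-spanning box across two blocks
  expect_identical(load_voi(voi_box(10, 30, 0, 16, 0, 16), fx$root, level = 1),
                   fx$vol[11:30, 1:16, 1:16])

  # boxes touching the padded dataset edge never expose pad voxels
  expect_identical(load_voi(voi_box(32, 40, 30, 33, 16, 20), fx$root, level = 1),
                   fx$vol[33:40, 31:33, 17:20])

  set.seed(53)
  for (case in 1:10) {
    lo <- c(sample(0:38, 1), sample(0:31, 1), sample(0:18, 1))
    hi <- pmin(lo + c(sample(1:40, 1), sample(1:33, 1), sample(1:20, 1)),
               c(40, 33, 20))
    box <- voi_box(lo[1], hi[1], lo[2], hi[2], lo[3], hi[3])
    expect_identical(load_voi(box, fx$root, level = 1),
                     fx$vol[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2],
                            (lo[3] + 1):hi[3]])
  }
})

test_that("progressive refinements quantize exactly and arrive plane-major", {
  fx <- small_tree()
  box <- voi_box(5, 38, 2, 33, 0, 20)
  full <- load_voi(box, fx$root, level = 1)
  seen <- integer(0)
  prog <- load_progressive(box, fx$root, level = 1,
                           callback = function(v) {
                             seen <<- c(seen, v$m)
                           })
  expect_identical(seen, 1:8)
  for (m in 1:8) {
    expect_identical(prog[[m]]$data, quantize_top(full, m, 8))
    err <- abs(full - prog[[m]]$data)
    expect_lte(max(err), max_error_bound(m, 8))
    expect_identical(prog[[m]]$complete, m == 8L)
  }
  expect_identical(prog[[8]]$data, full)

  # transfer order: all plane-m files precede any plane-(m+1) file
  log <- attr(prog, "transferred")
  planes_in_order <- vapply(log, function(p) parse_bitblock_relpath(p)$b, 0L)
  expect_true(all(diff(planes_in_order) >= 0))
})

test_that("half-bit mode transfers exactly half the plane files", {
  fx <- small_tree()
  box <- voi_box(0, 40, 0, 33, 0, 20)
  full <- load_progressive(box, fx$root, level = 1)
  half <- load_progressive(box, fx$root, level = 1, half_bit = TRUE)
  expect_length(half, 4L)
  expect_identical(length(attr(half, "transferred")),
                   length(attr(full, "transferred")) %/% 2L)
  # the half-bit result equals the 4-plane refinement of the full run
  expect_identical(half[[4]]$data, full[[4]]$data)
  expect_true(half[[4]]$complete)

  # a missing bitBlock is reported by address
  unlink(file.path(fx$root, "level1_data/z0/y0/x0/2.tif"))
  err <- tryCatch(load_progressive(box, fx$root, level = 1),
                  error = function(e) e)
  expect_s3_class(err, "bitvox_not_found")
  expect_match(conditionMessage(err), "level1_data/z0/y0/x0/2.tif",
               fixed = TRUE)
  # restore the file for later tests
  pl <- split_planes(dice(fx$vol, 16)[[1]]$data, 8)[[2]]
  write_bitblock(fx$root, bitplane_ref(1, 0, 0, 0, 2), pl)
  expect_identical(load_voi(box, fx$root, level = 1), fx$vol)
})
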