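test_that("mean downsampling matches the brute-force neighborhood oracle", {
  # constant volumes stay constant at ceil-halved dims
  const <- array(37L, dim = c(5, 4, 3))
  down <- downsample2x(const)
  expect_identical(dim(down), c(3L, 2L, 2L))
  expect_true(all(down == 37L))

  # mean of {0 x4, 255 x4} rounds half-up to 128
  v <- array(c(rep(0L, 4), rep(255L, 4)), dim = c(2, 2, 2))
  expect_identical(as.integer(downsample2x(v)), 128L)

  # odd-edge neighborhoods average fewer voxels
  line <- array(c(10L, 20L, 30L), dim = c(3, 1, 1))
  expect_identical(as.integer(downsample2x(line)), c(15L, 30L))

  set.seed(31)
  for (case in 1:5) {
    d <- sample(1:13, 3, replace = TRUE)
    a <- array(sample(0:255, prod(d), replace = TRUE), dim = d)
    expect_identical(downsample2x(a), oracle_downsample_mean(a))
  }

  # stride mode keeps even-index voxels
  a <- array(1:27, dim = c(3, 3, 3))
  expect_identical(downsample2x(a, method = "stride"),
                   a[c(1, 3), c(1, 3), c(1, 3)])
})

test_that("dicing pads edge blocks with zeros and loses nothing", {
  a <- array(sample(0:255, 128 * 10 * 16, replace = TRUE),
             dim = c(128, 10, 16))
  one <- dice(array(7L, dim = c(16, 16, 16)), 16)
  expect_length(one, 1L)
  expect_true(all(one[[1]]$data == 7L))

  set.seed(32)
  a <- array(sample(0:255, 130 * 10 * 16, replace = TRUE),
             dim = c(130, 10, 16))
  blocks <- dice(a, 16)
  expect_length(blocks, 9L * 1L * 1L)
  # last x-block: 2 valid columns, 14 zero-padded
  last <- blocks[[9]]
  expect_identical(last$data[1:2, 1:10, ], a[129:130, , ])
  expect_true(all(last$data[3:16, , ] == 0L))
  expect_true(all(last$data[, 11:16, ] == 0L))

  expect_length(dice(array(0L, dim = c(300, 256, 200)), 128), 3L * 2L * 2L)

  # reassembly of unpadded regions reproduces the input
  d <- dim(a)
  rebuilt <- array(0L, dim = d)
  for (blk in blocks) {
    x0 <- blk$k * 16; y0 <- blk$j * 16; z0 <- blk$i * 16
    xs <- (x0 + 1):min(x0 + 16, d[1])
    ys <- (y0 + 1):min(y0 + 16, d[2])
    zs <- (z0 + 1):min(z0 + 16, d[3])
    rebuilt[xs, ys, zs] <- blk$data[seq_along(xs), seq_along(ys), seq_along(zs)]
  }
  expect_identical(rebuilt, a)
})

test_that("reformat writes the planned tree and is end-to-end lossless", {
  fx <- small_tree()
  plan <- plan_pyramid(fx$meta)
  tifs <- list.files(fx$root, pattern = "[.]tif$", recursive = TRUE)
  expect_identical(length(tifs), as.integer(count_files(plan, 8)))
  expect_false(file.exists(file.path(fx$root, ".incomplete")))

  # full-volume, all-planes read-back is voxel-exact
  box <- voi_box(0, 40, 0, 33, 0, 20)
  expect_identical(load_voi(box, fx$root, level = 1), fx$vol)

  # every stored level equals downsample2x of the previous one
  prev <- fx$vol
  for (r in 2:fx$meta$levels) {
    d <- level_dims(fx$meta$dims, r)
    lev <- load_voi(box, fx$root, level = r)
    expect_identical(dim(lev), d)
    expect_identical(lev, downsample2x(prev))
    prev <- lev
  }
})

test_that("file accounting holds across awkward shapes", {
  set.seed(33)
  shapes <- list(c(32, 32, 32), c(33, 17, 9), c(48, 31, 40))
  for (d in shapes) {
    vol <- array(sample(0:255, prod(d), replace = TRUE), dim = d)
    root <- tempfile()
    reformat(vol_source_array(vol, 8), root, block_size = 16, name = "acc")
    expect_identical(
      length(list.files(root, pattern = "[.]tif$", recursive = TRUE)),
      as.integer(count_files(plan_pyramid(d, 16), 8)))
    unlink(root, recursive = TRUE)
  }
})

test_that("a failed conversion leaves the incomplete sentinel behind", {
  bad <- bitvox:::new_source(c(40, 40, 40), 8L, function(x0, x1, y0, y1, z0, z1) {
    stop("disk error")
  })
  root <- tempfile()
  expect_error(reformat(bad, root, block_size = 16, name = "bad"),
               "disk error")
  expect_true(file.exists(file.path(root, ".incomplete")))
  # and a complete tree refuses silent overwrite
  fx <- small_tree()
  expect_error(reformat(vol_source_array(fx$vol, 8), fx$root, block_size = 16),
               "force")
})

test_that("16-bit volumes round-trip through the full pipeline", {
  set.seed(34)
  vol <- array(sample(0:65535, 24^3, replace = TRUE), dim = c(24, 24, 24))
  root <- tempfile()
  meta <- reformat(vol_source_array(vol, 16), root, block_size = 16,
                   name = "deep")
  expect_identical(meta$bit_depth, 16L)
  box <- voi_box(0, 24, 0, 24, 0, 24)
  expect_identical(load_voi(box, root, level = 1), vol)
  # half of 16 planes = top 8
  prog <- load_progressive(box, root, level = 1, half_bit = TRUE)
  expect_length(prog, 8L)
  expect_identical(prog[[8]]$data, quantize_top(vol, 8, 16))
  unlink(root, recursive = TRUE)
})

test_that("TIFF, slice-directory and raw sources agree with the array source", {
  set.seed(35)
  vol <- array(sample(0:255, 20 * 15 * 6, replace = TRUE), dim = c(20, 15, 6))

  stack <- tempfile(fileext = ".tif")
  write_volume_tiff(vol, stack, bit_depth = 8)
  src_tiff <- vol_source_tiff(stack)
  expect_identical(src_tiff$dims, dim(vol))
  expect_identical(src_tiff$read_box(0L, 20L, 0L, 15L, 0L, 6L), vol)
  expect_identical(src_tiff$read_box(3L, 9L, 2L, 7L, 1L, 5L),
                   vol[4:9, 3:7, 2:5])

  dirp <- tempfile(); dir.create(dirp)
  for (z in 1:6) {
    tiff::writeTIFF(t(vol[, , z]) / 255, file.path(dirp, sprintf("s%02d.tif", z)),
                    bits.per.sample = 8L)
  }
  src_dir <- vol_source_dir(dirp)
  expect_identical(src_dir$read_box(0L, 20L, 0L, 15L, 0L, 6L), vol)

  rawp <- tempfile(fileext = ".raw")
  writeBin(as.integer(vol), rawp, size = 1)
  src_raw <- vol_source_raw(rawp, dim(vol), 8)
  expect_identical(src_raw$read_box(0L, 20L, 0L, 15L, 0L, 6L), vol)
  expect_identical(src_raw$read_box(5L, 12L, 0L, 15L, 2L, 4L),
                   vol[6:12, , 3:4])
  expect_error(src_raw$read_box(0L, 21L, 0L, 15L, 0L, 6L), "outside")
})
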