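# bitvox

Bit-plane-separated multiresolution volumes for teravoxel-scale microscopy,
in R.

## The problem

Whole-brain optical microscopy (fMOST, serial two-photon, light-sheet)
routinely produces 3D grayscale images of 10¹²⁺ voxels. Nobody views such a
volume whole: a viewer shows one window at a time, and over a network the
limiting resource is how many bytes must arrive before something useful is
on screen. bitvox implements a storage format and streaming discipline that
attacks this on two axes at once:

* **A block pyramid.** The volume is recursively 2×-downsampled per axis
  (ceiling division) until every axis is below the block edge *s* (default
  128), and each level is diced into a ceil-grid of *s*³ cubes. A window of
  volume *V* voxels is loaded at level

  *R* = ⌊log₂( *V* / (1024·1024·*M*) )⌋, clamped to [1, levels],

  where *M* (default 20) caps the per-request load in mebivoxels — so a
  request never drags in more than a bounded number of voxels no matter how
  large the window.

* **Bit-plane separation.** Every cube of *B*-bit voxels is stored as *B*
  separate files, one per bit significance position (plane 1 = most
  significant), each packed 8 voxels/byte into a small LZW-compressed TIFF.
  The loader fetches plane-major: after *m* planes the window equals the
  quantization (v ≫ (B−m)) ≪ (B−m) of the final image, with per-voxel error
  ≤ 2^(B−m)−1, shrinking monotonically. On high-contrast fluorescence data
  the most significant planes are sparse and compress to a small fraction
  of total storage, so the first usable image costs a fraction of the full
  transfer; "half-bit" mode stops at *B*/2 planes — half the files — with
  little visible difference.

The package covers the full pipeline: pyramid planner, lossless bit-plane
codec, a bounded-memory reformatter (TIFF stack / slice directory / raw
binary in, bitBlock tree + JSON metadata out), a static HTTP store/server
and fetcher, a progressive VOI loader, maximum-intensity projections,
orthogonal slices, point/line/contour annotations with mask rasterization
and SWC export, and a deterministic fluorescence-like phantom generator so
everything is testable without external data. A `bitvox` command-line tool
(`inst/bin/bitvox`) exposes `plan`, `reformat`, `serve`, `fetch`, `stats`,
`project`, `mask` and `synth`.

## Worked example

Plan the pyramid for a published whole-brain fMOST volume
(13,913 × 18,000 × 5,115 voxels, 8-bit) without touching a single voxel:

```r
library(bitvox)
plan_command(c(13913, 18000, 5115), block_size = 128, bit_depth = 8)
#> Volume 13913 x 18000 x 5115, block 128, 8-bit
#>   level 1:  13913 x  18000 x   5115 voxels, grid  109 x  141 x   40 = 614760 blocks
#>   level 2:   6957 x   9000 x   2558 voxels, grid   55 x   71 x   20 = 78100 blocks
#>   ...
#>   level 9:     55 x     71 x     20 voxels, grid    1 x    1 x    1 = 1 blocks
#> levels: 9
#> total blocks: 704,438
#> files (bit-plane layout, 8 planes/block): 5,635,504
#> files (one file per block): 704,438
#> raw size: 1,280,969,910,000 bytes (1193.00 GiB)
```

Nine levels and 5,635,504 bit-plane files follow from the dimensions alone;
the raw size is ~1.17 TiB. Now build a synthetic dataset, serve it, and
stream a window progressively:

```r
root <- file.path(tempdir(), "demo")
spec <- phantom_spec(dims = c(96, 96, 64), n_somas = 4, soma_radius = c(3, 5),
                     n_fibers = 3, seed = 42)
meta <- make_fixture_dataset(root, spec, block_size = 32)
glance(meta)
#> # A tibble: 1 × 8
#>   name    voxels bit_depth block_size levels total_blocks total_files raw_bytes
#> 1 phantom 589824         8         32      3           23         184    589824

rep <- plane_size_report(root, meta)
round(100 * sum(rep$fraction[1:4]), 1)   # top-4 planes' share of storage
#> [1] 13.6

h <- serve(root)                          # loopback HTTP server
box <- voi_box(16, 80, 16, 80, 8, 56)
prog <- load_progressive(box, h$url, level = 1)
for (v in prog[c(1, 2, 4, 8)])
  cat(sprintf("after %d plane(s): max abs error %d\n", v$m,
              max(abs(v$data - prog[[8]]$data))))
#> after 1 plane(s): max abs error 126
#> after 2 plane(s): max abs error 63
#> after 4 plane(s): max abs error 15
#> after 8 plane(s): max abs error 0
stop_server(h)
```

The storage split is strongly asymmetric — the four most significant planes
hold ~14% of the compressed bytes while carrying the image structure — and
each refinement halves the worst-case error until the read-back is
voxel-exact. `autoplot(rep)` and `autoplot(plan_pyramid(meta))` chart the
per-plane sizes and the pyramid shape.

See `vignettes/bitvox-methods.Rmd` for the format conventions (scan order,
bit order, TIFF geometry), the resolution-rule discussion, phantom design,
and known limitations.

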