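---
title: "Bit-plane-separated volume pyramids: format, streaming model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bit-plane-separated volume pyramids: format, streaming model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitvox)
```

## The problem

Mesoscopic whole-brain microscopy (fMOST, serial two-photon, light-sheet)
produces grayscale volumes of 10^12^ voxels and more. Browsing such a volume
over a network is bottlenecked by transfer: a viewer that must download a
complete sub-volume before showing anything feels unusable at realistic
bandwidths. bitvox implements a storage format and loading discipline built
around two observations:

1. **Multiresolution chunking.** A navigation window only ever needs a
   bounded number of voxels; storing the volume as a pyramid of 2×-downsampled
   copies, each diced into fixed-size cubes, lets a loader pick the coarsest
   level that fills the window and fetch only the cubes it covers.
2. **Bit significance is information ordering.** In a high-contrast
   fluorescence image, the most significant bits of each voxel carry the
   structures; the least significant bits are mostly sensor noise. Storing
   each bit-plane of each cube as its *own* compressed file lets the client
   fetch plane 1 of every covering cube first and render a rough image
   immediately, then refine it plane by plane while the user already
   interacts. The high planes are also the cheapest to move: being sparse,
   they compress far better than the noise-dominated low planes.

## The format

For a volume with level-1 dimensions $(d_x, d_y, d_z)$ and block edge $s$
(default 128; payloads require $s \equiv 0 \bmod 8$):

* Level $r$ has dimensions $\lceil d/2^{r-1} \rceil$ per axis; levels are
  generated until every axis is strictly below $s$. Both published level
  counts for the same whole-brain volume (9 at block 128, 7 at block 512)
  follow from exactly this stopping rule and ceiling-halving — no other
  reading reproduces them — which is why those are the package's fixed
  semantics.
* Each level is diced into a ceil-grid of $s^3$ cubes; edge cubes are
  zero-padded (background in fluorescence imaging is dark, so zero is the
  natural pad; the metadata records it).
* Each cube of $B$-bit voxels (B = 8 or 16) is decomposed into $B$ binary
  payloads. Payload $b$ holds bit $B-b$ of every voxel — plane 1 is the most
  significant — packed 8 voxels per byte. The payload is wrapped in a
  single-image 8-bit grayscale TIFF (width $s/8$, height $s^2$) and
  LZW-compressed. Compression must be lossless: payload bytes are packed
  bits, not intensities, so a lossy codec would corrupt arbitrary voxel bits.
  No LZW predictor is used for the same reason — horizontal differencing
  presumes intensity continuity that packed bits do not have.
* Files live in a four-level folder tree, `level{r}_data/z{i}/y{j}/x{k}/{b}.tif`
  with 0-based block indices, so every bitBlock has a stable relative URL,
  and a static HTTP server is a complete server implementation.

Three conventions are not forced by any printed constraint and are therefore
recorded in `metadata.json` so independent readers can interoperate: voxel
traversal order within a cube (x fastest, then y, then z — R's native array
order), bit packing order within a byte (MSB-first), and the TIFF geometry
of a payload. Any fixed choice works; an undeclared choice would make the
format ambiguous.

## Downsampling

Pyramid dimensions must halve with a ceiling (6957 from 13913) — that is
fixed by the published file accounting. The voxel *values* of coarser levels
are not constrained by any printed number, so the operator is a declared
choice: the default is the 2×2×2 arithmetic mean (fewer voxels in the
neighborhood at odd edges), rounded half-up to an integer, which is the
standard anti-aliased reduction for visualization pyramids. Strided
subsampling (`method = "stride"`) is available for bit-exact decimation.
The choice is recorded in the metadata.

The reformatter streams one z-slab of `block_size` depth at a time: a slab is
diced and written, its downsampled copy is appended to a temporary raw file,
and that file becomes the next level's input. Peak resident voxel data is
therefore a slab plus its half-size reduction, independent of volume depth —
the property that matters when the level-1 volume does not fit in memory.
Because slabs start at even offsets (the block edge is even), downsampling
never pairs voxels across a slab boundary.

## Progressive loading and the resolution rule

A navigation window is an axis-aligned half-open box in level-1 voxel
coordinates. The level it is loaded at is

$$R = \left\lfloor \log_2 \frac{(x_{max}-x_{min})(y_{max}-y_{min})(z_{max}-z_{min})}{1024 \times 1024 \times M} \right\rfloor$$

clamped to $[1, L]$, where $M$ (default 20) caps the per-request VOI size in
mebivoxels. The floor and the clamp are the package's reading: the bracket
must produce a valid integer level even for windows smaller than the cap.
One genuine open point: with 2× downsampling per axis, each level step
shrinks the voxel count 8×, so a base-8 logarithm would track the cap
tightly, while the base-2 form over-coarsens large windows. The package
implements base 2 as its default — matching the rule as published — and
exposes `log_base` for callers who want the tight variant. Within one
clamped range the rule is monotone: larger windows never load finer levels.

Loading is plane-major: all plane-1 files of the covering blocks, then all
plane-2 files, and so on; a refinement is emitted (and handed to the
caller's callback) as soon as its plane has fully arrived, before the next
plane is requested. After $m$ planes the image equals the top-$m$-bit
quantization $(v \gg (B-m)) \ll (B-m)$ of the final VOI, so the per-voxel
error is bounded by $2^{B-m}-1$ and non-increasing in $m$. Half-bit mode
stops at $B/2$ planes — exactly half the file transfers — which on
high-contrast data is visually near-indistinguishable from the full image.
R is single-threaded, so transfer and merge alternate rather than overlap;
the contract that matters (refinement $m$ available before any plane-$m{+}1$
transfer completes) is preserved, and the callback is the seam where a
threaded renderer would attach.

## The phantom generator

Module tests and the storage-asymmetry measurement need volumes with the
statistical signature of sparsely labelled fluorescence data: a dark, mildly
noisy background and a small fraction of bright voxels. The generator places
`n_somas` spherical Gaussian blobs (radius 4–8 voxels by default) at
mutually separated random centers and `n_fibers` random-walk polylines
rasterized as tubes (radius 1.5 voxels, 60 steps), then forms
`background + structures`, blurs with a separable Gaussian
(`blur_sigma = 1.5` voxels), adds Gaussian read noise
(`noise_sigma = 4`), and clips/quantizes to bit depth. The standard volume
is 300×256×200 voxels, amplitude 200 over background 10, seed 42, converted
with block 32 — a desk-scale stand-in for a teravoxel acquisition at block
128. Soma centers are rejected until pairwise separations exceed
$2.5\,r + 4 + 2\sigma_{blur}$; blobs fall below half-amplitude about
$1.7\,r$ from their center, so this keeps thresholded components disjoint
(the property the segmentation tests rely on). One RNG stream, seeded once,
drives soma placement, then fibers, then noise, in that order, so phantoms
are bit-reproducible from their spec.

What the phantom deliberately does not model: Poisson photon statistics
(noise is additive Gaussian — adequate for exercising a lossless codec,
wrong for calibrating a denoiser), PSF anisotropy, illumination gradients
and tile seams. Consequences drawn from it are about the *format* — e.g.
that the top four planes of a high-contrast volume occupy a small share of
compressed storage — not about any specific microscope. On the standard
phantom that top-4 share measures ≈13%, comfortably inside the sub-30%
regime reported for real high-contrast whole-brain data; low-contrast data
would erode the asymmetry, which is why the CLI also ships a `contrast-low`
preset.

## Numerical and degenerate-input choices

* All counting arithmetic is done in doubles (exact for integers below
  2^53^); level dimensions use the closed form $\lceil d/2^{r-1} \rceil$,
  which equals iterated ceil-halving (tested exhaustively over small ranges).
* Mean-downsample rounding is half-up (`floor(x + 0.5)`), applied to an
  exact integer-sum-over-count ratio.
* A volume already smaller than one block has a one-level pyramid; a volume
  exactly at the block size needs one halving (the stopping rule is strict
  inequality).
* Degenerate VOI boxes (min ≥ max) are rejected at construction; boxes that
  miss the dataset yield an empty cover and an error on load.
* Contour rasterization uses the even-odd rule at pixel centers with the
  standard half-open boundary convention (lower/left boundary pixels are
  inside, upper/right outside), making masks bit-reproducible.
* An interrupted conversion leaves an `.incomplete` sentinel in the output
  tree; a complete tree refuses to be overwritten without `force = TRUE`.

## Problem sizes used in the test suite

The suite runs against code-generated fixtures sized for completeness of
coverage rather than realism: a 40×33×20 random volume at block 16
(exercising every edge-padding case in a 184-file tree), phantoms between
48³ and 80×70×60 for generator properties, and the standard 300×256×200
phantom at block 32 (a 5,240-file, 5-level tree) for the end-to-end and
storage-share checks. Accounting arithmetic is additionally pinned to the
published whole-brain dimensions (13,913 × 18,000 × 5,115), which cost
nothing to plan since the planner touches no voxels.

## Known limitations

* The HTTP server is a minimal static responder intended for local serving
  and tests: sequential request handling, no TLS, no range requests, no
  caching headers. Any off-the-shelf static file server (nginx, caddy,
  `python -m http.server`) serves the same tree identically.
* One dataset per store root; multichannel and time-series data are out of
  scope.
* The loader fetches sequentially; a production viewer would pipeline
  requests across connections. The format imposes no such limit — files are
  independent.
* Annotation tooling covers storage, rasterization and SWC interchange, not
  automated detection or tracing.
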