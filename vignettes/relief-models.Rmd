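---
title: "From plate photograph to tactile solid: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From plate photograph to tactile solid: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reliefstl)
```

## The problem

Microbiology teaching leans almost entirely on sight: colony morphology on an
agar plate, cell arrangements under a microscope. For blind and visually
impaired learners that is a hard barrier. A practical remedy is to convert the
*image* of a plate or slide into a *tactile* 3D print: bright features become
raised features that can be read by touch. `reliefstl` implements that
conversion as a tested library and command-line tool: image in, watertight STL
solid out.

## The model

The conversion is a heightmap. Let $I(x, y) \in [0, 1]$ be the normalized
grayscale intensity of the (possibly resampled) image. The surface height at
each grid node is the linear map

$$ z(x, y) = b + h \cdot e(x, y), \qquad
   e = \begin{cases} I & \text{normal} \\ 1 - I & \text{inverted,} \end{cases} $$

where $b$ is the base-slab thickness (mm) and $h$ the relief height (mm) — the
"how pronounced should features feel" control. The solid is completed by a
flat bottom at $z = 0$ and vertical walls, producing a closed 2-manifold that
any slicer will accept. One STL unit is one millimetre.

Two end-to-end generators wrap this pipeline:

* **plate** — circular footprint (default 90 mm, a standard Petri dish),
  produced by masking the height grid to the inscribed disc, plus a raised rim
  annulus (default 2 mm high, 2 mm wide) so the dish boundary is feelable;
* **slide** — rectangular footprint (default 75 mm wide, the standard slide),
  with a raised frame band instead of a rim.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `relief_height_mm` | mm | 3 | tactile contrast; 0 gives a flat slab |
| `base_thickness_mm` | mm | 2 | structural slab; must be > 0 so walls never degenerate |
| `invert` | flag | off | choose whether light or dark regions rise |
| `smooth_sigma` | grid nodes | 0 (off) | photographic de-noising only |
| `resolution` | nodes | 256 | bounds a full plate below ~530k triangles |
| `diameter_mm` / `width_mm` | mm | 90 / 75 | standard dish and slide footprints |
| `rim/frame height, width` | mm | 2/2, 1.5/2 | feelable physical boundary |

Intensity is scaled **absolutely** ($I$ already lies in $[0,1]$ from the
8-bit range), not per-image min–max stretched: the same material prints at
the same height in every model, which keeps tactile reading consistent across
a teaching set. Whether the original browser tools normalize per image is
undocumented; absolute scaling is this package's documented choice.

Grayscale reduction uses the Rec. 601 luma ($0.299R + 0.587G + 0.114B$), the
de-facto default of common decoders; the source tools do not document their
weighting, so this is a design decision, not an upstream fact. Resampling is
bilinear (corner-aligned) — a smoother kernel could ring, and ringing would
print as spurious tactile bumps. 16-bit samples are reduced by integer
division by 257; alpha is composited over white (plate photographs are
opaque; a white backdrop stays low after the default non-inverted mapping).

## Solidification and its guarantees

A grid cell is emitted iff all four corner nodes are inside the footprint
mask. Each emitted cell's top is split along the fixed (low-row, low-col) →
(high-row, high-col) diagonal; the bottom repeats the cells at $z = 0$ with
reversed winding; every cell edge adjacent to an unemitted region or the grid
border extrudes a vertical wall quad. Consequences:

* **watertight by construction** — every undirected edge borders exactly two
  facets with opposite traversal, and $V - E + F = 2$;
* **no degenerate facets** — $b > 0$ forces positive wall height;
* **deterministic output** — the fixed diagonal and node-indexed vertex
  deduplication make byte-reproducible files; facet normals are recomputed
  from float32-quantized vertex winding at write time, so write → read →
  write is byte-identical.

The disc boundary is a staircase of axis-aligned walls (sub-node sized:
< 0.5 mm at default resolution) rather than a smoothed outline; stair walls
are simpler and manifold by construction. Exact-disc masks cannot produce two
cells meeting only at a corner (opposite corners of a lattice square have
equal summed squared distances to any center, so a disc cannot contain one
diagonal pair while excluding the other), which is why the disc pipeline
never pinches; hand-crafted masks that do pinch are rejected with a classed
error rather than silently emitting non-manifold geometry.

`mesh_volume()` (signed tetrahedron sum) is verified against an independent
prism-decomposition oracle; `validate_watertight()` reports boundary edges,
over-shared edges, winding conflicts, degenerate facets, component count and
Euler characteristic, and gates every STL write.

## Braille labels

Labels use Grade-1 (uncontracted) braille: 2×3 cells, letters from the
standard table, digits as the a–j patterns with one number-sign cell (dots
3-4-5-6) per digit run. Dimensions follow common tactile-signage practice:
2.5 mm dot pitch, 6 mm cell pitch, 1.5 mm dot diameter, 0.6 mm dot height.
Dots are embossed as spherical caps clamped to the dot height, additive and
localized (nodes beyond a dot radius are bitwise untouched). Two physical
guards fail loudly instead of printing an unreadable label: the grid must
resolve ≥ 3 nodes across a dot, and every node under a dot must lie on
included, unmasked area (the generators first flatten a margin strip to the
base height so dots sit on a clean field).

## What the synthetic generator emulates — and what it does not

`make_colony_image()` renders colonies as isotropic Gaussian bumps
($A e^{-r^2 / 2\sigma^2}$, default $A = 0.85$, $\sigma = 5$ px on a 256 px
image) over a uniform dark-agar background (0.1): soft edges like real colony
photographs, so downstream threshold counting tests the relief pipeline
rather than the generator. Centers sit on integer pixels inside 80% of the
inscribed radius (colonies live inside the dish, clear of rim and mask
boundary), pairwise separated by `8 * sigma` by default — at that separation
the cross-talk between bumps at the half-peak threshold is
$e^{-8} \approx 3\times10^{-4}$, so a provable margin, and the defined-count
teaching use case (generate $k$, feel and count $k$) holds 200/200 times in
the acceptance suite. Streak images place bumps along zigzag segments with
strictly decreasing counts (8:4:2:1), emulating a successful isolation
streak; the "overgrown" mode renders a confluent lawn (bump lattice at
$1.5\sigma$ spacing over 95% of the inscribed radius, so midpoints stay above
half peak and the thresholded lawn is one region covering most of the dish).

Not emulated: pigmentation and colour contrast (everything is grayscale
intensity), specular highlights and shadows of real plate photography,
agar-depth gradients, condensation, and out-of-focus microscopy artifacts. A
green count-recovery test therefore establishes that the *pipeline* preserves
well-separated bright objects as distinct touchable bumps — not that every
real photograph will segment as cleanly.

## Numerical choices and degenerate inputs

* Disc membership and annulus bands compare squared distances (no square
  roots), boundary-inclusive.
* Gaussian smoothing uses a separable kernel truncated at $4\sigma$ with
  half-sample reflect padding; it is a convex combination, so it can never
  push heights outside the data range.
* Images below 2×2 pixels, masks that leave no complete 2×2 node block, and
  non-manifold meshes are all rejected with specific condition classes;
  the CLI maps usage/parameter errors to exit 2 and processing errors to
  exit 1, naming the failing stage.
* ASCII STL uses 6-significant-digit scientific notation; binary is the
  default (a quarter of the size and what slicers expect).

## Known limitations

* JPEG and PNG are decoded by libjpeg/libpng; TIFF support is a built-in
  baseline reader (uncompressed, 8/16-bit, gray/RGB) — LZW or tiled TIFF is
  rejected.
* The image is assumed pre-cropped to the dish/slide; there is no automatic
  dish detection.
* No mesh decimation: output size is controlled only by `resolution`.
* The original web tools' exact triangulations are undocumented, so mesh
  equivalence with them is not claimed — only the same pixel-intensity-to-
  height semantics.

## A worked example

```{r example, eval = FALSE}
library(reliefstl)

# a synthetic plate with exactly 6 colonies
img <- make_colony_image(colony_field_spec(n_objects = 6, seed = 42))
png::writePNG(img$data / 255, "plate.png")

res <- generate_plate("plate.png",
                      plate_spec(relief = relief_params(3, 2)),
                      "plate.stl")
validate_watertight(res$mesh)

# the defined-count check: 6 bumps in, 6 bumps out
grid <- resample_grid(to_grayscale(img), 128)
hm <- apply_circular_mask(build_heightmap(grid, relief_params(3, 2), 90),
                          radius_mm = 45)
count_raised_regions(hm)
```
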