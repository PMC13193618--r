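# reliefstl

Convert photographs of agar plates and micrographs into **watertight,
3D-printable tactile models**. Pixel brightness becomes surface height —
colonies become bumps, growth patterns become textures — so microbiology
images can be read by touch. The package targets inclusive teaching:
blind and visually impaired learners get independent access to plate and
slide morphology, and models generated from synthetic images with a *known*
colony count support teaching and assessing cell/c.f.u. counting skills.

## The model

For normalized grayscale intensity `I(x, y) ∈ [0, 1]`, every grid node gets
the height

```
z(x, y) = b + h · e(x, y),    e = I   (or 1 − I when inverted)
```

with base-slab thickness `b` (default 2 mm) and relief height `h` (default
3 mm, the "how pronounced should it feel" control). The height grid is
closed into a solid — flat bottom at z = 0, vertical walls along the
footprint boundary — yielding a genus-0 closed 2-manifold (every edge shared
by exactly two outward-wound facets, V − E + F = 2) exported as binary or
ASCII STL, 1 unit = 1 mm.

Two generators wrap the pipeline:

* `generate_plate()` — circular Petri-dish footprint (default 90 mm) with a
  raised, feelable rim;
* `generate_slide()` — rectangular microscope-slide footprint (default
  75 mm wide) with a raised frame.

Optional Grade-1 braille labels (sample name or date) are embossed on a
flattened margin. `make_colony_image()` / `make_streak_image()` generate
deterministic synthetic plate photographs (Gaussian-bump colonies, streak
patterns, confluent lawns) with known object counts.

## Worked example

```r
library(reliefstl)

# a synthetic plate with exactly 6 colonies (deterministic in the seed)
img <- make_colony_image(colony_field_spec(n_objects = 6, seed = 42))
png::writePNG(img$data / 255, "plate.png")

res <- generate_plate("plate.png",
                      plate_spec(relief = relief_params(3, 2)),
                      "plate.stl")
#> {"grid_rows":256,"grid_cols":256,"triangles":204156,"vertices":102080,
#>  "bbox_mm":[89.294118,89.294118,4.847059],"volume_mm3":15631.213189,
#>  "stl":"plate.stl"}

validate_watertight(res$mesh)
#> <watertight_report> V=102080 E=306234 F=204156, chi=2, components=1
#>   closed 2-manifold: printable

# the defined-count teaching check: 6 colonies in, 6 touchable bumps out
grid <- resample_grid(to_grayscale(img), 128)
hm <- apply_circular_mask(build_heightmap(grid, relief_params(3, 2), 90),
                          radius_mm = 45)
count_raised_regions(hm)
#> [1] 6
```

The JSON summary says the 256×256 working grid produced a 204,156-facet
solid, ~89.3 mm across (the disc mask keeps nodes inside the 90 mm
diameter), 4.85 mm tall (2 mm base + rim/relief), enclosing ~15.6 cm³. The
watertight report confirms a printable single-component closed surface, and
thresholding the masked heightmap at `base + relief/2` recovers exactly the
6 generated colonies.

## Command line

```sh
Rscript inst/cli/reliefstl.R fixture --out plate.png --seed 42 --n 6
Rscript inst/cli/reliefstl.R plate --input plate.png --out plate.stl \
    --relief-mm 3 --base-mm 2 --diameter-mm 90 --label "EC 42"
Rscript inst/cli/reliefstl.R slide --input micrograph.png --out slide.stl \
    --width-mm 75 --invert
```

(After installation, use
`system.file("cli/reliefstl.R", package = "reliefstl")` as the script path.)
Exit codes: 0 success, 2 usage error, 1 processing error naming the failing
stage. Identical arguments produce byte-identical STL files.

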