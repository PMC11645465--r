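# rtdeinterp — de-interpolation of radiotherapy structure sets

Radiotherapy planning starts with contouring: organs at risk (OARs) and
target volumes are delineated as closed polygons on axial CT slices.
Auto-segmentation and slice interpolation fill in dense contours quickly,
but when those contours need editing, a dense stack is a liability — each
slice must be fixed by hand, and the common planning systems offer no
"undo interpolation". The practical remedy is **de-interpolation**:
delete the contours on intermediate slices so only a sparse subset
remains, edit that subset, and let the planning system re-interpolate.

`rtdeinterp` performs this thinning on standard DICOM RT Structure Set
(RTSTRUCT) files, independent of any treatment planning system. It is
aimed at medical physicists, dosimetrists and researchers who post-process
AI- or trainee-generated contours.

## The algorithm

Slices are numbered 1..N in ascending patient-z order. For a structure,
the **starting layer** s0 is its first (lowest-numbered) contoured slice.
Each contoured slice s gets a positional offset

    k = s − s0 + 1

so the start layer has k = 1. With interval n (the modular period,
conventionally 2–4):

* **keep mode** clears slice s iff `k mod n == 0` — every 1-in-n
  contoured slice is cleared, the rest survive;
* **erase mode** (`preserve_first = FALSE`) clears s iff `k mod n != 0`
  — all but every n-th slice are cleared;
* **erase mode** (`preserve_first = TRUE`) clears s iff `k mod n != 1`
  — the first slice is kept, the next n−1 cleared, and so on.

Offsets follow slice numbers, not ordinal position among contoured
slices, so gaps in the contoured range shift the pattern accordingly.
Every structure is processed independently with its own starting layer.
An optional layer range restricts clearing to a sub-stack, and a copy
option edits a duplicate structure while leaving the original untouched.

## Worked example

A phantom with one structure ("PTV") contoured on slices 10–20 of a
30-slice, 2.5 mm grid, thinned in keep mode with interval 3:

```r
library(rtdeinterp)

dir   <- tempfile("phantom")
files <- write_phantom_series(phantom_spec(), dir)   # 30 CT files + RTSTRUCT
loaded <- read_rtstruct(files$rtstruct, dir)

res <- deinterpolate_rtstruct(loaded$document, "all",
                              deinterp_params("keep", 3), loaded$grid)
print(res$report)
#> <deinterp_report> 1 structure(s)
#>   #1 'PTV': start 10, cleared 3 slice(s) [12,15,18], kept 8, removed 3 contour(s)
```

The start layer is detected as slice 10 (offset k = 1). Slice 11 has
offset 2 (not divisible by 3, kept); slices 12, 15 and 18 have offsets 3,
6 and 9 and are cleared. The surviving contoured slices are
10, 11, 13, 14, 16, 17, 19, 20. Erase mode with the same interval inverts
the pattern, leaving only slices 12, 15 and 18.

The same run from a shell, against any RTSTRUCT:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/deinterp.R", package="rtdeinterp"))') \
  --input rtstruct.dcm --ct-dir ct/ --structures PTV \
  --mode keep --interval 3 --output thinned.dcm --report report.json
```

`--dry-run` prints the clearing plan without writing; `--grid
"30:0:2.5"` (count:first_z:spacing) replaces the CT directory when only
the geometry is known. Mode and interval have no defaults on purpose: a
wrong silent default would destroy contours.

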