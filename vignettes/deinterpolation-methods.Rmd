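---
title: "De-interpolating structure-set contours: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De-interpolating structure-set contours: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtdeinterp)
```

## The problem

Dense, interpolated (or AI-generated) organ contours are slow to edit:
every axial CT slice carries a polygon that must be adjusted by hand.
De-interpolation deletes the contours on intermediate slices so a sparse
subset remains for editing, after which a planning system re-interpolates
the gaps. This package implements that thinning as a standalone operation
on DICOM RT Structure Set files.

## The clearing model

The data model is deliberately geometry-free: the algorithm never looks
at polygon shape, only at which slices carry contours.

Slices are numbered 1..N in ascending patient-z order. For each selected
structure the *starting layer* `s0` is its lowest contoured slice number,
found by walking the stack from slice 1 upward. A contoured slice `s` has
positional offset `k = s - s0 + 1` (the start layer itself has `k = 1`).
With interval `n`:

| mode | `preserve_first` | cleared when |
|------|------------------|--------------|
| keep | (ignored) | `k %% n == 0` |
| erase | `FALSE` | `k %% n != 0` |
| erase | `TRUE` | `k %% n != 1` |

```{r}
plan_clearing(10:20, deinterp_params("keep", 3))
```

Three consequences of this arithmetic are worth spelling out:

* In keep mode the start layer is never cleared (`1 %% n != 0` for all
  `n >= 2`), so `preserve_first` is a no-op there and only exercises
  erase mode.
* Keep and erase (without first-slice preservation) are exact
  complements: for the same contoured set and interval their cleared
  sets partition the contoured slices. The test suite checks this
  exhaustively for every contoured subset of a 12-slice stack and
  `n` in 2..4 against a brute-force oracle that walks the slices with a
  cyclic counter instead of modular arithmetic.
* Offsets are differences of *slice numbers*, not ranks among the
  contoured slices. A structure contoured on slices {10, 12, 14} with
  keep mode, n = 3 clears only slice 12 (`k = 3`); the gap shifts the
  pattern exactly as the slice arithmetic dictates.

A structure with several disjoint contoured z-ranges still uses one
global start layer, since the walk continues over all slices of the
image set. Re-running the tool on its own output is permitted but not
idempotent: the thinned structure has a new contoured set and the same
modular rule applies afresh.

## Parameters

* `mode` — pattern polarity. Because the bare labels are easy to invert
  in one's head ("keep" *clears* one in n), the aliases
  `clear-one-in-n` (= keep) and `keep-one-in-n` (= erase) are accepted
  everywhere.
* `interval` (n) — modular period, unitless, no default. Values 2–4 are
  the conventional editing range; larger values are accepted with a
  warning rather than rejected, since nothing in the arithmetic breaks.
* `preserve_first` — erase-mode phase choice. The command line requires
  it explicitly in erase mode because either phase is defensible and the
  wrong one silently deletes the first slice.
* `layer_range` — optional `c(lo, hi)` restricting *clearing* to a
  sub-stack; start-layer detection always uses the full contoured set,
  so the pattern's phase does not shift when a range is applied.
* `copy_before_edit` / `copy_suffix` — edit a duplicate (fresh ROI
  number, name + suffix) and keep the original untouched, the closest
  thing to an undo this operation can offer.

Mode and interval have no defaults by design: a silently assumed value
would destroy contours.

## Slice resolution and numerical choices

Contours are mapped to slices by the referenced CT image (SOP instance
UID) when available; otherwise by nearest z position. The z match must
fall *strictly* inside the half-spacing interval around a slice; a z
exactly midway between two slices raises an error instead of being
rounded, because one mis-assigned slice corrupts the whole modular
pattern. Planarity of a contour's vertices is likewise tolerated up to
half the slice spacing, so a contour maps to exactly one slice.

Slice numbering ascends with patient z. DICOM orders CT slices by
ImagePositionPatient, and nothing in the clearing arithmetic depends on
which anatomical direction "slice 1" is; the choice is documented rather
than configurable. Non-uniform slice spacing beyond tolerance triggers a
warning: the modular pattern is defined on slice indices, and on a
non-uniform grid indices and physical distance diverge.

On writing, edited structure sets receive fresh SOP/series instance UIDs
but keep the frame of reference and referenced CT series, so downstream
systems see a new structure-set instance on the same image set. Contours
that were read from a file and not edited re-emit their original
contour-data text verbatim, giving value-identical round trips for
untouched structures.

## The phantom generator

`phantom_spec()` describes a synthetic CT stack plus structures with
known contoured ranges; the default is a 30-slice, 2.5 mm grid with one
cylindrical structure contoured on slices 10–20 — the desk-scale
configuration all worked examples use. Shapes are cylinders, spheres
(radius shrinking toward the poles) and gapped cylinders (every other
slice empty, for testing gap arithmetic). Polygons are regular 24-gons
with optional seeded vertex jitter: enough vertices to resemble a real
contour, few enough to inspect by eye. CT pixel content is a constant
16×16 image, since only geometry matters here.

What the phantom does *not* emulate: realistic anatomy, multi-polygon
slices from real segmentations, oblique image orientations, non-axial
contours, or vendor-specific private DICOM attributes. Passing tests on
phantoms therefore demonstrate the slice arithmetic and the I/O contract,
not robustness to every real-world RTSTRUCT dialect — files using
compressed or big-endian transfer syntaxes are rejected explicitly.

Generation is driven by a dedicated deterministic stream (a Park–Miller
LCG seeded from the spec), so identical specs give byte-identical files
and phantom creation never perturbs the session RNG.

## Problem sizes and verification

All quantitative checks run on the 30-slice phantom (single- and
two-structure variants); the pattern invariants are verified exhaustively
over all 4095 contoured subsets of a 12-slice stack for n = 2, 3, 4 —
small enough to enumerate completely, large enough to cover every phase
and gap configuration up to three full periods. Written DICOM is
additionally cross-checked in the test suite by an independent reader
(pydicom) to guard against self-consistent but malformed output from the
package's own codec.

## Known limitations

* Re-interpolation is out of scope: the thinned structure is handed back
  to the planning system, which owns that step.
* Only little-endian uncompressed transfer syntaxes are read.
* Contour geometry is never edited — no vertex operations, no boolean
  operations, no mesh reconstruction.
* Point and open contours are carried through untouched and never
  cleared; only closed planar contours participate.
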