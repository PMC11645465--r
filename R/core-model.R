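#' Axial CT slice grid
#'
#' Describes the ordered stack of axial CT slices a structure set is
#' referenced to. Slice numbers are 1-based integers assigned in ascending
#' patient-z order, which is the frame all slice arithmetic in this package
#' counts in.
#'
#' @param z_positions Numeric vector of slice z positions in millimetres,
#'   strictly increasing.
#' @param spacing Nominal slice spacing in millimetres. Defaults to the
#'   median of consecutive differences.
#' @param tolerance Maximum allowed deviation (mm) of any consecutive
#'   z-difference from `spacing` before the grid is flagged non-uniform.
#' @param sop_instance_uids Optional character vector of the CT slices' SOP
#'   instance UIDs (one per slice), used to resolve contours that carry
#'   image references.
#'
#' @return An object of class `slice_grid` with fields `slice_count`,
#'   `z_positions`, `spacing`, `uniform`, and `sop_instance_uids`.
#' @examples
#' g <- slice_grid(seq(0, by = 2.5, length.out = 30))
#' g$slice_count
#' @export
slice_grid <- function(z_positions, spacing = NULL, tolerance = 0.01,
                       sop_instance_uids = NULL) {
  z_positions <- as.numeric(z_positions)
  if (length(z_positions) < 1L || anyNA(z_positions)) {
    stop("z_positions must be a non-empty numeric vector without NA")
  }
  if (is.unsorted(z_positions, strictly = TRUE)) {
    stop("z_positions must be strictly increasing (ascending-z slice order)")
  }
  dz <- diff(z_positions)
  if (is.null(spacing)) {
    spacing <- if (length(dz)) stats::median(dz) else 1
  }
  spacing <- as.numeric(spacing)
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be positive")
  uniform <- all(abs(dz - spacing) <= tolerance)
  if (!uniform) {
    warning("slice grid is non-uniform beyond tolerance (",
            format(tolerance), " mm); slice-number arithmetic assumes ",
            "uniform spacing", call. = FALSE)
  }
  if (!is.null(sop_instance_uids) &&
      length(sop_instance_uids) != length(z_positions)) {
    stop("sop_instance_uids must have one entry per slice")
  }
  structure(
    list(
      slice_count = length(z_positions),
      z_positions = z_positions,
      spacing = spacing,
      uniform = uniform,
      sop_instance_uids = sop_instance_uids
    ),
    class = "slice_grid"
  )
}

#' @export
print.slice_grid <- function(x, ...) {
  cat(sprintf("<slice_grid> %d slices, z %.2f..%.2f mm, spacing %.2f mm%s\n",
              x$slice_count, x$z_positions[1L],
              x$z_positions[x$slice_count], x$spacing,
              if (x$uniform) "" else " (non-uniform)"))
  invisible(x)
}

#' Map a z position to a slice number
#'
#' Finds the grid slice nearest to `z`. The match must fall strictly inside
#' the half-spacing interval around a slice: a z exactly midway between two
#' slices is ambiguous and raises an error rather than being silently
#' assigned, because a mis-assigned slice would corrupt the modular clearing
#' pattern.
#'
#' @param grid A [slice_grid()].
#' @param z z position in millimetres.
#' @return 1-based slice number.
#' @export
resolve_slice_number <- function(grid, z) {
  stopifnot(inherits(grid, "slice_grid"))
  d <- abs(grid$z_positions - z)
  i <- which.min(d)
  half <- grid$spacing / 2
  eps <- 1e-9 * max(1, abs(z))
  if (d[i] >= half - eps) {
    if (abs(d[i] - half) <= eps) {
      stop(sprintf(
        "z = %.4f mm lies midway between slices; slice assignment ambiguous",
        z), call. = FALSE)
    }
    stop(sprintf(
      "z = %.4f mm matches no slice within half-spacing tolerance (%.4f mm)",
      z, half), call. = FALSE)
  }
  i
}

#' Planar contour
#'
#' One closed polygon (or point / open polyline) lying on a single axial
#' plane, stored as patient-space millimetre coordinates.
#'
#' @param points Numeric matrix with columns x, y, z (mm), one row per
#'   vertex, in drawing order.
#' @param slice_number 1-based slice number on the referenced grid, or `NA`
#'   while unresolved.
#' @param geometric_type `"closed_planar"` (default), `"point"`, or
#'   `"open_planar"`. Only closed planar contours participate in
#'   de-interpolation; other types are carried through untouched.
#' @param referenced_sop_uid Optional SOP instance UID of the CT slice this
#'   contour references.
#' @param planarity_tol Maximum z spread (mm) tolerated across the vertices.
#' @param data_string Internal: the verbatim contour-data string from a
#'   source file, kept so an unedited contour round-trips byte-identically.
#' @return An object of class `planar_contour`.
#' @export
planar_contour <- function(points, slice_number = NA_integer_,
                           geometric_type = c("closed_planar", "point",
                                              "open_planar"),
                           referenced_sop_uid = NULL,
                           planarity_tol = 1e-3,
                           data_string = NULL) {
  geometric_type <- match.arg(geometric_type)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be an n x 3 (x, y, z) matrix")
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "z")
  if (geometric_type == "closed_planar" && nrow(points) < 3L) {
    stop("a closed planar contour needs at least 3 points")
  }
  zs <- points[, "z"]
  if (nrow(points) > 0L && diff(range(zs)) > planarity_tol) {
    stop(sprintf(
      "contour vertices are not coplanar: z spread %.4f mm exceeds %.4f mm",
      diff(range(zs)), planarity_tol))
  }
  structure(
    list(
      points = points,
      z = if (nrow(points)) stats::median(zs) else NA_real_,
      slice_number = as.integer(slice_number),
      geometric_type = geometric_type,
      referenced_sop_uid = referenced_sop_uid,
      data_string = data_string
    ),
    class = "planar_contour"
  )
}

#' Region-of-interest structure
#'
#' A named structure (organ at risk or target volume): an ROI number, a
#' display name, and its planar contours. A slice may carry several
#' polygons; they are all treated as one contoured slice.
#'
#' @param roi_number Integer identifier, unique within a structure set.
#' @param name Display name.
#' @param contours List of [planar_contour()] objects.
#' @param color Optional integer RGB triplet for display.
#' @return An object of class `rt_structure`.
#' @export
rt_structure <- function(roi_number, name, contours = list(), color = NULL) {
  roi_number <- as.integer(roi_number)
  if (length(roi_number) != 1L || is.na(roi_number)) {
    stop("roi_number must be a single integer")
  }
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("name must be a non-empty string")
  }
  ok <- vapply(contours, inherits, logical(1L), what = "planar_contour")
  if (!all(ok)) stop("contours must all be planar_contour objects")
  structure(
    list(roi_number = roi_number, name = name, contours = contours,
         color = color),
    class = "rt_structure"
  )
}

#' @export
print.rt_structure <- function(x, ...) {
  sl <- tryCatch(contoured_slices(x), error = function(e) integer())
  cat(sprintf("<rt_structure> #%d '%s': %d contour(s) on %d slice(s)\n",
              x$roi_number, x$name, length(x$contours), length(sl)))
  invisible(x)
}

#' Slices on which a structure is contoured
#'
#' Returns the distinct 1-based slice numbers carrying at least one
#' closed-planar contour of the structure, in ascending order. Multiple
#' polygons on one slice count once. Point and open contours are ignored:
#' they never participate in de-interpolation.
#'
#' @param structure An [rt_structure()] whose closed-planar contours all
#'   have a resolved `slice_number`.
#' @return Sorted integer vector of slice numbers (possibly empty).
#' @examples
#' s <- rt_structure(1, "organ", list(
#'   planar_contour(cbind(c(0, 1, 0), c(0, 0, 1), 5), slice_number = 3)
#' ))
#' contoured_slices(s)
#' @export
contoured_slices <- function(structure) {
  stopifnot(inherits(structure, "rt_structure"))
  planar <- Filter(function(ct) ct$geometric_type == "closed_planar",
                   structure$contours)
  if (length(planar) == 0L) return(integer())
  nums <- vapply(planar, function(ct) ct$slice_number, integer(1L))
  bad <- which(is.na(nums))
  if (length(bad)) {
    stop(sprintf(
      "structure '%s': contour %d has no resolved slice number",
      structure$name, bad[1L]))
  }
  sort(unique(nums))
}

#' De-interpolation parameters
#'
#' Bundles the options of a de-interpolation run. `mode` controls pattern
#' polarity: `"keep"` clears every 1-in-n contoured slice (leaving n-1 of
#' every n), `"erase"` clears every (n-1)-in-n (leaving 1 of every n). The
#' aliases `"clear-one-in-n"` (= keep) and `"keep-one-in-n"` (= erase) are
#' accepted to avoid the ambiguity of the short labels.
#'
#' @param mode `"keep"`, `"erase"`, or one of the aliases above.
#' @param interval The modular period n (integer >= 2). Values 2-4 are the
#'   conventional range; larger values are accepted with a warning.
#' @param preserve_first In erase mode, keep the structure's first contoured
#'   slice and clear the next n-1 (phase shift of the pattern). Ignored in
#'   keep mode, where the first slice is arithmetically never cleared.
#' @param layer_range Optional `c(lo, hi)` of 1-based slice numbers; slices
#'   outside the range are never cleared (start-layer detection still uses
#'   the full contoured set).
#' @param copy_before_edit Duplicate each structure and edit the copy,
#'   leaving the original untouched.
#' @param copy_suffix Suffix appended to the copied structure's name.
#' @return An object of class `deinterp_params`.
#' @examples
#' deinterp_params("keep", 3)
#' @export
deinterp_params <- function(mode, interval, preserve_first = FALSE,
                            layer_range = NULL, copy_before_edit = FALSE,
                            copy_suffix = "_edit") {
  mode <- match.arg(mode, c("keep", "erase", "clear-one-in-n",
                            "keep-one-in-n"))
  mode <- switch(mode, "clear-one-in-n" = "keep", "keep-one-in-n" = "erase",
                 mode)
  interval <- as.integer(interval)
  if (length(interval) != 1L || is.na(interval) || interval < 2L) {
    stop("interval must be a single integer >= 2")
  }
  if (interval > 4L) {
    warning("interval ", interval, " is outside the conventional 2-4 range",
            call. = FALSE)
  }
  stopifnot(is.logical(preserve_first), length(preserve_first) == 1L,
            !is.na(preserve_first))
  if (!is.null(layer_range)) {
    layer_range <- as.integer(layer_range)
    if (length(layer_range) != 2L || anyNA(layer_range) ||
        layer_range[1L] < 1L || layer_range[1L] > layer_range[2L]) {
      stop("layer_range must be c(lo, hi) with 1 <= lo <= hi")
    }
  }
  stopifnot(is.logical(copy_before_edit), length(copy_before_edit) == 1L)
  if (!is.character(copy_suffix) || length(copy_suffix) != 1L ||
      !nzchar(copy_suffix)) {
    stop("copy_suffix must be a non-empty string")
  }
  structure(
    list(mode = mode, interval = interval, preserve_first = preserve_first,
         layer_range = layer_range, copy_before_edit = copy_before_edit,
         copy_suffix = copy_suffix),
    class = "deinterp_params"
  )
}

#' @export
print.deinterp_params <- function(x, ...) {
  cat(sprintf("<deinterp_params> mode=%s interval=%d preserve_first=%s%s%s\n",
              x$mode, x$interval, x$preserve_first,
              if (is.null(x$layer_range)) "" else
                sprintf(" range=%d:%d", x$layer_range[1L], x$layer_range[2L]),
              if (x$copy_before_edit)
                paste0(" copy('", x$copy_suffix, "')") else ""))
  invisible(x)
}

# One report entry; internal constructor, validated against the partition
# invariant cleared + kept == originally contoured.
.report_entry <- function(structure, start_layer, cleared, kept,
                          contours_removed, params) {
  cleared <- sort(as.integer(cleared))
  kept <- sort(as.integer(kept))
  if (length(intersect(cleared, kept))) {
    stop("internal error: cleared and kept slice sets overlap")
  }
  list(
    roi_number = structure$roi_number,
    name = structure$name,
    start_layer = if (is.null(start_layer)) NA_integer_
                  else as.integer(start_layer),
    cleared = cleared,
    kept = kept,
    contours_removed = as.integer(contours_removed),
    mode = params$mode,
    interval = params$interval
  )
}

#' @export
print.deinterp_report <- function(x, ...) {
  cat(sprintf("<deinterp_report> %d structure(s)\n", length(x$entries)))
  for (e in x$entries) {
    cat(sprintf(
      "  #%d '%s': start %s, cleared %d slice(s) [%s], kept %d, removed %d contour(s)\n",
      e$roi_number, e$name,
      if (is.na(e$start_layer)) "-" else e$start_layer,
      length(e$cleared), paste(e$cleared, collapse = ","),
      length(e$kept), e$contours_removed))
  }
  invisible(x)
}

#' Serialise a de-interpolation report to JSON
#'
#' @param report A `deinterp_report` as returned by [deinterpolate()].
#' @param path Optional file path; when given, the JSON is written there.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "deinterp_report"))
  payload <- list(
    mode = report$params$mode,
    interval = report$params$interval,
    preserve_first = report$params$preserve_first,
    structures = lapply(report$entries, function(e) {
      list(
        roi_number = e$roi_number,
        name = e$name,
        start_layer = if (is.na(e$start_layer)) NULL else e$start_layer,
        cleared = as.list(e$cleared),
        kept = as.list(e$kept),
        contours_removed = e$contours_removed
      )
    })
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null",
                           pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
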