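#' Find the starting layer of a structure
#'
#' The starting layer is the first (lowest-numbered) slice on which the
#' structure has any contour; it is the phase origin of the modular
#' clearing pattern. The tool walks the image set from slice 1 upward, so
#' the start layer is simply the minimum contoured slice number.
#'
#' @param contoured Integer vector of contoured slice numbers (any order).
#' @return The minimum slice number, or `NA_integer_` when the structure
#'   has no contours.
#' @examples
#' find_start_layer(10:20)  # 10
#' find_start_layer(integer())  # NA
#' @export
find_start_layer <- function(contoured) {
  contoured <- as.integer(contoured)
  if (length(contoured) == 0L) return(NA_integer_)
  min(contoured)
}

#' Positional offset of a slice relative to the starting layer
#'
#' The clearing rule is phrased in terms of the difference between the
#' current slice number and the starting layer number, plus one: the start
#' layer itself has offset 1, the next slice offset 2, and so on. A slice
#' is cleared (keep mode) exactly when this offset is evenly divisible by
#' the interval n.
#'
#' @param slice Current slice number (must be >= `start`).
#' @param start Starting layer slice number.
#' @return Integer offset k = slice - start + 1.
#' @examples
#' positional_offset(11, 10)  # 2
#' positional_offset(15, 10)  # 6
#' @export
positional_offset <- function(slice, start) {
  slice <- as.integer(slice)
  start <- as.integer(start)
  if (any(is.na(slice)) || any(is.na(start))) stop("slice and start must be integers")
  if (any(slice < start)) {
    stop("slice (", paste(slice[slice < start], collapse = ","),
         ") lies before the starting layer (", start,
         "); slices before the start are never offset-evaluated")
  }
  slice - start + 1L
}

#' Plan which contoured slices to clear
#'
#' Applies the modular clearing rule to a structure's contoured slice set.
#' With start layer `s0` and offset `k = slice - s0 + 1`:
#'
#' * keep mode: clear where `k %% n == 0` (every 1-in-n cleared);
#' * erase mode, `preserve_first = FALSE`: clear where `k %% n != 0`
#'   (all but every n-th cleared);
#' * erase mode, `preserve_first = TRUE`: clear where `k %% n != 1`
#'   (keep the first, clear the next n-1, keep the (n+1)-th, ...).
#'
#' Offsets are computed from slice-number differences, not ordinal position
#' among the contoured slices, so gaps in the contoured range shift the
#' pattern exactly as the slice arithmetic dictates. An optional
#' `layer_range` restricts *clearing* to `lo <= slice <= hi`; start-layer
#' detection always uses the full contoured set.
#'
#' @param contoured Integer vector of contoured slice numbers.
#' @param params A [deinterp_params()].
#' @param roi_number Optional ROI number echoed into the plan.
#' @return An object of class `clear_plan` with fields `roi_number`,
#'   `start_layer`, `to_clear`, `kept`, `mode`, `interval`.
#' @examples
#' p <- plan_clearing(10:20, deinterp_params("keep", 3))
#' p$to_clear  # 12 15 18
#' @export
plan_clearing <- function(contoured, params, roi_number = NA_integer_) {
  stopifnot(inherits(params, "deinterp_params"))
  contoured <- sort(unique(as.integer(contoured)))
  start <- find_start_layer(contoured)
  if (is.na(start)) {
    plan <- list(roi_number = as.integer(roi_number),
                 start_layer = NA_integer_,
                 to_clear = integer(), kept = integer(),
                 mode = params$mode, interval = params$interval)
    class(plan) <- "clear_plan"
    return(plan)
  }
  k <- positional_offset(contoured, start)
  n <- params$interval
  clear <- switch(params$mode,
    keep = (k %% n) == 0L,
    erase = if (params$preserve_first) (k %% n) != 1L else (k %% n) != 0L
  )
  if (!is.null(params$layer_range)) {
    lo <- params$layer_range[1L]
    hi <- params$layer_range[2L]
    clear <- clear & contoured >= lo & contoured <= hi
  }
  plan <- list(
    roi_number = as.integer(roi_number),
    start_layer = start,
    to_clear = contoured[clear],
    kept = contoured[!clear],
    mode = params$mode,
    interval = n
  )
  class(plan) <- "clear_plan"
  plan
}

#' @export
print.clear_plan <- function(x, ...) {
  cat(sprintf("<clear_plan> roi %s, mode=%s n=%d, start %s\n",
              ifelse(is.na(x$roi_number), "-", x$roi_number), x$mode,
              x$interval,
              ifelse(is.na(x$start_layer), "-", x$start_layer)))
  cat("  clear:", if (length(x$to_clear)) paste(x$to_clear, collapse = " ")
                  else "(none)", "\n")
  cat("  keep: ", if (length(x$kept)) paste(x$kept, collapse = " ")
                  else "(none)", "\n")
  invisible(x)
}

#' Apply a clearing plan to a structure
#'
#' Removes every closed-planar contour whose slice number is in the plan's
#' `to_clear` set; all other contours (including point and open contours)
#' are passed through unchanged, point for point.
#'
#' @param structure An [rt_structure()].
#' @param plan A `clear_plan` from [plan_clearing()].
#' @param params The [deinterp_params()] the plan was made with (echoed into
#'   the report entry).
#' @return List with elements `structure` (the thinned structure) and
#'   `entry` (the per-structure report record: start layer, cleared and
#'   kept slice numbers, number of contours removed).
#' @export
apply_plan <- function(structure, plan, params) {
  stopifnot(inherits(structure, "rt_structure"), inherits(plan, "clear_plan"),
            inherits(params, "deinterp_params"))
  to_clear <- plan$to_clear
  drop <- vapply(structure$contours, function(ct) {
    ct$geometric_type == "closed_planar" && !is.na(ct$slice_number) &&
      ct$slice_number %in% to_clear
  }, logical(1L))
  out <- structure
  out$contours <- structure$contours[!drop]
  entry <- .report_entry(
    structure,
    start_layer = plan$start_layer,
    cleared = to_clear,
    kept = plan$kept,
    contours_removed = sum(drop),
    params = params
  )
  list(structure = out, entry = entry)
}

#' De-interpolate a set of structures
#'
#' Runs the full pipeline on each structure independently: detect its
#' starting layer, plan the modular clearing pattern, and remove the
#' planned contours. Each structure gets its own start layer. With
#' `copy_before_edit = TRUE` the original structure is left untouched and a
#' duplicate named `name + copy_suffix` (with a fresh ROI number) receives
#' the edits, so the operation can be undone by deleting the copy.
#'
#' @param structures List of [rt_structure()] objects to process.
#' @param params A [deinterp_params()].
#' @param grid Optional [slice_grid()]; when given, contoured slices and any
#'   `layer_range` are validated against `grid$slice_count`.
#' @return List with `structures` (the processed list) and `report`
#'   (class `deinterp_report`).
#' @examples
#' ring <- function(z, s) planar_contour(
#'   cbind(cos(seq(0, 2 * pi, length.out = 13))[-13] * 10,
#'         sin(seq(0, 2 * pi, length.out = 13))[-13] * 10, z),
#'   slice_number = s)
#' s <- rt_structure(1, "organ",
#'                   lapply(10:20, function(i) ring(i * 2.5, i)))
#' res <- deinterpolate(list(s), deinterp_params("keep", 3))
#' res$report$entries[[1]]$cleared  # 12 15 18
#' @export
deinterpolate <- function(structures, params, grid = NULL) {
  stopifnot(inherits(params, "deinterp_params"))
  if (inherits(structures, "rt_structure")) structures <- list(structures)
  ok <- vapply(structures, inherits, logical(1L), what = "rt_structure")
  if (!all(ok)) stop("structures must be rt_structure objects")
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "slice_grid"))
    if (!is.null(params$layer_range) &&
        params$layer_range[2L] > grid$slice_count) {
      stop("layer_range upper bound ", params$layer_range[2L],
           " exceeds slice count ", grid$slice_count)
    }
  }
  existing_rois <- vapply(structures, function(s) s$roi_number, integer(1L))
  next_roi <- if (length(existing_rois)) max(existing_rois) + 1L else 1L
  out <- list()
  entries <- list()
  for (s in structures) {
    contoured <- contoured_slices(s)
    if (!is.null(grid) && length(contoured) &&
        max(contoured) > grid$slice_count) {
      stop("structure '", s$name, "' is contoured on slice ",
           max(contoured), " beyond the grid's ", grid$slice_count,
           " slices")
    }
    target <- s
    if (params$copy_before_edit) {
      target$name <- paste0(s$name, params$copy_suffix)
      target$roi_number <- next_roi
      next_roi <- next_roi + 1L
    }
    plan <- plan_clearing(contoured, params, roi_number = target$roi_number)
    res <- apply_plan(target, plan, params)
    if (params$copy_before_edit) {
      out[[length(out) + 1L]] <- s  # original, untouched
    }
    out[[length(out) + 1L]] <- res$structure
    entries[[length(entries) + 1L]] <- res$entry
  }
  report <- structure(list(params = params, entries = entries),
                      class = "deinterp_report")
  list(structures = out, report = report)
}
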