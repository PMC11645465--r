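# RT Structure Set reading/writing on top of the minimal DICOM codec.
# Coordinates are patient-space millimetres as stored; no resampling or
# axis reorientation is performed.

.geom_type_to_dicom <- c(closed_planar = "CLOSED_PLANAR", point = "POINT",
                         open_planar = "OPEN_PLANAR")
.geom_type_from_dicom <- c(CLOSED_PLANAR = "closed_planar", POINT = "point",
                           OPEN_PLANAR = "open_planar",
                           OPEN_NONPLANAR = "open_planar")

# Random DICOM UID under the 2.25 (UUID-derived) root; draws from the
# session RNG so runs seeded with set.seed() are reproducible.
new_dicom_uid <- function() {
  digits <- c(sample(1:9, 1L), sample(0:9, 28L, replace = TRUE))
  paste0("2.25.", paste(digits, collapse = ""))
}

#' Build a slice grid from an explicit specification
#'
#' Lets callers describe the CT geometry without image files: the number of
#' slices, the z position of the first (lowest) slice, and the uniform
#' spacing.
#'
#' @param slice_count Number of axial slices.
#' @param first_z z position of slice 1 in millimetres.
#' @param spacing Slice spacing in millimetres.
#' @return A [slice_grid()].
#' @examples
#' grid_from_spec(30, 0, 2.5)
#' @export
grid_from_spec <- function(slice_count, first_z = 0, spacing = 2.5) {
  slice_count <- as.integer(slice_count)
  if (is.na(slice_count) || slice_count < 1L) {
    stop("slice_count must be a positive integer")
  }
  slice_grid(first_z + (seq_len(slice_count) - 1L) * spacing,
             spacing = spacing)
}

# Parse "count:first_z:spacing" (CLI syntax) into a slice_grid.
.grid_from_string <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 3L) {
    stop("grid specification must be 'count:first_z:spacing', got '", s, "'")
  }
  grid_from_spec(as.integer(parts[1L]), as.numeric(parts[2L]),
                 as.numeric(parts[3L]))
}

#' Read the geometry of a DICOM CT series
#'
#' Scans a directory of DICOM CT slices and assembles the axial slice grid
#' (z positions in ascending order, nominal spacing, SOP instance UIDs).
#' Pixel content is ignored; only geometry is used.
#'
#' @param ct_dir Directory containing the CT series.
#' @return A [slice_grid()] carrying the slices' SOP instance UIDs.
#' @export
read_ct_grid <- function(ct_dir) {
  if (!dir.exists(ct_dir)) stop("no such directory: '", ct_dir, "'")
  files <- list.files(ct_dir, full.names = TRUE)
  zs <- numeric()
  uids <- character()
  thickness <- NA_real_
  for (f in files) {
    parsed <- tryCatch(dcm_read(f), error = function(e) NULL)
    if (is.null(parsed)) next
    if (!identical(.dcm_get(parsed$dataset, "0008,0060"), "CT")) next
    ipp <- .dcm_num(parsed$dataset, "0020,0032")
    uid <- .dcm_get(parsed$dataset, "0008,0018")
    if (is.null(ipp) || length(ipp) != 3L || is.null(uid)) next
    zs <- c(zs, ipp[3L])
    uids <- c(uids, uid)
    st <- .dcm_num(parsed$dataset, "0018,0050")
    if (!is.null(st)) thickness <- st[1L]
  }
  if (length(zs) == 0L) {
    stop("no CT slices with geometry found in '", ct_dir, "'")
  }
  ord <- order(zs)
  slice_grid(zs[ord],
             spacing = if (length(zs) > 1L) NULL else thickness,
             sop_instance_uids = uids[ord])
}

# Coerce the grid_source argument of read_rtstruct into a slice_grid.
.resolve_grid_source <- function(grid_source) {
  if (inherits(grid_source, "slice_grid")) return(grid_source)
  if (is.character(grid_source) && length(grid_source) == 1L) {
    if (dir.exists(grid_source)) return(read_ct_grid(grid_source))
    if (grepl(":", grid_source, fixed = TRUE)) {
      return(.grid_from_string(grid_source))
    }
    stop("grid_source '", grid_source,
         "' is neither a directory nor a 'count:first_z:spacing' spec")
  }
  stop("grid_source must be a slice_grid, a CT directory, or a ",
       "'count:first_z:spacing' string")
}

#' Read a DICOM RT Structure Set
#'
#' Parses an RTSTRUCT file into the in-memory model, resolving every
#' closed-planar contour to a 1-based slice number on the referenced CT
#' grid. Resolution uses the contour's referenced image (SOP instance UID)
#' when the grid knows the CT UIDs; otherwise the contour z is matched to
#' the nearest slice within a strict half-spacing tolerance, with
#' ambiguity (z midway between slices) raised as an error. Point and open
#' contours are retained and flagged but never participate in clearing.
#'
#' @param path Path to the RTSTRUCT file.
#' @param grid_source The referenced CT geometry: a [slice_grid()], a
#'   directory containing the CT series, or a `"count:first_z:spacing"`
#'   string.
#' @return List with `document` (class `rtstruct_doc`) and `grid`
#'   (the resolved [slice_grid()]).
#' @export
read_rtstruct <- function(path, grid_source) {
  grid <- .resolve_grid_source(grid_source)
  parsed <- dcm_read(path)
  ds <- parsed$dataset
  modality <- .dcm_get(ds, "0008,0060")
  sop_class <- .dcm_get(ds, "0008,0016")
  if (!identical(modality, "RTSTRUCT") &&
      !identical(sop_class, DCM_UID_RTSTRUCT)) {
    stop("'", path, "' is not an RT Structure Set (modality ",
         if (is.null(modality)) "missing" else modality, ")", call. = FALSE)
  }

  # ROI number -> name from the StructureSetROISequence
  roi_seq <- .dcm_get(ds, "3006,0020", list())
  roi_names <- list()
  roi_order <- integer()
  for (item in roi_seq) {
    num <- .dcm_int(item, "3006,0022")
    nm <- .dcm_get(item, "3006,0026", paste0("ROI_", num))
    key <- as.character(num)
    if (!is.null(roi_names[[key]])) {
      stop("duplicate ROI number ", num, " in structure set")
    }
    roi_names[[key]] <- nm
    roi_order <- c(roi_order, num)
  }

  uid_to_slice <- NULL
  if (!is.null(grid$sop_instance_uids)) {
    uid_to_slice <- seq_len(grid$slice_count)
    names(uid_to_slice) <- grid$sop_instance_uids
  }

  structures <- list()
  contour_seq <- .dcm_get(ds, "3006,0039", list())
  seen_rois <- integer()
  for (item in contour_seq) {
    num <- .dcm_int(item, "3006,0084")
    key <- as.character(num)
    nm <- if (!is.null(roi_names[[key]])) roi_names[[key]]
          else paste0("ROI_", num)
    color <- .dcm_int(item, "3006,002A")
    contours <- list()
    for (ct in .dcm_get(item, "3006,0040", list())) {
      gt_dicom <- .dcm_get(ct, "3006,0042", "CLOSED_PLANAR")
      gt <- .geom_type_from_dicom[[gt_dicom]]
      if (is.null(gt)) gt <- "open_planar"
      data_string <- .dcm_get(ct, "3006,0050", "")
      vals <- as.numeric(strsplit(data_string, "\\", fixed = TRUE)[[1L]])
      pts <- matrix(vals, ncol = 3L, byrow = TRUE)
      ref_uid <- NULL
      img_seq <- .dcm_get(ct, "3006,0016", list())
      if (length(img_seq)) ref_uid <- .dcm_get(img_seq[[1L]], "0008,1155")
      slice_num <- NA_integer_
      if (!is.null(ref_uid) && !is.null(uid_to_slice) &&
          !is.na(uid_to_slice[ref_uid])) {
        slice_num <- unname(uid_to_slice[ref_uid])
      } else {
        z <- stats::median(pts[, 3L])
        if (gt == "closed_planar") {
          slice_num <- tryCatch(
            resolve_slice_number(grid, z),
            error = function(e) stop(
              "structure '", nm, "': ", conditionMessage(e), call. = FALSE))
        } else {
          slice_num <- tryCatch(resolve_slice_number(grid, z),
                                error = function(e) NA_integer_)
        }
      }
      contours[[length(contours) + 1L]] <- planar_contour(
        pts, slice_number = slice_num, geometric_type = gt,
        referenced_sop_uid = ref_uid,
        planarity_tol = grid$spacing / 2,
        data_string = data_string)
    }
    structures[[key]] <- rt_structure(num, nm, contours, color = color)
    seen_rois <- c(seen_rois, num)
  }
  # ROIs declared but carrying no contour sequence
  for (num in setdiff(roi_order, seen_rois)) {
    key <- as.character(num)
    structures[[key]] <- rt_structure(num, roi_names[[key]], list())
  }
  structures <- structures[order(vapply(structures, function(s) s$roi_number,
                                        integer(1L)))]

  doc <- structure(
    list(
      label = .dcm_get(ds, "3006,0002", "StructureSet"),
      sop_instance_uid = .dcm_get(ds, "0008,0018"),
      series_instance_uid = .dcm_get(ds, "0020,000E"),
      study_instance_uid = .dcm_get(ds, "0020,000D"),
      frame_of_reference_uid = .frame_of_reference(ds),
      referenced_series_uid = .referenced_series(ds),
      patient_name = .dcm_get(ds, "0010,0010", "Anonymous"),
      patient_id = .dcm_get(ds, "0010,0020", "ANON"),
      date = .dcm_get(ds, "0008,0020", "20240101"),
      time = .dcm_get(ds, "0008,0030", "120000"),
      structures = unname(structures),
      source = path
    ),
    class = "rtstruct_doc"
  )
  list(document = doc, grid = grid)
}

.frame_of_reference <- function(ds) {
  seq <- .dcm_get(ds, "3006,0010", list())
  if (length(seq)) .dcm_get(seq[[1L]], "0020,0052") else NULL
}

.referenced_series <- function(ds) {
  for (ref in .dcm_get(ds, "3006,0010", list())) {
    for (study in .dcm_get(ref, "3006,0012", list())) {
      for (series in .dcm_get(study, "3006,0014", list())) {
        uid <- .dcm_get(series, "0020,000E")
        if (!is.null(uid)) return(uid)
      }
    }
  }
  NULL
}

#' @export
print.rtstruct_doc <- function(x, ...) {
  cat(sprintf("<rtstruct_doc> '%s': %d structure(s)\n", x$label,
              length(x$structures)))
  for (s in x$structures) print(s)
  invisible(x)
}

#' List the structures of a structure-set document
#'
#' @param document An `rtstruct_doc`.
#' @return Data frame with one row per ROI, ordered by ROI number:
#'   `roi_number`, `name`, `n_contours` (all geometric types) and
#'   `n_slices` (distinct slices with closed-planar contours).
#' @export
list_structures <- function(document) {
  stopifnot(inherits(document, "rtstruct_doc"))
  rows <- lapply(document$structures, function(s) {
    data.frame(
      roi_number = s$roi_number,
      name = s$name,
      n_contours = length(s$contours),
      n_slices = length(contoured_slices(s)),
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(roi_number = integer(), name = character(),
               n_contours = integer(), n_slices = integer(),
               stringsAsFactors = FALSE)
  out[order(out$roi_number), , drop = FALSE]
}

# Format a point matrix as a DICOM decimal string ("x\\y\\z\\x\\y\\z...").
.format_contour_data <- function(points) {
  vals <- as.vector(t(points))
  paste(sprintf("%.4f", vals), collapse = "\\")
}

#' Write a structure-set document as a DICOM RTSTRUCT file
#'
#' Serialises the in-memory model back to a standards-conformant RT
#' Structure Set (explicit VR little endian). Contours read from a file
#' re-emit their original contour-data text verbatim, so structures the
#' edit did not touch are value-identical through a write/read round trip.
#' By default the output receives fresh SOP and series instance UIDs while
#' preserving the frame of reference and referenced CT series, marking it
#' as a new structure-set instance on the same image set.
#'
#' @param document An `rtstruct_doc`.
#' @param path Output file path.
#' @param grid Optional [slice_grid()]; when it carries CT SOP instance
#'   UIDs, contours lacking an image reference have one attached.
#' @param new_uid Generate fresh instance UIDs (default). Set `FALSE` to
#'   keep the document's UIDs, e.g. for deterministic phantom output.
#' @return The path, invisibly.
#' @export
write_rtstruct <- function(document, path, grid = NULL, new_uid = TRUE) {
  stopifnot(inherits(document, "rtstruct_doc"))
  doc <- document
  if (new_uid || is.null(doc$sop_instance_uid)) {
    doc$sop_instance_uid <- new_dicom_uid()
    doc$series_instance_uid <- new_dicom_uid()
  }
  if (is.null(doc$study_instance_uid)) doc$study_instance_uid <- new_dicom_uid()
  if (is.null(doc$frame_of_reference_uid)) {
    doc$frame_of_reference_uid <- new_dicom_uid()
  }

  uid_for_slice <- function(slice_number) {
    if (!is.null(grid) && !is.null(grid$sop_instance_uids) &&
        !is.na(slice_number) && slice_number >= 1L &&
        slice_number <= grid$slice_count) {
      grid$sop_instance_uids[[slice_number]]
    } else NULL
  }

  roi_items <- list()
  contour_items <- list()
  obs_items <- list()
  for (i in seq_along(doc$structures)) {
    s <- doc$structures[[i]]
    roi_items[[i]] <- list(
      "3006,0022" = list(vr = "IS", value = as.character(s$roi_number)),
      "3006,0024" = list(vr = "UI", value = doc$frame_of_reference_uid),
      "3006,0026" = list(vr = "LO", value = s$name),
      "3006,0036" = list(vr = "CS", value = "MANUAL")
    )
    cts <- lapply(s$contours, function(ct) {
      data_string <- if (!is.null(ct$data_string)) ct$data_string
                     else .format_contour_data(ct$points)
      item <- list(
        "3006,0042" = list(vr = "CS",
                           value = .geom_type_to_dicom[[ct$geometric_type]]),
        "3006,0046" = list(vr = "IS", value = as.character(nrow(ct$points))),
        "3006,0050" = list(vr = "DS", value = data_string)
      )
      ref <- ct$referenced_sop_uid
      if (is.null(ref)) ref <- uid_for_slice(ct$slice_number)
      if (!is.null(ref)) {
        item[["3006,0016"]] <- list(vr = "SQ", value = list(list(
          "0008,1150" = list(vr = "UI", value = DCM_UID_CT),
          "0008,1155" = list(vr = "UI", value = ref)
        )))
      }
      item
    })
    color <- if (is.null(s$color)) c(255L, 0L, 0L) else s$color
    contour_items[[i]] <- list(
      "3006,002A" = list(vr = "IS",
                         value = paste(color, collapse = "\\")),
      "3006,0040" = list(vr = "SQ", value = cts),
      "3006,0084" = list(vr = "IS", value = as.character(s$roi_number))
    )
    obs_items[[i]] <- list(
      "3006,0082" = list(vr = "IS", value = as.character(i)),
      "3006,0084" = list(vr = "IS", value = as.character(s$roi_number)),
      "3006,00A4" = list(vr = "CS", value = "ORGAN"),
      "3006,00A6" = list(vr = "PN", value = "")
    )
  }

  ref_frame_item <- list(
    "0020,0052" = list(vr = "UI", value = doc$frame_of_reference_uid)
  )
  if (!is.null(doc$referenced_series_uid)) {
    series_item <- list(
      "0020,000E" = list(vr = "UI", value = doc$referenced_series_uid)
    )
    if (!is.null(grid) && !is.null(grid$sop_instance_uids)) {
      series_item[["3006,0016"]] <- list(vr = "SQ", value = lapply(
        grid$sop_instance_uids, function(uid) list(
          "0008,1150" = list(vr = "UI", value = DCM_UID_CT),
          "0008,1155" = list(vr = "UI", value = uid)
        )))
    }
    ref_frame_item[["3006,0012"]] <- list(vr = "SQ", value = list(list(
      "0008,1150" = list(vr = "UI", value = "1.2.840.10008.3.1.2.3.1"),
      "0008,1155" = list(vr = "UI", value = doc$study_instance_uid),
      "3006,0014" = list(vr = "SQ", value = list(series_item))
    )))
  }

  ds <- list(
    "0008,0016" = list(vr = "UI", value = DCM_UID_RTSTRUCT),
    "0008,0018" = list(vr = "UI", value = doc$sop_instance_uid),
    "0008,0020" = list(vr = "DA", value = doc$date),
    "0008,0030" = list(vr = "TM", value = doc$time),
    "0008,0060" = list(vr = "CS", value = "RTSTRUCT"),
    "0008,0070" = list(vr = "LO", value = "rtdeinterp"),
    "0010,0010" = list(vr = "PN", value = doc$patient_name),
    "0010,0020" = list(vr = "LO", value = doc$patient_id),
    "0020,000D" = list(vr = "UI", value = doc$study_instance_uid),
    "0020,000E" = list(vr = "UI", value = doc$series_instance_uid),
    "0020,0010" = list(vr = "SH", value = "1"),
    "0020,0011" = list(vr = "IS", value = "1"),
    "3006,0002" = list(vr = "SH", value = doc$label),
    "3006,0008" = list(vr = "DA", value = doc$date),
    "3006,0009" = list(vr = "TM", value = doc$time),
    "3006,0010" = list(vr = "SQ", value = list(ref_frame_item)),
    "3006,0020" = list(vr = "SQ", value = roi_items),
    "3006,0039" = list(vr = "SQ", value = contour_items),
    "3006,0080" = list(vr = "SQ", value = obs_items)
  )
  dcm_write(path, ds, DCM_UID_RTSTRUCT, doc$sop_instance_uid)
  invisible(path)
}

#' De-interpolate selected structures of a document
#'
#' Document-level wrapper around [deinterpolate()]: selects structures by
#' name or ROI number, processes them, and splices the results back into
#' the document. Unselected structures are carried through untouched.
#'
#' @param document An `rtstruct_doc`.
#' @param selection Character vector of structure names, integer vector of
#'   ROI numbers, or `"all"`.
#' @param params A [deinterp_params()].
#' @param grid Optional [slice_grid()] for bounds validation.
#' @return List with `document` (edited) and `report`
#'   (class `deinterp_report`).
#' @export
deinterpolate_rtstruct <- function(document, selection, params, grid = NULL) {
  stopifnot(inherits(document, "rtstruct_doc"))
  names_avail <- vapply(document$structures, function(s) s$name,
                        character(1L))
  rois_avail <- vapply(document$structures, function(s) s$roi_number,
                       integer(1L))
  if (is.character(selection) && length(selection) == 1L &&
      identical(selection, "all")) {
    idx <- seq_along(document$structures)
  } else if (is.character(selection)) {
    missing <- setdiff(selection, names_avail)
    if (length(missing)) {
      stop("unknown structure(s): ", paste(missing, collapse = ", "),
           "; available: ", paste(names_avail, collapse = ", "),
           call. = FALSE)
    }
    idx <- which(names_avail %in% selection)
  } else {
    selection <- as.integer(selection)
    missing <- setdiff(selection, rois_avail)
    if (length(missing)) {
      stop("unknown ROI number(s): ", paste(missing, collapse = ", "),
           "; available: ", paste(rois_avail, collapse = ", "),
           call. = FALSE)
    }
    idx <- which(rois_avail %in% selection)
  }
  if (length(idx) == 0L) {
    report <- structure(list(params = params, entries = list()),
                        class = "deinterp_report")
    return(list(document = document, report = report))
  }
  res <- deinterpolate(document$structures[idx], params, grid = grid)
  out <- document
  if (params$copy_before_edit) {
    # deinterpolate() emits [original, copy] pairs; keep the document's
    # originals in place and append the copies, renumbered past the
    # document-wide maximum so ROI numbers stay unique in the whole set
    sel_rois <- rois_avail[idx]
    copies <- Filter(function(s) !(s$roi_number %in% sel_rois),
                     res$structures)
    next_roi <- max(rois_avail)
    for (j in seq_along(copies)) {
      next_roi <- next_roi + 1L
      old <- copies[[j]]$roi_number
      copies[[j]]$roi_number <- next_roi
      for (e in seq_along(res$report$entries)) {
        if (res$report$entries[[e]]$roi_number == old &&
            identical(res$report$entries[[e]]$name, copies[[j]]$name)) {
          res$report$entries[[e]]$roi_number <- next_roi
        }
      }
    }
    out$structures <- c(document$structures, copies)
  } else {
    out$structures[idx] <- res$structures
  }
  list(document = out, report = res$report)
}
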