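# Synthetic CT grids and RT-STRUCT phantoms with known contoured ranges,
# so every algorithm and I/O path is testable without downloading data.
# Polygons are regular 24-gons with optional seeded vertex jitter: enough
# vertices to look like a real contour, few enough to diff by eye. CT
# pixel content is a constant-valued minimal image; only geometry matters.

# Deterministic digit stream (Park-Miller LCG), independent of the session
# RNG so phantom generation never perturbs user-level randomness.
.lcg_stream <- function(seed) {
  state <- as.double(seed %% 2147483647L)
  if (state <= 0) state <- state + 2147483646
  list(
    next_int = function() {
      state <<- (state * 48271) %% 2147483647
      state
    },
    unif = function(n = 1L) {
      vapply(seq_len(n), function(i) {
        state <<- (state * 48271) %% 2147483647
        state / 2147483647
      }, numeric(1L))
    },
    uid = function() {
      digits <- vapply(seq_len(24L), function(i) {
        state <<- (state * 48271) %% 2147483647
        state %% 10
      }, numeric(1L))
      digits[1L] <- digits[1L] %% 9 + 1  # leading digit nonzero
      paste0("2.25.", paste(as.integer(digits), collapse = ""))
    }
  )
}

#' Specify a synthetic phantom
#'
#' Describes a CT slice stack plus one or more structures contoured over
#' known slice ranges. The default reproduces the canonical desk example:
#' a single structure contoured on slices 10-20 of a 30-slice image set.
#'
#' @param slice_count Number of CT slices (default 30).
#' @param spacing Slice spacing in mm (default 2.5, a common CT protocol).
#' @param first_z z of slice 1 in mm (default 0).
#' @param structures List of structure descriptions, each a list with
#'   `name`, `shape` (`"cylinder"`, `"sphere"`, or `"gapped-cylinder"`),
#'   `slices` = `c(lo, hi)` slice range, `radius` (mm) and `center`
#'   = `c(x, y)` (mm). Defaults to one cylindrical "PTV" on slices 10-20.
#' @param jitter Vertex jitter amplitude in mm (0 = perfect polygons).
#' @param seed Integer seed driving UIDs and jitter; identical seeds give
#'   byte-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @examples
#' phantom_spec()
#' @export
phantom_spec <- function(slice_count = 30L, spacing = 2.5, first_z = 0,
                         structures = list(
                           list(name = "PTV", shape = "cylinder",
                                slices = c(10L, 20L), radius = 25,
                                center = c(0, 0))
                         ),
                         jitter = 0, seed = 20240101L) {
  slice_count <- as.integer(slice_count)
  if (is.na(slice_count) || slice_count < 1L) {
    stop("slice_count must be a positive integer")
  }
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be positive")
  for (s in structures) {
    if (is.null(s$name) || is.null(s$shape) || is.null(s$slices) ||
        is.null(s$radius)) {
      stop("each structure needs name, shape, slices and radius")
    }
    if (!s$shape %in% c("cylinder", "sphere", "gapped-cylinder")) {
      stop("unknown shape '", s$shape, "'")
    }
    sl <- as.integer(s$slices)
    if (length(sl) != 2L || sl[1L] < 1L || sl[2L] > slice_count ||
        sl[1L] > sl[2L]) {
      stop("structure '", s$name, "': slice range must lie within 1..",
           slice_count)
    }
    if (s$radius <= 0) stop("structure '", s$name, "': radius must be > 0")
  }
  structure(
    list(slice_count = slice_count, spacing = spacing, first_z = first_z,
         structures = structures, jitter = jitter, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Polygon vertices for one slice of a phantom structure; NULL when the
# shape leaves the slice empty (gapped cylinder) or the sphere's radius
# vanishes there.
.phantom_polygon <- function(shape, slice, slices, radius, center, z,
                             jitter, stream) {
  lo <- slices[1L]; hi <- slices[2L]
  r <- switch(shape,
    cylinder = radius,
    "gapped-cylinder" = if ((slice - lo) %% 2L == 0L) radius else NA_real_,
    sphere = {
      mid <- (lo + hi) / 2
      half_span <- max((hi - lo) / 2, 0.5)
      frac <- (slice - mid) / half_span  # -1..1 across the slice range
      radius * sqrt(max(1 - frac^2, 0.01))
    })
  if (is.na(r)) return(NULL)
  theta <- seq(0, 2 * pi, length.out = 25L)[-25L]
  x <- center[1L] + r * cos(theta)
  y <- center[2L] + r * sin(theta)
  if (jitter > 0) {
    x <- x + (stream$unif(length(x)) - 0.5) * 2 * jitter
    y <- y + (stream$unif(length(y)) - 0.5) * 2 * jitter
  }
  cbind(x, y, z)
}

#' Generate an in-memory phantom structure set
#'
#' Builds the slice grid and an `rtstruct_doc` containing one closed
#' polygon per contoured slice of each specified structure. Generation is
#' fully deterministic given the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @return List with `document` (class `rtstruct_doc`) and `grid`
#'   ([slice_grid()] carrying synthetic CT SOP instance UIDs).
#' @examples
#' ph <- generate_phantom(phantom_spec())
#' contoured_slices(ph$document$structures[[1]])
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  stream <- .lcg_stream(spec$seed)
  study_uid <- stream$uid()
  ct_series_uid <- stream$uid()
  frame_uid <- stream$uid()
  rtstruct_series_uid <- stream$uid()
  rtstruct_sop_uid <- stream$uid()
  ct_sop_uids <- vapply(seq_len(spec$slice_count), function(i) stream$uid(),
                        character(1L))
  z <- spec$first_z + (seq_len(spec$slice_count) - 1L) * spec$spacing
  grid <- slice_grid(z, spacing = spec$spacing,
                     sop_instance_uids = ct_sop_uids)

  structures <- vector("list", length(spec$structures))
  for (i in seq_along(spec$structures)) {
    st <- spec$structures[[i]]
    contours <- list()
    for (slice in seq(st$slices[1L], st$slices[2L])) {
      pts <- .phantom_polygon(st$shape, slice, as.integer(st$slices),
                              st$radius,
                              if (is.null(st$center)) c(0, 0) else st$center,
                              z[slice], spec$jitter, stream)
      if (is.null(pts)) next
      contours[[length(contours) + 1L]] <- planar_contour(
        pts, slice_number = slice,
        referenced_sop_uid = ct_sop_uids[[slice]],
        planarity_tol = spec$spacing / 2)
    }
    structures[[i]] <- rt_structure(i, st$name, contours)
  }

  doc <- structure(
    list(
      label = "PhantomStruct",
      sop_instance_uid = rtstruct_sop_uid,
      series_instance_uid = rtstruct_series_uid,
      study_instance_uid = study_uid,
      frame_of_reference_uid = frame_uid,
      referenced_series_uid = ct_series_uid,
      patient_name = "Phantom^Synthetic",
      patient_id = "PHANTOM001",
      date = "20240101",
      time = "120000",
      structures = structures,
      source = NA_character_
    ),
    class = "rtstruct_doc"
  )
  list(document = doc, grid = grid, ct_sop_uids = ct_sop_uids,
       ct_series_uid = ct_series_uid)
}

# Minimal geometry-bearing CT slice dataset (16x16 constant image).
.phantom_ct_dataset <- function(ph, spec, slice) {
  rows <- 16L
  z <- ph$grid$z_positions[slice]
  list(
    "0008,0016" = list(vr = "UI", value = DCM_UID_CT),
    "0008,0018" = list(vr = "UI", value = ph$ct_sop_uids[[slice]]),
    "0008,0020" = list(vr = "DA", value = ph$document$date),
    "0008,0030" = list(vr = "TM", value = ph$document$time),
    "0008,0060" = list(vr = "CS", value = "CT"),
    "0008,0070" = list(vr = "LO", value = "rtdeinterp"),
    "0010,0010" = list(vr = "PN", value = ph$document$patient_name),
    "0010,0020" = list(vr = "LO", value = ph$document$patient_id),
    "0018,0050" = list(vr = "DS", value = sprintf("%g", spec$spacing)),
    "0020,000D" = list(vr = "UI", value = ph$document$study_instance_uid),
    "0020,000E" = list(vr = "UI", value = ph$ct_series_uid),
    "0020,0010" = list(vr = "SH", value = "1"),
    "0020,0011" = list(vr = "IS", value = "1"),
    "0020,0013" = list(vr = "IS", value = as.character(slice)),
    "0020,0032" = list(vr = "DS",
                       value = sprintf("-100.0000\\-100.0000\\%.4f", z)),
    "0020,0037" = list(vr = "DS",
                       value = "1\\0\\0\\0\\1\\0"),
    "0020,0052" = list(vr = "UI", value = ph$document$frame_of_reference_uid),
    "0028,0002" = list(vr = "US", value = 1L),
    "0028,0004" = list(vr = "CS", value = "MONOCHROME2"),
    "0028,0010" = list(vr = "US", value = rows),
    "0028,0011" = list(vr = "US", value = rows),
    "0028,0030" = list(vr = "DS", value = "12.5\\12.5"),
    "0028,0100" = list(vr = "US", value = 16L),
    "0028,0101" = list(vr = "US", value = 16L),
    "0028,0102" = list(vr = "US", value = 15L),
    "0028,0103" = list(vr = "US", value = 0L),
    "7FE0,0010" = list(vr = "OW", value = raw(rows * rows * 2L))
  )
}

#' Write a phantom CT series and matching RTSTRUCT to disk
#'
#' Emits one minimal DICOM CT file per slice (constant pixel content,
#' correct geometry) plus the structure set referencing them, all
#' deterministic given the spec's seed. Reading the RTSTRUCT back against
#' the CT directory reproduces the in-memory phantom model.
#'
#' @param spec A [phantom_spec()].
#' @param directory Output directory (created if needed).
#' @return List with file paths: `rtstruct` and character vector `ct`.
#' @export
write_phantom_series <- function(spec, directory) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory '", directory, "'")
  }
  ph <- generate_phantom(spec)
  ct_paths <- character(spec$slice_count)
  for (slice in seq_len(spec$slice_count)) {
    p <- file.path(directory, sprintf("ct_%03d.dcm", slice))
    dcm_write(p, .phantom_ct_dataset(ph, spec, slice), DCM_UID_CT,
              ph$ct_sop_uids[[slice]])
    ct_paths[slice] <- p
  }
  rs_path <- file.path(directory, "rtstruct.dcm")
  write_rtstruct(ph$document, rs_path, grid = ph$grid, new_uid = FALSE)
  list(rtstruct = rs_path, ct = ct_paths)
}
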