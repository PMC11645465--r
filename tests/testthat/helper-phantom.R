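# Shared fixtures: in-code contour builders and a positional brute-force
# oracle for the clearing pattern.

ring_contour <- function(slice, z, r = 20, nv = 12L, type = "closed_planar") {
  th <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
  planar_contour(cbind(r * cos(th), r * sin(th), z), slice_number = slice,
                 geometric_type = type)
}

# One closed polygon per requested slice (z = slice * spacing), optionally
# several polygons per slice.
make_structure <- function(slices, roi = 1L, name = "organ", spacing = 2.5,
                           polys_per_slice = 1L) {
  contours <- list()
  for (s in slices) {
    for (j in seq_len(polys_per_slice)) {
      contours[[length(contours) + 1L]] <-
        ring_contour(s, s * spacing, r = 20 - (j - 1) * 2)
    }
  }
  rt_structure(roi, name, contours)
}

# Independent oracle: walk slice numbers upward from the start layer with a
# cyclic 1..n counter (no modular arithmetic) and collect contoured slices
# falling on "clear" positions of the pattern.
oracle_cleared <- function(contoured, mode, n, preserve_first = FALSE) {
  contoured <- sort(unique(as.integer(contoured)))
  if (length(contoured) == 0L) return(integer())
  start <- contoured[[1L]]
  cleared <- integer()
  counter <- 0L
  for (s in seq(start, max(contoured))) {
    counter <- counter + 1L
    if (counter > n) counter <- 1L
    clear_here <- if (mode == "keep") counter == n
                  else if (preserve_first) counter != 1L
                  else counter != n
    if (clear_here && s %in% contoured) cleared <- c(cleared, s)
  }
  cleared
}

# All contoured slice subsets of 1..max_slice as a list of integer vectors.
all_subsets <- function(max_slice) {
  lapply(seq_len(2^max_slice - 1L), function(mask) {
    which(bitwAnd(mask, bitwShiftL(1L, seq_len(max_slice) - 1L)) != 0L)
  })
}

two_structure_spec <- function(seed = 4242L) {
  phantom_spec(
    slice_count = 30L, spacing = 2.5,
    structures = list(
      list(name = "PTV", shape = "cylinder", slices = c(10L, 20L),
           radius = 25, center = c(0, 0)),
      list(name = "Heart", shape = "sphere", slices = c(5L, 9L),
           radius = 30, center = c(40, -20))
    ),
    seed = seed
  )
}

# Contour point matrices of a structure, ordered by slice then vertex, for
# value-identity comparisons.
contour_points <- function(s) {
  lapply(s$contours, function(ct) ct$points)
}
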