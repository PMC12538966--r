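#' Distortion-factor grid for cylinder projections
#'
#' Multiplicative length-correction factors for vector fields computed on a
#' cylinder map, sampled on square tiles (10 px by default). The
#' `longitudinal` factor corrects displacements along the pole-to-pole axis
#' (map axis 1, rows); the `latitudinal` factor corrects displacements
#' parallel to the equator (map axis 2, columns, the periodic direction).
#' Factors multiply map-space vector components to recover true surface
#' lengths; angles are deliberately not corrected.
#'
#' @param longitudinal,latitudinal numeric matrices of positive per-tile
#'   factors (tile rows x tile cols).
#' @param tile_size tile edge length in pixels.
#' @return An object of class `distortion_grid`.
#' @export
distortion_grid <- function(longitudinal, latitudinal, tile_size = 10) {
  longitudinal <- as.matrix(longitudinal)
  latitudinal <- as.matrix(latitudinal)
  if (!identical(dim(longitudinal), dim(latitudinal))) {
    stop("factor grids must have identical shape")
  }
  if (any(longitudinal <= 0) || any(latitudinal <= 0)) {
    stop("distortion factors must be > 0")
  }
  if (tile_size < 1) stop("tile_size must be >= 1")
  structure(
    list(longitudinal = longitudinal, latitudinal = latitudinal,
         tile_size = tile_size),
    class = "distortion_grid"
  )
}

#' Reciprocal of a distortion grid
#'
#' Elementwise reciprocal factors; correcting with a grid and then with its
#' reciprocal restores a vector field exactly (up to float rounding).
#'
#' @param grid a [distortion_grid()].
#' @return A `distortion_grid`.
#' @export
invert_distortion <- function(grid) {
  stopifnot(inherits(grid, "distortion_grid"))
  distortion_grid(1 / grid$longitudinal, 1 / grid$latitudinal, grid$tile_size)
}

#' Correct vector lengths for cylinder-map distortion
#'
#' Multiplies, at each PIV node, the pole-to-pole (row) vector component by
#' the longitudinal factor and the equator-parallel (column) component by
#' the latitudinal factor of the tile containing the node (nearest-tile
#' lookup, no interpolation). Component signs, and hence directions per
#' component, are preserved.
#'
#' @param fields a 2D `vector_field_sequence`.
#' @param grid a [distortion_grid()] covering every node.
#' @return A corrected `vector_field_sequence`.
#' @export
correct_distortion <- function(fields, grid) {
  stopifnot(inherits(fields, "vector_field_sequence"),
            inherits(grid, "distortion_grid"))
  if (field_ndim(fields) != 2) {
    stop("distortion correction applies to 2D (cylinder-map) fields")
  }
  gs <- grid_shape(fields)
  # pixel coordinate of each node centre, per axis
  coord <- lapply(1:2, function(k) {
    fields$grid_origin[k] + (seq_len(gs[k]) - 1) * fields$grid_step[k]
  })
  tile <- lapply(1:2, function(k) {
    ti <- floor((coord[[k]] - 1) / grid$tile_size) + 1
    nt <- dim(grid$longitudinal)[k]
    if (any(ti < 1 | ti > nt)) {
      stop("PIV node outside the distortion grid along axis ", k)
    }
    ti
  })
  lon <- grid$longitudinal[tile[[1]], tile[[2]], drop = FALSE]
  lat <- grid$latitudinal[tile[[1]], tile[[2]], drop = FALSE]
  tt <- n_steps(fields)
  vec <- fields$vectors
  nspace <- tt * prod(gs)
  fac1 <- aperm(array(lon, c(gs, tt)), c(3, 1, 2))
  fac2 <- aperm(array(lat, c(gs, tt)), c(3, 1, 2))
  vec[seq_len(nspace)] <- vec[seq_len(nspace)] * fac1
  vec[seq_len(nspace) + nspace] <- vec[seq_len(nspace) + nspace] * fac2
  vector_field_sequence(vec, fields$validity,
                        grid_step = fields$grid_step,
                        grid_origin = fields$grid_origin)
}

#' Extract a surface-shell mask from a 3D volume
#'
#' Reconstructs the closed outer surface of a bright shell-like object
#' (e.g. an embryo whose outermost tissue layer carries the signal) and
#' thickens it into a voxel shell for masked 3D PIV. Steps: global
#' threshold -> gap bridging by morphological closing at scale `alpha`
#' (the reconstruction scale: gaps up to about `alpha` voxels are bridged)
#' -> interior filling (so only the outer boundary, not internal facets,
#' remains) -> one-voxel outer boundary -> thickening by `shell_in` voxels
#' inward and `shell_out` voxels outward. The result separates exterior
#' from interior background (closed-shell property).
#'
#' @param volume 3D numeric array with a closed bright shell-like object.
#' @param threshold intensity threshold; foreground is `volume >= threshold`.
#' @param alpha gap-bridging scale in voxels.
#' @param shell_in,shell_out shell thickness inward/outward of the surface,
#'   in voxels (defaults 6 and 3).
#' @return An object of class `surface_mask`: integer 0/1 array of the
#'   volume's shape.
#' @export
extract_surface_mask <- function(volume, threshold, alpha = 2,
                                 shell_in = 6, shell_out = 3) {
  if (length(dim(volume)) != 3) stop("`volume` must be a 3D array")
  fg <- volume >= threshold
  if (!any(fg)) stop("empty foreground: no voxel reaches the threshold")
  ball_a <- struct_offsets(max(1, round(alpha)), 3, "disc")
  closed <- binary_close(fg, ball_a)
  exterior <- flood_from_border(!closed)
  solid <- !exterior
  surface <- solid & !binary_erode(solid, struct_offsets(1, 3, "diamond"))
  shell <- binary_dilate(solid, struct_offsets(shell_out, 3, "disc")) &
    !binary_erode(solid, struct_offsets(shell_in + 1, 3, "disc"))
  shell <- shell | surface
  out <- array(as.integer(shell), dim(volume))
  class(out) <- c("surface_mask", class(out))
  out
}

#' Union of surface masks
#'
#' Voxelwise union of shell masks from different time points, giving one
#' static mask for all frames of a masked PIV run.
#'
#' @param masks list of binary arrays of identical shape.
#' @return A `surface_mask` (integer 0/1 array).
#' @export
combine_masks <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1)
  dims <- dim(masks[[1]])
  out <- array(FALSE, dims)
  for (m in masks) {
    if (!identical(dim(m), dims)) stop("mask shapes differ")
    out <- out | (m != 0)
  }
  out <- array(as.integer(out), dims)
  class(out) <- c("surface_mask", class(out))
  out
}
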