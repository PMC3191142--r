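# Spatial utilities: sphere ROIs on a voxel grid, thresholded-map
# intersection, the template goodness-of-fit score used to pick the DMN
# component among ICA maps, and ROI time-series extraction from 4-D data.
# Volumes are plain R arrays indexed [i, j, k(, t)]; world coordinates are
# millimetres with voxel (1,1,1) centred at `origin_mm`.

#' Voxel grid geometry
#'
#' @param dims Integer vector (nx, ny, nz).
#' @param voxel_size_mm Voxel edge lengths in mm (dx, dy, dz); anisotropic
#'   grids (e.g. 3.13 x 3.13 x 3.6 mm EPI voxels) are supported.
#' @param origin_mm World coordinate (mm) of the centre of voxel (1,1,1).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(dims, voxel_size_mm = c(1, 1, 1),
                       origin_mm = c(0, 0, 0)) {
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims < 1)) stop("dims must be 3 positive ints")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3 || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 positive numbers")
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3) stop("origin_mm must have 3 components")
  structure(list(dims = dims, voxel_size_mm = voxel_size_mm,
                 origin_mm = origin_mm), class = "voxel_grid")
}

#' Voxel mask
#'
#' @param grid A [voxel_grid()].
#' @param voxels Integer matrix with 3 columns (i, j, k), 1-based, all
#'   within the grid; zero rows give an empty mask.
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(grid, voxels) {
  stopifnot(inherits(grid, "voxel_grid"))
  voxels <- matrix(as.integer(voxels), ncol = 3,
                   dimnames = list(NULL, c("i", "j", "k")))
  if (nrow(voxels) > 0) {
    ok <- voxels[, 1] >= 1 & voxels[, 1] <= grid$dims[1] &
          voxels[, 2] >= 1 & voxels[, 2] <= grid$dims[2] &
          voxels[, 3] >= 1 & voxels[, 3] <= grid$dims[3]
    if (!all(ok)) stop("mask voxels must lie within the grid")
  }
  structure(list(grid = grid, voxels = voxels), class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("voxel_mask: %d voxels on a %s grid\n", nrow(x$voxels),
              paste(x$grid$dims, collapse = "x")))
  invisible(x)
}

.voxel_centers_mm <- function(grid, voxels) {
  sweep(sweep(voxels - 1, 2, grid$voxel_size_mm, `*`), 2,
        grid$origin_mm, `+`)
}

#' Spherical region of interest
#'
#' All voxels whose centre lies within `radius_mm` (inclusive) of
#' `center_mm`, measured between voxel centres in world (mm) coordinates.
#' Used both for the 10 mm ROI spheres placed at group peak coordinates and
#' for the 5 mm template spheres of the component-selection score.  A
#' centre far off the grid yields an empty mask rather than an error.
#'
#' @param grid A [voxel_grid()].
#' @param center_mm Sphere centre in world mm.
#' @param radius_mm Sphere radius in mm (>= 0).
#' @return A [voxel_mask()].
#' @export
sphere_mask <- function(grid, center_mm, radius_mm) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (radius_mm < 0) stop("radius_mm must be >= 0")
  center_mm <- as.numeric(center_mm)
  # candidate bounding box in index space
  lo <- pmax(1, ceiling((center_mm - radius_mm - grid$origin_mm) /
                          grid$voxel_size_mm) + 1)
  hi <- pmin(grid$dims, floor((center_mm + radius_mm - grid$origin_mm) /
                                grid$voxel_size_mm) + 1)
  if (any(lo > hi)) return(voxel_mask(grid, matrix(integer(0), 0, 3)))
  cand <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                k = lo[3]:hi[3], KEEP.OUT.ATTRS = FALSE))
  ctr <- .voxel_centers_mm(grid, cand)
  d2 <- rowSums(sweep(ctr, 2, center_mm, `-`)^2)
  voxel_mask(grid, cand[d2 <= radius_mm^2 + 1e-9, , drop = FALSE])
}

#' Keep mask voxels whose statistic exceeds a threshold
#'
#' Intersection of an ROI sphere with a statistical map: voxels of the mask
#' whose map value is strictly above `threshold` survive (the convention
#' used when intersecting the 10 mm spheres with the thresholded group DMN
#' t map).
#'
#' @param mask A [voxel_mask()].
#' @param stat_map 3-D numeric array on the mask's grid.
#' @param threshold Numeric cutoff (strict inequality).
#' @return A [voxel_mask()].
#' @export
intersect_with_threshold <- function(mask, stat_map, threshold) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!identical(as.integer(dim(stat_map)), mask$grid$dims))
    stop("stat_map dimensions do not match the mask grid")
  if (nrow(mask$voxels) == 0) return(mask)
  vals <- stat_map[mask$voxels]
  voxel_mask(mask$grid, mask$voxels[vals > threshold, , drop = FALSE])
}

#' Template goodness-of-fit score of a component map
#'
#' Average intensity over the union of the template sphere voxels minus the
#' average intensity over all voxels outside every sphere.  The score is
#' unchanged by adding a constant to the map and scales linearly with the
#' map.
#'
#' @param component_map 3-D numeric array.
#' @param template_spheres List of [voxel_mask()]s on the map's grid.
#' @return The scalar score.
#' @export
template_fit_score <- function(component_map, template_spheres) {
  if (length(template_spheres) == 0) stop("need at least one sphere")
  dims <- dim(component_map)
  inside <- array(FALSE, dims)
  for (m in template_spheres) {
    stopifnot(inherits(m, "voxel_mask"))
    if (!identical(as.integer(dims), m$grid$dims))
      stop("sphere grid does not match the component map")
    if (nrow(m$voxels) > 0) inside[m$voxels] <- TRUE
  }
  n_in <- sum(inside)
  if (n_in == 0) stop("no voxel inside the template spheres")
  if (n_in == length(inside)) stop("no voxel outside the template spheres")
  mean(component_map[inside]) - mean(component_map[!inside])
}

#' Pick the component best matching the template
#'
#' Scores every component map with [template_fit_score()] and returns the
#' maximiser; ties go to the lowest component index.
#'
#' @param component_maps List of 3-D arrays on one grid.
#' @param template_spheres List of [voxel_mask()]s.
#' @return List with `index` of the best-fit component and the vector of
#'   `scores`.
#' @export
select_best_component <- function(component_maps, template_spheres) {
  if (length(component_maps) == 0) stop("no component maps supplied")
  scores <- vapply(component_maps, template_fit_score, 1.0,
                   template_spheres = template_spheres)
  list(index = which.max(scores), scores = scores)
}

#' Average time course over an ROI
#'
#' Unweighted mean over the mask voxels at each time point of a 4-D volume
#' series.
#'
#' @param volumes 4-D numeric array (x, y, z, t) on the mask's grid.
#' @param mask A nonempty [voxel_mask()].
#' @return Numeric vector of length T.
#' @export
extract_roi_timeseries <- function(volumes, mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  d <- dim(volumes)
  if (length(d) != 4) stop("volumes must be a 4-D array")
  if (!identical(as.integer(d[1:3]), mask$grid$dims))
    stop("volume dimensions do not match the mask grid")
  if (nrow(mask$voxels) == 0) stop("mask is empty")
  flat <- matrix(volumes, prod(d[1:3]), d[4])
  lin <- mask$voxels[, 1] +
    (mask$voxels[, 2] - 1) * d[1] +
    (mask$voxels[, 3] - 1) * d[1] * d[2]
  colMeans(flat[lin, , drop = FALSE])
}

#' Serialize a voxel mask to/from JSON
#'
#' Plain-text interchange format for masks (grid geometry plus the 1-based
#' voxel index list).
#'
#' @param mask A [voxel_mask()].
#' @param path File path.
#' @return `write_mask_json` returns `path` invisibly; `read_mask_json`
#'   returns a [voxel_mask()].
#' @export
write_mask_json <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  jsonlite::write_json(list(dims = mask$grid$dims,
                            voxel_size_mm = mask$grid$voxel_size_mm,
                            origin_mm = mask$grid$origin_mm,
                            voxels = mask$voxels),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_json
#' @export
read_mask_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  voxel_mask(voxel_grid(obj$dims, obj$voxel_size_mm, obj$origin_mm),
             matrix(as.integer(obj$voxels), ncol = 3))
}
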