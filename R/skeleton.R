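#' Skeletonize a binary mask
#'
#' Medial-axis curve thinning: iterative homotopic erosion producing a
#' one-voxel-thick, 26-connected skeleton that preserves the mask's topology
#' (connected components and cycles).  Deletion order is deterministic
#' (six directional sub-cycles, fixed raster order), endpoints are
#' preserved.
#'
#' @param mask a `lymph_mask`.
#' @return an object of class `lymph_skeleton`: voxel coordinates (1-based,
#'   columns z, y, x), grid dimensions and geometry.
#' @export
skeletonize <- function(mask) {
  skel <- cpp_skeletonize3d(mask$data, dim(mask$data))
  idx <- which(skel)
  structure(list(coords = vox_coords(idx, dim(mask$data)),
                 dim = dim(mask$data),
                 spacing_um = mask$spacing_um,
                 origin_um = mask$origin_um),
            class = "lymph_skeleton")
}

#' @export
#' @method print lymph_skeleton
print.lymph_skeleton <- function(x, ...) {
  cat(sprintf("<lymph_skeleton> %d voxels on a %s grid\n",
              nrow(x$coords), paste(x$dim, collapse = "x")))
  invisible(x)
}

# linear (1-based) index <-> (z, y, x) voxel coordinates, dim = c(nz, ny, nx)
vox_coords <- function(idx, dims) {
  idx0 <- idx - 1L
  z <- idx0 %% dims[1]
  r <- idx0 %/% dims[1]
  y <- r %% dims[2]
  x <- r %/% dims[2]
  cbind(z = z + 1L, y = y + 1L, x = x + 1L)
}

vox_index <- function(coords, dims) {
  (coords[, 1] - 1L) + dims[1] * ((coords[, 2] - 1L) + dims[2] * (coords[, 3] - 1L)) + 1L
}

# physical (z,y,x) um coordinates of voxel centers
vox_um <- function(coords, spacing, origin) {
  sweep(sweep(coords - 0.5, 2, spacing, `*`), 2, origin, `+`)
}
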