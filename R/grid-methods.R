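#' Construct a VolumeGrid
#'
#' @param values 3D numeric array, `dim = c(nz, ny, nx)`.
#' @param spacing numeric(3), voxel spacing (dz, dy, dx) in mm.
#' @param origin numeric(3), physical centre of voxel (1,1,1) in mm;
#'   default places voxel centres at half-spacing from zero.
#' @return a [VolumeGrid-class].
#' @examples
#' g <- volumeGrid(array(0, c(4, 4, 4)), spacing = c(2.5, 1, 1))
#' dim(g)
#' @export
volumeGrid <- function(values, spacing = c(1, 1, 1), origin = spacing / 2) {
  new("VolumeGrid", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a BinaryMask
#'
#' @param voxels 3D logical array (or coercible), `dim = c(nz, ny, nx)`.
#' @param spacing numeric(3), voxel spacing (dz, dy, dx) in mm.
#' @param origin numeric(3), physical centre of voxel (1,1,1) in mm.
#' @param grid optionally, a [VolumeGrid-class] or [BinaryMask-class] whose
#'   geometry is copied (overrides `spacing`/`origin`).
#' @return a [BinaryMask-class].
#' @export
binaryMask <- function(voxels, spacing = c(1, 1, 1), origin = spacing / 2,
                       grid = NULL) {
  if (!is.null(grid)) {
    spacing <- spacing(grid)
    origin <- origin(grid)
  }
  storage.mode(voxels) <- "logical"
  new("BinaryMask", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @rdname spacing
#' @export
setMethod("spacing", "VolumeGrid", function(x) x@spacing)
#' @rdname spacing
#' @export
setMethod("spacing", "BinaryMask", function(x) x@spacing)

#' @rdname origin
#' @export
setMethod("origin", "VolumeGrid", function(x) x@origin)
#' @rdname origin
#' @export
setMethod("origin", "BinaryMask", function(x) x@origin)

#' @rdname voxelValues
#' @export
setMethod("voxelValues", "VolumeGrid", function(x) x@values)

#' @rdname maskArray
#' @export
setMethod("maskArray", "BinaryMask", function(x) x@voxels)

#' @rdname nVoxels
#' @export
setMethod("nVoxels", "BinaryMask", function(x) sum(x@voxels))
#' @rdname nVoxels
#' @export
setMethod("nVoxels", "QuantizedRegion", function(x) sum(!is.na(x@levels)))

#' @rdname grayLevels
#' @export
setMethod("grayLevels", "QuantizedRegion",
          function(x) as.integer(x@levels[!is.na(x@levels)]))

#' @export
setMethod("dim", "VolumeGrid", function(x) dim(x@values))
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@voxels))

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object)
  cat(sprintf("VolumeGrid %d x %d x %d (nz x ny x nx)\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing (z,y,x): %s mm\n",
              paste(format(object@spacing), collapse = " x ")))
  rng <- range(object@values)
  cat(sprintf("  value range: [%.3f, %.3f]\n", rng[1], rng[2]))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object)
  cat(sprintf("BinaryMask %d x %d x %d, %d voxels (%.2f cm^3)\n",
              d[1], d[2], d[3], sum(object@voxels),
              sum(object@voxels) * prod(object@spacing) / 1000))
})

setMethod("show", "QuantizedRegion", function(object) {
  lv <- grayLevels(object)
  cat(sprintf("QuantizedRegion: %d voxels, Ng = %d, levels in [%d, %d], SUV scale max %.3f\n",
              length(lv), object@Ng, min(lv), max(lv), object@cohortSuvmax))
})

setMethod("show", "PhantomCase", function(object) {
  lb <- object@labels
  cat(sprintf("PhantomCase %s: PET%s / MFC%s, biopsy site %s\n",
              as.character(lb$case_id %||% "?"), lb$pet_class, lb$mfc_class,
              lb$biopsy_site))
  cat(sprintf("  CT %s, PET %s\n",
              paste(dim(object@ct), collapse = "x"),
              paste(dim(object@pet), collapse = "x")))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- geometry helpers ------------------------------------------------------

sameGeometry <- function(a, b, tol = 1e-6) {
  identical(dim(a), dim(b)) &&
    all(abs(spacing(a) - spacing(b)) < tol) &&
    all(abs(origin(a) - origin(b)) < tol)
}

stopIfGeometryDiffers <- function(a, b, what = "masks") {
  if (!sameGeometry(a, b))
    stop(what, " are not defined on the same grid", call. = FALSE)
  invisible(TRUE)
}

# physical centre coordinates of voxels along one axis (1 = z, 2 = y, 3 = x)
axisCenters <- function(x, axis) {
  origin(x)[axis] + (seq_len(dim(x)[axis]) - 1) * spacing(x)[axis]
}

#' Bounding box of a mask in voxel indices
#'
#' @param mask a non-empty [BinaryMask-class].
#' @return integer matrix 3 x 2 with rows (z, y, x), columns (min, max).
#' @export
maskBoundingBox <- function(mask) {
  idx <- which(mask@voxels, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty input mask", call. = FALSE)
  bb <- t(apply(idx, 2, range))
  dimnames(bb) <- list(c("z", "y", "x"), c("min", "max"))
  bb
}

#' Dice overlap coefficient between two masks
#'
#' `2 |A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b [BinaryMask-class] objects on the same grid.
#' @return numeric in `[0, 1]`.
#' @export
diceCoefficient <- function(a, b) {
  stopIfGeometryDiffers(a, b)
  na <- sum(a@voxels); nb <- sum(b@voxels)
  if (na + nb == 0L) return(1)
  2 * sum(a@voxels & b@voxels) / (na + nb)
}

maskFromArray <- function(arr, like) {
  binaryMask(arr, grid = like)
}

emptyLike <- function(like) {
  binaryMask(array(FALSE, dim(like)), grid = like)
}
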