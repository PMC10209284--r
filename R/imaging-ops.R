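## Grid/mask primitives shared by every segmentation stage.
##
## Axis semantics used throughout: an "axial" split is along z (inferior /
## superior), a "coronal" split along y (anterior / posterior) and a
## "sagittal" split along x (patient right / left). Splitting planes sit at
## the midpoint of the mask's own bounding box, and the boundary slice is
## assigned to the low side.

#' Split a mask at the midpoint of its bounding box
#'
#' The split plane is the midpoint of the mask's own bounding box along the
#' chosen axis (not the volume midpoint). The union of the two sides is the
#' input mask and their intersection is empty; when the bounding box has odd
#' extent the central slice goes to the low side.
#'
#' @param mask a non-empty [BinaryMask-class].
#' @param axis "axial" (z), "coronal" (y) or "sagittal" (x).
#' @param side "low" (inferior / anterior / patient-left) or "high".
#' @return a [BinaryMask-class] restricted to the chosen half-space.
#' @export
splitHalf <- function(mask, axis = c("axial", "coronal", "sagittal"),
                      side = c("low", "high")) {
  axis <- match.arg(axis)
  side <- match.arg(side)
  if (nVoxels(mask) == 0L) stop("empty input mask", call. = FALSE)
  ax <- switch(axis, axial = 1L, coronal = 2L, sagittal = 3L)
  bb <- maskBoundingBox(mask)
  mid <- (bb[ax, 1] + bb[ax, 2]) / 2
  idx <- seq_len(dim(mask)[ax])
  keep <- if (side == "low") idx <= mid else idx > mid
  arr <- mask@voxels
  sel <- slice.index(arr, ax)
  arr <- arr & keep[sel]
  binaryMask(arr, grid = mask)
}

#' Label the connected components of a mask
#'
#' @param mask a [BinaryMask-class].
#' @param connectivity 6 or 26 (default), 3D voxel connectivity.
#' @return integer array of component labels (0 = background), same dim as
#'   the mask.
#' @export
connectedComponents <- function(mask, connectivity = 26L) {
  if (!connectivity %in% c(6L, 26L))
    stop("connectivity must be 6 or 26", call. = FALSE)
  lab <- cpp_label3d(as.vector(mask@voxels), dim(mask), as.integer(connectivity))
  array(lab, dim(mask))
}

#' Select a single connected component by an extent criterion
#'
#' `longest_axial` keeps the component occupying the most z slices,
#' `widest_lateral` the one occupying the most x slices. Ties are broken by
#' larger voxel count, then by smaller component centroid z.
#'
#' @param mask a non-empty [BinaryMask-class].
#' @param criterion "longest_axial" or "widest_lateral".
#' @param connectivity 6 or 26 (default).
#' @return a [BinaryMask-class] containing exactly one component.
#' @export
selectComponent <- function(mask, criterion = c("longest_axial", "widest_lateral"),
                            connectivity = 26L) {
  criterion <- match.arg(criterion)
  if (nVoxels(mask) == 0L) stop("empty input mask", call. = FALSE)
  lab <- connectedComponents(mask, connectivity)
  idx <- which(lab > 0L, arr.ind = TRUE)
  l <- lab[lab > 0L]
  ax <- if (criterion == "longest_axial") 1L else 3L
  extent <- tapply(idx[, ax], l, function(v) length(unique(v)))
  count <- tapply(l, l, length)
  cz <- tapply(idx[, 1L], l, mean)
  ord <- order(-extent, -count, cz)
  best <- as.integer(names(extent)[ord[1L]])
  binaryMask(lab == best, grid = mask)
}

#' Transfer a mask onto another grid by voxel-centre containment
#'
#' A target voxel belongs to the output iff its physical centre falls inside
#' an in-mask source voxel (nearest-neighbour containment). Used to carry
#' CT-derived masks onto the PET grid of a co-registered acquisition.
#'
#' @param mask a [BinaryMask-class] on the source grid.
#' @param target a [VolumeGrid-class] or [BinaryMask-class] supplying the
#'   target geometry.
#' @return a [BinaryMask-class] on the target grid.
#' @export
transferMask <- function(mask, target) {
  ds <- dim(mask); dt <- dim(target)
  sps <- spacing(mask); spt <- spacing(target)
  ors <- origin(mask); ort <- origin(target)
  # physical extents (outer voxel faces); error when they do not overlap
  for (a in 1:3) {
    sLo <- ors[a] - sps[a] / 2; sHi <- ors[a] + (ds[a] - 0.5) * sps[a]
    tLo <- ort[a] - spt[a] / 2; tHi <- ort[a] + (dt[a] - 0.5) * spt[a]
    if (min(sHi, tHi) <= max(sLo, tLo)) stop("disjoint grids", call. = FALSE)
  }
  # source voxel index containing each target voxel centre, per axis
  idxAxis <- lapply(1:3, function(a) {
    centers <- ort[a] + (seq_len(dt[a]) - 1) * spt[a]
    i <- floor((centers - ors[a]) / sps[a] + 0.5) + 1
    i[i < 1 | i > ds[a]] <- NA_integer_
    as.integer(i)
  })
  src <- mask@voxels
  out <- array(FALSE, dt)
  iz <- idxAxis[[1]]; iy <- idxAxis[[2]]; ix <- idxAxis[[3]]
  okz <- !is.na(iz); oky <- !is.na(iy); okx <- !is.na(ix)
  if (any(okz) && any(oky) && any(okx)) {
    sub <- src[iz[okz], iy[oky], ix[okx], drop = FALSE]
    out[okz, oky, okx] <- sub
  }
  binaryMask(out, spacing = spt, origin = ort)
}

#' Mask set operations
#'
#' Union, intersection and set difference of two masks on the same grid.
#'
#' @param a,b [BinaryMask-class] objects on the same grid.
#' @return a [BinaryMask-class].
#' @export
maskUnion <- function(a, b) {
  stopIfGeometryDiffers(a, b)
  binaryMask(a@voxels | b@voxels, grid = a)
}

#' @rdname maskUnion
#' @export
maskIntersect <- function(a, b) {
  stopIfGeometryDiffers(a, b)
  binaryMask(a@voxels & b@voxels, grid = a)
}

#' @rdname maskUnion
#' @export
maskDifference <- function(a, b) {
  stopIfGeometryDiffers(a, b)
  binaryMask(a@voxels & !b@voxels, grid = a)
}

## ---- morphology ------------------------------------------------------------

# integer voxel offsets inside a physical ball of the given radius
ballOffsets <- function(radius_mm, spacing) {
  r <- abs(radius_mm)
  nmax <- pmax(0L, as.integer(floor(r / spacing)))
  g <- expand.grid(dz = -nmax[1]:nmax[1], dy = -nmax[2]:nmax[2],
                   dx = -nmax[3]:nmax[3])
  d2 <- (g$dz * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dx * spacing[3])^2
  as.matrix(g[d2 <= r^2 + 1e-9, , drop = FALSE])
}

#' Morphological closing of a mask by a physical ball
#'
#' Binary dilation followed by erosion with a ball structuring element whose
#' radius is given in millimetres (so the element adapts to anisotropic
#' spacing). Voxels outside the volume are treated as background.
#'
#' @param mask a [BinaryMask-class].
#' @param radius_mm ball radius in mm.
#' @return a [BinaryMask-class].
#' @export
morphClose <- function(mask, radius_mm) {
  off <- ballOffsets(radius_mm, spacing(mask))
  if (nrow(off) <= 1L) return(mask)
  storage.mode(off) <- "integer"
  d <- dim(mask)
  v <- cpp_binary_morph(as.vector(mask@voxels), d, off, 1L)
  v <- cpp_binary_morph(v, d, off, 0L)
  binaryMask(array(v, d), grid = mask)
}

#' Fill interior cavities of a mask
#'
#' Background voxels not 6-connected to the volume border are counted as
#' interior and added to the mask.
#'
#' @param mask a [BinaryMask-class].
#' @return a [BinaryMask-class] with all enclosed cavities filled.
#' @export
fillHoles <- function(mask) {
  comp <- binaryMask(!mask@voxels, grid = mask)
  lab <- connectedComponents(comp, 6L)
  d <- dim(mask)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  border <- border[border > 0L]
  holes <- lab > 0L & !(lab %in% border)
  binaryMask(mask@voxels | holes, grid = mask)
}

#' Drop connected components below a voxel-count threshold
#'
#' @param mask a [BinaryMask-class].
#' @param min_voxels smallest component size kept.
#' @param connectivity 6 or 26 (default).
#' @return a [BinaryMask-class].
#' @export
removeSmallComponents <- function(mask, min_voxels, connectivity = 26L) {
  if (nVoxels(mask) == 0L) return(mask)
  lab <- connectedComponents(mask, connectivity)
  counts <- tabulate(lab[lab > 0L])
  keep <- which(counts >= min_voxels)
  binaryMask(array(lab %in% keep, dim(mask)), grid = mask)
}
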