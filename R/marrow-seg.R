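## Whole-bone-marrow segmentation from CT: thresholding and morphology give
## the filled skeleton, then compact bone and the spinal canal are removed.

#' Parameters for marrow segmentation
#'
#' @param bone_hu_threshold HU above which a voxel counts as skeleton
#'   (marrow included); default 150.
#' @param compact_bone_hu_threshold HU above which a voxel counts as compact
#'   bone; default 300. Must exceed `bone_hu_threshold`.
#' @param closing_radius_mm ball radius of the morphological closing; default 4.
#' @param min_component_voxels components smaller than this are dropped;
#'   default 200.
#' @return validated list of class `MarrowSegParams`.
#' @export
marrowSegParams <- function(bone_hu_threshold = 150,
                            compact_bone_hu_threshold = 300,
                            closing_radius_mm = 4,
                            min_component_voxels = 200L) {
  if (compact_bone_hu_threshold <= bone_hu_threshold)
    stop("compact_bone_hu_threshold must exceed bone_hu_threshold",
         call. = FALSE)
  if (closing_radius_mm <= 0) stop("closing radius must be positive",
                                   call. = FALSE)
  p <- list(bone_hu_threshold = bone_hu_threshold,
            compact_bone_hu_threshold = compact_bone_hu_threshold,
            closing_radius_mm = closing_radius_mm,
            min_component_voxels = as.integer(min_component_voxels))
  class(p) <- "MarrowSegParams"
  p
}

#' Segment the filled skeleton from CT
#'
#' Threshold at `bone_hu_threshold`, morphological closing by a physical
#' ball, 3D hole filling, and removal of components below
#' `min_component_voxels`.
#'
#' @param ct a [VolumeGrid-class] in Hounsfield units.
#' @param params a `MarrowSegParams` list.
#' @return a [BinaryMask-class] covering compact bone, marrow and any
#'   enclosed cavities.
#' @export
segmentSkeleton <- function(ct, params = marrowSegParams()) {
  skeletonParts(ct, params)$filled
}

# raw threshold mask plus the closed and filled skeleton masks
skeletonParts <- function(ct, params) {
  bone <- voxelValues(ct) >= params$bone_hu_threshold
  if (!any(bone)) stop("no bone detected", call. = FALSE)
  raw <- binaryMask(bone, grid = ct)
  closed <- morphClose(raw, params$closing_radius_mm)
  filled <- removeSmallComponents(fillHoles(closed),
                                  params$min_component_voxels)
  list(raw = raw, closed = closed, filled = filled)
}

# largest interior cavity of the raw threshold mask (its filled holes: the
# closing ball would fill a canal lumen outright, and closing fillets at
# bone junctions must not count as cavities) whose centroid lies in the
# posterior half of the torso; NULL when there is no cavity
findSpinalCanal <- function(parts) {
  skeleton <- parts$filled
  cav <- fillHoles(parts$raw)@voxels & !parts$raw@voxels
  if (!any(cav)) return(NULL)
  lab <- connectedComponents(binaryMask(cav, grid = skeleton), 26L)
  idx <- which(lab > 0L, arr.ind = TRUE)
  l <- lab[lab > 0L]
  sizes <- tapply(l, l, length)
  cy <- tapply(idx[, 2L], l, mean)
  bb <- maskBoundingBox(skeleton)
  ymid <- (bb[2, 1] + bb[2, 2]) / 2
  cand <- names(sizes)[cy > ymid]
  if (length(cand) == 0L) return(NULL)
  best <- as.integer(cand[which.max(sizes[cand])])
  binaryMask(lab == best, grid = skeleton)
}

#' Segment the whole bone marrow from CT
#'
#' The filled skeleton minus compact bone (voxels at or above
#' `compact_bone_hu_threshold`) minus the spinal canal, identified as the
#' largest interior low-HU cavity whose centroid lies in the posterior half
#' of the torso.
#'
#' @inheritParams segmentSkeleton
#' @param override optional [BinaryMask-class] replacing the automatic
#'   result, standing in for expert manual editing.
#' @return a [BinaryMask-class] of the marrow.
#' @export
segmentBoneMarrow <- function(ct, params = marrowSegParams(), override = NULL) {
  if (!is.null(override)) return(override)
  parts <- skeletonParts(ct, params)
  marrow <- parts$filled@voxels &
    (voxelValues(ct) < params$compact_bone_hu_threshold)
  marrow <- binaryMask(marrow, grid = ct)
  canal <- findSpinalCanal(parts)
  if (!is.null(canal)) marrow <- maskDifference(marrow, canal)
  marrow
}
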