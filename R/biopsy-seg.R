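## Biopsy-site segmentation: extract the sternum or a posterior iliac crest
## marrow region from the whole bone marrow mask by half-space removals,
## extent-based component selection and sagittal slab division.

#' PelvisRegions: the five sagittal slabs of the pelvis
#'
#' Five pairwise-disjoint masks whose union is the input pelvis mask,
#' ordered patient-right to patient-left (R1 is the far-right region).
#'
#' @slot regions list of five [BinaryMask-class] objects, R1..R5.
#' @export
setClass("PelvisRegions", representation(regions = "list"),
  validity = function(object) {
    if (length(object@regions) != 5L) return("exactly 5 regions required")
    if (!all(vapply(object@regions, inherits, TRUE, "BinaryMask")))
      return("regions must be BinaryMask objects")
    TRUE
  })

setMethod("show", "PelvisRegions", function(object) {
  cat("PelvisRegions (R1 far patient-right .. R5 far patient-left):\n")
  cat(sprintf("  voxels: %s\n",
              paste(vapply(object@regions, nVoxels, 0L), collapse = ", ")))
})

#' Remove limb marrow from the whole bone marrow mask
#'
#' When `humeri`/`femora` masks are not supplied the limbs are identified
#' automatically from the connected components of the marrow mask: femora
#' are components whose centroid z lies in the inferior fifth of the mask
#' bounding box; humeri are components whose centroid x lies outside the
#' x-range of the torso component (the largest remaining component).
#'
#' @param marrow a non-empty [BinaryMask-class].
#' @param humeri,femora optional [BinaryMask-class] masks on the same grid.
#' @return a [BinaryMask-class]: marrow minus limbs.
#' @export
removeLimbs <- function(marrow, humeri = NULL, femora = NULL) {
  if (nVoxels(marrow) == 0L) stop("empty marrow mask", call. = FALSE)
  if (is.null(humeri) && is.null(femora)) {
    limbs <- autoLimbMask(marrow)
    return(maskDifference(marrow, limbs))
  }
  out <- marrow
  if (!is.null(humeri)) out <- maskDifference(out, humeri)
  if (!is.null(femora)) out <- maskDifference(out, femora)
  out
}

#' Automatically identified limb (humeri + femora) marrow
#'
#' @param marrow a non-empty [BinaryMask-class].
#' @return a [BinaryMask-class] holding the limb components.
#' @export
autoLimbMask <- function(marrow) {
  lab <- connectedComponents(marrow, 26L)
  idx <- which(lab > 0L, arr.ind = TRUE)
  l <- lab[lab > 0L]
  sizes <- tapply(l, l, length)
  cz <- tapply(idx[, 1L], l, mean)
  cx <- tapply(idx[, 3L], l, mean)
  bb <- maskBoundingBox(marrow)
  zCut <- bb[1, 1] + 0.2 * (bb[1, 2] - bb[1, 1])
  femoraIds <- as.integer(names(sizes)[cz <= zCut])
  restIds <- setdiff(as.integer(names(sizes)), femoraIds)
  if (length(restIds) == 0L) return(emptyLike(marrow))
  torso <- restIds[which.max(sizes[as.character(restIds)])]
  tIdx <- idx[l == torso, , drop = FALSE]
  txr <- range(tIdx[, 3L])
  humeriIds <- restIds[restIds != torso &
                         (cx[as.character(restIds)] < txr[1] |
                            cx[as.character(restIds)] > txr[2])]
  binaryMask(array(lab %in% c(femoraIds, humeriIds), dim(marrow)),
             grid = marrow)
}

#' Segment the sternal biopsy region
#'
#' Pipeline: (1) remove the posterior half of the working mask (spine);
#' (2) remove everything in the inferior half of the torso bounding box
#' (pelvic region); (3) keep the longest component in the axial direction
#' (the sternum); (4) intersect with an axis-aligned cube whose top face is
#' flush with the most superior sternum voxel and whose x/y centre is the
#' sternum centroid. The cube edge defaults to 40 voxels of the clinical CT
#' grid, rescaled to the current spacing so its physical extent is kept.
#'
#' @param marrowNoLimbs [BinaryMask-class], marrow with limbs removed.
#' @param cubeEdge cube edge: a single voxel count, a length-3 integer
#'   vector (z, y, x) or NULL for the spacing-scaled default.
#' @return a [BinaryMask-class] of the sternal biopsy site.
#' @export
segmentSternumSite <- function(marrowNoLimbs, cubeEdge = NULL) {
  if (nVoxels(marrowNoLimbs) == 0L) stop("empty input mask", call. = FALSE)
  work <- splitHalf(marrowNoLimbs, "coronal", "low")      # drop posterior half
  if (nVoxels(work) == 0L)
    stop("sternum segmentation: empty after posterior removal", call. = FALSE)
  torsoBB <- maskBoundingBox(marrowNoLimbs)
  zmid <- (torsoBB[1, 1] + torsoBB[1, 2]) / 2
  arr <- work@voxels
  keep <- seq_len(dim(work)[1]) > zmid                    # drop inferior half
  arr <- arr & keep[slice.index(arr, 1L)]
  work <- binaryMask(arr, grid = work)
  if (nVoxels(work) == 0L)
    stop("sternum segmentation: empty after inferior-torso removal",
         call. = FALSE)
  sternum <- selectComponent(work, "longest_axial")
  out <- sternumCube(sternum, cubeEdge)
  if (nVoxels(out) == 0L)
    stop("sternum segmentation: empty after cube intersection", call. = FALSE)
  out
}

#' Divide the pelvis into five sagittal slabs
#'
#' Four equidistant sagittal planes are placed across the pelvis bounding
#' box (at fractions 1/5..4/5 of its index span); a boundary voxel goes to
#' the lower-fraction slab. Slabs are returned in patient-right to
#' patient-left order (R1 has the largest x indices).
#'
#' @param pelvis a non-empty [BinaryMask-class].
#' @return a [PelvisRegions-class].
#' @export
dividePelvis <- function(pelvis) {
  if (nVoxels(pelvis) == 0L) stop("empty pelvis mask", call. = FALSE)
  bb <- maskBoundingBox(pelvis)
  if (bb[3, 2] - bb[3, 1] + 1 < 5) stop("pelvis too thin to divide",
                                        call. = FALSE)
  cuts <- floor(bb[3, 1] + (bb[3, 2] - bb[3, 1]) * (1:4) / 5)
  lo <- c(bb[3, 1], cuts + 1)
  hi <- c(cuts, bb[3, 2])
  xidx <- slice.index(pelvis@voxels, 3L)
  slabs <- lapply(1:5, function(k)
    binaryMask(pelvis@voxels & xidx >= lo[k] & xidx <= hi[k], grid = pelvis))
  new("PelvisRegions", regions = rev(slabs))   # R1 = largest x = patient right
}

#' Segment a posterior iliac-crest biopsy region
#'
#' Pipeline: (1) remove the superior half of the working mask (torso);
#' (2) keep the widest component in the sagittal plane (most occupied x
#' slices: the pelvis); (3) divide the pelvis into five sagittal slabs and
#' keep R1+R2 for the right side or R4+R5 for the left; (4) remove the
#' anterior half of the kept mask, leaving the posterior iliac crest.
#'
#' @param marrowNoLimbs [BinaryMask-class], marrow with limbs removed.
#' @param side "left" or "right" (patient side).
#' @return a [BinaryMask-class] of the iliac biopsy site.
#' @export
segmentIliacSite <- function(marrowNoLimbs, side = c("left", "right")) {
  side <- match.arg(side)
  if (nVoxels(marrowNoLimbs) == 0L) stop("empty input mask", call. = FALSE)
  work <- splitHalf(marrowNoLimbs, "axial", "low")        # drop superior half
  if (nVoxels(work) == 0L)
    stop("iliac segmentation: empty after superior removal", call. = FALSE)
  pelvis <- selectComponent(work, "widest_lateral")
  regions <- dividePelvis(pelvis)@regions
  kept <- if (side == "right") maskUnion(regions[[1]], regions[[2]])
          else maskUnion(regions[[4]], regions[[5]])
  if (nVoxels(kept) == 0L)
    stop("iliac segmentation: empty after slab selection", call. = FALSE)
  out <- splitHalf(kept, "coronal", "high")               # drop anterior half
  if (nVoxels(out) == 0L)
    stop("iliac segmentation: empty after anterior removal", call. = FALSE)
  out
}

#' Segment the biopsy-site marrow for a case
#'
#' Removes the limbs then dispatches to the site-specific pipeline.
#'
#' @param marrow [BinaryMask-class] whole bone marrow.
#' @param site biopsy site code: "S", "LIC" or "RIC".
#' @param humeri,femora optional limb masks passed to [removeLimbs()].
#' @param cubeEdge passed to [segmentSternumSite()] for site "S".
#' @return a [BinaryMask-class], exactly one site mask.
#' @export
selectBiopsyMask <- function(marrow, site, humeri = NULL, femora = NULL,
                             cubeEdge = NULL) {
  if (!is.character(site) || length(site) != 1L ||
      !site %in% c("S", "LIC", "RIC"))
    stop("unknown biopsy site code: ", deparse(site), call. = FALSE)
  noLimbs <- removeLimbs(marrow, humeri, femora)
  switch(site,
         S = segmentSternumSite(noLimbs, cubeEdge),
         LIC = segmentIliacSite(noLimbs, "left"),
         RIC = segmentIliacSite(noLimbs, "right"))
}
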