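#' Voxel spacing in millimetres
#'
#' @param x a [VolumeGrid-class] or [BinaryMask-class].
#' @return numeric(3), spacing (dz, dy, dx) in mm.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' Physical origin (centre of voxel 1,1,1) in millimetres
#'
#' @param x a [VolumeGrid-class] or [BinaryMask-class].
#' @return numeric(3), (z, y, x) position in mm.
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' Scalar voxel values of a volume
#'
#' @param x a [VolumeGrid-class].
#' @return 3D numeric array, `dim = c(nz, ny, nx)`.
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' Logical membership array of a mask
#'
#' @param x a [BinaryMask-class].
#' @return 3D logical array, `dim = c(nz, ny, nx)`.
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' Number of voxels in a mask or quantized region
#'
#' @param x a [BinaryMask-class] or [QuantizedRegion-class].
#' @return integer count of in-mask voxels.
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' Gray levels of a quantized region
#'
#' @param x a [QuantizedRegion-class].
#' @return integer vector of in-mask levels (1..Ng).
#' @export
setGeneric("grayLevels", function(x) standardGeneric("grayLevels"))
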