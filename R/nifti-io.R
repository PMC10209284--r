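## NIfTI input/output.
##
## Internally volumes are kept as (z, y, x) arrays with z inferior->superior,
## y anterior->posterior and x patient-left->patient-right. NIfTI world
## coordinates are RAS, so on read the image is first reoriented to RAS with
## the stored affine, then the j (anterior) axis is reversed; on write the
## inverse layout is produced with a diagonal affine. Any input orientation
## is therefore honoured through its affine.

internalFromRas <- function(arrRas, pixdimRas, originRas) {
  nj <- dim(arrRas)[2]
  vals <- aperm(arrRas[, nj:1, , drop = FALSE], c(3, 2, 1))
  spacing <- rev(pixdimRas)                     # (dz, dy, dx)
  orig <- c(originRas[3],
            -(originRas[2] + (nj - 1) * pixdimRas[2]),
            originRas[1])
  list(values = vals, spacing = spacing, origin = orig)
}

#' Read a NIfTI volume as a VolumeGrid
#'
#' The affine is consumed to reorient the data into the package's anatomical
#' axis convention regardless of the on-disk orientation.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [VolumeGrid-class].
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  RNifti::orientation(img) <- "RAS"
  mat <- RNifti::xform(img)
  pd <- sqrt(colSums(mat[1:3, 1:3]^2))          # spacing from the affine
  g <- internalFromRas(array(as.numeric(img), dim(img)[1:3]), pd, mat[1:3, 4])
  volumeGrid(g$values, spacing = g$spacing, origin = g$origin)
}

#' Read a NIfTI 0/1 volume as a BinaryMask
#'
#' @param path path to a `.nii` or `.nii.gz` file holding a 0/1 volume.
#' @return a [BinaryMask-class]; any nonzero voxel is in the mask.
#' @export
readMask <- function(path) {
  g <- readVolume(path)
  binaryMask(g@values != 0, grid = g)
}

writeCanonicalNifti <- function(values, spacing, orig, path, datatype) {
  arrRas <- aperm(values, c(3, 2, 1))           # -> (x, yPosterior, z)
  nj <- dim(arrRas)[2]
  arrRas <- arrRas[, nj:1, , drop = FALSE]      # j now increases to Anterior
  pixdimRas <- rev(spacing)                     # (dx, dy, dz)
  originRas <- c(orig[3], -orig[2] - (nj - 1) * pixdimRas[2], orig[1])
  img <- RNifti::asNifti(arrRas, datatype = datatype)
  mat <- diag(c(pixdimRas, 1))
  mat[1:3, 4] <- originRas
  RNifti::sform(img) <- structure(mat, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a VolumeGrid or BinaryMask to NIfTI
#'
#' Masks are stored as 0/1 integer volumes.
#'
#' @param x a [VolumeGrid-class] or [BinaryMask-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
writeVolume <- function(x, path) {
  writeCanonicalNifti(voxelValues(x), spacing(x), origin(x), path, "float")
}

#' @rdname writeVolume
#' @export
writeMask <- function(x, path) {
  v <- array(0L, dim(x))
  v[x@voxels] <- 1L
  writeCanonicalNifti(v, spacing(x), origin(x), path, "uint8")
}
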