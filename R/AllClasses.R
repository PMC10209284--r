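#' @useDynLib bmradiomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' VolumeGrid: a 3D scalar image with physical geometry
#'
#' A scalar volume (HU for CT, SUV for PET) on a regular grid. Arrays are
#' stored with `dim = c(nz, ny, nx)` under a fixed anatomical convention:
#' the z index increases inferior to superior, the y index anterior to
#' posterior, and the x index patient-left to patient-right. `spacing` and
#' `origin` are in millimetres, ordered (z, y, x); `origin` is the physical
#' coordinate of the centre of voxel (1, 1, 1).
#'
#' @slot values 3D numeric array, `dim = c(nz, ny, nx)`.
#' @slot spacing numeric(3), voxel spacing in mm, (dz, dy, dx), all > 0.
#' @slot origin numeric(3), physical position of voxel (1,1,1) in mm.
#' @export
setClass("VolumeGrid",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "'values' must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "'spacing' must be 3 positive finite numbers")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "'origin' must be 3 finite numbers")
    if (any(dim(object@values) < 1L))
      msg <- c(msg, "all grid dimensions must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' BinaryMask: a voxel set on a VolumeGrid geometry
#'
#' Membership indicator per voxel, carrying the same (z, y, x) geometry as
#' [VolumeGrid-class]. Masks produced by the segmentation operations never
#' contain voxels outside the grid bounds by construction.
#'
#' @slot voxels 3D logical array, `dim = c(nz, ny, nx)`.
#' @slot spacing numeric(3), voxel spacing in mm, (dz, dy, dx).
#' @slot origin numeric(3), physical position of voxel (1,1,1) in mm.
#' @export
setClass("BinaryMask",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@voxels)) != 3L || !is.logical(object@voxels))
      msg <- c(msg, "'voxels' must be a 3D logical array")
    if (anyNA(object@voxels))
      msg <- c(msg, "'voxels' must not contain NA")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "'spacing' must be 3 positive numbers")
    if (length(object@origin) != 3L)
      msg <- c(msg, "'origin' must have length 3")
    if (length(msg)) msg else TRUE
  })

#' QuantizedRegion: uniformly quantized SUV values inside a mask
#'
#' Gray levels in 1..Ng for every in-mask voxel, obtained by linear rescaling
#' of SUV between 0 and a cohort-wide SUVmax (see [quantizeSUV()]). Levels are
#' stored as an integer array over the mask bounding box with `NA` outside the
#' mask, so texture matrices can be built by array shifts.
#'
#' @slot levels integer 3D array, values in 1..Ng or NA outside the mask.
#' @slot Ng integer, number of gray levels (>= 2).
#' @slot cohortSuvmax numeric, the SUV scaling maximum used.
#' @slot spacing numeric(3), voxel spacing of the underlying PET grid.
#' @export
setClass("QuantizedRegion",
  representation(levels = "array", Ng = "integer", cohortSuvmax = "numeric",
                 spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@Ng) != 1L || object@Ng < 2L)
      msg <- c(msg, "'Ng' must be a single integer >= 2")
    lv <- object@levels[!is.na(object@levels)]
    if (length(lv) == 0L)
      msg <- c(msg, "region contains no in-mask voxels")
    else if (any(lv < 1L) || any(lv > object@Ng))
      msg <- c(msg, "levels must lie in [1, Ng]")
    if (length(object@cohortSuvmax) != 1L || object@cohortSuvmax <= 0)
      msg <- c(msg, "'cohortSuvmax' must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' PhantomCase: one synthetic patient
#'
#' Paired CT/PET phantom volumes with construction-time ground-truth masks and
#' the per-patient labels the analysis consumes (PET visual class, flow
#' cytometry class, biopsy site).
#'
#' @slot ct [VolumeGrid-class] in Hounsfield units.
#' @slot pet [VolumeGrid-class] in SUV units, co-registered with `ct`.
#' @slot truth named list of [BinaryMask-class] on the CT grid:
#'   `whole_marrow`, `sternum_site`, `left_iliac_site`, `right_iliac_site`,
#'   `humeri`, `femora`, `spinal_canal`.
#' @slot labels named list: `case_id`, `pet_class` ("+"/"-"), `mfc_class`
#'   ("+"/"-"), `biopsy_site` ("S", "LIC" or "RIC"), `age`, `sex`, `seed`.
#' @export
setClass("PhantomCase",
  representation(ct = "VolumeGrid", pet = "VolumeGrid", truth = "list",
                 labels = "list"),
  validity = function(object) {
    need <- c("whole_marrow", "sternum_site", "left_iliac_site",
              "right_iliac_site", "humeri", "femora", "spinal_canal")
    msg <- character()
    if (!all(need %in% names(object@truth)))
      msg <- c(msg, paste("truth must contain:", paste(need, collapse = ", ")))
    lb <- object@labels
    if (!all(c("pet_class", "mfc_class", "biopsy_site") %in% names(lb)))
      msg <- c(msg, "labels must contain pet_class, mfc_class, biopsy_site")
    else {
      if (!lb$pet_class %in% c("+", "-")) msg <- c(msg, "pet_class must be '+' or '-'")
      if (!lb$mfc_class %in% c("+", "-")) msg <- c(msg, "mfc_class must be '+' or '-'")
      if (!lb$biopsy_site %in% c("S", "LIC", "RIC"))
        msg <- c(msg, "biopsy_site must be one of 'S', 'LIC', 'RIC'")
    }
    if (length(msg)) msg else TRUE
  })
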