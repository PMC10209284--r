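## Synthetic PET/CT phantom cohort.
##
## The phantom is a schematic skeleton painted in Hounsfield units on a CT
## grid: a vertical spine cylinder enclosing a low-HU spinal canal near the
## posterior midline, an anterior sternum slab in the upper torso, a
## laterally wide pelvis with two posterior iliac-crest wings, and humeral /
## femoral cylinders. Every bone is a compact-bone shell around a marrow
## interior. The paired PET volume carries baseline marrow uptake plus, for
## PET-positive cases, focal Gaussian lesions confined to the marrow.
## Ground-truth masks are recorded at construction.

# run expr under a fixed RNG state, restoring the caller's stream
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Phantom geometry and intensity specification
#'
#' Defaults describe a downscaled whole-body acquisition: CT 96 x 96 x 192 at
#' 2 x 2 x 2.5 mm and PET 48 x 48 x 96 at 4 x 4 x 5 mm (same 192 x 192 x
#' 480 mm field of view). `fullSize = TRUE` switches to the clinical matrix
#' (CT 512 x 512 at 0.9766 mm in-plane, PET 168 x 168 at 4.0728 mm).
#' Anatomy is given in millimetres; HU values must satisfy
#' compact bone > detection threshold > marrow > soft tissue.
#'
#' @param fullSize use clinical matrix sizes instead of the downscaled grid.
#' @param hu named list of intensities: `air`, `soft`, `marrow`, `bone`,
#'   `canal` (Hounsfield units).
#' @param anatomy named list of structure geometries in mm; see the default
#'   for the expected fields. Pass modified copies to move or rescale bones.
#' @param uptake named list: `baseline_mean`, `baseline_sd` (per-voxel
#'   marrow SUV texture drawn from a Gamma with these moments, truncated at
#'   mean + 5 sd), `background` SUV,
#'   `noise_sd` (additive Gaussian image noise), `lesion_lambda` (Poisson
#'   mean for extra lesions), `lesion_radius` and `lesion_peak` (uniform
#'   ranges), all in SUV / mm.
#' @return a validated list of class `PhantomSpec`.
#' @export
phantomSpec <- function(fullSize = FALSE, hu = NULL, anatomy = NULL,
                        uptake = NULL) {
  spec <- list(
    ct_dim = c(192L, 96L, 96L), ct_spacing = c(2.5, 2, 2),
    pet_dim = c(96L, 48L, 48L), pet_spacing = c(5, 4, 4),
    hu = list(air = -1000, soft = 30, marrow = 150, bone = 700, canal = 15),
    ct_noise_sd = 0,
    anatomy = list(
      soft_body = list(x = c(20, 172), y = c(30, 160), z = c(105, 460)),
      spine = list(x = 96, y = 128, r = 16, shell = 3, z = c(178, 445),
                   canal_r = 3.5, canal_dy = 6),
      sternum = list(x = c(76, 116), y = c(40, 56), z = c(330, 450), shell = 3),
      pelvis_body = list(x = c(32, 160), y = c(100, 150), z = c(110, 160),
                         shell = 3),
      pelvis_wing = list(span = c(24, 168), width = 24, y = c(108, 152),
                         z = c(112, 168), shell = 3),
      femur = list(xc = c(61, 131), y = 120, r = 12, shell = 3, z = c(12, 100)),
      humerus = list(xc = c(12, 180), y = 120, r = 9, shell = 3,
                     z = c(350, 455))),
    uptake = list(baseline_mean = 1.5, baseline_sd = 0.3, background = 0.2,
                  noise_sd = 0.05, lesion_lambda = 4,
                  lesion_radius = c(6, 15), lesion_peak = c(4, 12)))
  if (fullSize) {
    spec$ct_dim <- c(192L, 512L, 512L)
    spec$ct_spacing <- c(2.5, 0.9766, 0.9766)
    spec$pet_dim <- c(96L, 168L, 168L)
    spec$pet_spacing <- c(5, 4.0728, 4.0728)
  }
  if (!is.null(hu)) spec$hu[names(hu)] <- hu
  if (!is.null(anatomy))
    for (nm in names(anatomy)) spec$anatomy[[nm]][names(anatomy[[nm]])] <-
      anatomy[[nm]]
  if (!is.null(uptake)) spec$uptake[names(uptake)] <- uptake
  validatePhantomSpec(spec)
  class(spec) <- "PhantomSpec"
  spec
}

validatePhantomSpec <- function(spec) {
  with(spec$hu, {
    if (!(bone > marrow && marrow > soft && soft > air))
      stop("HU ordering violated: need bone > marrow > soft > air",
           call. = FALSE)
  })
  ext <- spec$ct_dim * spec$ct_spacing       # physical extent (z, y, x)
  an <- spec$anatomy
  zr <- function(v) range(v)
  fits <- c(
    an$spine$z, an$sternum$z, an$pelvis_body$z, an$pelvis_wing$z,
    an$femur$z, an$humerus$z) >= 0 &
    c(an$spine$z, an$sternum$z, an$pelvis_body$z, an$pelvis_wing$z,
      an$femur$z, an$humerus$z) <= ext[1]
  xfits <- c(an$spine$x - an$spine$r, an$spine$x + an$spine$r,
             an$sternum$x, an$pelvis_wing$span,
             an$femur$xc - an$femur$r, an$femur$xc + an$femur$r,
             an$humerus$xc - an$humerus$r, an$humerus$xc + an$humerus$r)
  if (!all(fits) || any(xfits < 0) || any(xfits > ext[3]))
    stop("phantom structures do not fit inside the grid", call. = FALSE)
  invisible(TRUE)
}

#' Randomly perturbed phantom geometry
#'
#' Draws sizes and positions uniformly within bounds that preserve the
#' geometric predicates the segmentation rules rely on (inter-bone gaps, the
#' sternum being the longest axial component after removals, the pelvis the
#' widest lateral one).
#'
#' @param seed integer RNG seed.
#' @param base a `PhantomSpec` to perturb (default [phantomSpec()]).
#' @return a `PhantomSpec`.
#' @export
randomPhantomSpec <- function(seed, base = phantomSpec()) {
  withSeed(seed, {
    u <- function(lo, hi) stats::runif(1, lo, hi)
    dxy <- u(-4, 4)                 # common lateral shift of the midline
    an <- list(
      spine = list(x = 96 + dxy, y = 128 + u(-3, 3), r = u(14.5, 17.5),
                   z = c(u(174, 182), u(440, 450))),
      sternum = list(x = c(96 + dxy - u(18, 22), 96 + dxy + u(18, 22)),
                     y = c(u(38, 44), u(54, 60)),
                     z = c(u(324, 336), u(446, 454))),
      pelvis_body = list(x = c(96 + dxy - u(60, 68), 96 + dxy + u(60, 68)),
                         y = c(u(98, 104), u(146, 152)),
                         z = c(u(108, 114), u(156, 162))),
      pelvis_wing = list(span = c(96 + dxy - u(70, 76), 96 + dxy + u(70, 76)),
                         width = u(22, 27),
                         y = c(u(106, 110), u(150, 154)),
                         z = c(u(110, 116), u(164, 170))),
      femur = list(xc = 96 + dxy + c(-u(32, 38), u(32, 38)), r = u(10.5, 13),
                   z = c(u(10, 16), u(94, 100))),
      humerus = list(xc = c(u(11, 14), u(178, 181)), r = u(8, 9.5),
                     z = c(u(346, 354), u(450, 458))))
    phantomSpec(hu = base$hu, uptake = base$uptake, anatomy = an)
  })
}

## ---- CT painting -----------------------------------------------------------

# logical array for an axis-aligned box given mm ranges over centre coords
boxArr <- function(zc, yc, xc, z, y, x) {
  zin <- zc >= z[1] & zc <= z[2]
  yin <- yc >= y[1] & yc <= y[2]
  xin <- xc >= x[1] & xc <= x[2]
  outer(zin, outer(yin, xin, "&"), "&")
}

# vertical cylinder: centre (x0, y0), radius r, z range (mm)
cylArr <- function(zc, yc, xc, x0, y0, r, z) {
  if (r <= 0) return(array(FALSE, c(length(zc), length(yc), length(xc))))
  sec <- outer((yc - y0)^2, (xc - x0)^2, "+") <= r^2
  outer(zc >= z[1] & zc <= z[2], sec, "&")
}

inset <- function(v, s) c(v[1] + s, v[2] - s)

# paint all bones; returns CT values plus the truth component arrays
buildSkeletonArrays <- function(spec) {
  d <- spec$ct_dim; sp <- spec$ct_spacing
  zc <- (seq_len(d[1]) - 0.5) * sp[1]
  yc <- (seq_len(d[2]) - 0.5) * sp[2]
  xc <- (seq_len(d[3]) - 0.5) * sp[3]
  an <- spec$anatomy

  sp_out <- cylArr(zc, yc, xc, an$spine$x, an$spine$y, an$spine$r, an$spine$z)
  sp_in <- cylArr(zc, yc, xc, an$spine$x, an$spine$y,
                  an$spine$r - an$spine$shell, inset(an$spine$z, an$spine$shell))
  canal <- if (an$spine$canal_r > 0)
    cylArr(zc, yc, xc, an$spine$x, an$spine$y + an$spine$canal_dy,
           an$spine$canal_r, inset(an$spine$z, an$spine$shell * 2))
  else array(FALSE, d)

  st_out <- boxArr(zc, yc, xc, an$sternum$z, an$sternum$y, an$sternum$x)
  st_in <- boxArr(zc, yc, xc, inset(an$sternum$z, an$sternum$shell),
                  inset(an$sternum$y, an$sternum$shell),
                  inset(an$sternum$x, an$sternum$shell))

  pb <- an$pelvis_body; pw <- an$pelvis_wing
  wings_x <- list(c(pw$span[1], pw$span[1] + pw$width),
                  c(pw$span[2] - pw$width, pw$span[2]))
  pv_out <- boxArr(zc, yc, xc, pb$z, pb$y, pb$x) |
    boxArr(zc, yc, xc, pw$z, pw$y, wings_x[[1]]) |
    boxArr(zc, yc, xc, pw$z, pw$y, wings_x[[2]])
  pv_in <- boxArr(zc, yc, xc, inset(pb$z, pb$shell), inset(pb$y, pb$shell),
                  inset(pb$x, pb$shell)) |
    boxArr(zc, yc, xc, inset(pw$z, pw$shell), inset(pw$y, pw$shell),
           inset(wings_x[[1]], pw$shell)) |
    boxArr(zc, yc, xc, inset(pw$z, pw$shell), inset(pw$y, pw$shell),
           inset(wings_x[[2]], pw$shell))

  fe <- an$femur
  fe_out <- cylArr(zc, yc, xc, fe$xc[1], fe$y, fe$r, fe$z) |
    cylArr(zc, yc, xc, fe$xc[2], fe$y, fe$r, fe$z)
  fe_in <- cylArr(zc, yc, xc, fe$xc[1], fe$y, fe$r - fe$shell, inset(fe$z, fe$shell)) |
    cylArr(zc, yc, xc, fe$xc[2], fe$y, fe$r - fe$shell, inset(fe$z, fe$shell))

  hu_ <- an$humerus
  hu_out <- cylArr(zc, yc, xc, hu_$xc[1], hu_$y, hu_$r, hu_$z) |
    cylArr(zc, yc, xc, hu_$xc[2], hu_$y, hu_$r, hu_$z)
  hu_in <- cylArr(zc, yc, xc, hu_$xc[1], hu_$y, hu_$r - hu_$shell,
                  inset(hu_$z, hu_$shell)) |
    cylArr(zc, yc, xc, hu_$xc[2], hu_$y, hu_$r - hu_$shell,
           inset(hu_$z, hu_$shell))

  outAll <- sp_out | st_out | pv_out | fe_out | hu_out
  inAll <- (sp_in | st_in | pv_in | fe_in | hu_in) & !canal
  soft <- boxArr(zc, yc, xc, an$soft_body$z, an$soft_body$y, an$soft_body$x)

  ct <- array(spec$hu$air, d)
  ct[soft] <- spec$hu$soft
  ct[outAll] <- spec$hu$bone
  ct[inAll] <- spec$hu$marrow
  ct[canal] <- spec$hu$canal

  list(ct = ct, marrow = inAll, canal = canal, bone = outAll,
       sternum_marrow = st_in & inAll, pelvis_marrow = pv_in & inAll,
       humeri = hu_in & inAll, femora = fe_in & inAll)
}

# edge of the sternal biopsy cube in grid voxels: 40 voxels of the clinical
# CT (0.9766 x 0.9766 x 2.5 mm) converted to the current spacing so the
# physical extent is preserved
sternumCubeEdge <- function(spacing, edge_vox = 40L,
                            ref_spacing = c(2.5, 0.9766, 0.9766)) {
  pmax(1L, as.integer(round(edge_vox * ref_spacing / spacing)))
}

# intersect a sternum mask with the biopsy cube: top face flush with the most
# superior voxel, x/y centred on the mask centroid
sternumCube <- function(mask, edge = NULL) {
  if (is.null(edge)) edge <- sternumCubeEdge(spacing(mask))
  if (length(edge) == 1L) edge <- rep(as.integer(edge), 3L)
  idx <- which(mask@voxels, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty sternum mask", call. = FALSE)
  ztop <- max(idx[, 1])
  cy <- round(mean(idx[, 2])); cx <- round(mean(idx[, 3]))
  zr <- c(ztop - edge[1] + 1L, ztop)
  yr <- cy + c(-floor((edge[2] - 1) / 2), ceiling((edge[2] - 1) / 2))
  xr <- cx + c(-floor((edge[3] - 1) / 2), ceiling((edge[3] - 1) / 2))
  keep <- idx[, 1] >= zr[1] & idx[, 1] <= zr[2] &
    idx[, 2] >= yr[1] & idx[, 2] <= yr[2] &
    idx[, 3] >= xr[1] & idx[, 3] <= xr[2]
  arr <- array(FALSE, dim(mask))
  arr[idx[keep, , drop = FALSE]] <- TRUE
  binaryMask(arr, grid = mask)
}

# truth biopsy-site masks derived from the truth marrow components with the
# same geometric rules the segmentation implements
truthSiteMasks <- function(parts, grid) {
  sternum <- binaryMask(parts$sternum_marrow, grid = grid)
  pelvis <- binaryMask(parts$pelvis_marrow, grid = grid)
  sternum_site <- sternumCube(sternum)
  regions <- dividePelvis(pelvis)
  right <- splitHalf(maskUnion(regions@regions[[1]], regions@regions[[2]]),
                     "coronal", "high")
  left <- splitHalf(maskUnion(regions@regions[[4]], regions@regions[[5]]),
                    "coronal", "high")
  list(sternum_site = sternum_site, left_iliac_site = left,
       right_iliac_site = right)
}

## ---- PET painting ----------------------------------------------------------

buildPet <- function(spec, marrowCT, siteCT, petPositive) {
  d <- spec$pet_dim; sp <- spec$pet_spacing
  up <- spec$uptake
  ctGrid <- binaryMask(marrowCT, spacing = spec$ct_spacing,
                       origin = spec$ct_spacing / 2)
  petGeom <- volumeGrid(array(0, d), spacing = sp, origin = sp / 2)
  marrowPET <- transferMask(ctGrid, petGeom)@voxels

  # per-voxel Gamma texture field for the marrow baseline, truncated at
  # mean + 5 sd: a PET-negative read means no focal uptake, so the
  # homogeneous field must not contain focal-like outliers
  shape <- (up$baseline_mean / up$baseline_sd)^2
  scale <- up$baseline_sd^2 / up$baseline_mean
  baseline <- stats::rgamma(sum(marrowPET), shape = shape, scale = scale)
  baseline <- pmin(baseline, up$baseline_mean + 5 * up$baseline_sd)

  suv <- array(up$background, d)
  suv[marrowPET] <- baseline

  if (petPositive) {
    nLesion <- stats::rpois(1, up$lesion_lambda) + 1L
    # first lesion centred in the biopsy-site region, the rest anywhere in marrow
    siteIdx <- which(siteCT, arr.ind = TRUE)
    marIdx <- which(marrowCT, arr.ind = TRUE)
    centers <- matrix(0, nLesion, 3)
    pick <- siteIdx[sample.int(nrow(siteIdx), 1L), ]
    centers[1, ] <- (pick - 0.5) * spec$ct_spacing
    if (nLesion > 1L)
      for (i in 2:nLesion) {
        pick <- marIdx[sample.int(nrow(marIdx), 1L), ]
        centers[i, ] <- (pick - 0.5) * spec$ct_spacing
      }
    radii <- stats::runif(nLesion, up$lesion_radius[1], up$lesion_radius[2])
    peaks <- stats::runif(nLesion, up$lesion_peak[1], up$lesion_peak[2])
    mi <- which(marrowPET, arr.ind = TRUE)
    pos <- sweep(mi, 2, 0.5) %*% diag(sp)       # mm coords of marrow voxels
    add <- numeric(nrow(mi))
    for (i in seq_len(nLesion)) {
      d2 <- (pos[, 1] - centers[i, 1])^2 + (pos[, 2] - centers[i, 2])^2 +
        (pos[, 3] - centers[i, 3])^2
      sig <- radii[i] / 2
      add <- add + peaks[i] * exp(-d2 / (2 * sig^2))
    }
    suv[marrowPET] <- suv[marrowPET] + add
  }

  if (up$noise_sd > 0)
    suv <- suv + array(stats::rnorm(prod(d), 0, up$noise_sd), d)
  suv[suv < 0] <- 0
  volumeGrid(suv, spacing = sp, origin = sp / 2)
}

## ---- case / cohort generation ---------------------------------------------

#' Generate one synthetic PET/CT case
#'
#' Deterministic given `seed`: the CT, PET and truth masks are bit-identical
#' across repeated calls.
#'
#' @param spec a `PhantomSpec` from [phantomSpec()].
#' @param labels named list with `pet_class` ("+"/"-"), `mfc_class`,
#'   `biopsy_site` ("S"/"LIC"/"RIC") and optionally `case_id`, `age`, `sex`.
#' @param seed integer RNG seed.
#' @return a [PhantomCase-class].
#' @export
generatePhantom <- function(spec = phantomSpec(),
                            labels = list(pet_class = "-", mfc_class = "-",
                                          biopsy_site = "S"),
                            seed = 1L) {
  validatePhantomSpec(spec)
  parts <- buildSkeletonArrays(spec)
  assemblePhantom(spec, parts, labels, seed)
}

# shared between generatePhantom and generateCohort (which reuses the CT
# and precomputed truth sites across cases with identical anatomy)
assemblePhantom <- function(spec, parts, labels, seed, sites = NULL) {
  ctGrid <- volumeGrid(parts$ct, spacing = spec$ct_spacing,
                       origin = spec$ct_spacing / 2)
  if (spec$ct_noise_sd > 0)
    ctGrid@values <- ctGrid@values +
      withSeed(seed + 1L, array(stats::rnorm(prod(dim(ctGrid)), 0,
                                             spec$ct_noise_sd), dim(ctGrid)))
  if (is.null(sites)) sites <- truthSiteMasks(parts, ctGrid)
  siteArr <- switch(labels$biopsy_site,
                    S = sites$sternum_site@voxels,
                    LIC = sites$left_iliac_site@voxels,
                    RIC = sites$right_iliac_site@voxels)
  pet <- withSeed(seed, buildPet(spec, parts$marrow, siteArr,
                                 labels$pet_class == "+"))
  truth <- list(
    whole_marrow = binaryMask(parts$marrow, grid = ctGrid),
    sternum_site = sites$sternum_site,
    left_iliac_site = sites$left_iliac_site,
    right_iliac_site = sites$right_iliac_site,
    humeri = binaryMask(parts$humeri, grid = ctGrid),
    femora = binaryMask(parts$femora, grid = ctGrid),
    spinal_canal = binaryMask(parts$canal, grid = ctGrid))
  labels$seed <- as.integer(seed)
  if (is.null(labels$case_id)) labels$case_id <- sprintf("case_%04d", seed)
  new("PhantomCase", ct = ctGrid, pet = pet, truth = truth, labels = labels)
}

#' Cohort-level specification
#'
#' Class proportions default to the study structure: 31/39 PET-negative,
#' 24/39 MFC-negative, 12 discordant PET-/MFC+ cases (the PET+/MFC- count
#' follows from the marginals), and biopsy sites drawn with frequencies
#' 22:15:2 for sternum : left : right posterior iliac crest.
#'
#' @param n number of cases (>= 4).
#' @param pet_neg_prop,mfc_neg_prop proportions of PET- and MFC- cases.
#' @param discordant_pet_neg_mfc_pos number of PET-/MFC+ cases, realized
#'   exactly; NULL (default) scales the study's 12/39 rate to `n`.
#' @param site_props named numeric, relative frequencies for sites S/LIC/RIC.
#' @param vary_anatomy draw a fresh [randomPhantomSpec()] per case.
#' @param seed integer RNG seed.
#' @return a validated list of class `CohortSpec`.
#' @export
cohortSpec <- function(n = 39L, pet_neg_prop = 31 / 39, mfc_neg_prop = 24 / 39,
                       discordant_pet_neg_mfc_pos = NULL,
                       site_props = c(S = 22, LIC = 15, RIC = 2),
                       vary_anatomy = FALSE, seed = 1L) {
  if (n < 4L) stop("cohort needs n >= 4", call. = FALSE)
  if (is.null(discordant_pet_neg_mfc_pos))
    discordant_pet_neg_mfc_pos <- round(n * 12 / 39)
  if (pet_neg_prop < 0 || pet_neg_prop > 1 || mfc_neg_prop < 0 ||
      mfc_neg_prop > 1)
    stop("class proportions must lie in [0, 1]", call. = FALSE)
  spec <- list(n = as.integer(n), pet_neg_prop = pet_neg_prop,
               mfc_neg_prop = mfc_neg_prop,
               d_pet_neg_mfc_pos = as.integer(discordant_pet_neg_mfc_pos),
               site_props = site_props / sum(site_props),
               vary_anatomy = isTRUE(vary_anatomy), seed = as.integer(seed))
  class(spec) <- "CohortSpec"
  spec
}

# integer class counts by largest-remainder rounding
apportion <- function(n, props) {
  raw <- n * props
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}

#' Realize the label table of a synthetic cohort
#'
#' Label marginals and the discordance count are exact, not stochastic.
#'
#' @param cspec a `CohortSpec`.
#' @return data.frame with columns case_id, pet_class, mfc_class,
#'   biopsy_site, age, sex, seed.
#' @export
cohortLabels <- function(cspec) {
  n <- cspec$n
  petNeg <- as.integer(round(n * cspec$pet_neg_prop))
  mfcNeg <- as.integer(round(n * cspec$mfc_neg_prop))
  mfcPos <- n - mfcNeg
  d1 <- cspec$d_pet_neg_mfc_pos
  petPos <- n - petNeg
  mfcPosInPetPos <- mfcPos - d1
  if (d1 > petNeg || d1 > mfcPos || mfcPosInPetPos < 0 ||
      mfcPosInPetPos > petPos)
    stop("infeasible discordance counts for the requested class proportions",
         call. = FALSE)
  withSeed(cspec$seed, {
    pet <- sample(rep(c("-", "+"), c(petNeg, petPos)))
    mfc <- rep("-", n)
    mfc[sample(which(pet == "-"), d1)] <- "+"
    if (mfcPosInPetPos > 0)
      mfc[sample(which(pet == "+"), mfcPosInPetPos)] <- "+"
    siteCounts <- apportion(n, cspec$site_props)
    site <- sample(rep(names(cspec$site_props), siteCounts))
    data.frame(case_id = sprintf("case_%04d", seq_len(n)),
               pet_class = pet, mfc_class = mfc, biopsy_site = site,
               age = round(stats::rnorm(n, 56.6, 7.9)),
               sex = sample(c("m", "f"), n, replace = TRUE,
                            prob = c(11, 28) / 39),
               seed = cspec$seed + seq_len(n),
               stringsAsFactors = FALSE)
  })
}

#' Generate a labelled synthetic cohort
#'
#' @param cspec a `CohortSpec`.
#' @param pspec a `PhantomSpec` shared by all cases (ignored when
#'   `cspec$vary_anatomy` is TRUE).
#' @return list of [PhantomCase-class] objects with a `labels` attribute
#'   holding the cohort data.frame.
#' @export
generateCohort <- function(cspec = cohortSpec(), pspec = phantomSpec()) {
  tab <- cohortLabels(cspec)
  sharedParts <- if (!cspec$vary_anatomy) buildSkeletonArrays(pspec) else NULL
  sharedSites <- if (!cspec$vary_anatomy && pspec$ct_noise_sd == 0) {
    ctGrid <- volumeGrid(sharedParts$ct, spacing = pspec$ct_spacing,
                         origin = pspec$ct_spacing / 2)
    truthSiteMasks(sharedParts, ctGrid)
  } else NULL
  cases <- lapply(seq_len(nrow(tab)), function(i) {
    lb <- as.list(tab[i, c("case_id", "pet_class", "mfc_class", "biopsy_site",
                           "age", "sex")])
    if (cspec$vary_anatomy) {
      ps <- randomPhantomSpec(tab$seed[i], base = pspec)
      generatePhantom(ps, lb, seed = tab$seed[i])
    } else {
      assemblePhantom(pspec, sharedParts, lb, seed = tab$seed[i],
                      sites = sharedSites)
    }
  })
  attr(cases, "labels") <- tab
  cases
}

#' Write a cohort to disk as NIfTI pairs plus a labels CSV
#'
#' @param cases result of [generateCohort()].
#' @param dir output directory (created if needed).
#' @param masks also write the truth masks.
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cases, dir, masks = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (case in cases) {
    id <- case@labels$case_id
    writeVolume(case@ct, file.path(dir, paste0(id, "_ct.nii.gz")))
    writeVolume(case@pet, file.path(dir, paste0(id, "_pet.nii.gz")))
    if (masks)
      for (nm in names(case@truth))
        writeMask(case@truth[[nm]],
                  file.path(dir, paste0(id, "_", nm, ".nii.gz")))
  }
  utils::write.csv(attr(cases, "labels"), file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  invisible(dir)
}
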