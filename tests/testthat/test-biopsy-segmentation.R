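test_that("limb removal with and without explicit masks", {
  seg <- cachedSeg()
  tr <- seg$case@truth
  out <- removeLimbs(seg$marrow, tr$humeri, tr$femora)
  expect_equal(sum(maskArray(out) & maskArray(tr$humeri)), 0L)
  expect_equal(sum(maskArray(out) & maskArray(tr$femora)), 0L)

  empty <- binaryMask(array(FALSE, dim(seg$marrow)), grid = seg$marrow)
  expect_identical(maskArray(removeLimbs(seg$marrow, empty, empty)),
                   maskArray(seg$marrow))

  # automatic identification recovers the true limbs
  limbs <- autoLimbMask(seg$marrow)
  truthLimbs <- maskUnion(tr$humeri, tr$femora)
  expect_gte(diceCoefficient(limbs, truthLimbs), 0.9)

  expect_error(removeLimbs(empty), "empty marrow mask")
})

test_that("sternal site segmentation recovers the phantom truth", {
  seg <- cachedSeg()
  site <- segmentSternumSite(seg$noLimbs)
  expect_gte(diceCoefficient(site, seg$case@truth$sternum_site), 0.9)

  # confined to the biopsy cube: bounding-box edges within the scaled
  # 40-voxel edge for this grid spacing
  edge <- bmradiomics:::sternumCubeEdge(spacing(site))
  bb <- maskBoundingBox(site)
  expect_true(all(bb[, 2] - bb[, 1] + 1 <= edge))

  # a sternum smaller than the cube is kept whole by the cube intersection
  small <- array(FALSE, c(30, 10, 10))
  small[5:9, 4:6, 4:6] <- TRUE
  sm <- binaryMask(small)
  out <- bmradiomics:::sternumCube(sm, 40L)
  expect_identical(maskArray(out), small)
})

test_that("pelvis division yields five disjoint slabs covering the pelvis", {
  box <- array(FALSE, c(6, 6, 60))
  box[2:5, 2:5, 3:52] <- TRUE                  # 50 voxels wide
  r <- dividePelvis(binaryMask(box))@regions
  expect_length(r, 5L)
  expect_equal(vapply(r, nVoxels, 0L), rep(160L, 5))

  # 52-wide box: widths 11,10,10,10,11 under the plane/boundary convention
  box2 <- array(FALSE, c(4, 4, 60))
  box2[2:3, 2:3, 4:55] <- TRUE
  r2 <- dividePelvis(binaryMask(box2))@regions
  widths <- vapply(r2, function(m) {
    bb <- maskBoundingBox(m); bb[3, 2] - bb[3, 1] + 1L
  }, 0L)
  expect_equal(widths, c(11L, 10L, 10L, 10L, 11L))  # R1 (far right) first

  un <- Reduce(`|`, lapply(r2, maskArray))
  expect_identical(un, box2)
  for (i in 1:4) for (j in (i + 1):5)
    expect_false(any(maskArray(r2[[i]]) & maskArray(r2[[j]])))

  thin <- array(FALSE, c(4, 4, 6)); thin[2, 2, 2:4] <- TRUE
  expect_error(dividePelvis(binaryMask(thin)), "too thin")
})

test_that("iliac site segmentation recovers the phantom truth on both sides", {
  seg <- cachedSeg()
  left <- segmentIliacSite(seg$noLimbs, "left")
  right <- segmentIliacSite(seg$noLimbs, "right")
  expect_gte(diceCoefficient(left, seg$case@truth$left_iliac_site), 0.9)
  expect_gte(diceCoefficient(right, seg$case@truth$right_iliac_site), 0.9)
  expect_false(any(maskArray(left) & maskArray(right)))

  # the right site occupies larger x indices (patient right) than the left
  expect_gt(min(which(maskArray(right), arr.ind = TRUE)[, 3]),
            max(which(maskArray(left), arr.ind = TRUE)[, 3]))

  # nothing of the anterior half of the kept pelvis slabs survives
  pelvis <- selectComponent(splitHalf(seg$noLimbs, "axial", "low"),
                            "widest_lateral")
  regions <- dividePelvis(pelvis)@regions
  keptRight <- maskUnion(regions[[1]], regions[[2]])
  anterior <- splitHalf(keptRight, "coronal", "low")
  expect_equal(sum(maskArray(right) & maskArray(anterior)), 0L)
})

test_that("selectBiopsyMask dispatches on the site code", {
  seg <- cachedSeg()
  s <- selectBiopsyMask(seg$marrow, "S")
  expect_identical(maskArray(s), maskArray(segmentSternumSite(seg$noLimbs)))
  ric <- selectBiopsyMask(seg$marrow, "RIC")
  expect_gte(diceCoefficient(ric, seg$case@truth$right_iliac_site), 0.9)
  expect_error(selectBiopsyMask(seg$marrow, "X"), "unknown biopsy site")

  # every site mask is contained in the whole marrow mask
  for (code in c("S", "LIC", "RIC")) {
    m <- selectBiopsyMask(seg$marrow, code)
    expect_true(all(maskArray(seg$marrow)[maskArray(m)]))
  }
})

test_that("segmentation is invariant to the on-disk orientation of the CT", {
  seg <- cachedSeg()
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(seg$case@ct, f)
  img <- RNifti::readNifti(f)
  RNifti::orientation(img) <- "PIL"            # permuted + flipped axes
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f2)
  ct2 <- readVolume(f2)
  marrow2 <- segmentBoneMarrow(ct2)
  expect_identical(maskArray(marrow2), maskArray(seg$marrow))
  site2 <- selectBiopsyMask(marrow2, "LIC")
  expect_identical(maskArray(site2),
                   maskArray(selectBiopsyMask(seg$marrow, "LIC")))
})
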