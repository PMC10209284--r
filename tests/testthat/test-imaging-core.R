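test_that("splitHalf splits at the mask bounding-box midpoint", {
  arr <- array(FALSE, c(4, 12, 4))
  arr[2, 2:11, 2] <- TRUE                      # 10-voxel bar along y
  m <- binaryMask(arr)
  hi <- splitHalf(m, "coronal", "high")
  lo <- splitHalf(m, "coronal", "low")
  expect_equal(sort(which(maskArray(hi), arr.ind = TRUE)[, 2]), 7:11)
  expect_equal(sort(which(maskArray(lo), arr.ind = TRUE)[, 2]), 2:6)

  # a single-slice mask stays on the low side (boundary convention)
  arr1 <- array(FALSE, c(3, 5, 3)); arr1[, 3, ] <- TRUE
  s <- binaryMask(arr1)
  expect_equal(nVoxels(splitHalf(s, "coronal", "low")), nVoxels(s))
  expect_equal(nVoxels(splitHalf(s, "coronal", "high")), 0L)

  expect_error(splitHalf(binaryMask(array(FALSE, c(2, 2, 2))), "axial"),
               "empty input mask")
})

test_that("splitHalf partitions any mask: low and high are disjoint and cover it", {
  set.seed(1)
  for (i in 1:1000) {
    m <- randomMask(c(sample(3:8, 1), sample(3:8, 1), sample(3:8, 1)), p = 0.5)
    if (nVoxels(m) == 0L) next
    ax <- sample(c("axial", "coronal", "sagittal"), 1)
    lo <- splitHalf(m, ax, "low")
    hi <- splitHalf(m, ax, "high")
    expect_identical(maskArray(lo) | maskArray(hi), maskArray(m))
    expect_false(any(maskArray(lo) & maskArray(hi)))
  }
})

test_that("selectComponent picks by extent with size then centroid tie-breaks", {
  arr <- array(FALSE, c(32, 10, 40))
  arr[2:21, 2:4, 2:5] <- TRUE                  # z-extent 20
  arr[24:31, 2:4, 8:12] <- TRUE                # z-extent 8
  m <- binaryMask(arr)
  sel <- selectComponent(m, "longest_axial")
  expect_equal(unname(maskBoundingBox(sel)[1, ]), c(2, 21))

  arr2 <- array(FALSE, c(10, 10, 50))
  arr2[2:3, 2:3, 2:31] <- TRUE                 # x-extent 30
  arr2[6:7, 2:3, 35:46] <- TRUE                # x-extent 12
  sel2 <- selectComponent(binaryMask(arr2), "widest_lateral")
  expect_equal(unname(maskBoundingBox(sel2)[3, ]), c(2, 31))

  # identical extents: the larger component wins
  arr3 <- array(FALSE, c(12, 12, 12))
  arr3[2:6, 2:5, 2:6] <- TRUE                  # 100 voxels, z-extent 5
  arr3[8:12, 8:9, 2:6] <- TRUE                 # 50 voxels, z-extent 5
  sel3 <- selectComponent(binaryMask(arr3), "longest_axial")
  expect_equal(nVoxels(sel3), 100L)

  expect_error(selectComponent(binaryMask(array(FALSE, c(2, 2, 2)))), "empty")
})

test_that("selectComponent always returns a single 26-connected component", {
  set.seed(2)
  for (i in 1:50) {
    m <- randomMask(c(8, 8, 8), p = 0.3)
    if (nVoxels(m) == 0L) next
    sel <- selectComponent(m, sample(c("longest_axial", "widest_lateral"), 1))
    lab <- connectedComponents(sel, 26L)
    expect_equal(max(lab), 1L)
  }
})

test_that("transferMask maps by physical voxel-centre containment", {
  # identical grids: identity
  m <- randomMask(c(5, 5, 5), p = 0.5)
  g <- volumeGrid(array(0, c(5, 5, 5)))
  expect_identical(maskArray(transferMask(m, g)), maskArray(m))

  # one clinical-CT voxel against the PET grid: in the output iff a PET
  # voxel centre falls inside the CT voxel (checked by direct geometry)
  ctsp <- c(2.5, 0.9766, 0.9766); petsp <- c(5, 4.0728, 4.0728)
  src <- array(FALSE, c(8, 8, 8)); src[3, 4, 5] <- TRUE
  ct <- binaryMask(src, spacing = ctsp, origin = ctsp / 2)
  pet <- volumeGrid(array(0, c(4, 4, 4)), spacing = petsp, origin = petsp / 2)
  out <- transferMask(ct, pet)
  expected <- array(FALSE, c(4, 4, 4))
  for (z in 1:4) for (y in 1:4) for (x in 1:4) {
    cen <- (c(z, y, x) - 0.5) * petsp
    lo <- (c(3, 4, 5) - 1) * ctsp; hi <- c(3, 4, 5) * ctsp
    expected[z, y, x] <- all(cen >= lo) && all(cen < hi)
  }
  expect_identical(maskArray(out), expected)

  # a full source grid covers the shared extent of the target
  full <- binaryMask(array(TRUE, c(8, 8, 8)), spacing = ctsp,
                     origin = ctsp / 2)
  outFull <- transferMask(full, pet)
  cov <- array(FALSE, c(4, 4, 4))
  for (z in 1:4) for (y in 1:4) for (x in 1:4)
    cov[z, y, x] <- all((c(z, y, x) - 0.5) * petsp < c(8, 8, 8) * ctsp)
  expect_identical(maskArray(outFull), cov)

  far <- binaryMask(array(TRUE, c(2, 2, 2)), origin = c(1000, 1000, 1000))
  expect_error(transferMask(far, pet), "disjoint grids")
})

test_that("transferMask is idempotent on one grid and monotone in the mask", {
  set.seed(3)
  a <- randomMask(c(6, 6, 6), p = 0.3)
  g <- volumeGrid(array(0, c(6, 6, 6)))
  expect_identical(maskArray(transferMask(transferMask(a, g), g)),
                   maskArray(transferMask(a, g)))
  b <- binaryMask(maskArray(a) | (array(runif(216), dim = c(6, 6, 6)) < 0.2))
  tgt <- volumeGrid(array(0, c(3, 3, 3)), spacing = c(2, 2, 2),
                    origin = c(1, 1, 1))
  ta <- transferMask(a, tgt); tb <- transferMask(b, tgt)
  expect_true(all(maskArray(tb)[maskArray(ta)]))
})

test_that("masks survive a NIfTI roundtrip, whatever the stored orientation", {
  g <- volumeGrid(array(rnorm(6 * 5 * 4), c(6, 5, 4)),
                  spacing = c(2.5, 2, 1), origin = c(1.25, 1, 0.5))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(g, f)
  b <- readVolume(f)
  expect_equal(spacing(b), spacing(g))
  expect_equal(origin(b), origin(g))
  expect_equal(voxelValues(b), voxelValues(g), tolerance = 1e-6)

  # rewrite the same image in a flipped on-disk orientation
  img <- RNifti::readNifti(f)
  RNifti::orientation(img) <- "LPI"
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f2)
  b2 <- readVolume(f2)
  expect_equal(voxelValues(b2), voxelValues(g), tolerance = 1e-6)
  expect_equal(origin(b2), origin(g))

  m <- binaryMask(voxelValues(g) > 0, grid = g)
  fm <- withr::local_tempfile(fileext = ".nii.gz")
  writeMask(m, fm)
  expect_identical(maskArray(readMask(fm)), maskArray(m))
})
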