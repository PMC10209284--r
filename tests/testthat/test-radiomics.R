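test_that("uniform quantization follows the rescaling rule with clamping", {
  pet <- volumeGrid(array(c(10, 5, 0, 2.5, 7.5, 10, 1, 2), c(2, 2, 2)))
  mask <- binaryMask(array(TRUE, c(2, 2, 2)))
  q <- quantizeSUV(pet, mask, Ng = 64L, cohortSuvmax = 10)
  lv <- q@levels
  expect_equal(lv[1, 1, 1], 64L)               # I(x) = cohort maximum
  expect_equal(lv[2, 1, 1], 32L)               # midpoint
  expect_equal(lv[1, 2, 1], 1L)                # zero clamps to level 1
  expect_equal(lv[2, 2, 1], 16L)
  expect_true(all(grayLevels(q) >= 1L & grayLevels(q) <= 64L))

  expect_error(quantizeSUV(pet, mask, 64L, cohortSuvmax = 5),
               "scaling maximum violated")
  expect_error(quantizeSUV(pet, binaryMask(array(FALSE, c(2, 2, 2))), 64L, 10),
               "empty mask")
})

test_that("the co-occurrence matrix matches brute-force pair enumeration", {
  # constant block: a single diagonal entry
  q <- regionFromLevels(array(3L, c(3, 3, 3)), Ng = 8L)
  P <- glcmMatrix(q)
  expect_equal(P[3, 3], 1)
  expect_equal(sum(P), 1)

  # two-voxel region with levels 2 and 5: symmetric halves
  lev2 <- array(c(2L, 5L), c(2, 1, 1))
  P2 <- glcmMatrix(regionFromLevels(lev2, 8L))
  expect_equal(P2[2, 5], 0.5)
  expect_equal(P2[5, 2], 0.5)

  set.seed(7)
  for (i in 1:20) {
    lev <- randomRegion(c(5, 5, 5), Ng = 6L, p = 0.7)
    if (sum(!is.na(lev)) < 2) next
    q <- regionFromLevels(lev, 6L)
    expect_equal(glcmMatrix(q), oracleGlcm(lev, 6L), tolerance = 1e-12)
  }

  # isolated voxels only: no co-occurring pair
  iso <- array(NA_integer_, c(3, 3, 3)); iso[1, 1, 1] <- 2L; iso[3, 3, 3] <- 4L
  expect_error(glcmMatrix(regionFromLevels(iso, 8L)), "degenerate region")
})

test_that("GLCM features obey the hand-computed identities", {
  qc <- regionFromLevels(array(4L, c(3, 3, 3)), 8L)
  f <- glcmFeatures(glcmMatrix(qc))
  expect_equal(unname(f["Energy"]), 1)
  expect_equal(unname(f["Entropy"]), 0)
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["Homogeneity"]), 1)
  expect_equal(unname(f["Correlation"]), 0)    # constant region convention

  # two-level checkerboard pair matrix
  P <- matrix(0, 2, 2); P[1, 2] <- 0.5; P[2, 1] <- 0.5
  f2 <- glcmFeatures(P)
  expect_equal(unname(f2["Contrast"]), 1)
  expect_equal(unname(f2["Dissimilarity"]), 1)
  expect_equal(unname(f2["AutoCorrelation"]), 2)

  set.seed(8)
  for (i in 1:20) {
    M <- matrix(runif(36), 6, 6); M <- (M + t(M)); M <- M / sum(M)
    f3 <- glcmFeatures(M)
    expect_lte(f3[["Energy"]], 1)
    expect_lte(f3[["Entropy"]], log2(sum(M > 0)) + 1e-12)
  }
})

test_that("run-length features match brute-force run enumeration", {
  # single voxel: 13 runs of length 1
  q1 <- regionFromLevels(array(4L, c(1, 1, 1)), 8L)
  g <- glrlmFeatures(q1)
  expect_equal(unname(g["SRE"]), 1)
  expect_equal(unname(g["LRE"]), 1)
  expect_equal(unname(g["LGRE"]), 1 / 16)
  expect_equal(unname(g["HGRE"]), 16)
  expect_equal(unname(g["RP"]), 1)             # 13 runs / (13 * 1 voxel)

  # constant 1x1x8 bar: one along-axis run of length 8, the rest length 1
  bar <- array(2L, c(8, 1, 1))
  qb <- regionFromLevels(bar, 4L)
  expect_equal(glrlmFeatures(qb), oracleGlrlmFeatures(bar, 4L),
               tolerance = 1e-12)

  set.seed(9)
  for (i in 1:15) {
    lev <- randomRegion(c(4, 5, 4), Ng = 5L, p = 0.75)
    if (sum(!is.na(lev)) < 2) next
    q <- regionFromLevels(lev, 5L)
    got <- glrlmFeatures(q)
    expect_equal(got, oracleGlrlmFeatures(lev, 5L), tolerance = 1e-12)
    expect_lte(got[["SRE"]], 1)
    expect_gte(got[["LRE"]], 1)
  }
})

test_that("NGTDM features match a voxel-by-voxel oracle", {
  qc <- regionFromLevels(array(5L, c(3, 3, 3)), 8L)
  f <- ngtdmFeatures(qc)
  expect_equal(unname(f["ContrastNGTDM"]), 0)  # single level convention
  expect_equal(unname(f["Complexity"]), 0)
  expect_equal(unname(f["Coarseness"]), 1e6)   # capped

  set.seed(10)
  for (i in 1:15) {
    lev <- randomRegion(c(4, 4, 4), Ng = 5L, p = 0.8)
    if (sum(!is.na(lev)) < 3) next
    q <- regionFromLevels(lev, 5L)
    expect_equal(ngtdmFeatures(q), oracleNgtdmFeatures(lev, 5L),
                 tolerance = 1e-10)
  }

  iso <- array(NA_integer_, c(3, 3, 3)); iso[1, 1, 1] <- 2L; iso[3, 3, 3] <- 4L
  expect_error(ngtdmFeatures(regionFromLevels(iso, 8L)), "isolated voxels")
})

test_that("SUV and histogram features use population moments on levels", {
  pet <- volumeGrid(array(2.5, c(2, 2, 1)))
  mask <- binaryMask(array(TRUE, c(2, 2, 1)))
  q <- quantizeSUV(pet, mask, 64L, 10)
  h <- histogramSuvFeatures(pet, mask, q)
  expect_equal(unname(h["SUVmax"]), unname(h["SUVmean"]))
  expect_equal(unname(h["VarianceG"]), 0)
  expect_equal(unname(h["Skewness"]), 0)       # undefined -> 0
  expect_equal(unname(h["Kurtosis"]), 0)

  # equiprobable levels 1..4: population variance 1.25, zero skewness
  pet2 <- volumeGrid(array(c(1, 2, 3, 4) * 10 / 64, c(4, 1, 1)))
  mask2 <- binaryMask(array(TRUE, c(4, 1, 1)))
  q2 <- quantizeSUV(pet2, mask2, 64L, 10)
  expect_equal(sort(grayLevels(q2)), 1:4)
  h2 <- histogramSuvFeatures(pet2, mask2, q2)
  expect_equal(unname(h2["VarianceG"]), 1.25)
  expect_equal(unname(h2["Skewness"]), 0)
})

test_that("the assembled panel has 32 features and is scale invariant", {
  set.seed(11)
  pet <- volumeGrid(array(runif(125, 0, 8), c(5, 5, 5)))
  mask <- binaryMask(array(runif(125) < 0.8, c(5, 5, 5)))
  fv <- extractFeatures(pet, mask, Ng = 64L, cohortSuvmax = 10)
  expect_length(fv, 32L)
  expect_identical(names(fv), featurePanel()$name)
  expect_equal(sum(featurePanel()$family == "glrlm"), 13L)

  # doubling SUV and the scaling maximum together leaves texture unchanged
  pet2 <- volumeGrid(2 * voxelValues(pet))
  fv2 <- extractFeatures(pet2, mask, Ng = 64L, cohortSuvmax = 20)
  texture <- setdiff(featurePanel()$name, c("SUVmax", "SUVmean"))
  expect_equal(fv2[texture], fv[texture])
  expect_equal(unname(fv2["SUVmax"]), 2 * unname(fv["SUVmax"]))
})
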