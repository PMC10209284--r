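# Heavy fixtures built once per test run and shared across files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# one default phantom with its segmented marrow and limb-free working mask
cachedSeg <- function() {
  memo("seg", function() {
    case <- generatePhantom(seed = 101L,
                            labels = list(pet_class = "+", mfc_class = "-",
                                          biopsy_site = "S"))
    marrow <- segmentBoneMarrow(case@ct)
    list(case = case, marrow = marrow, noLimbs = removeLimbs(marrow))
  })
}

# strong-effect synthetic cohort (n = 40, default lesion model) with the
# extracted long feature table
cachedStrongCohort <- function() {
  memo("cohort40", function() {
    cases <- generateCohort(cohortSpec(n = 40L, seed = 20L))
    feats <- extractCohortFeatures(cases)
    list(cases = cases, features = feats)
  })
}

randomMask <- function(dims, p = 0.4) {
  binaryMask(array(runif(prod(dims)) < p, dims))
}

# a quantized region from a random level array (NA outside mask)
randomRegion <- function(dims, Ng = 8L, p = 0.8) {
  lev <- array(sample.int(Ng, prod(dims), replace = TRUE), dims)
  keep <- array(runif(prod(dims)) < p, dims)
  lev[!keep] <- NA_integer_
  storage.mode(lev) <- "integer"
  lev
}

regionFromLevels <- function(lev, Ng) {
  pet <- volumeGrid(array(ifelse(is.na(lev), 0, lev), dim(lev)))
  mask <- binaryMask(!is.na(lev))
  quantizeSUV(pet, mask, Ng = Ng, cohortSuvmax = Ng)
}
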