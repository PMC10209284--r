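## SUV quantization and the 32-feature radiomic panel: SUVmax/SUVmean,
## 3 histogram features on quantized levels, 9 GLCM, 13 GLRLM and 5 NGTDM
## texture features. GLCM and GLRLM accumulate the 13 unique 3D directions
## at Chebyshev distance 1 into a single merged matrix; NGTDM uses masked
## 26-neighbourhoods.

# the 13 unique 3D direction offsets (z, y, x), leading component positive
DIRECTIONS13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

# all 26 neighbour offsets
OFFSETS26 <- rbind(DIRECTIONS13, -DIRECTIONS13)

#' Names of the 32-feature radiomic panel
#'
#' @return data.frame with columns `name` and `family` ("suv", "histogram",
#'   "glcm", "glrlm", "ngtdm"), in the canonical panel order.
#' @export
featurePanel <- function() {
  data.frame(
    name = c("SUVmax", "SUVmean",
             "VarianceG", "Skewness", "Kurtosis",
             "Energy", "Contrast", "Entropy", "Homogeneity", "Correlation",
             "SumAverage", "Variance", "Dissimilarity", "AutoCorrelation",
             "SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE", "SRLGE",
             "SRHGE", "LRLGE", "LRHGE", "GLV", "RLV",
             "Coarseness", "ContrastNGTDM", "Busyness", "Complexity",
             "Strength"),
    family = rep(c("suv", "histogram", "glcm", "glrlm", "ngtdm"),
                 c(2L, 3L, 9L, 13L, 5L)),
    stringsAsFactors = FALSE)
}

#' Uniform SUV quantization
#'
#' Rescales in-mask SUV linearly between 0 and a cohort-wide SUV maximum
#' onto `Ng` gray levels: `level = round(Ng * I(x) / cohortSuvmax)`, with
#' round-half-away-from-zero, clamped below at 1 so every level lies in
#' 1..Ng.
#'
#' @param pet [VolumeGrid-class] in SUV units.
#' @param mask [BinaryMask-class] on the PET grid.
#' @param Ng number of gray levels (default 64).
#' @param cohortSuvmax SUV scaling maximum; must be at least the in-mask
#'   maximum (typically the maximum SUVmax across the study cohort).
#' @return a [QuantizedRegion-class].
#' @export
quantizeSUV <- function(pet, mask, Ng = 64L, cohortSuvmax) {
  stopIfGeometryDiffers(pet, mask, "PET volume and mask")
  if (nVoxels(mask) == 0L) stop("empty mask", call. = FALSE)
  if (Ng < 2L) stop("Ng must be >= 2", call. = FALSE)
  vals <- voxelValues(pet)
  inmax <- max(vals[mask@voxels])
  if (inmax > cohortSuvmax * (1 + 1e-12))
    stop("scaling maximum violated: in-mask SUV exceeds cohortSuvmax",
         call. = FALSE)
  bb <- maskBoundingBox(mask)
  sub <- vals[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2], bb[3, 1]:bb[3, 2],
              drop = FALSE]
  msub <- mask@voxels[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2], bb[3, 1]:bb[3, 2],
                      drop = FALSE]
  lev <- floor(Ng * sub / cohortSuvmax + 0.5)   # round half away from zero
  lev[lev < 1] <- 1
  lev[!msub] <- NA_integer_
  storage.mode(lev) <- "integer"
  new("QuantizedRegion", levels = lev, Ng = as.integer(Ng),
      cohortSuvmax = as.numeric(cohortSuvmax), spacing = spacing(pet))
}

# index ranges of the overlap when shifting an array by (dz, dy, dx);
# NULL when the shifted array does not overlap the original
shiftRanges <- function(d, off) {
  out <- vector("list", 3L)
  for (a in 1:3) {
    lo <- max(1, 1 - off[a]); hi <- min(d[a], d[a] - off[a])
    if (lo > hi) return(NULL)
    out[[a]] <- list(src = lo:hi)
  }
  out
}

#' Gray-level co-occurrence matrix of a quantized region
#'
#' Counts voxel pairs at Chebyshev distance 1 (13 unique 3D directions, both
#' voxels in-mask), symmetrized and merged into one matrix, normalized to
#' sum 1.
#'
#' @param q a [QuantizedRegion-class].
#' @return numeric `Ng x Ng` matrix summing to 1.
#' @export
glcmMatrix <- function(q) {
  lev <- q@levels
  Ng <- q@Ng
  d <- dim(lev)
  counts <- matrix(0, Ng, Ng)
  for (k in seq_len(nrow(DIRECTIONS13))) {
    off <- DIRECTIONS13[k, ]
    r <- shiftRanges(d, off)
    if (is.null(r)) next
    a <- lev[r[[1]]$src, r[[2]]$src, r[[3]]$src, drop = FALSE]
    b <- lev[r[[1]]$src + off[1], r[[2]]$src + off[2], r[[3]]$src + off[3],
             drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    code <- (a[ok] - 1L) * Ng + b[ok]
    tab <- tabulate(code, Ng * Ng)
    counts <- counts + matrix(tab, Ng, Ng, byrow = TRUE)
  }
  counts <- counts + t(counts)                  # count each pair in both orders
  total <- sum(counts)
  if (total == 0) stop("degenerate region: no co-occurring voxel pairs",
                       call. = FALSE)
  counts / total
}

#' GLCM features
#'
#' Nine features of a normalized co-occurrence matrix: Energy, Contrast,
#' Entropy (base-2, with 0 log 0 = 0), Homogeneity, Correlation (0 for a
#' constant region), SumAverage, Variance, Dissimilarity, AutoCorrelation.
#'
#' @param P normalized `Ng x Ng` co-occurrence matrix.
#' @return named numeric(9).
#' @export
glcmFeatures <- function(P) {
  Ng <- nrow(P)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  pi_ <- rowSums(P)
  mu_i <- sum(seq_len(Ng) * pi_)
  sd_i <- sqrt(sum((seq_len(Ng) - mu_i)^2 * pi_))
  # P is symmetric so row and column marginals coincide
  corr <- if (sd_i > 0) sum((i - mu_i) * (j - mu_i) * P) / (sd_i * sd_i) else 0
  mu <- sum((i + j) * P) / 2
  nz <- P > 0
  c(Energy = sum(P^2),
    Contrast = sum((i - j)^2 * P),
    Entropy = -sum(P[nz] * log2(P[nz])),
    Homogeneity = sum(P / (1 + abs(i - j))),
    Correlation = corr,
    SumAverage = mu,
    Variance = sum((i - mu)^2 * P),
    Dissimilarity = sum(abs(i - j) * P),
    AutoCorrelation = sum(i * j * P))
}

# merged run-length matrix over the 13 directions: rows = gray level,
# columns = run length
glrlmMatrix <- function(q) {
  lev <- q@levels
  d <- dim(lev)
  idx <- which(!is.na(lev), arr.ind = TRUE)
  v <- lev[!is.na(lev)]
  Lmax <- max(d)
  r <- matrix(0, q@Ng, Lmax)
  base <- max(d) + 2L
  for (k in seq_len(nrow(DIRECTIONS13))) {
    off <- DIRECTIONS13[k, ]
    lead <- which(off != 0)[1]
    t <- idx[, lead]                 # advances by 1 per step along the line
    # line id: anchor point of the line through each voxel
    lz <- idx[, 1] - t * off[1]
    ly <- idx[, 2] - t * off[2]
    lx <- idx[, 3] - t * off[3]
    line <- (lz + base) + (2 * base) * ((ly + base) + (2 * base) *
                                          (lx + base))
    ord <- order(line, t)
    lo <- line[ord]; to <- t[ord]; vo <- v[ord]
    n <- length(vo)
    newRun <- c(TRUE, lo[-1] != lo[-n] | to[-1] != to[-n] + 1 |
                  vo[-1] != vo[-n])
    starts <- which(newRun)
    lens <- diff(c(starts, n + 1L))
    key <- (lens - 1L) * q@Ng + vo[starts]
    tab <- tabulate(key, q@Ng * Lmax)
    r <- r + matrix(tab, q@Ng, Lmax)
  }
  r
}

#' GLRLM features
#'
#' Thirteen features of the merged gray-level run-length matrix: SRE, LRE,
#' GLN, RLN, RP (runs per direction-voxel, denominator `13 * Np`), LGRE,
#' HGRE, SRLGE, SRHGE, LRLGE, LRHGE, GLV, RLV (run-weighted variances of
#' level and length).
#'
#' @param q a [QuantizedRegion-class].
#' @return named numeric(13).
#' @export
glrlmFeatures <- function(q) {
  r <- glrlmMatrix(q)
  Nr <- sum(r)
  Np <- nVoxels(q)
  i <- matrix(seq_len(nrow(r)), nrow(r), ncol(r))
  l <- t(matrix(seq_len(ncol(r)), ncol(r), nrow(r)))
  mu_i <- sum(r * i) / Nr
  mu_l <- sum(r * l) / Nr
  c(SRE = sum(r / l^2) / Nr,
    LRE = sum(r * l^2) / Nr,
    GLN = sum(rowSums(r)^2) / Nr,
    RLN = sum(colSums(r)^2) / Nr,
    RP = Nr / (13 * Np),
    LGRE = sum(r / i^2) / Nr,
    HGRE = sum(r * i^2) / Nr,
    SRLGE = sum(r / (i^2 * l^2)) / Nr,
    SRHGE = sum(r * i^2 / l^2) / Nr,
    LRLGE = sum(r * l^2 / i^2) / Nr,
    LRHGE = sum(r * i^2 * l^2) / Nr,
    GLV = sum(r * (i - mu_i)^2) / Nr,
    RLV = sum(r * (l - mu_l)^2) / Nr)
}

#' NGTDM features
#'
#' Amadasun-King neighbourhood gray-tone difference features with
#' 26-neighbourhoods restricted to the mask: Coarseness (capped at 1e6),
#' Contrast, Busyness, Complexity, Strength. Voxels without any in-mask
#' neighbour are excluded; a region with only isolated voxels is an error.
#'
#' @param q a [QuantizedRegion-class].
#' @return named numeric(5).
#' @export
ngtdmFeatures <- function(q) {
  lev <- q@levels
  d <- dim(lev)
  Ng <- q@Ng
  nsum <- array(0, d)
  ncnt <- array(0L, d)
  for (k in seq_len(nrow(OFFSETS26))) {
    off <- OFFSETS26[k, ]
    r <- shiftRanges(d, off)
    if (is.null(r)) next
    nb <- lev[r[[1]]$src + off[1], r[[2]]$src + off[2], r[[3]]$src + off[3],
              drop = FALSE]
    ok <- !is.na(nb)
    nb[!ok] <- 0L
    nsum[r[[1]]$src, r[[2]]$src, r[[3]]$src] <-
      nsum[r[[1]]$src, r[[2]]$src, r[[3]]$src] + nb
    ncnt[r[[1]]$src, r[[2]]$src, r[[3]]$src] <-
      ncnt[r[[1]]$src, r[[2]]$src, r[[3]]$src] + ok
  }
  use <- !is.na(lev) & ncnt > 0L
  if (sum(use) < 2L) stop("isolated voxels only: NGTDM undefined",
                          call. = FALSE)
  vv <- lev[use]
  dev <- abs(vv - nsum[use] / ncnt[use])
  N <- sum(use)
  s <- vapply(seq_len(Ng), function(g) sum(dev[vv == g]), 0)
  n_i <- tabulate(vv, Ng)
  p <- n_i / N
  present <- p > 0
  Ngp <- sum(present)
  gi <- seq_len(Ng)

  psum <- sum(p * s)
  coarse <- if (psum < 1e-6) 1e6 else 1 / psum

  ii <- matrix(gi[present], Ngp, Ngp)
  jj <- t(ii)
  pii <- matrix(p[present], Ngp, Ngp)
  pjj <- t(pii)
  sii <- matrix(s[present], Ngp, Ngp)
  sjj <- t(sii)

  contrast <- if (Ngp > 1)
    sum(pii * pjj * (ii - jj)^2) / (Ngp * (Ngp - 1)) * sum(s) / N else 0
  busyDen <- sum(abs(ii * pii - jj * pjj))
  busy <- if (busyDen > 0) psum / busyDen else 0
  complexity <- sum(abs(ii - jj) * (pii * sii + pjj * sjj) /
                      (N * (pii + pjj)))
  strength <- sum((pii + pjj) * (ii - jj)^2) / (1e-12 + sum(s))

  c(Coarseness = coarse, ContrastNGTDM = contrast, Busyness = busy,
    Complexity = complexity, Strength = strength)
}

#' SUV and histogram features
#'
#' SUVmax and SUVmean on the raw SUV values; population variance, skewness
#' and excess kurtosis on the quantized gray levels. For a constant region
#' skewness and kurtosis are undefined and reported as 0.
#'
#' @param pet [VolumeGrid-class] in SUV units.
#' @param mask [BinaryMask-class] on the PET grid (>= 2 voxels).
#' @param q the matching [QuantizedRegion-class].
#' @return named numeric(5): SUVmax, SUVmean, VarianceG, Skewness, Kurtosis.
#' @export
histogramSuvFeatures <- function(pet, mask, q) {
  if (nVoxels(mask) < 2L) stop("need at least 2 in-mask voxels", call. = FALSE)
  suv <- voxelValues(pet)[mask@voxels]
  g <- grayLevels(q)
  m <- mean(g)
  v <- mean((g - m)^2)                           # population moments
  if (v > 0) {
    sk <- mean((g - m)^3) / v^1.5
    ku <- mean((g - m)^4) / v^2 - 3
  } else {
    sk <- 0; ku <- 0
  }
  c(SUVmax = max(suv), SUVmean = mean(suv), VarianceG = v, Skewness = sk,
    Kurtosis = ku)
}

#' Extract the full 32-feature panel for a region
#'
#' @param pet [VolumeGrid-class] in SUV units.
#' @param mask [BinaryMask-class] on the PET grid (transfer CT masks with
#'   [transferMask()] first).
#' @param Ng number of gray levels (default 64).
#' @param cohortSuvmax SUV scaling maximum shared across the cohort.
#' @return named numeric(32) in [featurePanel()] order.
#' @export
extractFeatures <- function(pet, mask, Ng = 64L, cohortSuvmax) {
  q <- quantizeSUV(pet, mask, Ng, cohortSuvmax)
  out <- c(histogramSuvFeatures(pet, mask, q)[c("SUVmax", "SUVmean",
                                                "VarianceG", "Skewness",
                                                "Kurtosis")],
           glcmFeatures(glcmMatrix(q)),
           glrlmFeatures(q),
           ngtdmFeatures(q))
  stopifnot(identical(names(out), featurePanel()$name))
  out
}
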