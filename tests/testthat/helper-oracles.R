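# Naive brute-force oracles, written with explicit loops and independent of
# the package's vectorized implementations. `lev` is always a 3D integer
# array with NA outside the mask.

.oracleDirs <- matrix(c(
  1, 0, 0,  0, 1, 0,  0, 0, 1,
  1, 1, 0,  1, -1, 0,  1, 0, 1,  1, 0, -1,
  0, 1, 1,  0, 1, -1,
  1, 1, 1,  1, 1, -1,  1, -1, 1,  1, -1, -1), ncol = 3, byrow = TRUE)

.inBounds <- function(p, d) all(p >= 1) && all(p <= d)

oracleGlcm <- function(lev, Ng) {
  d <- dim(lev)
  C <- matrix(0, Ng, Ng)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    v <- lev[z, y, x]
    if (is.na(v)) next
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      q <- c(z + dz, y + dy, x + dx)
      if (!.inBounds(q, d)) next
      w <- lev[q[1], q[2], q[3]]
      if (!is.na(w)) C[v, w] <- C[v, w] + 1
    }
  }
  if (sum(C) == 0) stop("oracle: no pairs")
  C / sum(C)
}

oracleGlcmFeatures <- function(P) {
  Ng <- nrow(P)
  en <- 0; co <- 0; ent <- 0; hom <- 0; dis <- 0; ac <- 0; sa <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    p <- P[i, j]
    en <- en + p^2
    co <- co + (i - j)^2 * p
    if (p > 0) ent <- ent - p * log2(p)
    hom <- hom + p / (1 + abs(i - j))
    dis <- dis + abs(i - j) * p
    ac <- ac + i * j * p
    sa <- sa + (i + j) * p / 2
  }
  mi <- 0; for (i in 1:Ng) mi <- mi + i * sum(P[i, ])
  mj <- 0; for (j in 1:Ng) mj <- mj + j * sum(P[, j])
  si <- 0; for (i in 1:Ng) si <- si + (i - mi)^2 * sum(P[i, ])
  sj <- 0; for (j in 1:Ng) sj <- sj + (j - mj)^2 * sum(P[, j])
  si <- sqrt(si); sj <- sqrt(sj)
  corr <- 0
  if (si > 0 && sj > 0) {
    for (i in 1:Ng) for (j in 1:Ng)
      corr <- corr + (i - mi) * (j - mj) * P[i, j]
    corr <- corr / (si * sj)
  }
  va <- 0
  for (i in 1:Ng) for (j in 1:Ng) va <- va + (i - sa)^2 * P[i, j]
  c(Energy = en, Contrast = co, Entropy = ent, Homogeneity = hom,
    Correlation = corr, SumAverage = sa, Variance = va, Dissimilarity = dis,
    AutoCorrelation = ac)
}

oracleGlrlmMatrix <- function(lev, Ng) {
  d <- dim(lev)
  r <- matrix(0, Ng, max(d))
  for (k in seq_len(nrow(.oracleDirs))) {
    dir <- .oracleDirs[k, ]
    for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
      v <- lev[z, y, x]
      if (is.na(v)) next
      prev <- c(z, y, x) - dir
      if (.inBounds(prev, d)) {
        w <- lev[prev[1], prev[2], prev[3]]
        if (!is.na(w) && w == v) next       # not a run start
      }
      len <- 1
      q <- c(z, y, x) + dir
      while (.inBounds(q, d)) {
        w <- lev[q[1], q[2], q[3]]
        if (is.na(w) || w != v) break
        len <- len + 1
        q <- q + dir
      }
      r[v, len] <- r[v, len] + 1
    }
  }
  r
}

oracleGlrlmFeatures <- function(lev, Ng) {
  r <- oracleGlrlmMatrix(lev, Ng)
  Nr <- sum(r)
  Np <- sum(!is.na(lev))
  out <- c(SRE = 0, LRE = 0, GLN = 0, RLN = 0, RP = Nr / (13 * Np), LGRE = 0,
           HGRE = 0, SRLGE = 0, SRHGE = 0, LRLGE = 0, LRHGE = 0, GLV = 0,
           RLV = 0)
  mi <- 0; ml <- 0
  for (i in seq_len(nrow(r))) for (l in seq_len(ncol(r))) {
    mi <- mi + r[i, l] * i / Nr
    ml <- ml + r[i, l] * l / Nr
  }
  for (i in seq_len(nrow(r))) for (l in seq_len(ncol(r))) {
    v <- r[i, l]
    if (v == 0) next
    out["SRE"] <- out["SRE"] + v / l^2 / Nr
    out["LRE"] <- out["LRE"] + v * l^2 / Nr
    out["LGRE"] <- out["LGRE"] + v / i^2 / Nr
    out["HGRE"] <- out["HGRE"] + v * i^2 / Nr
    out["SRLGE"] <- out["SRLGE"] + v / (i^2 * l^2) / Nr
    out["SRHGE"] <- out["SRHGE"] + v * i^2 / l^2 / Nr
    out["LRLGE"] <- out["LRLGE"] + v * l^2 / i^2 / Nr
    out["LRHGE"] <- out["LRHGE"] + v * i^2 * l^2 / Nr
    out["GLV"] <- out["GLV"] + v * (i - mi)^2 / Nr
    out["RLV"] <- out["RLV"] + v * (l - ml)^2 / Nr
  }
  for (i in seq_len(nrow(r))) out["GLN"] <- out["GLN"] + sum(r[i, ])^2 / Nr
  for (l in seq_len(ncol(r))) out["RLN"] <- out["RLN"] + sum(r[, l])^2 / Nr
  out
}

oracleNgtdmFeatures <- function(lev, Ng) {
  d <- dim(lev)
  s <- numeric(Ng); n <- integer(Ng); N <- 0
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    v <- lev[z, y, x]
    if (is.na(v)) next
    nb <- c()
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      q <- c(z + dz, y + dy, x + dx)
      if (!.inBounds(q, d)) next
      w <- lev[q[1], q[2], q[3]]
      if (!is.na(w)) nb <- c(nb, w)
    }
    if (length(nb) == 0) next
    N <- N + 1
    n[v] <- n[v] + 1L
    s[v] <- s[v] + abs(v - mean(nb))
  }
  p <- n / N
  pres <- which(p > 0)
  Ngp <- length(pres)
  psum <- sum(p * s)
  coarse <- if (psum < 1e-6) 1e6 else 1 / psum
  contrast <- 0; busyDen <- 0; complexity <- 0; strengthNum <- 0
  for (i in pres) for (j in pres) {
    contrast <- contrast + p[i] * p[j] * (i - j)^2
    busyDen <- busyDen + abs(i * p[i] - j * p[j])
    complexity <- complexity + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) /
      (N * (p[i] + p[j]))
    strengthNum <- strengthNum + (p[i] + p[j]) * (i - j)^2
  }
  contrast <- if (Ngp > 1) contrast / (Ngp * (Ngp - 1)) * sum(s) / N else 0
  busy <- if (busyDen > 0) psum / busyDen else 0
  strength <- strengthNum / (1e-12 + sum(s))
  c(Coarseness = coarse, ContrastNGTDM = contrast, Busyness = busy,
    Complexity = complexity, Strength = strength)
}

oracleHistogram <- function(lev) {
  g <- lev[!is.na(lev)]
  m <- sum(g) / length(g)
  v <- sum((g - m)^2) / length(g)
  if (v > 0)
    c(VarianceG = v, Skewness = sum((g - m)^3) / length(g) / v^1.5,
      Kurtosis = sum((g - m)^4) / length(g) / v^2 - 3)
  else c(VarianceG = 0, Skewness = 0, Kurtosis = 0)
}

# the 27 texture features (histogram on levels + GLCM + GLRLM + NGTDM)
oracleTextureFeatures <- function(lev, Ng) {
  c(oracleHistogram(lev),
    oracleGlcmFeatures(oracleGlcm(lev, Ng)),
    oracleGlrlmFeatures(lev, Ng),
    oracleNgtdmFeatures(lev, Ng))
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracleMannWhitneyExact <- function(x, y) {
  all <- c(x, y)
  m <- length(x)
  ustat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  mu <- m * length(y) / 2
  obs <- abs(ustat(x, y) - mu)
  combs <- utils::combn(length(all), m)
  us <- apply(combs, 2, function(ix) ustat(all[ix], all[-ix]))
  mean(abs(us - mu) >= obs - 1e-12)
}
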