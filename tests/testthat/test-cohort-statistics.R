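test_that("Mann-Whitney matches exact enumeration and the normal approximation", {
  r <- mannWhitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3)                     # 2/6 arrangements as extreme
  expect_equal(r$p, oracleMannWhitneyExact(c(1, 2), c(3, 4)))

  # identical multisets: U = mn/2
  x <- c(1, 3, 5)
  expect_equal(mannWhitney(x, x)$U, 4.5)

  # exact branch agrees with enumeration on random small samples
  set.seed(21)
  for (i in 1:20) {
    x <- round(rnorm(sample(2:5, 1)), 6)
    y <- round(rnorm(sample(2:5, 1)) + 0.5, 6)
    expect_equal(mannWhitney(x, y)$p, oracleMannWhitneyExact(x, y),
                 tolerance = 1e-10)
  }

  # large samples: tie- and continuity-corrected normal formula, by hand
  set.seed(22)
  x <- round(rnorm(20), 1); y <- round(rnorm(25, 0.3), 1)
  r2 <- mannWhitney(x, y)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  rk <- rank(c(x, y))
  U <- sum(rk[1:n1]) - n1 * (n1 + 1) / 2
  tie <- table(c(x, y))
  s2 <- n1 * n2 / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
  z <- (abs(U - n1 * n2 / 2) - 0.5) / sqrt(s2)
  expect_equal(r2$U, U)
  expect_equal(r2$p, 2 * stats::pnorm(-z), tolerance = 1e-10)

  # degenerate: every value identical
  expect_equal(mannWhitney(rep(2, 4), rep(2, 6))$p, 1)
})

test_that("Spearman correlation is tie-aware with a t-approximate p-value", {
  expect_equal(spearmanRank(1:8, (1:8)^2)$rho, 1)
  expect_equal(spearmanRank(1:8, rev(1:8))$rho, -1)

  # binary against continuous, n = 6: Pearson on mid-ranks by hand
  x <- c(0, 0, 0, 1, 1, 1)
  y <- c(2.1, 1.3, 3.2, 4.8, 2.9, 5.0)
  r <- spearmanRank(y, x)
  rho <- stats::cor(rank(y), rank(x))
  expect_equal(r$rho, rho, tolerance = 1e-12)
  tstat <- rho * sqrt(4 / (1 - rho^2))
  expect_equal(r$p, 2 * stats::pt(-abs(tstat), 4), tolerance = 1e-10)

  expect_warning(r0 <- spearmanRank(rep(1, 5), 1:5), "zero rank variance")
  expect_true(is.na(r0$rho))
})

test_that("Benjamini-Hochberg is the step-up procedure", {
  expect_equal(benjaminiHochberg(rep(0.05, 8)), rep(0.05, 8))
  expect_equal(benjaminiHochberg(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  set.seed(23)
  p <- runif(50)
  q <- benjaminiHochberg(p)
  expect_true(all(q >= p - 1e-12))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("group screening returns one calibrated row per feature", {
  co <- cachedStrongCohort()
  biopsy <- co$features[co$features$mask_kind == "biopsy", ]
  res <- compareGroups(biopsy, "PET")
  expect_equal(nrow(res), 32L)
  expect_true(all(res$bh_q >= res$mannwhitney_p - 1e-12))

  # heterogeneity features separate the classes with a positive correlation
  ent <- res[res$feature == "Entropy", ]
  expect_lt(ent$mannwhitney_p, 0.05)
  expect_gt(ent$spearman_rho, 0)

  # constant features are uninformative: p = 1
  flat <- biopsy
  for (f in featurePanel()$name) flat[[f]] <- 1
  resFlat <- compareGroups(flat, "PET")
  expect_true(all(resFlat$mannwhitney_p == 1))

  one <- biopsy; one$pet_class <- "+"
  expect_error(compareGroups(one, "PET"), "non-empty")
})

test_that("whole-vs-biopsy correlation behaves at the null and under signal", {
  co <- cachedStrongCohort()
  # copying whole-marrow rows as biopsy rows gives rho = 1 everywhere
  w <- co$features[co$features$mask_kind == "whole_marrow", ]
  fake <- rbind(w, transform(w, mask_kind = "biopsy"))
  resCopy <- wholeVsBiopsyCorrelation(fake)
  expect_true(all(abs(resCopy$spearman_rho - 1) < 1e-12))

  # shared lesion burden links the two masks in the synthetic cohort
  res <- wholeVsBiopsyCorrelation(co$features)
  expect_gt(stats::median(res$spearman_rho, na.rm = TRUE), 0.5)

  # independent features at n = 39: |rho| < 0.32 for about 95% of pairs
  set.seed(24)
  rhos <- replicate(400, stats::cor(rank(rnorm(39)), rank(rnorm(39))))
  expect_gt(mean(abs(rhos) < 0.32), 0.90)

  expect_error(wholeVsBiopsyCorrelation(w), "both mask kinds")
})
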