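## Group-difference and correlation screening of the feature table:
## Mann-Whitney U per feature between PET+/- (or MFC+/-) groups, Spearman
## rank correlation against the 0/1 class coding, Benjamini-Hochberg
## correction, and whole-marrow vs biopsy-site correlation.

#' Mann-Whitney U test
#'
#' Two-sided. Exact p by enumeration when both samples together hold at most
#' 12 observations with no ties; otherwise the normal approximation with tie
#' and continuity corrections. If every value in both groups is identical
#' the test is degenerate and p = 1.
#'
#' @param x,y numeric samples for the two groups.
#' @return list with elements `U` (the statistic for `x`) and `p`.
#' @export
mannWhitney <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L)
    stop("both groups must be non-empty", call. = FALSE)
  if (length(unique(c(x, y))) == 1L)
    return(list(U = length(x) * length(y) / 2, p = 1))
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 12L && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (tie-aware), with a two-sided p-value
#' from the t approximation on n - 2 degrees of freedom. When either
#' variable has zero rank variance the coefficient is undefined and NA is
#' returned with a warning.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return list with elements `rho` and `p`.
#' @export
spearmanRank <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need paired samples with n >= 3", call. = FALSE)
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    warning("zero rank variance: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ht$estimate), p = ht$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate control: in ascending order
#' `q_(i) = min_(j>=i) m p_(j) / j`, capped at 1, reported in input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values.
#' @export
benjaminiHochberg <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

featureColumns <- function(df) {
  nm <- featurePanel()$name
  missing <- setdiff(nm, colnames(df))
  if (length(missing))
    stop("feature table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  nm
}

#' Feature screening between the two classes of a grouping
#'
#' For each of the 32 features: Mann-Whitney p between the groups, Spearman
#' rho and p against the class coded 0/1 (negative class = 0, so a positive
#' rho means larger values in PET+/MFC+ cases), and Benjamini-Hochberg
#' q-values over the feature family.
#'
#' @param features data.frame with one row per case, the 32 feature columns
#'   and a `pet_class` / `mfc_class` column ("+"/"-").
#' @param grouping "PET" or "MFC".
#' @param alpha significance level for the marker columns (default 0.05).
#' @param bh_family "features" (default; the 32 tests of this analysis) or
#'   "none" to leave q-values for a cross-analysis correction via
#'   [benjaminiHochberg()] on the pooled p-values.
#' @return data.frame with columns feature, mannwhitney_p, spearman_rho,
#'   spearman_p, bh_q, significant_raw, significant_bh.
#' @export
compareGroups <- function(features, grouping = c("PET", "MFC"), alpha = 0.05,
                          bh_family = c("features", "none")) {
  grouping <- match.arg(grouping)
  bh_family <- match.arg(bh_family)
  cls <- features[[if (grouping == "PET") "pet_class" else "mfc_class"]]
  if (is.null(cls)) stop("missing class column for grouping ", grouping,
                         call. = FALSE)
  pos <- cls == "+"
  if (!any(pos) || all(pos))
    stop("both groups must be non-empty", call. = FALSE)
  nm <- featureColumns(features)
  rows <- lapply(nm, function(f) {
    v <- features[[f]]
    mw <- mannWhitney(v[pos], v[!pos])
    sp <- suppressWarnings(spearmanRank(v, as.numeric(pos)))
    data.frame(feature = f, mannwhitney_p = mw$p, spearman_rho = sp$rho,
               spearman_p = sp$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bh_q <- if (bh_family == "features") benjaminiHochberg(out$mannwhitney_p)
              else NA_real_
  out$significant_raw <- out$mannwhitney_p < alpha
  out$significant_bh <- !is.na(out$bh_q) & out$bh_q < alpha
  out
}

#' Correlation between whole-marrow and biopsy-site features
#'
#' Per-feature Spearman correlation between the whole-bone-marrow value and
#' the biopsy-site value across cases.
#'
#' @param features data.frame in long mask-kind format: columns `case_id`,
#'   `mask_kind` ("biopsy" or "whole_marrow") and the 32 features.
#' @return data.frame with columns feature, spearman_rho, spearman_p.
#' @export
wholeVsBiopsyCorrelation <- function(features) {
  if (!all(c("biopsy", "whole_marrow") %in% features$mask_kind))
    stop("feature table must contain both mask kinds", call. = FALSE)
  b <- features[features$mask_kind == "biopsy", ]
  w <- features[features$mask_kind == "whole_marrow", ]
  common <- intersect(b$case_id, w$case_id)
  b <- b[match(common, b$case_id), ]
  w <- w[match(common, w$case_id), ]
  nm <- featureColumns(features)
  rows <- lapply(nm, function(f) {
    sp <- suppressWarnings(spearmanRank(w[[f]], b[[f]]))
    data.frame(feature = f, spearman_rho = sp$rho, spearman_p = sp$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
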