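## End-to-end pipeline: phantom cohort -> marrow and biopsy-site masks ->
## two-pass feature extraction (cohort SUV scaling maximum first, features
## second) -> screening statistics -> oversampling and the classifier suite,
## with CSV/JSON artifacts and a reproducibility manifest.

#' Default pipeline configuration
#'
#' Sections mirror the pipeline stages; every stage reads only its own
#' section plus the global seed. The configuration round-trips through YAML
#' unchanged.
#'
#' @param seed global RNG seed.
#' @param outdir output directory.
#' @param n cohort size.
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function(seed = 1L, outdir = "bmradiomics_run",
                                  n = 39L) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    phantom = list(n = as.integer(n), pet_neg_prop = 31 / 39,
                   mfc_neg_prop = 24 / 39, discordant_pet_neg_mfc_pos = "auto",
                   vary_anatomy = FALSE, full_size = FALSE,
                   save_volumes = FALSE),
    marrow = list(bone_hu_threshold = 150, compact_bone_hu_threshold = 300,
                  closing_radius_mm = 4, min_component_voxels = 200L),
    biopsy = list(cube_edge = "auto", save_masks = TRUE),
    features = list(Ng = 64L, cohort_suvmax = "cohort_max"),
    stats = list(alpha = 0.05, bh_family = "features"),
    ml = list(folds = 5L, smote_k = 5L, smote_mode = "pre_cv"))
}

requiredSections <- c("phantom", "marrow", "biopsy", "features", "stats", "ml")

validatePipelineConfig <- function(config) {
  for (s in c("seed", "outdir", requiredSections))
    if (is.null(config[[s]]))
      stop("pipeline configuration is missing the [", s, "] section",
           call. = FALSE)
  invisible(TRUE)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config configuration list.
#' @return the configuration list (read) or the path, invisibly (write).
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validatePipelineConfig(cfg)
  cfg
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15L)
  invisible(path)
}

configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              pretty = FALSE), tmp)
  unname(tools::md5sum(tmp))
}

# segment one case: whole marrow and the labelled biopsy site, on CT and PET
segmentCase <- function(case, marrowParams, cubeEdge = NULL) {
  marrow <- segmentBoneMarrow(case@ct, marrowParams)
  site <- selectBiopsyMask(marrow, case@labels$biopsy_site,
                           cubeEdge = cubeEdge)
  list(marrow = marrow, site = site,
       marrowPET = transferMask(marrow, case@pet),
       sitePET = transferMask(site, case@pet))
}

#' Extract the feature table of a cohort
#'
#' Two passes: the cohort SUV scaling maximum (the largest SUVmax over all
#' masks in the cohort) is measured first, then the 32-feature panel is
#' extracted for the biopsy-site and whole-marrow masks of every case.
#'
#' @param cases list of [PhantomCase-class] from [generateCohort()].
#' @param segmented optional precomputed list from the internal per-case
#'   segmentation (used by [runPipeline()]); when NULL each case is
#'   segmented here.
#' @param Ng gray levels for quantization.
#' @param cohortSuvmax numeric to override the measured cohort maximum.
#' @param marrowParams a `MarrowSegParams` list.
#' @return data.frame in long mask-kind format: case_id, mask_kind
#'   ("biopsy"/"whole_marrow"), pet_class, mfc_class, biopsy_site and the
#'   32 feature columns; the scaling maximum is in attribute
#'   `cohort_suvmax`.
#' @export
extractCohortFeatures <- function(cases, segmented = NULL, Ng = 64L,
                                  cohortSuvmax = NULL,
                                  marrowParams = marrowSegParams()) {
  if (is.null(segmented))
    segmented <- lapply(cases, segmentCase, marrowParams = marrowParams)
  suvmaxes <- vapply(seq_along(cases), function(i) {
    v <- voxelValues(cases[[i]]@pet)
    max(v[segmented[[i]]$marrowPET@voxels])
  }, 0)
  smax <- if (is.null(cohortSuvmax)) max(suvmaxes) else cohortSuvmax
  rows <- lapply(seq_along(cases), function(i) {
    case <- cases[[i]]
    seg <- segmented[[i]]
    fb <- extractFeatures(case@pet, seg$sitePET, Ng, smax)
    fw <- extractFeatures(case@pet, seg$marrowPET, Ng, smax)
    meta <- data.frame(case_id = case@labels$case_id,
                       pet_class = case@labels$pet_class,
                       mfc_class = case@labels$mfc_class,
                       biopsy_site = case@labels$biopsy_site,
                       stringsAsFactors = FALSE)
    rbind(cbind(meta, mask_kind = "biopsy", as.data.frame(t(fb))),
          cbind(meta, mask_kind = "whole_marrow", as.data.frame(t(fw))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cohort_suvmax") <- smax
  out
}

# oversampled copy of a biopsy-feature table for one grouping
oversampleFeatures <- function(biopsy, grouping, k, seed) {
  nm <- featurePanel()$name
  cls <- biopsy[[if (grouping == "PET") "pet_class" else "mfc_class"]]
  sm <- safeLevelSmote(as.matrix(biopsy[, nm]), cls, k = k, seed = seed)
  out <- as.data.frame(sm$X)
  out$pet_class <- if (grouping == "PET") as.character(sm$y) else NA
  out$mfc_class <- if (grouping == "MFC") as.character(sm$y) else NA
  out
}

#' Run the whole pipeline
#'
#' Generates (or accepts) a synthetic cohort, segments every case, extracts
#' the feature table, runs the screening statistics for both groupings on
#' the original and oversampled data, runs the classifier suite, and writes
#' all artifacts plus a JSON manifest to the output directory. Deterministic
#' for a fixed configuration.
#'
#' @param config configuration list (see [defaultPipelineConfig()]) or the
#'   path to a YAML file.
#' @param cases optional pre-generated cohort (otherwise generated from the
#'   `[phantom]` section).
#' @return invisible list with the feature table, stats tables, ML reports
#'   and the manifest.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), cases = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  validatePipelineConfig(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  ph <- config$phantom
  pspec <- phantomSpec(fullSize = isTRUE(ph$full_size))
  if (is.null(cases)) {
    disc <- ph$discordant_pet_neg_mfc_pos
    if (identical(disc, "auto")) disc <- NULL
    cspec <- cohortSpec(n = ph$n, pet_neg_prop = ph$pet_neg_prop,
                        mfc_neg_prop = ph$mfc_neg_prop,
                        discordant_pet_neg_mfc_pos = disc,
                        vary_anatomy = isTRUE(ph$vary_anatomy), seed = seed)
    cases <- generateCohort(cspec, pspec)
  }
  labels <- attr(cases, "labels")
  if (!is.null(labels))
    utils::write.csv(labels, file.path(outdir, "cohort.csv"),
                     row.names = FALSE)

  mp <- config$marrow
  marrowParams <- marrowSegParams(mp$bone_hu_threshold,
                                  mp$compact_bone_hu_threshold,
                                  mp$closing_radius_mm,
                                  mp$min_component_voxels)
  cubeEdge <- if (identical(config$biopsy$cube_edge, "auto")) NULL
              else config$biopsy$cube_edge
  segmented <- lapply(cases, segmentCase, marrowParams = marrowParams,
                      cubeEdge = cubeEdge)
  if (isTRUE(config$biopsy$save_masks))
    for (i in seq_along(cases)) {
      id <- cases[[i]]@labels$case_id
      writeMask(segmented[[i]]$marrow,
                file.path(outdir, paste0(id, "_marrow.nii.gz")))
      writeMask(segmented[[i]]$site,
                file.path(outdir, paste0(id, "_biopsy.nii.gz")))
    }
  if (isTRUE(ph$save_volumes)) writeCohort(cases, outdir, masks = FALSE)

  fs <- config$features
  smax <- if (identical(fs$cohort_suvmax, "cohort_max")) NULL
          else fs$cohort_suvmax
  features <- extractCohortFeatures(cases, segmented, Ng = fs$Ng,
                                    cohortSuvmax = smax)
  utils::write.csv(features, file.path(outdir, "features.csv"),
                   row.names = FALSE)

  biopsy <- features[features$mask_kind == "biopsy", ]
  alpha <- config$stats$alpha
  stats_ <- list()
  mlrep <- list()
  folds <- config$ml$folds
  nm <- featurePanel()$name
  for (grouping in c("PET", "MFC")) {
    stats_[[paste0(tolower(grouping), "_original")]] <-
      compareGroups(biopsy, grouping, alpha = alpha)
    over <- oversampleFeatures(biopsy, grouping, config$ml$smote_k,
                               seed + match(grouping, c("PET", "MFC")))
    stats_[[paste0(tolower(grouping), "_oversampled")]] <-
      compareGroups(over, grouping, alpha = alpha)
    cls <- biopsy[[if (grouping == "PET") "pet_class" else "mfc_class"]]
    if (min(table(cls)) >= folds)
      mlrep[[paste0(tolower(grouping), "_original")]] <-
        runModelSuite(as.matrix(biopsy[, nm]), cls, folds = folds,
                      seed = seed)
    if (identical(config$ml$smote_mode, "within_folds")) {
      if (min(table(cls)) >= folds)
        mlrep[[paste0(tolower(grouping), "_smote_within_folds")]] <-
          runModelSuite(as.matrix(biopsy[, nm]), cls, folds = folds,
                        seed = seed, smote = TRUE,
                        smote_k = config$ml$smote_k)
    } else {
      ocls <- over[[if (grouping == "PET") "pet_class" else "mfc_class"]]
      if (min(table(ocls)) >= folds)
        mlrep[[paste0(tolower(grouping), "_oversampled")]] <-
          runModelSuite(as.matrix(over[, nm]), ocls, folds = folds,
                        seed = seed)
    }
  }
  wb <- wholeVsBiopsyCorrelation(features)

  for (nmv in names(stats_))
    utils::write.csv(stats_[[nmv]],
                     file.path(outdir, paste0("stats_", nmv, ".csv")),
                     row.names = FALSE)
  for (nmv in names(mlrep))
    utils::write.csv(mlrep[[nmv]],
                     file.path(outdir, paste0("ml_", nmv, ".csv")),
                     row.names = FALSE)
  utils::write.csv(wb, file.path(outdir, "whole_vs_biopsy.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "bmradiomics",
    version = as.character(utils::packageVersion("bmradiomics")),
    seed = seed,
    n_cases = length(cases),
    cohort_suvmax = attr(features, "cohort_suvmax"),
    config_hash = configHash(config))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(features = features, stats = stats_, ml = mlrep,
                 whole_vs_biopsy = wb, manifest = manifest,
                 segmented = segmented, cases = cases))
}
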