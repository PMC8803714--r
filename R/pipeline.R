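# End-to-end orchestration: reference -> suppression -> detection ->
# fast-marching pre-segmentation -> quantification -> filtering, plus the
# packaged synthetic-study experiments.

#' Pipeline configuration
#'
#' Bundles the per-module settings plus matching options and a seed. Unknown
#' fields are rejected so that serialized configurations cannot silently
#' drift.
#'
#' @param reference [reference_config()].
#' @param detection [detection_config()].
#' @param fastmarch [fastmarch_config()].
#' @param matching list with `max_dist_mm` for [match_lesions()].
#' @param seed integer seed recorded with every output.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(reference = reference_config(),
                            detection = detection_config(),
                            fastmarch = fastmarch_config(),
                            matching = list(max_dist_mm = 10),
                            seed = 1L) {
  stopifnot(inherits(reference, "reference_config"),
            inherits(detection, "detection_config"),
            inherits(fastmarch, "fastmarch_config"))
  extra <- setdiff(names(matching), "max_dist_mm")
  if (length(extra) > 0)
    stop("unknown matching option(s): ", paste(extra, collapse = ", "))
  structure(list(reference = reference, detection = detection,
                 fastmarch = fastmarch, matching = matching,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# 32-bit FNV-1a over the serialized config; recorded in every output
config_hash <- function(config) {
  s <- jsonlite::serializeJSON(unclass(config), digits = 10)
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^31 * (h >= 2^31)), b)
    h <- (as.numeric(h) %% 2^32 + 2^32) %% 2^32
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", h)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

mask_centroid_mm <- function(idx, dims, spacing) {
  ijk <- arrayInd(idx, dims)
  (colMeans(ijk) - 0.5) * spacing
}

#' Run the full analysis pipeline
#'
#' Reference quantification, physiological-uptake suppression, per-
#' compartment blob detection, fast-marching pre-segmentation of each
#' candidate (in descending response order; a candidate whose seed already
#' lies in an accepted segment is folded into it as a duplicate),
#' quantification, and rule-based filtering. Deterministic for a fixed
#' input and configuration; every record carries its provenance and the
#' configuration hash.
#'
#' @param pet SUV `voxel_grid` or path to a NIfTI file.
#' @param labels label `voxel_grid` or path.
#' @param config [pipeline_config()].
#' @param out_dir optional directory for `references.json` and
#'   `lesions.json`.
#' @return object of class `psma_analysis`: `references`
#'   (`reference_values`), `records` (all segmented candidates with
#'   `kept`/`reject_reason`), `lesions` (kept records), `candidates`
#'   (raw detection table), `config_hash`, `config`.
#' @export
analyze <- function(pet, labels, config = pipeline_config(), out_dir = NULL) {
  if (is.character(pet)) pet <- run_stage("grid_io", read_volume(pet, "suv"))
  if (is.character(labels))
    labels <- run_stage("grid_io", read_volume(labels, "label"))
  run_stage("grid_io", stopifnot(same_frame(pet, labels)))

  refs <- run_stage("reference",
                    reference_values(pet, labels, config$reference))
  bp <- refs$blood_pool

  supp <- run_stage("detection",
                    fit_suppression(pet, labels, config$detection))
  cands <- run_stage("detection",
                     detect_lesions(pet, labels, config$detection,
                                    blood_pool = bp, suppression = supp))
  cands <- cands[order(-cands$response, cands$i, cands$j, cands$k), ,
                 drop = FALSE]

  dims <- dim(pet$data)
  accepted <- array(FALSE, dims)
  records <- list()
  for (r in seq_len(nrow(cands))) {
    cand <- as.list(cands[r, ])
    if (accepted[cand$i, cand$j, cand$k]) {
      records[[length(records) + 1]] <-
        list(candidate = cand, duplicate = TRUE, kept = FALSE,
             reject_reason = "duplicate")
      next
    }
    seg <- run_stage("segmentation", tryCatch(
      fast_march_segment(pet, data.frame(cand), config$fastmarch,
                         blood_pool = bp),
      error = function(e) e))
    if (inherits(seg, "error")) {
      records[[length(records) + 1]] <-
        list(candidate = cand, duplicate = FALSE, kept = FALSE,
             reject_reason = paste0("segmentation: ", conditionMessage(seg)))
      next
    }
    q <- run_stage("segmentation", quantify(pet, seg))
    idx <- which(mask_array(seg))
    accepted[idx] <- TRUE  # later, lower-response seeds inside are duplicates
    rec <- c(list(candidate = cand, duplicate = FALSE, mask_idx = idx,
                  centroid_mm = mask_centroid_mm(idx, dims, pet$spacing),
                  spacing = pet$spacing), q)
    records[[length(records) + 1]] <- rec
  }

  segged <- vapply(records, function(x) !is.null(x$mask_idx), TRUE)
  records[segged] <- run_stage("filter",
    filter_candidates(records[segged], labels,
                      config$detection$rules, blood_pool = bp))
  records_kept <- vapply(records, `[[`, TRUE, "kept")

  out <- structure(list(references = refs, records = records,
                        lesions = records[records_kept],
                        candidates = cands,
                        config_hash = config_hash(config),
                        config = config),
                   class = "psma_analysis")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(blood_pool = refs$blood_pool, liver = refs$liver,
           n_voxels = as.list(refs$n_voxels), gmm = refs$gmm,
           flags = refs$flags, config_hash = out$config_hash),
      file.path(out_dir, "references.json"),
      auto_unbox = TRUE, digits = 10, null = "null")
    jsonlite::write_json(
      lapply(out$records, record_to_json),
      file.path(out_dir, "lesions.json"),
      auto_unbox = TRUE, digits = 10, null = "null")
  }
  out
}

record_to_json <- function(rec) {
  base <- list(candidate = rec$candidate, kept = rec$kept,
               reject_reason = rec$reject_reason %||% NA)
  if (!is.null(rec$mask_idx))
    base <- c(base, list(centroid_mm = rec$centroid_mm,
                         suv_max = rec$suv_max, suv_peak = rec$suv_peak,
                         suv_mean = rec$suv_mean, volume_ml = rec$volume_ml,
                         n_voxels = rec$n_voxels, flags = rec$flags))
  base
}

#' @export
print.psma_analysis <- function(x, ...) {
  cat(sprintf(paste0("<psma_analysis  blood pool %.3f  liver %.3f  ",
                     "%d candidates -> %d lesions  config %s>\n"),
              x$references$blood_pool, x$references$liver,
              nrow(x$candidates), length(x$lesions), x$config_hash))
  invisible(x)
}

#' Kept-lesion table of an analysis
#' @param analysis a `psma_analysis`.
#' @return data.frame, one row per kept lesion.
#' @export
lesions_table <- function(analysis) {
  if (length(analysis$lesions) == 0)
    return(data.frame(compartment = character(), suv_max = numeric(),
                      suv_peak = numeric(), suv_mean = numeric(),
                      volume_ml = numeric()))
  do.call(rbind, lapply(analysis$lesions, function(rec)
    data.frame(compartment = rec$candidate$compartment,
               x_mm = rec$centroid_mm[1], y_mm = rec$centroid_mm[2],
               z_mm = rec$centroid_mm[3], suv_max = rec$suv_max,
               suv_peak = rec$suv_peak, suv_mean = rec$suv_mean,
               volume_ml = rec$volume_ml, response = rec$candidate$response,
               stringsAsFactors = FALSE)))
}

#' Write kept lesion masks as one labeled NIfTI volume (lesion i = id i)
#' @param analysis a `psma_analysis`.
#' @param template `voxel_grid` supplying geometry.
#' @param path output NIfTI path.
#' @export
write_lesion_masks <- function(analysis, template, path) {
  lab <- array(0L, dim(template$data))
  for (i in seq_along(analysis$lesions))
    lab[analysis$lesions[[i]]$mask_idx] <- i
  write_volume(voxel_grid(lab, template$spacing, template$affine,
                          kind = "label"), path)
}

# ---- packaged experiments ---------------------------------------------------

# records for threshold-detector components so match_lesions can score them
threshold_records <- function(suv, mask, thr) {
  cands <- threshold_detect(suv, mask, thr)
  arr <- mask_array(mask) & suv$data >= thr
  lab <- label_components(arr)
  dims <- dim(suv$data)
  lapply(seq_len(nrow(cands)), function(r) {
    cand <- as.list(cands[r, ])
    comp_id <- lab[cand$i, cand$j, cand$k]
    idx <- which(lab == comp_id)
    list(candidate = cand, mask_idx = idx, spacing = suv$spacing,
         centroid_mm = mask_centroid_mm(idx, dims, suv$spacing))
  })
}

lesion_search_mask <- function(suv, labels, cfg, blood_pool) {
  comp <- label_components(suv$data >
                             cfg$rules$body_threshold_frac * blood_pool)
  body <- comp == which.max(tabulate(comp[comp > 0]))
  arr <- (body & labels$data == 0L) |
    array(labels$data %in% c(ALL_BONE_IDS, 7L), dim(labels$data))
  binary_mask(arr, "lesion_search", suv)
}

#' Run a packaged synthetic-study experiment
#'
#' Mirrors the three study designs on synthetic data:
#' \describe{
#'   \item{`reference_sd`}{n lesion-free phantoms; automated blood-pool and
#'     liver references versus three emulated manual readers placing
#'     jittered fixed spheres (1 cm in the thoracic aorta, 3 cm in the
#'     liver); reports the across-patient SD per method.}
#'   \item{`detection_sensitivity`}{n phantoms with lesions; full pipeline;
#'     matched sensitivity with Wilson CI and false positives per patient.}
#'   \item{`threshold_comparison`}{same pipeline plus fixed-threshold
#'     baseline detectors at SUV 4.3 and SUV 3.0; reports all
#'     sensitivities.}
#'   \item{`reproducibility`}{n phantoms analyzed twice; ICC(2,1) of
#'     SUVmax/SUVpeak/SUVmean across the two runs over all kept lesions.}
#' }
#'
#' @param name experiment name.
#' @param n number of synthetic patients.
#' @param seed integer seed; results are reproducible from it.
#' @param config [pipeline_config()].
#' @param variability [suite_variability()].
#' @return list with an `agreement_report` under `$report` plus
#'   experiment-specific detail fields.
#' @export
run_experiment <- function(name = c("reference_sd", "detection_sensitivity",
                                    "threshold_comparison",
                                    "reproducibility"),
                           n = 20, seed = 1L,
                           config = pipeline_config(),
                           variability = suite_variability()) {
  name <- match.arg(name)
  switch(name,
         reference_sd = experiment_reference_sd(n, seed, config, variability),
         detection_sensitivity =
           experiment_detection(n, seed, config, variability, thresholds = NULL),
         threshold_comparison =
           experiment_detection(n, seed, config, variability,
                                thresholds = c(4.3, 3.0)),
         reproducibility = experiment_reproducibility(n, seed, config,
                                                      variability))
}

experiment_reference_sd <- function(n, seed, config, variability) {
  specs <- phantom_suite(n, variability, seed = seed, lesions = FALSE)
  set.seed(seed + 1L)
  methods <- c("automated", paste0("reader_", 1:3))
  bp <- matrix(NA_real_, n, 4, dimnames = list(NULL, methods))
  lv <- matrix(NA_real_, n, 4, dimnames = list(NULL, methods))
  truth_bp <- truth_lv <- numeric(n)
  for (p in seq_len(n)) {
    ph <- make_phantom(specs[[p]])
    refs <- reference_values(ph$suv, ph$labels, config$reference)
    bp[p, 1] <- refs$blood_pool
    lv[p, 1] <- refs$liver
    truth_bp[p] <- specs[[p]]$organs[[2]]$suv
    truth_lv[p] <- specs[[p]]$organs[[1]]$suv
    for (rd in 1:3) {
      # manual emulation: fixed sphere with reader placement jitter
      bp[p, 1 + rd] <- sphere_roi_reference(
        ph$suv, c(192, 208, runif(1, 270, 340)) + c(rnorm(2, 0, 2), 0), 10)
      lv[p, 1 + rd] <- sphere_roi_reference(
        ph$suv, c(145, 185, 225) + rnorm(3, 0, 4), 30)
    }
  }
  sds <- rbind(blood_pool = reference_sd(bp), liver = reference_sd(lv))
  pe <- list(
    blood_pool_automated = pearson(truth_bp, bp[, 1]),
    liver_automated = pearson(truth_lv, lv[, 1]))
  report <- make_report(
    sd_per_method = setNames(as.vector(t(sds)),
                             paste(rep(rownames(sds), each = 4),
                                   colnames(sds), sep = ".")),
    pearson = pe)
  list(report = report, blood_pool = bp, liver = lv,
       truth = list(blood_pool = truth_bp, liver = truth_lv))
}

experiment_detection <- function(n, seed, config, variability, thresholds) {
  specs <- phantom_suite(n, variability, seed = seed, lesions = TRUE)
  matched <- total <- fp <- 0
  thr_names <- sprintf("suv_%.1f", thresholds)
  thr_matched <- setNames(numeric(length(thresholds)), thr_names)
  sub_thr_total <- setNames(numeric(length(thresholds)), thr_names)
  per_patient <- list()
  for (p in seq_len(n)) {
    ph <- make_phantom(specs[[p]])
    an <- analyze(ph$suv, ph$labels, config)
    mres <- match_lesions(ph$truth, an$lesions, dims = dim(ph$suv$data),
                          max_dist_mm = config$matching$max_dist_mm)
    matched <- matched + nrow(mres$pairs)
    total <- total + length(ph$truth$lesions)
    fp <- fp + length(mres$false_positives)
    det <- list(blob = mres)
    if (length(thresholds) > 0) {
      smask <- lesion_search_mask(ph$suv, ph$labels, config$detection,
                                  an$references$blood_pool)
      for (ti in seq_along(thresholds)) {
        trecs <- threshold_records(ph$suv, smask, thresholds[ti])
        tm <- match_lesions(ph$truth, trecs, dims = dim(ph$suv$data),
                            max_dist_mm = config$matching$max_dist_mm)
        thr_matched[ti] <- thr_matched[ti] + nrow(tm$pairs)
        det[[thr_names[ti]]] <- tm
      }
      realized <- vapply(ph$truth$lesions, `[[`, 0, "realized_suvmax")
      for (ti in seq_along(thresholds))
        sub_thr_total[ti] <- sub_thr_total[ti] +
          sum(realized < thresholds[ti])
    }
    per_patient[[p]] <- det
  }
  sens <- list(blob = sensitivity(c(matched, total)))
  for (ti in seq_along(thresholds))
    sens[[names(thr_matched)[ti]]] <-
      sensitivity(c(thr_matched[ti], total))
  report <- make_report(sensitivity = sens, fp_per_patient = fp / n)
  list(report = report, matched = matched, total = total,
       fp_per_patient = fp / n,
       n_truth_below_threshold = sub_thr_total,
       per_patient = per_patient)
}

experiment_reproducibility <- function(n, seed, config, variability) {
  vb <- variability
  vb$n_lesions <- pmax(vb$n_lesions, 5L)  # ensure enough lesions for ICC
  specs <- phantom_suite(n, vb, seed = seed, lesions = TRUE)
  m1 <- m2 <- list()
  for (p in seq_len(n)) {
    ph <- make_phantom(specs[[p]])
    a1 <- analyze(ph$suv, ph$labels, config)
    a2 <- analyze(ph$suv, ph$labels, config)
    m1[[p]] <- lesions_table(a1)
    m2[[p]] <- lesions_table(a2)
  }
  t1 <- do.call(rbind, m1)
  t2 <- do.call(rbind, m2)
  stopifnot(nrow(t1) == nrow(t2))
  icc <- c(suv_max = icc2(cbind(t1$suv_max, t2$suv_max)),
           suv_peak = icc2(cbind(t1$suv_peak, t2$suv_peak)),
           suv_mean = icc2(cbind(t1$suv_mean, t2$suv_mean)))
  list(report = make_report(icc = icc), icc = icc,
       run1 = t1, run2 = t2)
}

modify_checked <- function(defaults, overrides, what) {
  if (is.null(overrides)) return(defaults)
  extra <- setdiff(names(overrides), names(defaults))
  if (length(extra) > 0)
    stop("unknown ", what, " option(s): ", paste(extra, collapse = ", "))
  utils::modifyList(defaults, overrides)
}

#' Read a pipeline configuration from JSON
#'
#' Accepts a JSON object with any subset of `reference`, `detection`,
#' `fastmarch`, `matching` and `seed`; unknown keys anywhere are rejected.
#' Omitted fields keep their package defaults.
#'
#' @param path JSON file path.
#' @return [pipeline_config()]
#' @export
pipeline_config_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  extra <- setdiff(names(x), c("reference", "detection", "fastmarch",
                               "matching", "seed"))
  if (length(extra) > 0)
    stop("unknown config section(s): ", paste(extra, collapse = ", "))
  ref <- do.call(reference_config,
                 modify_checked(formals_defaults(reference_config),
                                as_plain(x$reference), "reference"))
  det_defaults <- formals_defaults(detection_config)
  det_over <- as_plain(x$detection)
  if (!is.null(det_over$suppression))
    det_over$suppression <- modify_checked(det_defaults$suppression,
                                           det_over$suppression,
                                           "detection$suppression")
  if (!is.null(det_over$rules))
    det_over$rules <- modify_checked(det_defaults$rules, det_over$rules,
                                     "detection$rules")
  det <- do.call(detection_config,
                 modify_checked(det_defaults, det_over, "detection"))
  fm <- do.call(fastmarch_config,
                modify_checked(formals_defaults(fastmarch_config),
                               as_plain(x$fastmarch), "fastmarch"))
  matching <- modify_checked(list(max_dist_mm = 10), as_plain(x$matching),
                             "matching")
  pipeline_config(reference = ref, detection = det, fastmarch = fm,
                  matching = matching, seed = x$seed %||% 1L)
}

formals_defaults <- function(fn) {
  lapply(as.list(formals(fn)), eval, envir = environment(fn))
}

as_plain <- function(x) if (is.null(x)) NULL else as.list(x)
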