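#' Write a subject-visit study to disk
#'
#' Writes the image set as NIfTI-1 volumes (`vfa.nii.gz`, `dynamic.nii.gz`,
#' `pre.nii.gz`, `post.nii.gz`, `roi.nii.gz`) plus a JSON sidecar
#' (`study.json`) carrying the acquisition metadata, haematocrit, relaxivity
#' and input-function parameters, and a ground-truth sidecar (`truth.json`)
#' when the study is synthetic.
#'
#' @param study A `synthetic_study` (or compatible list).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pix <- study$acq$voxel_size
  wr <- function(x, f) RNifti::writeNifti(
    RNifti::asNifti(x, pixdim = pix), file.path(dir, f))
  wr(study$vfa, "vfa.nii.gz")
  wr(study$dynamic, "dynamic.nii.gz")
  wr(study$pre, "pre.nii.gz")
  wr(study$post, "post.nii.gz")
  wr(study$roi * 1, "roi.nii.gz")
  side <- list(
    tr = study$acq$tr,
    flip_angles_vfa = study$acq$flip_angles_vfa,
    dynamic_flip_angle = study$acq$dynamic_flip_angle,
    n_phases = study$acq$n_phases,
    phase_interval = study$acq$phase_interval,
    baseline_frames = study$acq$baseline_frames,
    voxel_size = study$acq$voxel_size,
    noise_sd = study$acq$noise_sd,
    noise_model = study$acq$noise_model,
    haematocrit = study$haematocrit,
    r1 = study$r1,
    aif_params = unclass(study$aif_params))
  jsonlite::write_json(side, file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(study$truth))
    jsonlite::write_json(
      list(whole_joint_median_ktrans = study$truth$whole_joint_median_ktrans,
           n_enhancing = sum(study$truth$enhancing),
           n_synovial = sum(study$roi > 0)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a subject-visit study from disk
#'
#' Loads the NIfTI volumes and JSON sidecar written by [write_study()],
#' validating that all grids agree and that the sidecar carries the fields
#' the analysis needs.
#'
#' @param dir Directory containing the study files.
#' @return A list of class `"dynamic_study"` with the images, the
#'   reconstructed [acquisition_spec()], `haematocrit`, `r1`, `aif_params`,
#'   `t_min` and `cp`.
#' @export
read_study <- function(dir) {
  need <- c("vfa.nii.gz", "dynamic.nii.gz", "pre.nii.gz", "post.nii.gz",
            "roi.nii.gz", "study.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("study directory is missing: ", paste(missing, collapse = ", "))
  side <- jsonlite::read_json(file.path(dir, "study.json"),
                              simplifyVector = TRUE)
  for (f in c("tr", "flip_angles_vfa", "dynamic_flip_angle",
              "phase_interval", "baseline_frames", "haematocrit"))
    if (is.null(side[[f]]))
      stop("study sidecar is missing required field: ", f)
  rd <- function(f) {
    x <- RNifti::readNifti(file.path(dir, f))
    array(as.numeric(x), dim(x))
  }
  vfa <- rd("vfa.nii.gz"); dynamic <- rd("dynamic.nii.gz")
  pre <- rd("pre.nii.gz"); post <- rd("post.nii.gz")
  roi <- rd("roi.nii.gz"); storage.mode(roi) <- "integer"
  grid <- dim(pre)
  bad <- character(0)
  if (!identical(dim(vfa)[1:3], grid)) bad <- c(bad, "vfa.nii.gz")
  if (!identical(dim(dynamic)[1:3], grid)) bad <- c(bad, "dynamic.nii.gz")
  if (!identical(dim(post), grid)) bad <- c(bad, "post.nii.gz")
  if (!identical(dim(roi), grid)) bad <- c(bad, "roi.nii.gz")
  if (length(bad))
    stop("grid mismatch against pre.nii.gz in: ", paste(bad, collapse = ", "))
  n_phases <- dim(dynamic)[4]
  acq <- acquisition_spec(
    tr = side$tr, flip_angles_vfa = side$flip_angles_vfa,
    dynamic_flip_angle = side$dynamic_flip_angle,
    n_phases = n_phases, phase_interval = side$phase_interval,
    baseline_frames = side$baseline_frames,
    voxel_size = side$voxel_size, grid_shape = grid,
    noise_sd = if (is.null(side$noise_sd)) 0 else side$noise_sd,
    noise_model = if (is.null(side$noise_model)) "gaussian" else
      side$noise_model)
  aifp <- if (!is.null(side$aif_params)) do.call(
    aif_parameters, side$aif_params[names(side$aif_params) %in%
                                      names(formals(aif_parameters))])
    else aif_parameters()
  t_min <- dynamic_time_grid(acq)
  r1 <- if (is.null(side$r1)) 3.5 else side$r1
  structure(list(vfa = vfa, dynamic = dynamic, pre = pre, post = post,
                 roi = roi, acq = acq, haematocrit = side$haematocrit,
                 r1 = r1, aif_params = aifp, t_min = t_min,
                 cp = haematocrit_correct(
                   population_aif_blood(t_min, aifp), side$haematocrit)),
            class = "dynamic_study")
}

#' Analyse one subject-visit study
#'
#' The full per-study imaging chain: VFA T1 mapping, signal-to-concentration
#' conversion of the dynamic series, voxelwise extended Tofts fitting inside
#' the synovial ROI, shuffle-subtraction/Otsu segmentation of the enhancing
#' pannus, and median biomarker extraction per region and whole joint for
#' both the semiautomatic (VEP) and manual arms.
#'
#' @param study A `synthetic_study` or [read_study()] result.
#' @param init_grid Starting values for the voxel fits (see
#'   [fit_tofts_volume()]); the default `"auto"` single data-driven start is
#'   appropriate for high-SNR data.
#' @param neighbourhood Shuffle neighbourhood (`"inplane"` or `"3d"`).
#' @return A list of class `"study_analysis"`: `t1map`, `pk` (`pk_maps`),
#'   `vep` (`vep_result`), `biomarkers` (long data frame with a `method`
#'   column covering both arms, including the VEP volume as biomarker
#'   `vep_ml`), and `counts` (voxels fitted / flagged implausible).
#' @export
analyze_study <- function(study, init_grid = "auto",
                          neighbourhood = "inplane") {
  acq <- study$acq
  t1map <- fit_vfa_t1(study$vfa, acq$flip_angles_vfa, acq$tr)
  roi_mask <- study$roi > 0
  fit_mask <- roi_mask & t1map$fit_ok

  dm <- dim(study$pre)
  nvox <- prod(dm)
  dyn <- matrix(study$dynamic, nrow = nvox)
  idx <- which(fit_mask)
  conv <- signal_to_concentration(
    dyn[idx, , drop = FALSE], acq$baseline_frames,
    t10 = t1map$t1[idx], r1 = study$r1, tr = acq$tr,
    flip_angle = acq$dynamic_flip_angle)
  conc <- matrix(0, nvox, acq$n_phases)
  cc <- conv$concentration
  cc[!conv$valid] <- 0  # invalid time points excluded from the fit as zeros
  conc[idx, ] <- cc

  pk <- fit_tofts_volume(array(conc, c(dm, acq$n_phases)), study$cp,
                         study$t_min, fit_mask, init_grid = init_grid,
                         baseline_frames = acq$baseline_frames)

  sh <- shuffle_subtract(study$pre, study$post, neighbourhood)
  vep <- build_vep_mask(sh, study$roi, acq$voxel_size,
                        region_names = synovial_region_names())

  bm_vep <- extract_median_biomarkers(pk, study$roi, vep, method = "vep")
  bm_vep$method <- "semiauto"
  bm_man <- extract_median_biomarkers(pk, study$roi, method = "manual")
  bm_man$method <- "manual"
  vol <- vep$volumes
  bm_vol <- data.frame(region = vol$region, label = vol$label,
                       biomarker = "vep_ml", value = vol$volume_ml,
                       n_voxels = vol$voxels, method = "semiauto",
                       stringsAsFactors = FALSE)
  biomarkers <- rbind(bm_vep, bm_man, bm_vol)

  structure(list(
    t1map = t1map, pk = pk, vep = vep, biomarkers = biomarkers,
    counts = list(voxels_in_roi = sum(roi_mask),
                  voxels_fitted = sum(pk$fitted),
                  voxels_implausible = sum(pk$fitted & !pk$plausible),
                  vep_voxels = sum(vep$mask & roi_mask))),
    class = "study_analysis")
}

#' Repeatability / discrimination / responsiveness statistics from a
#' biomarker table
#'
#' Consumes the long biomarker table produced by the imaging chain (columns
#' `subject_id`, `group`, `visit`, `region`, `biomarker`, `value`, `method`)
#' and computes, per biomarker and segmentation method, the whole-joint
#' test-retest repeatability panel (baseline vs 1-month), the baseline OA-HV
#' standardised mean difference, and the 6-month responsiveness counts.
#'
#' @param biomarkers Long biomarker data frame.
#' @param visit_pair Visits forming the test-retest pair.
#' @param change_visit Visit whose change from `visit_pair[1]` is assessed
#'   against the SDD.
#' @param scale `"auto"`, `"absolute"` or `"relative"` (passed to
#'   [repeatability_metrics()]).
#' @param sdd_override Optional externally specified SDD used for the
#'   responsiveness count instead of the one estimated from the test-retest
#'   pair (e.g. a nominal SDD from a repeatability specification).
#' @return A list of class `"biomarker_stats"` with data frames
#'   `repeatability`, `discrimination` and `responsiveness`.
#' @export
cohort_statistics <- function(biomarkers,
                              visit_pair = c("baseline", "month1"),
                              change_visit = "month6",
                              scale = "auto",
                              sdd_override = NULL) {
  wj <- biomarkers[biomarkers$region == "whole_joint" &
                     is.finite(biomarkers$value), , drop = FALSE]
  if (!nrow(wj)) stop("no whole-joint rows in the biomarker table")
  combos <- unique(wj[, c("biomarker", "method")])
  rep_rows <- list(); dis_rows <- list(); resp_rows <- list()
  for (i in seq_len(nrow(combos))) {
    bm <- combos$biomarker[i]; me <- combos$method[i]
    d <- wj[wj$biomarker == bm & wj$method == me, , drop = FALSE]
    v1 <- d[d$visit == visit_pair[1], ]
    v2 <- d[d$visit == visit_pair[2], ]
    ids <- intersect(v1$subject_id, v2$subject_id)
    oa_base <- v1$value[v1$group == "oa"]
    oa_mean <- if (length(oa_base)) mean(oa_base) else NA_real_

    rm <- NULL
    if (length(ids) >= 3L) {
      rec <- test_retest_records(
        ids, v1$value[match(ids, v1$subject_id)],
        v2$value[match(ids, v2$subject_id)])
      rm <- try(repeatability_metrics(rec, oa_mean = oa_mean, scale = scale),
                silent = TRUE)
      if (inherits(rm, "try-error")) rm <- NULL
    }
    if (!is.null(rm))
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        biomarker = bm, method = me, sigma_b2 = rm$sigma_b2,
        sigma_w2 = rm$sigma_w2, icc = rm$icc, icc_lower = rm$icc_lower,
        icc_upper = rm$icc_upper, scale = rm$scale,
        wsd_or_wcv = rm$wsd_or_wcv, sdd = rm$sdd, oa_mean = rm$oa_mean,
        sdd_pct_of_mean = rm$sdd_pct_of_mean, n_subjects = rm$n_subjects,
        stringsAsFactors = FALSE)

    oa <- v1$value[v1$group == "oa"]; hv <- v1$value[v1$group == "hv"]
    if (length(oa) >= 2L && length(hv) >= 2L) {
      gc <- try(standardized_mean_difference(oa, hv), silent = TRUE)
      if (!inherits(gc, "try-error"))
        dis_rows[[length(dis_rows) + 1L]] <- data.frame(
          biomarker = bm, method = me, mean_oa = gc$mean_oa,
          mean_hv = gc$mean_hv, pooled_sd = gc$pooled_sd, smd = gc$smd,
          stringsAsFactors = FALSE)
    }

    v3 <- d[d$visit == change_visit, ]
    cid <- intersect(v1$subject_id, v3$subject_id)
    sdd_use <- if (!is.null(sdd_override)) sdd_override
               else if (!is.null(rm)) rm$sdd else NA_real_
    sc_use <- if (!is.null(rm)) rm$scale else "absolute"
    if (length(cid) && is.finite(sdd_use)) {
      base <- v1$value[match(cid, v1$subject_id)]
      chg <- v3$value[match(cid, v3$subject_id)] - base
      grp <- v1$group[match(cid, v1$subject_id)]
      for (g in unique(grp)) {
        n_exc <- responsiveness_count(
          chg[grp == g], sdd_use, scale = sc_use,
          baseline = base[grp == g])
        resp_rows[[length(resp_rows) + 1L]] <- data.frame(
          biomarker = bm, method = me, group = g, n = sum(grp == g),
          n_exceeding_sdd = n_exc, sdd = sdd_use, scale = sc_use,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(
    repeatability = do.call(rbind, rep_rows),
    discrimination = do.call(rbind, dis_rows),
    responsiveness = do.call(rbind, resp_rows)),
    class = "biomarker_stats")
}

#' @export
print.biomarker_stats <- function(x, ...) {
  cat("Biomarker statistics\n-- repeatability --\n")
  print(x$repeatability, row.names = FALSE, digits = 3)
  cat("-- discrimination (baseline OA vs HV) --\n")
  print(x$discrimination, row.names = FALSE, digits = 3)
  cat("-- responsiveness (|change| > SDD) --\n")
  print(x$responsiveness, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Run the full simulation-and-analysis pipeline
#'
#' Orchestrates simulate -> T1 map -> concentration -> fit -> segment ->
#' extract -> statistics for a configured synthetic cohort, or a stats-only
#' run on a prebuilt biomarker CSV. Configuration may be a YAML file path or
#' an equivalent nested list; every stage is seeded from `seed` so a rerun
#' with the same configuration reproduces identical outputs.
#'
#' Config keys (all optional): `cohort` ([cohort_spec()] arguments),
#' `acquisition` ([acquisition_spec()] arguments), `phantom`
#' ([phantom_spec()] arguments), `aif` ([aif_parameters()] arguments),
#' `fit` (`init_grid: auto|grid`), `segmentation` (`neighbourhood`),
#' `stats` (`scale`, `sdd_override`, `visit_pair`, `change_visit`),
#' `biomarker_csv` (stats-only input), `write_images` (save NIfTI studies).
#'
#' @param config YAML path or list.
#' @param out Output directory for CSV/JSON artefacts (`NULL` = in-memory
#'   only).
#' @param seed Integer seed overriding the config's cohort seed.
#' @return A list of class `"pipeline_result"`: `metadata`, `biomarkers`,
#'   `stats`, `counts` and `manifest`.
#' @export
run_pipeline <- function(config = list(), out = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  log_msg <- function(...) message("[synodce] ", sprintf(...))

  stats_cfg <- config$stats %||% list()
  if (!is.null(config$biomarker_csv)) {
    log_msg("stats-only run on %s", config$biomarker_csv)
    bm <- utils::read.csv(config$biomarker_csv, stringsAsFactors = FALSE)
    res <- cohort_statistics(
      bm,
      visit_pair = stats_cfg$visit_pair %||% c("baseline", "month1"),
      change_visit = stats_cfg$change_visit %||% "month6",
      scale = stats_cfg$scale %||% "auto",
      sdd_override = stats_cfg$sdd_override)
    return(finalize_pipeline(NULL, bm, res, NULL, config, out))
  }

  coh_args <- config$cohort %||% list()
  if (!is.null(seed)) coh_args$seed <- as.integer(seed)
  if (!is.null(coh_args$group_means)) coh_args$group_means <-
    unlist(coh_args$group_means)
  cohort <- do.call(cohort_spec, coh_args)
  acq <- do.call(acquisition_spec, config$acquisition %||% list())
  ph_args <- config$phantom %||% list()
  ph_args$grid_shape <- ph_args$grid_shape %||% acq$grid_shape
  ph_args$voxel_size <- ph_args$voxel_size %||% acq$voxel_size
  pspec <- do.call(phantom_spec, ph_args)
  aifp <- do.call(aif_parameters, config$aif %||% list())

  log_msg("simulating cohort: %d OA + %d HV, grid %s",
          cohort$n_oa, cohort$n_hv, paste(acq$grid_shape, collapse = "x"))
  phantom <- generate_phantom(pspec, seed = cohort$seed)
  syn <- generate_cohort(cohort, phantom, acq, aifp, images = TRUE)

  if (!is.null(out) && isTRUE(config$write_images)) {
    for (nm in names(syn$studies))
      write_study(syn$studies[[nm]], file.path(out, "images", nm))
  }

  init_grid <- (config$fit %||% list())$init_grid %||% "auto"
  if (identical(init_grid, "grid")) init_grid <- tofts_init_grid()
  nbhd <- (config$segmentation %||% list())$neighbourhood %||% "inplane"

  bm_all <- list(); counts <- list()
  for (i in seq_len(nrow(syn$metadata))) {
    nm <- paste(syn$metadata$subject_id[i], syn$metadata$visit[i], sep = ".")
    an <- analyze_study(syn$studies[[nm]], init_grid = init_grid,
                        neighbourhood = nbhd)
    b <- an$biomarkers
    b$subject_id <- syn$metadata$subject_id[i]
    b$group <- syn$metadata$group[i]
    b$visit <- syn$metadata$visit[i]
    bm_all[[nm]] <- b
    counts[[nm]] <- an$counts
    log_msg("analysed %s: %d/%d voxels fitted, %d implausible, VEP %d voxels",
            nm, an$counts$voxels_fitted, an$counts$voxels_in_roi,
            an$counts$voxels_implausible, an$counts$vep_voxels)
  }
  biomarkers <- do.call(rbind, bm_all)
  rownames(biomarkers) <- NULL

  res <- cohort_statistics(
    biomarkers,
    visit_pair = stats_cfg$visit_pair %||% c("baseline", "month1"),
    change_visit = stats_cfg$change_visit %||% "month6",
    scale = stats_cfg$scale %||% "auto",
    sdd_override = stats_cfg$sdd_override)

  finalize_pipeline(syn$metadata, biomarkers, res, counts, config, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

finalize_pipeline <- function(metadata, biomarkers, stats, counts, config,
                              out) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("synodce")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(d, f) if (!is.null(d))
      utils::write.csv(d, file.path(out, f), row.names = FALSE)
    wcsv(metadata, "metadata.csv")
    wcsv(biomarkers, "biomarkers.csv")
    wcsv(stats$repeatability, "repeatability.csv")
    wcsv(stats$discrimination, "group_comparison.csv")
    wcsv(stats$responsiveness, "responsiveness.csv")
    files <- list.files(out, pattern = "\\.csv$", full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(files))
    names(manifest$checksums) <- basename(files)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(metadata = metadata, biomarkers = biomarkers,
                 stats = stats, counts = counts, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result: ",
      if (is.null(x$metadata)) "stats-only run"
      else paste0(length(unique(x$metadata$subject_id)), " subjects, ",
                  length(unique(x$metadata$visit)), " visits"), "\n",
      sep = "")
  print(x$stats)
  invisible(x)
}
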