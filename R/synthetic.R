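#' Forward-simulate one subject-visit image set from a phantom
#'
#' Generates all images the analysis pipeline consumes for one subject-visit:
#' the variable flip angle SPGR stack, the 4D dynamic series, and the
#' pre/post-contrast pair used for segmentation. Tissue concentration curves
#' come from the extended Tofts forward model driven by the
#' haematocrit-corrected population input function (bolus arriving after the
#' pre-contrast baseline frames), and signals from the SPGR equation with
#' \eqn{R_1(t) = 1/T_{10} + r_1 C(t)}. Noise is added per the acquisition's
#' noise model; all randomness is controlled by `seed`.
#'
#' @param phantom A [generate_phantom()] result.
#' @param acq An [acquisition_spec()]; its `grid_shape` must match the
#'   phantom.
#' @param aif_params [aif_parameters()]; if its `bolus_arrival_offset` is 0
#'   the offset is set to the end of the baseline frames.
#' @param haematocrit Subject haematocrit, a fraction in (0, 1).
#' @param r1 Contrast agent relaxivity (L/mmol/s).
#' @param ktrans_scale Multiplier applied to the phantom's enhancing-voxel
#'   Ktrans before simulation (used by the cohort generator to set the
#'   subject's true biomarker level).
#' @param seed Integer seed for the noise draw.
#' @return A list of class `"synthetic_study"`: `vfa` (4D, last dim = flip
#'   angle), `dynamic` (4D, last dim = time), `pre`, `post` (3D), `roi`,
#'   `acq`, `t_min`, `cp`, `haematocrit` and `truth` (the per-voxel
#'   parameter maps actually simulated, plus the enhancing mask and the true
#'   whole-joint enhancing-median Ktrans).
#' @export
generate_subject_images <- function(phantom, acq, aif_params = aif_parameters(),
                                    haematocrit = 0.42, r1 = 3.5,
                                    ktrans_scale = 1, seed = 1L) {
  stopifnot(inherits(phantom, "phantom"), inherits(acq, "acquisition_spec"))
  if (!identical(dim(phantom$labels), as.integer(acq$grid_shape)))
    stop("phantom and acquisition grids do not match")
  if (!is.finite(haematocrit) || haematocrit <= 0 || haematocrit >= 1)
    stop("`haematocrit` must be a fraction in (0, 1)")

  dm <- dim(phantom$labels)
  nv <- prod(dm)
  t_min <- dynamic_time_grid(acq)
  if (aif_params$bolus_arrival_offset == 0)
    aif_params$bolus_arrival_offset <-
      acq$baseline_frames * acq$phase_interval / 60
  cp <- haematocrit_correct(population_aif_blood(t_min, aif_params),
                            haematocrit)

  ktrans <- phantom$ktrans * ifelse(phantom$enhancing, ktrans_scale, 1)
  ve <- phantom$ve; vp <- phantom$vp; t10 <- phantom$t10; m0 <- phantom$m0

  # voxels sharing (ktrans, ve, vp, t10, m0) share one concentration/signal
  # curve; phantom regions are piecewise-constant so this is a handful of
  # curves rather than one per voxel
  key <- paste(ktrans, ve, vp, t10, m0, sep = "|")
  uk <- unique(key)
  grp <- match(key, uk)
  parts <- do.call(rbind, strsplit(uk, "|", fixed = TRUE))
  storage.mode(parts) <- "double"

  n_t <- acq$n_phases
  dyn_curves <- matrix(0, length(uk), n_t)
  for (g in seq_along(uk)) {
    p <- parts[g, ]
    conc <- extended_tofts_forward(p[1], p[2], p[3], cp, t_min)
    r1t <- 1 / p[4] + r1 * conc
    dyn_curves[g, ] <- spgr_signal(p[5], 1 / r1t, acq$dynamic_flip_angle,
                                   acq$tr)
  }
  dynamic <- dyn_curves[grp, , drop = FALSE]

  n_fa <- length(acq$flip_angles_vfa)
  vfa <- matrix(0, nv, n_fa)
  for (j in seq_len(n_fa))
    vfa[, j] <- spgr_signal(as.vector(m0), as.vector(t10),
                            acq$flip_angles_vfa[j], acq$tr)

  set.seed(seed)
  dynamic <- add_noise(dynamic, acq$noise_sd, acq$noise_model)
  vfa <- add_noise(vfa, acq$noise_sd, acq$noise_model)

  pre <- dynamic[, acq$baseline_frames]
  post <- dynamic[, n_t]

  dim(vfa) <- c(dm, n_fa)
  dim(dynamic) <- c(dm, n_t)
  dim(pre) <- dm; dim(post) <- dm

  enh_k <- ktrans[phantom$enhancing & phantom$roi > 0]
  structure(list(
    vfa = vfa, dynamic = dynamic, pre = pre, post = post,
    roi = phantom$roi, acq = acq, t_min = t_min, cp = cp,
    haematocrit = haematocrit, r1 = r1, aif_params = aif_params,
    truth = list(ktrans = ktrans, ve = ve, vp = vp, t10 = t10, m0 = m0,
                 enhancing = phantom$enhancing,
                 whole_joint_median_ktrans =
                   if (length(enh_k)) stats::median(enh_k) else NA_real_)),
    class = "synthetic_study")
}

add_noise <- function(x, sd, model) {
  if (sd == 0) return(x)
  n <- length(x)
  if (model == "gaussian") {
    x + stats::rnorm(n, 0, sd)
  } else {
    re <- x + stats::rnorm(n, 0, sd)
    im <- stats::rnorm(n, 0, sd)
    out <- sqrt(re^2 + im^2)
    dim(out) <- dim(x)
    out
  }
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic subject-visit study: grid ",
      paste(dim(x$pre), collapse = "x"), ", ", x$acq$n_phases,
      " dynamic phases, hct ", x$haematocrit, "\n", sep = "")
  invisible(x)
}

#' Cohort specification
#'
#' Defines a two-group longitudinal cohort with a test-retest structure:
#' baseline and 1-month visits measure the same underlying state (separated
#' only by within-subject variation), and the 6-month visit may add a true
#' change. Per-subject true whole-joint biomarker levels are drawn as
#' `group mean + N(0, between_subject_sd)`; each visit adds
#' `N(0, within_subject_sd)`. Defaults emulate the study design the package
#' targets: 14 OA and 6 healthy-volunteer subjects, whole-joint Ktrans
#' between/within-subject variances of 2.1e-4 and 2.4e-5 (min^-2), OA group
#' mean 0.039 /min with HV 0.01 /min lower, haematocrit ~ N(0.42, 0.02).
#'
#' @param n_oa,n_hv Group sizes (>= 0, not both 0).
#' @param visits Visit names in temporal order.
#' @param group_means Named numeric: true mean whole-joint Ktrans (/min) per
#'   group (`oa`, `hv`).
#' @param between_subject_sd,within_subject_sd Standard deviations of the
#'   biomarker (same units), >= 0.
#' @param month6_changes Optional numeric vector of true 6-month changes, one
#'   per OA subject (recycled/zero-padded); HV subjects change by 0.
#' @param haematocrit_mean,haematocrit_sd Haematocrit distribution
#'   (truncated to (0.2, 0.65)).
#' @param seed Integer seed making the whole cohort reproducible.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_oa = 14L, n_hv = 6L,
                        visits = c("baseline", "month1", "month6"),
                        group_means = c(oa = 0.039, hv = 0.029),
                        between_subject_sd = sqrt(2.1e-4),
                        within_subject_sd = sqrt(2.4e-5),
                        month6_changes = NULL,
                        haematocrit_mean = 0.42, haematocrit_sd = 0.02,
                        seed = 1L) {
  if (n_oa < 0 || n_hv < 0) stop("group sizes must be >= 0")
  if (n_oa + n_hv == 0) stop("cohort is empty: n_oa + n_hv = 0")
  if (between_subject_sd < 0 || within_subject_sd < 0 || haematocrit_sd < 0)
    stop("standard deviations must be >= 0")
  if (!all(c("oa", "hv") %in% names(group_means)))
    stop("`group_means` must be named with `oa` and `hv`")
  structure(list(n_oa = as.integer(n_oa), n_hv = as.integer(n_hv),
                 visits = visits, group_means = group_means,
                 between_subject_sd = between_subject_sd,
                 within_subject_sd = within_subject_sd,
                 month6_changes = month6_changes,
                 haematocrit_mean = haematocrit_mean,
                 haematocrit_sd = haematocrit_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw the true biomarker levels and metadata of a cohort
#'
#' Samples each subject's underlying whole-joint biomarker level and the
#' per-visit true values (subject level + within-subject noise + any assigned
#' 6-month change), together with haematocrits. This is the statistical core
#' of the cohort generator and is usable on its own for Monte-Carlo work on
#' the repeatability statistics, without simulating any images.
#'
#' @param cohort A [cohort_spec()].
#' @return Data frame with columns `subject_id`, `group`, `visit`,
#'   `haematocrit`, `subject_level`, `true_value`, `seed`.
#' @export
simulate_biomarker_truth <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  set.seed(cohort$seed)
  n <- cohort$n_oa + cohort$n_hv
  group <- c(rep("oa", cohort$n_oa), rep("hv", cohort$n_hv))
  ids <- sprintf("S%02d", seq_len(n))
  level <- cohort$group_means[group] +
    stats::rnorm(n, 0, cohort$between_subject_sd)
  hct <- pmin(pmax(stats::rnorm(n, cohort$haematocrit_mean,
                                cohort$haematocrit_sd), 0.2), 0.65)
  changes <- numeric(n)
  if (!is.null(cohort$month6_changes) && cohort$n_oa > 0) {
    ch <- rep_len(c(cohort$month6_changes,
                    rep(0, max(0, cohort$n_oa - length(cohort$month6_changes)))),
                  cohort$n_oa)
    changes[seq_len(cohort$n_oa)] <- ch
  }
  rows <- list()
  for (v in cohort$visits) {
    tv <- level + stats::rnorm(n, 0, cohort$within_subject_sd) +
      if (v == "month6") changes else 0
    rows[[v]] <- data.frame(subject_id = ids, group = group, visit = v,
                            haematocrit = hct, subject_level = unname(level),
                            true_value = pmax(unname(tv), 1e-4),
                            seed = cohort$seed, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a full synthetic cohort
#'
#' Draws the cohort truth table with [simulate_biomarker_truth()] and, when
#' `images = TRUE`, forward-simulates every subject-visit image set. Each
#' subject-visit's enhancing-voxel Ktrans field is scaled multiplicatively so
#' that its true whole-joint median Ktrans equals the subject's drawn true
#' value (exact in the noiseless forward model).
#'
#' @param cohort A [cohort_spec()].
#' @param phantom A [generate_phantom()] result shared across subjects.
#' @param acq An [acquisition_spec()].
#' @param aif_params [aif_parameters()].
#' @param images Simulate images (`TRUE`) or return only the truth table.
#' @return A list of class `"synthetic_cohort"`: `metadata` (the truth
#'   table; the subject/group/visit/haematocrit columns form the cohort
#'   metadata CSV) and `studies` (named list of
#'   `"<subject>.<visit>"` [generate_subject_images()] results, or `NULL`).
#' @export
generate_cohort <- function(cohort, phantom = NULL, acq = NULL,
                            aif_params = aif_parameters(), images = TRUE) {
  meta <- simulate_biomarker_truth(cohort)
  studies <- NULL
  if (images) {
    stopifnot(inherits(phantom, "phantom"), inherits(acq, "acquisition_spec"))
    base_med <- stats::median(phantom$ktrans[phantom$enhancing &
                                               phantom$roi > 0])
    if (!is.finite(base_med) || base_med <= 0)
      stop("phantom has no enhancing synovial voxels to calibrate against")
    studies <- vector("list", nrow(meta))
    names(studies) <- paste(meta$subject_id, meta$visit, sep = ".")
    for (i in seq_len(nrow(meta))) {
      studies[[i]] <- generate_subject_images(
        phantom, acq, aif_params,
        haematocrit = meta$haematocrit[i],
        ktrans_scale = meta$true_value[i] / base_med,
        seed = as.integer((as.numeric(cohort$seed) * 1009 + i) %% 2147483647))
    }
  }
  structure(list(metadata = meta, studies = studies, cohort = cohort),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", x$cohort$n_oa, " OA + ", x$cohort$n_hv,
      " HV subjects, visits: ", paste(x$cohort$visits, collapse = ", "),
      if (is.null(x$studies)) " (truth table only)" else
        paste0(" (", length(x$studies), " image sets)"), "\n", sep = "")
  invisible(x)
}
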