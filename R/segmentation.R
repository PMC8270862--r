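#' Shuffle-transform image subtraction
#'
#' Motion-tolerant pre/post-contrast subtraction. For each voxel of the
#' post-contrast image the subtrahend is the pre-contrast value, within a
#' local neighbourhood of that voxel, that minimises the absolute difference;
#' the signed minimising difference is returned. Where post equals any
#' pre-neighbour the output is exactly zero, so small residual
#' misregistration (up to one voxel for the in-plane 3x3 neighbourhood)
#' vanishes from the subtraction instead of producing rim artefact.
#'
#' Ties are broken by the smallest spatial offset, then by lexicographic
#' order of the offset vector. The neighbourhood is clipped at the volume
#' edges.
#'
#' @param pre,post 3D numeric arrays of identical dimensions (2D matrices are
#'   treated as single-slice volumes).
#' @param neighbourhood `"inplane"` (3x3 within slice, the default) or
#'   `"3d"` (3x3x3).
#' @return An object of class `"shuffle_diff"`: the signed difference array
#'   with attribute `neighbourhood`.
#' @export
shuffle_subtract <- function(pre, post, neighbourhood = c("inplane", "3d")) {
  neighbourhood <- match.arg(neighbourhood)
  if (is.matrix(pre)) dim(pre) <- c(dim(pre), 1L)
  if (is.matrix(post)) dim(post) <- c(dim(post), 1L)
  if (!identical(dim(pre), dim(post)))
    stop("`pre` and `post` dimensions differ: ",
         paste(dim(pre), collapse = "x"), " vs ",
         paste(dim(post), collapse = "x"))
  dm <- dim(pre)
  if (length(dm) != 3L) stop("inputs must be 2D or 3D arrays")

  dz_range <- if (neighbourhood == "3d") -1:1 else 0L
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = dz_range)
  # priority: smallest offset first, then lexicographic (dx, dy, dz)
  ord <- order(offs$dx^2 + offs$dy^2 + offs$dz^2, offs$dx, offs$dy, offs$dz)
  offs <- offs[ord, ]

  best_abs <- array(Inf, dm)
  best_diff <- array(0, dm)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  for (k in seq_len(nrow(offs))) {
    dx <- offs$dx[k]; dy <- offs$dy[k]; dz <- offs$dz[k]
    # destination voxels whose neighbour (x+dx, y+dy, z+dz) is in range
    xs <- max(1, 1 - dx):min(nx, nx - dx)
    ys <- max(1, 1 - dy):min(ny, ny - dy)
    zs <- max(1, 1 - dz):min(nz, nz - dz)
    d <- post[xs, ys, zs, drop = FALSE] -
      pre[xs + dx, ys + dy, zs + dz, drop = FALSE]
    ad <- abs(d)
    cur_abs <- best_abs[xs, ys, zs, drop = FALSE]
    better <- ad < cur_abs  # strict: earlier (higher-priority) offset wins ties
    if (any(better)) {
      cur_diff <- best_diff[xs, ys, zs, drop = FALSE]
      cur_abs[better] <- ad[better]
      cur_diff[better] <- d[better]
      best_abs[xs, ys, zs] <- cur_abs
      best_diff[xs, ys, zs] <- cur_diff
    }
  }
  structure(best_diff, class = "shuffle_diff", neighbourhood = neighbourhood)
}

#' Otsu threshold of an intensity sample
#'
#' Histogram-based threshold maximising the between-class variance
#' \eqn{\omega_0\omega_1(\mu_0 - \mu_1)^2} over the inner edges of a 256-bin
#' histogram spanning the sample range. The returned value is the bin edge;
#' voxels strictly above it form the upper class. Works on signed samples
#' (the shuffle difference keeps its sign so de-enhancing voxels are
#' representable).
#'
#' @param values Numeric sample with at least two distinct finite values.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold (signal units).
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L)
    stop("Otsu threshold undefined for a constant sample")
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(
    pmin(pmax(findInterval(values, breaks, rightmost.closed = TRUE), 1L),
         n_bins),
    nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  n <- w[n_bins]; mt <- m[n_bins]
  # candidate thresholds: inner edges after bins 1 .. n_bins-1
  w0 <- w[-n_bins]; w1 <- n - w0
  mu0 <- m[-n_bins] / w0
  mu1 <- (mt - m[-n_bins]) / w1
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  breaks[which.max(bcv) + 1L]
}

#' Build the volume-of-enhancing-pannus (VEP) mask
#'
#' Applies Otsu thresholding to the shuffle-subtracted difference, sampling
#' the histogram only within the synovial ROI union (so empty background does
#' not dominate it), and intersects the resulting enhancing mask with the ROI
#' label map. Volumes are reported per region and for the whole joint in mL.
#'
#' @param diff A [shuffle_subtract()] result (or plain array of the same
#'   dimensions).
#' @param roi Integer ROI label volume (0 = outside; positive labels are
#'   synovial regions).
#' @param voxel_size Voxel dimensions in mm (length 3).
#' @param region_names Optional named character vector mapping labels to
#'   region names.
#' @return An object of class `"vep_result"`: `mask` (logical array),
#'   `threshold`, and `volumes` — a data frame with one row per region plus a
#'   `whole_joint` row (columns `region`, `label`, `voxels`, `volume_ml`).
#' @export
build_vep_mask <- function(diff, roi, voxel_size, region_names = NULL) {
  diff <- unclass(diff)
  if (!identical(dim(diff), dim(roi)))
    stop("difference and ROI grids are not aligned")
  if (any(voxel_size <= 0)) stop("`voxel_size` must be positive (mm)")
  in_roi <- roi > 0
  if (!any(in_roi)) stop("ROI is empty")
  thr <- otsu_threshold(diff[in_roi])
  enhancing <- diff > thr
  vep <- enhancing & in_roi

  vox_ml <- prod(voxel_size) / 1000  # mm^3 -> mL
  labels <- sort(unique(roi[in_roi]))
  counts <- vapply(labels, function(l) sum(vep[roi == l]), numeric(1))
  nm <- if (!is.null(region_names)) region_names[as.character(labels)]
        else paste0("region_", labels)
  volumes <- data.frame(
    region = c(nm, "whole_joint"),
    label = c(labels, NA),
    voxels = c(counts, sum(counts)),
    volume_ml = c(counts, sum(counts)) * vox_ml,
    stringsAsFactors = FALSE)
  structure(list(mask = vep, threshold = thr, volumes = volumes,
                 voxel_size = voxel_size),
            class = "vep_result")
}

#' @export
print.vep_result <- function(x, ...) {
  cat("Volume of enhancing pannus (threshold ", signif(x$threshold, 4),
      "):\n", sep = "")
  print(x$volumes, row.names = FALSE)
  invisible(x)
}

#' Default synovial region names
#'
#' The seven synovial regions used throughout the package, keyed by label.
#' @return Named character vector (names are labels "1".."7").
#' @export
synovial_region_names <- function() {
  c(`1` = "suprapatellar", `2` = "hoffa_fat_pad", `3` = "medial_perimeniscal",
    `4` = "lateral_perimeniscal", `5` = "intercondylar_notch",
    `6` = "posterior_medial_femoral_condyle",
    `7` = "posterior_lateral_femoral_condyle")
}

#' Extract median biomarker values per ROI and whole joint
#'
#' Computes the median of each pharmacokinetic biomarker map over the voxels
#' of each synovial region and over the union of all regions (whole joint).
#' With `method = "vep"` (semiautomatic arm) medians are taken over the
#' intersection of the region with the enhancing-pannus mask; with
#' `method = "manual"` over the full region. A region with no contributing
#' voxels yields `NA`, never zero.
#'
#' @param pk A `pk_maps` object from [fit_tofts_volume()] (or a named list of
#'   arrays).
#' @param roi Integer ROI label volume.
#' @param vep Optional [build_vep_mask()] result (required for
#'   `method = "vep"`).
#' @param method `"vep"` or `"manual"`.
#' @param biomarkers Which maps to summarise.
#' @param region_names Optional label-to-name mapping.
#' @return Data frame with columns `region`, `label`, `biomarker`, `value`,
#'   `n_voxels`.
#' @export
extract_median_biomarkers <- function(pk, roi, vep = NULL,
                                      method = c("vep", "manual"),
                                      biomarkers = c("ktrans", "ve", "vp",
                                                     "iauc60"),
                                      region_names = synovial_region_names()) {
  method <- match.arg(method)
  if (method == "vep") {
    if (is.null(vep)) stop("`vep` mask is required for method = \"vep\"")
    sel <- vep$mask
  } else {
    sel <- roi > 0
  }
  if (!identical(dim(roi), dim(sel)))
    stop("ROI and mask grids are not aligned")
  labels <- sort(unique(roi[roi > 0]))
  rows <- list()
  for (bm in biomarkers) {
    vol <- pk[[bm]]
    if (is.null(vol)) stop("biomarker map not found: ", bm)
    if (!identical(dim(vol), dim(roi)))
      stop("biomarker map grid does not match the ROI")
    for (l in labels) {
      idx <- sel & roi == l
      vals <- vol[idx]
      vals <- vals[is.finite(vals)]
      nm <- if (!is.null(region_names) && as.character(l) %in% names(region_names))
        region_names[[as.character(l)]] else paste0("region_", l)
      rows[[length(rows) + 1L]] <- data.frame(
        region = nm, label = l, biomarker = bm,
        value = if (length(vals)) stats::median(vals) else NA_real_,
        n_voxels = length(vals), stringsAsFactors = FALSE)
    }
    idx <- sel & roi > 0
    vals <- vol[idx]; vals <- vals[is.finite(vals)]
    rows[[length(rows) + 1L]] <- data.frame(
      region = "whole_joint", label = NA_integer_, biomarker = bm,
      value = if (length(vals)) stats::median(vals) else NA_real_,
      n_voxels = length(vals), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
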