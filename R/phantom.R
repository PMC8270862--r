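#' Acquisition specification
#'
#' Describes the simulated SPGR acquisitions: the variable flip angle T1
#' mapping stack, the dynamic contrast-enhanced series, and the pre/post
#' subtraction pair. Defaults follow a 3 T knee DCE protocol: TR 4 ms, VFA
#' flip angles 2/6/14 degrees, dynamic flip angle 14 degrees, 35 dynamic
#' phases. The phase interval is configurable (default 10 s, giving a
#' ~5.8 min acquisition typical of 3D SPGR knee DCE).
#'
#' @param tr Repetition time in seconds.
#' @param flip_angles_vfa Flip angles (degrees) of the T1-mapping stack.
#' @param dynamic_flip_angle Flip angle (degrees) of the dynamic series.
#' @param n_phases Number of dynamic phases (>= 2).
#' @param phase_interval Seconds between dynamic phases.
#' @param baseline_frames Pre-bolus frames before contrast arrival.
#' @param voxel_size Voxel dimensions in mm.
#' @param grid_shape Grid dimensions in voxels.
#' @param noise_sd Additive noise standard deviation (signal units).
#' @param noise_model `"gaussian"` or `"rician"`.
#' @return A list of class `"acquisition_spec"`.
#' @export
acquisition_spec <- function(tr = 0.004,
                             flip_angles_vfa = c(2, 6, 14),
                             dynamic_flip_angle = 14,
                             n_phases = 35L,
                             phase_interval = 10,
                             baseline_frames = 5L,
                             voxel_size = c(2.5, 2.5, 4),
                             grid_shape = c(64L, 64L, 16L),
                             noise_sd = 0,
                             noise_model = c("gaussian", "rician")) {
  noise_model <- match.arg(noise_model)
  if (tr <= 0) stop("`tr` must be positive")
  if (any(flip_angles_vfa <= 0 | flip_angles_vfa > 90) ||
      dynamic_flip_angle <= 0 || dynamic_flip_angle > 90)
    stop("flip angles must be in (0, 90] degrees")
  if (n_phases < 2L) stop("`n_phases` must be >= 2")
  if (phase_interval <= 0) stop("`phase_interval` must be positive")
  if (baseline_frames < 1L || baseline_frames >= n_phases)
    stop("`baseline_frames` must be in [1, n_phases)")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  structure(list(
    tr = tr, flip_angles_vfa = flip_angles_vfa,
    dynamic_flip_angle = dynamic_flip_angle,
    n_phases = as.integer(n_phases), phase_interval = phase_interval,
    baseline_frames = as.integer(baseline_frames),
    voxel_size = voxel_size, grid_shape = as.integer(grid_shape),
    noise_sd = noise_sd, noise_model = noise_model),
    class = "acquisition_spec")
}

#' Dynamic time grid of an acquisition (minutes)
#'
#' @param acq An [acquisition_spec()].
#' @return Time of each dynamic frame in minutes, starting at 0.
#' @export
dynamic_time_grid <- function(acq) {
  (seq_len(acq$n_phases) - 1) * acq$phase_interval / 60
}

#' Default per-region tissue parameters of the digital knee phantom
#'
#' Seven synovial regions with mildly varying microvascular parameters around
#' typical synovitis values (Ktrans of order 0.02-0.06 /min, ve ~ 0.3,
#' vp ~ 0.02, native T1 ~ 1.2 s at 3 T), plus bone (short T1) and fluid
#' (long T1) compartments, all non-enhancing outside the synovium.
#'
#' @return Data frame with columns `label`, `region`, `ktrans`, `ve`, `vp`,
#'   `t10`, `m0`.
#' @export
default_tissue_table <- function() {
  nm <- synovial_region_names()
  data.frame(
    label = c(1:7, 8L, 9L, 0L),
    region = c(unname(nm), "bone", "fluid", "background"),
    ktrans = c(0.050, 0.035, 0.045, 0.040, 0.060, 0.030, 0.025, 0, 0, 0),
    ve = c(0.32, 0.28, 0.30, 0.30, 0.35, 0.25, 0.27, 0.2, 1.0, 0.3),
    vp = c(0.020, 0.015, 0.020, 0.018, 0.025, 0.012, 0.015, 0, 0, 0),
    t10 = c(rep(1.2, 7), 0.37, 3.5, 1.0),
    m0 = c(rep(1000, 7), 600, 1200, 800),
    stringsAsFactors = FALSE)
}

#' Phantom specification
#'
#' Defines the digital knee-like phantom: grid, voxel size, region geometry
#' and per-region tissue parameters. The default geometry places the seven
#' synovial regions as non-overlapping ellipsoids on a ring around a central
#' bone cylinder with a small fluid pocket — invented plumbing that carries
#' the regions' distinct parameters, not an anatomical model.
#'
#' @param grid_shape Voxels per axis (at least 16 in-plane and 4 slices for
#'   the default geometry).
#' @param voxel_size mm per axis.
#' @param tissue_table Per-region parameters as in [default_tissue_table()].
#' @param enhancing_fraction Fraction of synovial voxels that enhance
#'   (the rest get `ktrans = 0`, `vp = 0`), in \[0, 1\].
#' @param regions Optional list of ellipsoid definitions
#'   (`list(label=, centre=, semi_axes=)`) replacing the default ring layout.
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 16L),
                         voxel_size = c(2.5, 2.5, 4),
                         tissue_table = default_tissue_table(),
                         enhancing_fraction = 0.5,
                         regions = NULL) {
  if (length(grid_shape) != 3L || any(grid_shape[1:2] < 16L) ||
      grid_shape[3] < 4L)
    stop("`grid_shape` must be at least 16x16 in-plane and 4 slices")
  if (enhancing_fraction < 0 || enhancing_fraction > 1)
    stop("`enhancing_fraction` must be in [0, 1]")
  req <- c("label", "region", "ktrans", "ve", "vp", "t10", "m0")
  if (!all(req %in% names(tissue_table)))
    stop("`tissue_table` must have columns: ", paste(req, collapse = ", "))
  if (any(tissue_table$ktrans < 0) || any(tissue_table$vp < 0) ||
      any(tissue_table$vp > 1) || any(tissue_table$ve <= 0) ||
      any(tissue_table$t10 <= 0))
    stop("tissue parameters violate invariants (ktrans >= 0, 0 <= vp <= 1, ve > 0, t10 > 0)")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size,
                 tissue_table = tissue_table,
                 enhancing_fraction = enhancing_fraction,
                 regions = regions),
            class = "phantom_spec")
}

default_region_layout <- function(grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  ring_r <- 0.30 * min(nx, ny)
  # semi-axes sized so neighbouring ellipsoids on the ring cannot touch
  sep <- 2 * ring_r * sin(pi / 7)
  ax <- 0.45 * sep
  az <- max(1.2, 0.22 * nz)
  regs <- lapply(1:7, function(l) {
    th <- 2 * pi * (l - 1) / 7
    list(label = l,
         centre = c(cx + ring_r * cos(th), cy + ring_r * sin(th), cz),
         semi_axes = c(ax, ax, az))
  })
  # central bone cylinder (as a flat ellipsoid) and a small fluid pocket
  regs[[8]] <- list(label = 8L, centre = c(cx, cy, cz),
                    semi_axes = c(0.12 * min(nx, ny), 0.12 * min(nx, ny),
                                  0.45 * nz))
  regs[[9]] <- list(label = 9L,
                    centre = c(0.15 * nx, 0.15 * ny, cz),
                    semi_axes = c(0.05 * nx, 0.05 * ny, max(1, 0.10 * nz)))
  regs
}

#' Generate a digital phantom: label volume and tissue parameter maps
#'
#' Rasterises the region layout into an integer label volume and fills
#' voxelwise `ktrans`, `ve`, `vp`, `t10` and `m0` maps from the tissue table.
#' A seeded random subset of synovial voxels of size `enhancing_fraction` is
#' marked enhancing; the remaining synovial voxels have their `ktrans` and
#' `vp` set to zero (non-enhancing synovium). Identical spec and seed give
#' bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed for the enhancing-voxel draw.
#' @return A list of class `"phantom"`: `labels` (integer array; synovial
#'   regions 1-7, bone 8, fluid 9, background 0), `roi` (labels masked to
#'   1-7), `enhancing` (logical array), parameter arrays `ktrans`, `ve`,
#'   `vp`, `t10`, `m0`, plus `voxel_size` and the `spec`.
#' @export
generate_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  custom <- !is.null(spec$regions)
  regions <- if (custom) spec$regions else default_region_layout(dm)
  if (!custom &&
      length(intersect(vapply(regions, function(r) as.integer(r$label),
                              integer(1)), 1:7)) < 7L)
    stop("default phantom layout requires all 7 synovial labels")

  xg <- seq_len(dm[1]); yg <- seq_len(dm[2]); zg <- seq_len(dm[3])
  coords <- list(
    x = array(rep(xg, times = dm[2] * dm[3]), dm),
    y = array(rep(rep(yg, each = dm[1]), times = dm[3]), dm),
    z = array(rep(zg, each = dm[1] * dm[2]), dm))

  labels <- array(0L, dm)
  for (r in regions) {
    inside <- ((coords$x - r$centre[1]) / r$semi_axes[1])^2 +
      ((coords$y - r$centre[2]) / r$semi_axes[2])^2 +
      ((coords$z - r$centre[3]) / r$semi_axes[3])^2 <= 1
    clash <- inside & labels != 0L
    if (any(clash))
      stop("overlapping region definitions: labels ",
           paste(sort(unique(c(labels[clash], r$label))), collapse = ", "))
    labels[inside] <- as.integer(r$label)
  }

  tt <- spec$tissue_table
  lut <- function(col) {
    v <- stats::setNames(tt[[col]], as.character(tt$label))
    out <- v[as.character(labels)]
    bg <- v[["0"]]
    out[is.na(out)] <- bg
    array(unname(out), dm)
  }
  ktrans <- lut("ktrans"); ve <- lut("ve"); vp <- lut("vp")
  t10 <- lut("t10"); m0 <- lut("m0")

  synovial <- labels %in% 1:7
  dim(synovial) <- dm
  enhancing <- array(FALSE, dm)
  idx <- which(synovial)
  if (length(idx)) {
    set.seed(seed)
    n_enh <- round(spec$enhancing_fraction * length(idx))
    enhancing[sample(idx, n_enh)] <- TRUE
  }
  off <- synovial & !enhancing
  ktrans[off] <- 0; vp[off] <- 0

  roi <- labels
  roi[!synovial] <- 0L
  structure(list(labels = labels, roi = roi, enhancing = enhancing,
                 ktrans = ktrans, ve = ve, vp = vp, t10 = t10, m0 = m0,
                 voxel_size = spec$voxel_size, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("Digital phantom ", paste(dim(x$labels), collapse = "x"),
      " (", sum(x$roi > 0), " synovial voxels, ",
      sum(x$enhancing), " enhancing)\n", sep = "")
  invisible(x)
}
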