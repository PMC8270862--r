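# Independent brute-force Otsu: split the actual sample at every inner edge
# of the same 256-bin histogram and maximise the between-class variance
# computed from the raw values.
otsu_brute <- function(values, n_bins = 256L) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)[2:n_bins]
  bcv <- vapply(edges, function(e) {
    lo <- values[values <= e]; hi <- values[values > e]
    if (!length(lo) || !length(hi)) return(-Inf)
    w0 <- length(lo) / length(values); w1 <- 1 - w0
    w0 * w1 * (mean(lo) - mean(hi))^2
  }, numeric(1))
  edges[which.max(bcv)]
}

# Standard acquisition/phantom fixtures on a small grid
small_acq <- function(grid = c(16L, 16L, 4L), noise_sd = 0, ...) {
  acquisition_spec(grid_shape = grid, voxel_size = c(2.5, 2.5, 4),
                   noise_sd = noise_sd, ...)
}

small_phantom <- function(grid = c(16L, 16L, 4L), seed = 1L, ...) {
  generate_phantom(phantom_spec(grid_shape = grid,
                                voxel_size = c(2.5, 2.5, 4), ...),
                   seed = seed)
}

# Standard dynamic time grid and plasma curve for voxel-level tests
test_time_grid <- function(n = 35L, dt_s = 10) (seq_len(n) - 1) * dt_s / 60

test_cp <- function(t = test_time_grid(), hct = 0.42,
                    offset = 5 * 10 / 60) {
  haematocrit_correct(
    population_aif_blood(t, aif_parameters(bolus_arrival_offset = offset)),
    hct)
}
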