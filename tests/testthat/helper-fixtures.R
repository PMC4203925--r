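# Small in-code fixtures shared across test files.

tiny_grid <- function(n = 8L, spacing = 2) image_grid(rep(n, 3), rep(spacing, 3))

# random SUV volume with an embedded box GTV; returns list(volume, gtv)
random_case <- function(n = 8L, seed = 1L) {
  set.seed(seed)
  g <- tiny_grid(n)
  vals <- array(runif(n^3, 0.1, 10), dim = rep(n, 3))
  member <- array(FALSE, dim = rep(n, 3))
  lo <- 2L; hi <- n - 1L
  member[lo:hi, lo:hi, lo:hi] <- TRUE
  list(volume = suv_volume(vals, g), gtv = roi_mask(member, g, "GTV"))
}

# dose_map directly from an array of Gy values
make_dose_map <- function(dose, grid, params = prescription_params()) {
  structure(list(grid = grid, dose = dose, params = params,
                 level_doses_gy = numeric(0)),
            class = "dose_map")
}

# independent per-voxel oracle for the level-bin rule:
# explicit loop, bin k iff boundaries[k] <= u < boundaries[k+1], top closed
brute_force_level_counts <- function(volume, gtv, cutoff_suv, n_levels) {
  max_suv <- max(volume$values[gtv$member])
  b <- seq(cutoff_suv / max_suv * 100, 100, length.out = n_levels + 1L)
  counts <- integer(n_levels)
  idx <- which(gtv$member)
  for (v in idx) {
    u <- volume$values[v] / max_suv * 100
    for (k in seq_len(n_levels)) {
      in_bin <- if (k == n_levels) u >= b[k] && u <= b[k + 1L]
                else u >= b[k] && u < b[k + 1L]
      if (in_bin) { counts[k] <- counts[k] + 1L; break }
    }
  }
  counts
}

small_phantom_params <- function(seed = 1L, ...) {
  phantom_params(shape = c(24, 24, 24), gtv_volume_ccm = 8, seed = seed, ...)
}
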