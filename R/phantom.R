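#' Parameters for the synthetic dual-tracer phantom
#'
#' The phantom emulates a co-registered dual-tracer PET case: an ellipsoidal
#' gross tumor volume with heterogeneous uptake, a muscle reference slab, and
#' two smooth tracer fields whose within-tumor spatial correlation is
#' controlled by `correlation_rho`. Defaults reproduce the cohort averages of
#' the canine study the pipeline is modeled on: GTV 63.3 ccm, SUV_max 12.5
#' for the glycolysis tracer (A) and 2.8 for the hypoxia tracer (B), on a
#' 2 mm isotropic grid.
#'
#' @param shape grid shape (voxels per axis); default `c(48, 48, 48)`.
#' @param spacing voxel spacing in mm; default 2 mm isotropic.
#' @param gtv_volume_ccm target GTV volume in ccm; default 63.3.
#' @param correlation_rho inter-tracer spatial correlation in `[-1, 1]`;
#'   default 0.5 (tracers partially co-localized).
#' @param smoothness_mm Gaussian correlation length of the uptake fields in
#'   mm; default 4.
#' @param suv_max_a,suv_max_b within-GTV SUV maxima of the two tracers;
#'   defaults 12.5 and 2.8. Must exceed `background_suv`.
#' @param background_suv muscle/background SUV level; default 0.7.
#' @param seed integer RNG seed; the phantom is bit-reproducible from it.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(48, 48, 48), spacing = c(2, 2, 2),
                           gtv_volume_ccm = 63.3, correlation_rho = 0.5,
                           smoothness_mm = 4, suv_max_a = 12.5,
                           suv_max_b = 2.8, background_suv = 0.7, seed = 1L) {
  grid <- image_grid(shape, spacing)
  if (abs(correlation_rho) > 1) stop("correlation_rho must lie in [-1, 1]")
  if (gtv_volume_ccm <= 0) stop("gtv_volume_ccm must be > 0")
  if (smoothness_mm <= 0) stop("smoothness_mm must be > 0")
  if (background_suv <= 0) stop("background_suv must be > 0")
  if (suv_max_a <= background_suv || suv_max_b <= background_suv)
    stop("suv_max values must exceed background_suv")
  structure(list(grid = grid, gtv_volume_ccm = gtv_volume_ccm,
                 correlation_rho = correlation_rho,
                 smoothness_mm = smoothness_mm,
                 suv_max_a = suv_max_a, suv_max_b = suv_max_b,
                 background_suv = background_suv, seed = as.integer(seed)),
            class = "phantom_params")
}

# Ellipsoid semi-axes (mm) with ratio 1 : 1.2 : 0.8 for a target volume.
# The flattened third (axial) axis makes single-slice top levels reachable.
ellipsoid_semiaxes_mm <- function(volume_ccm) {
  ratio <- c(1, 1.2, 0.8)
  a <- (volume_ccm * 1000 / (4 / 3 * pi * prod(ratio)))^(1 / 3)
  a * ratio
}

#' Generate a synthetic dual-tracer phantom case
#'
#' Construction: (1) the GTV is an ellipsoid (axis ratio 1:1.2:0.8) centred
#' in the grid, sized to `gtv_volume_ccm`; the muscle ROI is a disjoint slab
#' at the grid edge. (2) Three latent Gaussian random fields (Gaussian-
#' filtered white noise, standardized) with correlation length
#' `smoothness_mm` are mixed as
#' `Z_i = sqrt(|rho|) * s_i * L_shared + sqrt(1 - |rho|) * L_i`,
#' with `s_a = 1` and `s_b = sign(rho)`, so the two latent fields have
#' correlation exactly `rho`. (3) Inside the GTV the latent field passes
#' through a softplus map (strictly positive, monotone, preserves the field
#' topology) and is rescaled linearly so the within-GTV maximum equals the
#' requested `suv_max`; outside the GTV the SUV is the background level, with
#' 5% coefficient-of-variation noise over the muscle slab so tumor-to-muscle
#' cut-offs are well defined but nontrivial.
#'
#' The caller's RNG state is left untouched.
#'
#' @param params a [phantom_params].
#' @return An object of class `phantom_case` with fields `tracer_a`,
#'   `tracer_b` ([suv_volume]), `gtv`, `muscle` ([roi_mask]), the latent
#'   fields `latent_a`, `latent_b` (arrays), and `params`.
#' @export
generate_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  grid <- params$grid
  semi <- ellipsoid_semiaxes_mm(params$gtv_volume_ccm)
  half_extent_mm <- (grid$shape - 1) * grid$spacing / 2
  if (any(semi + grid$spacing > half_extent_mm))
    stop("GTV larger than grid: semi-axes ", paste(round(semi, 1), collapse = "/"),
         " mm do not fit")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed)

  # voxel-centre coordinates (mm) relative to the grid centre
  ax <- lapply(1:3, function(i) (seq_len(grid$shape[i]) - (grid$shape[i] + 1) / 2) * grid$spacing[i])
  r2 <- outer(outer((ax[[1]] / semi[1])^2, (ax[[2]] / semi[2])^2, `+`),
              (ax[[3]] / semi[3])^2, `+`)
  gtv <- roi_mask(r2 <= 1, grid, label = "GTV")

  muscle_member <- array(FALSE, dim = grid$shape)
  n_slab <- max(2L, min(3L, grid$shape[1]))
  muscle_member[seq_len(n_slab), , ] <- TRUE
  if (any(muscle_member & gtv$member))
    stop("muscle slab overlaps the GTV; enlarge the grid")
  muscle <- roi_mask(muscle_member, grid, label = "muscle")

  sigma_vox <- params$smoothness_mm / grid$spacing
  latent <- function() {
    f <- gaussian_smooth_3d(array(stats::rnorm(prod(grid$shape)), dim = grid$shape),
                            sigma_vox)
    (f - mean(f)) / stats::sd(f)
  }
  l_shared <- latent(); l_a <- latent(); l_b <- latent()
  rho <- params$correlation_rho
  w <- sqrt(abs(rho))
  z_a <- w * l_shared + sqrt(1 - abs(rho)) * l_a
  z_b <- w * sign(rho + (rho == 0)) * l_shared + sqrt(1 - abs(rho)) * l_b

  # one muscle-noise draw shared by both tracers, so rho = 1 with equal
  # suv_max yields bit-identical fields
  muscle_noise <- 1 + 0.05 * stats::rnorm(voxel_count(muscle))
  to_suv <- function(z, suv_max) {
    v <- array(params$background_suv, dim = grid$shape)
    v[muscle$member] <- pmax(params$background_suv * muscle_noise, 0.01)
    t <- log1p(exp(z[gtv$member]))  # softplus: positive, monotone
    t <- (t - min(t)) / (max(t) - min(t))
    v[gtv$member] <- params$background_suv + t * (suv_max - params$background_suv)
    suv_volume(v, grid)
  }
  tracer_a <- to_suv(z_a, params$suv_max_a)
  tracer_b <- to_suv(z_b, params$suv_max_b)

  structure(list(tracer_a = tracer_a, tracer_b = tracer_b,
                 gtv = gtv, muscle = muscle,
                 latent_a = z_a, latent_b = z_b, params = params),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("phantom_case: GTV %.1f ccm (%d voxels), rho = %.2f, SUV_max a/b = %.3g/%.3g, seed %d\n",
              volume_ccm(x$gtv), voxel_count(x$gtv), x$params$correlation_rho,
              max(x$tracer_a$values[x$gtv$member]),
              max(x$tracer_b$values[x$gtv$member]), x$params$seed))
  invisible(x)
}

#' Generate phantoms over a sweep of inter-tracer correlations
#'
#' All parameters other than `correlation_rho` — including the seed — are
#' held fixed, so differences along the sweep are attributable to the
#' correlation alone.
#'
#' @param base a [phantom_params].
#' @param rhos numeric vector of correlations in `[-1, 1]`.
#' @return list of `phantom_case`, one per element of `rhos`.
#' @export
make_correlation_sweep <- function(base, rhos) {
  stopifnot(inherits(base, "phantom_params"))
  if (length(rhos) && any(abs(rhos) > 1)) stop("all rhos must lie in [-1, 1]")
  lapply(rhos, function(r) {
    p <- base
    p$correlation_rho <- r
    generate_phantom(p)
  })
}

#' Cohort summary table of the modeled canine study
#'
#' Per-case tumor characteristics of the five-dog PET/CT cohort the phantom
#' generator is calibrated against: GTV volume, threshold-defined sub-volume
#' of each tracer/time point, and within-GTV SUV maxima. The last row
#' (`dog == "Avg."`) holds the column means.
#'
#' @return data.frame with columns `dog`, `tumor_type`, `localization`,
#'   `gtv_ccm`, `fdg_subvol_ccm`, `cu3_subvol_ccm`, `cu24_subvol_ccm`,
#'   `suv_max_fdg`, `suv_max_cu3`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "canine_cohort_summary.csv", package = "dosepaint",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
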