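#' Threshold specification for the dose-painting cut-off
#'
#' Three cut-off conventions are supported, following common PET practice:
#' `percent_max` (cut-off at a percentage of SUV_max within the GTV, the usual
#' FDG rule at 40%), `absolute_suv` (a fixed SUV, e.g. 1.4 for 3 h Cu-ATSM,
#' reflecting tumor hypoxia below ~10 mmHg oxygen tension), and
#' `tumor_to_muscle` (a multiple of the mean muscle SUV, used when no absolute
#' calibration exists, e.g. 24 h Cu-ATSM).
#'
#' @param method one of `"percent_max"`, `"absolute_suv"`, `"tumor_to_muscle"`.
#' @param value positive number: percent of SUV_max in (0, 100] for
#'   `percent_max`; an SUV for `absolute_suv`; a ratio for `tumor_to_muscle`.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(method = c("percent_max", "absolute_suv", "tumor_to_muscle"),
                           value) {
  method <- match.arg(method)
  value <- as.numeric(value)
  if (length(value) != 1L || !is.finite(value) || value <= 0)
    stop("threshold value must be a single positive number")
  if (method == "percent_max" && value > 100)
    stop("percent_max value must be in (0, 100]")
  structure(list(method = method, value = value), class = "threshold_spec")
}

#' Compute the absolute SUV cut-off for the high-risk sub-volume
#'
#' @param volume an [suv_volume].
#' @param gtv an [roi_mask] delineating the gross tumor volume (non-empty).
#' @param spec a [threshold_spec].
#' @param muscle an [roi_mask] of the muscle reference region; required (and
#'   non-empty) only for the `tumor_to_muscle` method. The reference statistic
#'   is the mean SUV over the muscle ROI.
#' @return the absolute SUV cut-off (positive scalar). If the cut-off is at or
#'   above the GTV SUV_max the result carries the attribute
#'   `empty_subvolume = TRUE` and a warning is issued: the high-risk
#'   sub-volume would be empty.
#' @export
compute_cutoff <- function(volume, gtv, spec, muscle = NULL) {
  stopifnot(inherits(volume, "suv_volume"), inherits(gtv, "roi_mask"),
            inherits(spec, "threshold_spec"))
  assert_same_grid(volume, gtv)
  if (voxel_count(gtv) == 0L) stop("GTV mask is empty")
  suv_max <- max(volume$values[gtv$member])
  cutoff <- switch(spec$method,
    percent_max = spec$value / 100 * suv_max,
    absolute_suv = spec$value,
    tumor_to_muscle = {
      if (is.null(muscle)) stop("tumor_to_muscle method requires a muscle mask")
      assert_same_grid(volume, muscle)
      if (voxel_count(muscle) == 0L) stop("muscle mask is empty")
      spec$value * mean(volume$values[muscle$member])
    })
  # at cutoff == suv_max the sub-volume is the (non-empty) argmax voxel set,
  # so only a strictly larger cut-off is flagged
  if (cutoff > suv_max) {
    warning(sprintf("cut-off %.4g >= GTV SUV_max %.4g: empty high-risk sub-volume",
                    cutoff, suv_max))
    attr(cutoff, "empty_subvolume") <- TRUE
  }
  cutoff
}

#' Partition the high-risk sub-volume into equal-width dose levels
#'
#' The sub-volume (GTV voxels with SUV at or above the cut-off) is divided
#' into `n_levels` bins of equal width in percent-of-SUV_max between the
#' cut-off percentage and 100. Bins are half-open `[lower, upper)` with the
#' top bin closed at 100, so a voxel exactly at the cut-off belongs to the
#' first level and the maximum-uptake voxel to the last. The bin midpoints
#' (in % of max) drive the dose prescription ([level_dose]).
#'
#' @param volume an [suv_volume].
#' @param gtv an [roi_mask]; assignment is restricted to GTV voxels.
#' @param cutoff_suv absolute SUV cut-off, strictly below the GTV SUV_max.
#' @param n_levels number of dose-escalation levels (default 5).
#' @return An object of class `dose_level_set` with fields `n_levels`,
#'   `cutoff_suv`, `cutoff_pct`, `max_suv`, `boundaries_pct` (length
#'   `n_levels + 1`), `iso_pct` (bin midpoints), `level_masks` (list of
#'   [roi_mask], labels `"DP1"`..), `dropped_levels` (empty until
#'   [drop_degenerate_levels]), and `grid`.
#' @export
build_dose_levels <- function(volume, gtv, cutoff_suv, n_levels = 5L) {
  stopifnot(inherits(volume, "suv_volume"), inherits(gtv, "roi_mask"))
  assert_same_grid(volume, gtv)
  n_levels <- as.integer(n_levels)
  if (n_levels < 1L) stop("n_levels must be >= 1")
  if (voxel_count(gtv) == 0L) stop("GTV mask is empty")
  cutoff_suv <- as.numeric(cutoff_suv)
  max_suv <- max(volume$values[gtv$member])
  if (cutoff_suv >= max_suv)
    stop("empty high-risk sub-volume: cut-off is at or above the GTV SUV_max")
  if (cutoff_suv <= 0) stop("cut-off must be positive")
  cutoff_pct <- cutoff_suv / max_suv * 100
  boundaries_pct <- seq(cutoff_pct, 100, length.out = n_levels + 1L)
  iso_pct <- (boundaries_pct[-1L] + boundaries_pct[-(n_levels + 1L)]) / 2

  pct <- volume$values / max_suv * 100
  # bin k: boundaries[k] <= u < boundaries[k+1]; top bin closed at 100
  assignment <- array(findInterval(pct, boundaries_pct, rightmost.closed = TRUE),
                      dim = dim(pct))
  assignment[!gtv$member] <- 0L
  assignment[assignment > n_levels] <- 0L  # GTV voxels below cut-off

  level_masks <- lapply(seq_len(n_levels), function(k)
    roi_mask(assignment == k, volume$grid, label = paste0("DP", k)))

  structure(list(n_levels = n_levels,
                 cutoff_suv = cutoff_suv,
                 cutoff_pct = cutoff_pct,
                 max_suv = max_suv,
                 boundaries_pct = boundaries_pct,
                 iso_pct = iso_pct,
                 level_masks = level_masks,
                 dropped_levels = integer(0),
                 grid = volume$grid),
            class = "dose_level_set")
}

#' @export
print.dose_level_set <- function(x, ...) {
  cat(sprintf("dose_level_set: %d levels, cut-off SUV %.3g (%.1f%% of max %.3g)\n",
              x$n_levels, x$cutoff_suv, x$cutoff_pct, x$max_suv))
  for (k in seq_len(x$n_levels)) {
    note <- if (k %in% x$dropped_levels) "  [dropped]" else ""
    cat(sprintf("  DP%d: [%.1f, %.1f)%% iso %.1f%%, %d voxels (%.2f ccm)%s\n",
                k, x$boundaries_pct[k], x$boundaries_pct[k + 1L], x$iso_pct[k],
                voxel_count(x$level_masks[[k]]), volume_ccm(x$level_masks[[k]]), note))
  }
  invisible(x)
}

#' Check a substructure for single-slice degeneracy
#'
#' A dose-level substructure confined to a single axial slice (third voxel
#' axis) is not a usable volume for arc-therapy optimization; in practice such
#' top levels are lost at plan transfer. A mask is valid when its voxels
#' occupy at least two distinct axial indices.
#'
#' @param mask an [roi_mask].
#' @return list with `valid` (logical) and `n_slices` (distinct axial indices
#'   occupied; 0 for an empty mask).
#' @export
check_substructure_validity <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  occupied <- apply(mask$member, 3L, any)
  n_slices <- sum(occupied)
  list(valid = n_slices > 1L, n_slices = as.integer(n_slices))
}

#' Drop single-slice dose levels and merge their voxels downward
#'
#' Each level failing [check_substructure_validity] (assessed on the levels as
#' built) is recorded in `dropped_levels`; its voxels are merged into the
#' nearest lower surviving level so they still receive an escalated dose, or
#' removed from the escalation (reverting to the base dose) when no lower
#' level survives. One message is emitted per dropped level naming the level
#' and its axial slice count.
#'
#' @param levels a `dose_level_set` from [build_dose_levels].
#' @return the updated `dose_level_set`.
#' @export
drop_degenerate_levels <- function(levels) {
  stopifnot(inherits(levels, "dose_level_set"))
  validity <- lapply(levels$level_masks, check_substructure_validity)
  valid <- vapply(validity, `[[`, logical(1), "valid")
  if (all(valid)) return(levels)
  dropped <- which(!valid)
  masks <- lapply(levels$level_masks, `[[`, "member")
  for (k in rev(dropped)) {
    target <- max(c(0L, which(valid[seq_len(k - 1L)])))
    if (target > 0L) {
      masks[[target]] <- masks[[target]] | masks[[k]]
      dest <- sprintf("voxels merged into DP%d", target)
    } else {
      dest <- "voxels revert to base dose"
    }
    message(sprintf("dropping degenerate dose level DP%d (%d axial slice(s)); %s",
                    k, validity[[k]]$n_slices, dest))
    masks[[k]] <- array(FALSE, dim = levels$grid$shape)
  }
  levels$level_masks <- lapply(seq_along(masks), function(k)
    roi_mask(masks[[k]], levels$grid, label = paste0("DP", k)))
  levels$dropped_levels <- dropped
  levels
}

#' Per-level volumes in ccm
#' @param levels a `dose_level_set`.
#' @return data.frame with columns `level` and `volume_ccm`.
#' @export
level_volumes <- function(levels) {
  data.frame(level = seq_len(levels$n_levels),
             volume_ccm = vapply(levels$level_masks, volume_ccm, numeric(1)))
}
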