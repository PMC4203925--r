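#' Joint 2D dose histogram of two prescription maps over the GTV
#'
#' Each GTV voxel contributes one count at (dose in plan A, dose in plan B).
#' Both axes share one set of equal-width bin edges spanning from just below
#' the smallest to just above the largest GTV dose of either map. Bins are
#' half-open `[lower, upper)` with the top bin closed, so every voxel is
#' counted exactly once.
#'
#' @param map_a,map_b `dose_map` objects on one grid.
#' @param gtv an [roi_mask] (non-empty).
#' @param bin_width_gy bin width in Gy; default 0.5, which resolves the six
#'   discrete prescription doses of a five-level plan without empty-bin noise.
#' @return An object of class `joint_dose_histogram` with `bin_edges_gy`,
#'   `counts` (matrix, rows = map A bins), and `n_voxels`.
#' @export
joint_dose_histogram <- function(map_a, map_b, gtv, bin_width_gy = 0.5) {
  stopifnot(inherits(map_a, "dose_map"), inherits(map_b, "dose_map"),
            inherits(gtv, "roi_mask"))
  assert_same_grid(map_a, map_b); assert_same_grid(map_a, gtv)
  if (bin_width_gy <= 0) stop("bin_width_gy must be > 0")
  if (voxel_count(gtv) == 0L) stop("GTV mask is empty")
  da <- map_a$dose[gtv$member]
  db <- map_b$dose[gtv$member]
  lo <- min(da, db) - bin_width_gy
  hi <- max(da, db) + bin_width_gy
  nb <- ceiling((hi - lo) / bin_width_gy)
  edges <- lo + bin_width_gy * seq.int(0L, nb)
  ia <- findInterval(da, edges, rightmost.closed = TRUE)
  ib <- findInterval(db, edges, rightmost.closed = TRUE)
  counts <- matrix(0L, nb, nb)
  for (v in seq_along(ia)) counts[ia[v], ib[v]] <- counts[ia[v], ib[v]] + 1L
  structure(list(bin_edges_gy = edges, counts = counts, n_voxels = length(da)),
            class = "joint_dose_histogram")
}

#' Quality volume histogram (QVH) of two prescription maps
#'
#' The quality index (QI) at a voxel is the ratio of the two planned doses,
#' numerator plan A ("covering" plan) over denominator plan B (reference
#' plan). The QVH curve gives, for each ratio threshold x on a fixed grid
#' from 0 to 2 in steps of 0.001, the fraction of GTV voxels with QI >= x —
#' the dose-volume-histogram convention applied to the ratio. A voxel is
#' satisfactory when its QI lies in the closed band (default [0.95, 1.05]);
#' `qi_fraction` is the fraction of satisfactory voxels, 1 for a perfect
#' match.
#'
#' @param map_a,map_b `dose_map` objects on one grid; numerator/denominator.
#' @param gtv an [roi_mask]; every GTV voxel of `map_b` must have dose > 0
#'   (guaranteed for prescription maps, which assign at least the base dose).
#' @param band closed acceptance interval for the ratio; default
#'   `c(0.95, 1.05)`.
#' @return An object of class `qvh_result` with `ratios`, `curve`
#'   (data.frame: `ratio`, `fraction`), `qi_fraction`, `band`.
#' @export
qvh <- function(map_a, map_b, gtv, band = c(0.95, 1.05)) {
  stopifnot(inherits(map_a, "dose_map"), inherits(map_b, "dose_map"),
            inherits(gtv, "roi_mask"))
  assert_same_grid(map_a, map_b); assert_same_grid(map_a, gtv)
  if (length(band) != 2L || band[1] > band[2]) stop("band must be ascending (low, high)")
  if (voxel_count(gtv) == 0L) stop("GTV mask is empty")
  da <- map_a$dose[gtv$member]
  db <- map_b$dose[gtv$member]
  if (any(db <= 0))
    stop("zero dose in the denominator map inside the GTV: not a prescription map")
  ratios <- da / db
  xs <- seq(0, 2, by = 0.001)
  sr <- sort(ratios)
  n <- length(sr)
  # fraction of voxels with ratio >= x  (count of sr < x via left-open search)
  frac <- (n - findInterval(xs, sr, left.open = TRUE)) / n
  qi_fraction <- mean(ratios >= band[1] & ratios <= band[2])
  structure(list(ratios = ratios,
                 curve = data.frame(ratio = xs, fraction = frac),
                 qi_fraction = qi_fraction,
                 band = band),
            class = "qvh_result")
}

#' Dice overlap of two dose-level sets, level by level
#'
#' Dice coefficient `2|A & B| / (|A| + |B|)` between corresponding dose
#' levels of two plans. In `bin` mode (default) the per-level masks are
#' compared; in `cumulative` mode the super-threshold unions of levels >= k.
#' When both masks of a level are empty the coefficient is undefined and
#' reported as `NA` (never 0/0 coerced to agreement) — this happens when a
#' top level vanished in both plans.
#'
#' @param levels_a,levels_b `dose_level_set` objects on one grid with equal
#'   `n_levels`.
#' @param mode `"bin"` or `"cumulative"`.
#' @return An object of class `dice_result`: data.frame `per_level` with
#'   columns `level`, `dice` (`NA` when undefined), plus the `mode`.
#' @export
dice_per_level <- function(levels_a, levels_b, mode = c("bin", "cumulative")) {
  stopifnot(inherits(levels_a, "dose_level_set"), inherits(levels_b, "dose_level_set"))
  mode <- match.arg(mode)
  assert_same_grid(levels_a, levels_b)
  if (levels_a$n_levels != levels_b$n_levels)
    stop("dose level sets have different n_levels")
  n <- levels_a$n_levels
  mask_at <- function(lv, k) {
    if (mode == "bin") return(lv$level_masks[[k]]$member)
    Reduce(`|`, lapply(k:n, function(j) lv$level_masks[[j]]$member))
  }
  dice <- vapply(seq_len(n), function(k) {
    a <- mask_at(levels_a, k); b <- mask_at(levels_b, k)
    na <- sum(a); nb <- sum(b)
    if (na + nb == 0L) return(NA_real_)
    2 * sum(a & b) / (na + nb)
  }, numeric(1))
  structure(list(per_level = data.frame(level = seq_len(n), dice = dice),
                 mode = mode),
            class = "dice_result")
}

#' Full comparison of two dose-painting plans
#'
#' Bundles the joint 2D dose histogram, QVH with QI fraction, and per-level
#' Dice coefficients for a pair of prescription maps over a common GTV,
#' together with summary scalars.
#'
#' @param map_a,map_b `dose_map` objects (A is the QVH numerator).
#' @param levels_a,levels_b the corresponding `dose_level_set`s.
#' @param gtv an [roi_mask].
#' @param config list of settings: `band` (default `c(0.95, 1.05)`),
#'   `bin_width_gy` (0.5), `dice_mode` (`"bin"`), `case_id` (`""`).
#' @return An object of class `comparison_report`.
#' @export
compare_plans <- function(map_a, levels_a, map_b, levels_b, gtv,
                          config = list()) {
  cfg <- utils::modifyList(list(band = c(0.95, 1.05), bin_width_gy = 0.5,
                                dice_mode = "bin", case_id = ""), config)
  hist <- joint_dose_histogram(map_a, map_b, gtv, cfg$bin_width_gy)
  q <- qvh(map_a, map_b, gtv, cfg$band)
  d <- dice_per_level(levels_a, levels_b, cfg$dice_mode)
  summary <- list(
    case_id = cfg$case_id,
    qi_fraction = q$qi_fraction,
    mean_dose_a_gy = mean(map_a$dose[gtv$member]),
    mean_dose_b_gy = mean(map_b$dose[gtv$member]),
    n_voxels = voxel_count(gtv),
    level_volumes_a_ccm = level_volumes(levels_a)$volume_ccm,
    level_volumes_b_ccm = level_volumes(levels_b)$volume_ccm)
  structure(list(histogram = hist, qvh = q, dice = d, summary = summary,
                 config = cfg),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report%s: %d GTV voxels\n",
              if (nzchar(x$summary$case_id)) paste0(" [", x$summary$case_id, "]") else "",
              x$summary$n_voxels))
  cat(sprintf("  QI fraction in [%.2f, %.2f]: %.2f\n",
              x$qvh$band[1], x$qvh$band[2], x$qvh$qi_fraction))
  d <- x$dice$per_level
  cat(sprintf("  Dice (%s): %s\n", x$dice$mode,
              paste(sprintf("DP%d=%.2f", d$level, d$dice), collapse = " ")))
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' Schema: `{case_id, qi_fraction, band, dice: [{level, value|null}, ...],
#' histogram: {edges, counts}, qvh_curve: [[x, fraction], ...]}`.
#'
#' @param report a `comparison_report`.
#' @param path output path (`.json`).
#' @return invisibly `path`.
#' @export
write_comparison_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  d <- report$dice$per_level
  obj <- list(
    case_id = report$summary$case_id,
    qi_fraction = report$qvh$qi_fraction,
    band = report$qvh$band,
    dice = lapply(seq_len(nrow(d)), function(i)
      list(level = d$level[i],
           value = if (is.na(d$dice[i])) NULL else d$dice[i])),
    dice_mode = report$dice$mode,
    mean_dose_a_gy = report$summary$mean_dose_a_gy,
    mean_dose_b_gy = report$summary$mean_dose_b_gy,
    n_voxels = report$summary$n_voxels,
    histogram = list(edges = report$histogram$bin_edges_gy,
                     counts = report$histogram$counts),
    qvh_curve = unname(as.matrix(report$qvh$curve)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
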