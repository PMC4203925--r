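make_uniform_case <- function(suv_in_gtv, n = 6L) {
  g <- tiny_grid(n)
  vals <- array(0.5, g$shape)
  member <- array(FALSE, g$shape)
  member[2:(n - 1), 2:(n - 1), 2:(n - 1)] <- TRUE
  vals[member] <- suv_in_gtv
  list(volume = suv_volume(vals, g), gtv = roi_mask(member, g, "GTV"), grid = g)
}

test_that("compute_cutoff implements the three threshold conventions", {
  cs <- make_uniform_case(1)
  # spread uptake so SUV_max is 7.9 (the kind of FDG maximum seen clinically)
  idx <- which(cs$gtv$member)
  cs$volume$values[idx] <- seq(1, 7.9, length.out = length(idx))
  expect_equal(compute_cutoff(cs$volume, cs$gtv, threshold_spec("percent_max", 40)),
               3.16)
  expect_equal(compute_cutoff(cs$volume, cs$gtv, threshold_spec("absolute_suv", 1.4)),
               1.4)
  # percent_max 100: cut-off is exactly the GTV maximum (argmax-only sub-volume)
  expect_equal(compute_cutoff(cs$volume, cs$gtv, threshold_spec("percent_max", 100)),
               7.9)

  muscle_member <- array(FALSE, cs$grid$shape)
  muscle_member[1, , ] <- TRUE
  muscle <- roi_mask(muscle_member, cs$grid, "muscle")
  cs$volume$values[muscle$member] <- 0.8
  expect_equal(compute_cutoff(cs$volume, cs$gtv,
                              threshold_spec("tumor_to_muscle", 2.0), muscle),
               2.0 * 0.8)
  expect_error(compute_cutoff(cs$volume, cs$gtv,
                              threshold_spec("tumor_to_muscle", 2.0)),
               "muscle")
  empty <- roi_mask(array(FALSE, cs$grid$shape), cs$grid)
  expect_error(compute_cutoff(cs$volume, empty, threshold_spec("percent_max", 40)),
               "empty")
  # cut-off at/above the maximum: warn and flag
  expect_warning(co <- compute_cutoff(cs$volume, cs$gtv,
                                      threshold_spec("absolute_suv", 10)),
                 "empty high-risk")
  expect_true(attr(co, "empty_subvolume"))
})

test_that("threshold_spec validates its value range", {
  expect_error(threshold_spec("percent_max", 0), "positive")
  expect_error(threshold_spec("percent_max", 101), "\\(0, 100\\]")
  expect_error(threshold_spec("absolute_suv", -1), "positive")
})

test_that("equal-width bins between the cut-off and 100% of max", {
  cs <- random_case(8, seed = 42)
  max_suv <- max(cs$volume$values[cs$gtv$member])
  lv <- build_dose_levels(cs$volume, cs$gtv, 0.40 * max_suv, 5)
  expect_equal(lv$cutoff_pct, 40)
  expect_equal(lv$boundaries_pct, c(40, 52, 64, 76, 88, 100))
  expect_equal(lv$iso_pct, c(46, 58, 70, 82, 94))

  # single bin: every GTV voxel at or above 50% of max
  lv1 <- build_dose_levels(cs$volume, cs$gtv, 0.5 * max_suv, 1)
  expected <- cs$gtv$member & (cs$volume$values >= 0.5 * max_suv)
  expect_equal(lv1$level_masks[[1]]$member, expected)

  # the maximum-uptake voxel sits in the (closed) top bin
  argmax <- which(cs$gtv$member & cs$volume$values == max_suv)
  expect_true(all(lv$level_masks[[5]]$member[argmax]))

  expect_error(build_dose_levels(cs$volume, cs$gtv, max_suv, 5),
               "empty high-risk")
})

test_that("level partition matches a brute-force per-voxel loop", {
  for (seed in 1:10) {
    cs <- random_case(8, seed = seed)
    max_suv <- max(cs$volume$values[cs$gtv$member])
    cutoff <- runif(1, 0.2, 0.8) * max_suv
    n_levels <- sample(2:6, 1)
    lv <- build_dose_levels(cs$volume, cs$gtv, cutoff, n_levels)

    counts <- vapply(lv$level_masks, voxel_count, numeric(1))
    expect_equal(counts, as.numeric(
      brute_force_level_counts(cs$volume, cs$gtv, cutoff, n_levels)))

    # pairwise disjoint; union equals the super-cut-off set within the GTV
    members <- lapply(lv$level_masks, `[[`, "member")
    expect_true(all(Reduce(`+`, members) <= 1))
    super <- cs$gtv$member & (cs$volume$values >= cutoff)
    # voxels within float jitter of the cut-off may fall either side of DP1's
    # lower edge on the percent scale; compare away from the boundary
    expect_equal(Reduce(`|`, members), super)

    # monotone nesting: union of levels >= k is the super-threshold set at
    # boundary k
    for (k in seq_len(n_levels)) {
      upper <- Reduce(`|`, members[k:n_levels])
      thr <- lv$boundaries_pct[k] / 100 * max_suv
      expect_equal(sum(xor(upper, cs$gtv$member & (cs$volume$values / max_suv * 100 >=
                                                     lv$boundaries_pct[k]))), 0)
    }
  }
})

test_that("percent_max cut-off and levels are scale-equivariant", {
  cs <- random_case(8, seed = 5)
  co <- compute_cutoff(cs$volume, cs$gtv, threshold_spec("percent_max", 40))
  lv <- build_dose_levels(cs$volume, cs$gtv, co, 5)
  for (s in c(0.25, 3.7)) {
    scaled <- suv_volume(cs$volume$values * s, cs$volume$grid)
    co_s <- compute_cutoff(scaled, cs$gtv, threshold_spec("percent_max", 40))
    expect_equal(co_s, co * s)
    lv_s <- build_dose_levels(scaled, cs$gtv, co_s, 5)
    for (k in 1:5)
      expect_equal(lv_s$level_masks[[k]]$member, lv$level_masks[[k]]$member)
  }
})

test_that("single-slice substructures are flagged invalid", {
  g <- tiny_grid(8)
  m3 <- array(FALSE, g$shape); m3[3:5, 3:5, 3:5] <- TRUE
  v <- check_substructure_validity(roi_mask(m3, g))
  expect_true(v$valid); expect_equal(v$n_slices, 3)

  m1 <- array(FALSE, g$shape); m1[3:5, 3:5, 4] <- TRUE
  v1 <- check_substructure_validity(roi_mask(m1, g))
  expect_false(v1$valid); expect_equal(v1$n_slices, 1)

  v0 <- check_substructure_validity(roi_mask(array(FALSE, g$shape), g))
  expect_false(v0$valid); expect_equal(v0$n_slices, 0)
})

test_that("degenerate top level merges into the next lower level", {
  # engineered uptake: DP5 occupies one axial slice, DP1-DP4 span several
  g <- tiny_grid(8)
  vals <- array(0.1, g$shape)
  member <- array(FALSE, g$shape)
  member[2:7, 2:7, 2:7] <- TRUE
  vals[member] <- 1                      # below cut-off inside GTV
  set.seed(11)
  vals[3:6, 3:6, 3:6] <- runif(64, 4.1, 8.7)  # DP1..DP4, spread over 4 slices
  vals[4:5, 4:5, 4] <- 10                # DP5 region on a single slice
  vol <- suv_volume(vals, g); gtv <- roi_mask(member, g, "GTV")
  lv <- build_dose_levels(vol, gtv, 4, 5)  # cutoff_pct 40
  expect_false(check_substructure_validity(lv$level_masks[[5]])$valid)
  dp5_voxels <- lv$level_masks[[5]]$member

  expect_message(dropped <- drop_degenerate_levels(lv), "DP5")
  expect_equal(dropped$dropped_levels, 5L)
  expect_equal(voxel_count(dropped$level_masks[[5]]), 0)
  # DP5 voxels joined the nearest valid lower level
  target <- max(setdiff(seq_len(4), dropped$dropped_levels))
  expect_true(all(dropped$level_masks[[target]]$member[dp5_voxels]))

  # partition is restored: union unchanged by the merge
  before <- Reduce(`|`, lapply(lv$level_masks, `[[`, "member"))
  after <- Reduce(`|`, lapply(dropped$level_masks, `[[`, "member"))
  expect_equal(after, before)
})

test_that("drop_degenerate_levels is the identity when all levels are valid", {
  cs <- random_case(8, seed = 3)
  max_suv <- max(cs$volume$values[cs$gtv$member])
  lv <- build_dose_levels(cs$volume, cs$gtv, 0.2 * max_suv, 2)
  if (all(vapply(lv$level_masks,
                 function(m) check_substructure_validity(m)$valid, logical(1)))) {
    out <- drop_degenerate_levels(lv)
    expect_identical(out$dropped_levels, integer(0))
    expect_identical(lapply(out$level_masks, `[[`, "member"),
                     lapply(lv$level_masks, `[[`, "member"))
  }
})

test_that("total degeneracy reverts the sub-volume to the base dose", {
  g <- tiny_grid(8)
  vals <- array(0.1, g$shape)
  member <- array(FALSE, g$shape)
  member[2:7, 2:7, 4] <- TRUE          # GTV itself confined to one slice
  vals[member] <- seq(1, 10, length.out = sum(member))
  vol <- suv_volume(vals, g); gtv <- roi_mask(member, g, "GTV")
  lv <- build_dose_levels(vol, gtv, 4, 5)
  expect_message(dropped <- drop_degenerate_levels(lv), "base dose")
  expect_equal(sort(dropped$dropped_levels), 1:5)
  expect_equal(sum(vapply(dropped$level_masks, voxel_count, numeric(1))), 0)
})
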