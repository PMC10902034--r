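ref_design <- y_design()

test_that("segmentation recovers bimodal masks under either polarity", {
  truth <- rasterize_design(ref_design, 8)$pixels
  img <- 0.2 + 0.6 * truth
  expect_identical(as_mask_px(segment_culture(img)), truth)
  expect_identical(as_mask_px(segment_culture(0.8 - 0.6 * truth,
                                              polarity = "dark")), truth)
  expect_error(segment_culture(matrix(0.5, 5, 5)), "constant")
})

test_that("segmentation of a rendered scene matches ground truth (Jaccard >= 0.95)", {
  sc <- generate_scene(scene_params(seed = 21))
  truth <- sc$culture_mask$pixels
  img <- withr::with_seed(1, 0.25 + 0.5 * truth +
                            matrix(rnorm(length(truth), 0, 0.05),
                                   nrow(truth)))
  got <- as_mask_px(segment_culture(bpq::image_grid(img, 4)))
  jac <- sum(got & truth) / sum(got | truth)
  expect_gte(jac, 0.95)
})

test_that("growth expansion: identity masks give unit ratios everywhere", {
  m <- rasterize_design(ref_design, 8)
  part <- partition_regions(m, ref_design, 0.3)
  gr <- growth_expansion(m, m, part)
  expect_true(all(gr$expansion_ratio == 1))
  expect_true(all(gr$percent_change == 0))
})

test_that("growth confined to one tip region only moves that ratio", {
  m3 <- rasterize_design(ref_design, 8)
  part <- partition_regions(m3, ref_design, 0.3)
  m14 <- m3
  # disjoint addition beyond the stem's free endpoint -> tip_stem territory
  sk <- design_skeleton(ref_design)
  bi <- which.min(abs(bpq:::grid_y(m3) - (sk["stem", "y1"] + 40)))
  bj <- which.min(abs(bpq:::grid_x(m3) - sk["stem", "x1"]))
  m14$pixels[(bi - 4):(bi + 4), (bj - 4):(bj + 4)] <- TRUE
  part2 <- partition_regions(m14, ref_design, 0.3)
  gr <- growth_expansion(m3, m14, part2)
  r <- setNames(gr$expansion_ratio, gr$region)
  expect_gt(r[["tip_stem"]], 1)
  expect_equal(r[["trunk"]], 1)
  expect_equal(r[["tip_left"]], 1)
  expect_equal(r[["tip_right"]], 1)
})

test_that("growth on a synthetic timecourse reproduces the pixel-count oracle", {
  tc <- generate_timecourse(day3_scene_params(seed = 13),
                            scene_params(seed = 13))
  part <- partition_regions(tc$day14$culture_mask, ref_design, 0.3)
  gr <- growth_expansion(tc$day3$culture_mask, tc$day14$culture_mask, part)
  r <- setNames(gr$expansion_ratio, gr$region)
  # oracle: direct pixel counting on the ground-truth label map
  for (code in 1:4) {
    nm <- names(bpq:::.LABELS)[bpq:::.LABELS == code]
    o3 <- sum(tc$day3$culture_mask$pixels & part$labels == code)
    o14 <- sum(tc$day14$culture_mask$pixels & part$labels == code)
    expect_equal(r[[nm]], o14 / o3)
  }
  expect_gt(r[["tips"]], r[["trunk"]])
})

test_that("opening-based extraction leaves a clean Y untouched", {
  m <- rasterize_design(ref_design, 4)
  ext <- extract_invasion(m, 7.5, 10)
  expect_equal(sum(ext$invasion_mask$pixels), 0)
  expect_identical(ext$main_mask$pixels, m$pixels)
  # idempotence: re-extracting from the main mask finds nothing
  ext2 <- extract_invasion(ext$main_mask, 7.5, 10)
  expect_equal(sum(ext2$invasion_mask$pixels), 0)
  expect_error(extract_invasion(m, 40), "radius")
})

test_that("a 20 um protrusion is fully extracted and areas are conserved", {
  ps <- 4
  m <- rasterize_design(ref_design, ps)
  sk <- design_skeleton(ref_design)
  # horizontal tube width 20 um (5 px) sticking out of the trunk's side
  ri <- which.min(abs(bpq:::grid_y(m) - 500))
  cj <- which.min(abs(bpq:::grid_x(m) - 50))
  tube_rows <- (ri - 2):(ri + 2)
  tube_cols <- cj:(cj + 20)
  m$pixels[tube_rows, tube_cols] <- TRUE
  radius_px <- 11 / ps + 1
  ext <- extract_invasion(m, radius_px, 5)
  tube_outside <- m$pixels
  tube_outside[] <- FALSE
  tube_outside[tube_rows, tube_cols] <- TRUE
  ymask <- rasterize_design(ref_design, ps)$pixels
  # the tube base blends into the main stroke within one opening radius;
  # beyond that reach every tube pixel must land in the invasion mask
  tube_far <- tube_outside & !ymask &
    bpq:::cpp_edt_sq(ymask) > (radius_px + 1)^2
  expect_gt(sum(tube_far), 30)
  expect_true(all(ext$invasion_mask$pixels[tube_far]))
  # conservation: main + invasion + discarded == original foreground
  expect_identical(sum(ext$main_mask$pixels) + sum(ext$invasion_mask$pixels) +
                     ext$discarded_px, sum(m$pixels))
  # agreement with the brute-force opening oracle
  expect_identical(ext$main_mask$pixels | ext$invasion_mask$pixels |
                     (m$pixels & !binary_opening(m$pixels, radius_px)),
                   m$pixels)
})

test_that("per-region invasion normalization behaves and is scale-consistent", {
  for (ps in c(4, 8)) {
    sc <- generate_scene(dcis_scene_params(seed = 17, pixel_size = ps))
    part <- partition_regions(sc$culture_mask, ref_design, 0.3)
    ext <- extract_invasion(sc$culture_mask, 30 / ps, 160 / ps^2)
    ir <- invasion_per_region(ext, partition = part)
    ni <- setNames(ir$normalized_invasion, ir$group)
    if (ps == 4) ni4 <- ni else
      expect_equal(unname(ni), unname(ni4), tolerance = 0.25)
    expect_gt(ni[["trunk"]], ni[["tips"]])
  }
  # empty invasion mask -> all zeros
  m <- rasterize_design(ref_design, 8)
  part <- partition_regions(m, ref_design, 0.3)
  empty <- bpq:::grid_like(m, matrix(FALSE, nrow(m$pixels), ncol(m$pixels)))
  ir0 <- invasion_per_region(empty, m, part)
  expect_true(all(ir0$normalized_invasion == 0))
})

test_that("ki67 ratio: trivial channels and planted-fraction recovery", {
  sc <- generate_scene(scene_params(seed = 19))
  part <- partition_regions(sc$culture_mask, ref_design, 0.3)
  same <- ki67_ratio(sc$dapi, sc$dapi, part)
  expect_true(all(same$ratio == 1))
  blank <- bpq:::grid_like(sc$dapi, matrix(0, nrow(sc$dapi$pixels),
                                           ncol(sc$dapi$pixels)))
  none <- ki67_ratio(sc$dapi, blank, part)
  expect_true(all(none$ratio == 0))
  kr <- ki67_ratio(sc$dapi, sc$ki67, part)
  got <- setNames(kr$ratio, kr$region)
  planted <- sc$ground_truth$ki67_fraction
  for (nm in names(planted))
    expect_lt(abs(got[[nm]] - planted[[nm]]), 0.05)
  expect_lt(abs(got[["tips"]] - sc$ground_truth$ki67_fraction_group[["tips"]]),
            0.05)
  expect_true(all(kr$ratio >= 0 & kr$ratio <= 1))
})

test_that("ki67 reports are mirror-equivariant", {
  sc <- generate_scene(scene_params(seed = 23))
  part <- partition_regions(sc$culture_mask, ref_design, 0.3)
  kr <- ki67_ratio(sc$dapi, sc$ki67, part)
  partm <- partition_regions(mirror_grid(sc$culture_mask), ref_design, 0.3)
  krm <- ki67_ratio(mirror_grid(sc$dapi), mirror_grid(sc$ki67), partm)
  g <- setNames(kr$ratio, kr$region); gm <- setNames(krm$ratio, krm$region)
  expect_equal(gm[["tip_left"]], g[["tip_right"]])
  expect_equal(gm[["tip_right"]], g[["tip_left"]])
  expect_equal(gm[["tip_stem"]], g[["tip_stem"]])
  expect_equal(gm[["trunk"]], g[["trunk"]])
})

test_that("viability: trivial channels and planted dead fraction", {
  sc <- generate_scene(viability_scene_params(seed = 29))
  blank <- bpq:::grid_like(sc$pi, matrix(0, nrow(sc$pi$pixels),
                                         ncol(sc$pi$pixels)))
  expect_equal(viability(sc$dapi, blank)$viability_percent, 100)
  thr <- otsu_threshold(sc$dapi$pixels)
  all_dead <- viability(sc$dapi, sc$dapi, pi_threshold = thr)
  expect_equal(all_dead$viability_percent, 0)
  v <- viability(sc$dapi, sc$pi)
  expect_gte(v$n_nuclei, 500)
  expect_lt(abs(v$viability_percent - sc$ground_truth$viability_percent), 2)
  expect_error(viability(blank, blank), "constant|no nuclei")
})

test_that("confluence series normalizes to the first frame", {
  f1 <- matrix(FALSE, 20, 20); f1[1:10, ] <- TRUE
  f2 <- matrix(TRUE, 20, 20)
  cs <- confluence_series(list(f1, f1, f2), c(0, 4, 8))
  expect_equal(cs$normalized, c(1, 1, 2))
  grow <- confluence_series(list(f1, f1 | rbind(f1[-1, ], FALSE), f2),
                            c(0, 4, 8))
  expect_true(all(diff(grow$normalized) >= 0))
  expect_error(confluence_series(list(f1, f2), c(0, -1)), "increasing")
  expect_error(confluence_series(list(matrix(FALSE, 5, 5)), 0), "zero confluence")
})
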