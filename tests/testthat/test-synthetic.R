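test_that("unit growth factors and no protrusions reproduce the rasterized design", {
  p <- scene_params(growth_factor_tip_stem = 1, growth_factor_tip_branch = 1,
                    growth_factor_trunk = 1, protrusion_count = 0, seed = 4)
  sc <- generate_scene(p)
  ref <- rasterize_design(p$design, p$pixel_size, p$margin)
  expect_identical(sc$culture_mask$pixels, ref$pixels)
})

test_that("scenes are bit-identical for the same seed and differ across seeds", {
  s1 <- generate_scene(scene_params(seed = 5))
  s2 <- generate_scene(scene_params(seed = 5))
  s3 <- generate_scene(scene_params(seed = 6))
  expect_identical(s1$culture_mask$pixels, s2$culture_mask$pixels)
  expect_identical(s1$dapi$pixels, s2$dapi$pixels)
  expect_identical(s1$ground_truth, s2$ground_truth)
  expect_false(identical(s1$dapi$pixels, s3$dapi$pixels))
})

test_that("ground truth bookkeeping is pixel-exact", {
  sc <- generate_scene(scene_params(seed = 8))
  px2 <- sc$params$pixel_size^2
  a <- sc$ground_truth$region_areas_um2
  expect_equal(sum(a[c("trunk", "tip_stem", "tip_left", "tip_right")]),
               sum(sc$culture_mask$pixels) * px2)
  expect_identical(sum(sc$labels > 0), sum(sc$culture_mask$pixels))
  expect_equal(a[["tips"]], sum(a[c("tip_stem", "tip_left", "tip_right")]))
})

test_that("planted Ki67 fractions fall within their binomial intervals", {
  p <- scene_params(ki67_fraction = c(tip_stem = 0.5, tip_left = 0.5,
                                      tip_right = 0.5, trunk = 0.1),
                    seed = 12)
  sc <- generate_scene(p)
  expect_gte(sc$ground_truth$n_nuclei, 500)
  got <- sc$ground_truth$ki67_fraction_group
  grp <- ifelse(sc$nuclei$region == "trunk", "trunk", "tips")
  n_grp <- table(grp)
  expect_lt(abs(got[["trunk"]] - 0.1),
            1.96 * sqrt(0.1 * 0.9 / n_grp[["trunk"]]))
  expect_lt(abs(got[["tips"]] - 0.5),
            1.96 * sqrt(0.25 / n_grp[["tips"]]))
})

test_that("timecourse masks are nested and reduce to equality for equal params", {
  tc <- generate_timecourse(day3_scene_params(seed = 2), scene_params(seed = 2))
  expect_true(all(tc$day14$culture_mask$pixels | !tc$day3$culture_mask$pixels))
  same <- generate_timecourse(day3_scene_params(seed = 3),
                              day3_scene_params(seed = 3))
  expect_identical(same$day3$culture_mask$pixels,
                   same$day14$culture_mask$pixels)
  expect_error(
    generate_timecourse(scene_params(seed = 1), day3_scene_params(seed = 1)),
    "monotone")
})

test_that("a growth factor of 2 doubles the maximal outward extent", {
  base <- day3_scene_params(growth_factor_tip_stem = 1,
                            growth_factor_tip_branch = 1,
                            growth_factor_trunk = 1, seed = 1)
  grown <- day3_scene_params(growth_factor_tip_stem = 2,
                             growth_factor_tip_branch = 2,
                             growth_factor_trunk = 2, seed = 1)
  tc <- generate_timecourse(base, grown)
  d <- tc$day3$params$design
  reach <- function(scene) {
    m <- scene$culture_mask
    idx <- which(m$pixels)
    ri <- (idx - 1) %% nrow(m$pixels) + 1
    ci <- (idx - 1) %/% nrow(m$pixels) + 1
    ns <- bpq:::nearest_segment(bpq:::grid_x(m)[ci], bpq:::grid_y(m)[ri], d)
    max(ns$dist)
  }
  expect_equal(reach(tc$day14), 2 * reach(tc$day3),
               tolerance = 2 * tc$day3$params$pixel_size / 100)
})

test_that("protrusion placement follows the region weights", {
  inv <- sapply(1:6, function(s) {
    sc <- generate_scene(dcis_scene_params(seed = s))
    sc$ground_truth$invasion_area_um2
  })
  # trunk-weighted mode plants most invasion area at the trunk
  expect_gt(mean(inv["trunk", ] > inv["tips", ]), 0.8)
})

test_that("parameter validation catches inconsistent settings", {
  expect_error(scene_params(growth_factor_trunk = 0.5), ">= 1")
  expect_error(scene_params(dead_fraction = 1.5), "dead_fraction")
  expect_error(scene_params(ki67_fraction = c(tips = 0.5, trunk = 0.1)),
               "ki67_fraction")
  expect_error(scene_params(protrusion_region_weights = c(tips = 0.5,
                                                          trunk = 0.2)),
               "sum to 1")
  expect_error(generate_scene(scene_params(nuclei_density = 1e-9)),
               "zero nuclei")
})

test_that("scenes round-trip to a directory of plain-text files", {
  sc <- generate_scene(viability_scene_params(seed = 1))
  dir <- file.path(tempdir(), "scene_rt")
  write_scene(sc, dir)
  expect_true(all(file.exists(file.path(dir,
    c("mask.pgm", "labels.pgm", "dapi.pgm", "ki67.pgm", "pi.pgm",
      "ground_truth.json")))))
  back <- read_pgm(file.path(dir, "mask.pgm"))
  expect_identical(back$pixels > 0, sc$culture_mask$pixels)
  expect_equal(back$pixel_size, sc$culture_mask$pixel_size)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$n_nuclei, sc$ground_truth$n_nuclei)
})
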