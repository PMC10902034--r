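test_that("y_design validates its arguments and names the offending field", {
  expect_s3_class(y_design(), "y_design")
  expect_error(y_design(stem_length = 0), "stem_length")
  expect_error(y_design(branch_length = -5), "branch_length")
  expect_error(y_design(stroke_width = 0), "stroke_width")
  expect_error(y_design(branch_angle = 0), "branch_angle")
  expect_error(y_design(branch_angle = 180), "branch_angle")
})

test_that("skeleton has three segments from the branch point, mirror-symmetric", {
  sk <- design_skeleton(y_design(1000, 1000, 60, 100))
  expect_equal(nrow(sk), 3)
  # common endpoint at the branch point
  expect_true(all(sk[, "x0"] == 0 & sk[, "y0"] == 0))
  # free branch endpoints at (+-1000 sin30, -1000 cos30)
  expect_equal(unname(sk["left", c("x1", "y1")]), c(-500, -866.0254),
               tolerance = 1e-6)
  expect_equal(unname(sk["right", c("x1", "y1")]), c(500, -866.0254),
               tolerance = 1e-6)
  # endpoints at distance L from the branch point for any angle
  sk2 <- design_skeleton(y_design(800, 650, 100, 80))
  expect_equal(unname(sqrt(sk2[, "x1"]^2 + sk2[, "y1"]^2)),
               c(800, 650, 650), tolerance = 1e-9)
  expect_equal(sk2["left", "x1"], -sk2["right", "x1"])
})

test_that("rasterization reproduces the printed stroke width and angle", {
  d <- y_design()
  g5 <- rasterize_design(d, 5)
  expect_equal(measure_stroke_width(g5), 100, tolerance = 5 / 100)  # +-1 px
  g10 <- rasterize_design(d, 10)
  expect_equal(measure_branch_angle(g10), 60, tolerance = 1 / 60)   # +-1 deg
  # single connected component; mirrored design rasterizes to the mirror
  expect_equal(max(label_components(g10$pixels)), 1L)
  expect_identical(mirror_cols(g10$pixels), g10$pixels)  # symmetric design
  expect_error(rasterize_design(d, 30), "too coarse")
})

test_that("stroke width converges to the design value as pixels shrink", {
  d <- y_design()
  w <- vapply(c(10, 5, 2.5), function(ps)
    measure_stroke_width(rasterize_design(d, ps)), numeric(1))
  expect_true(all(abs(w - 100) <= c(10, 5, 2.5)))
})

test_that("partition labels are complete, exclusive and mirror-symmetric", {
  d <- y_design()
  m <- rasterize_design(d, 4)
  part <- partition_regions(m, d, 0.3)
  expect_setequal(unique(as.vector(part$labels[m$pixels])), 1:4)
  expect_true(all(part$labels[!m$pixels] == 0L))
  a <- region_areas(part)
  # completeness: labelled areas sum exactly to foreground area
  expect_identical(sum(part$labels > 0L), sum(m$pixels))
  # mirror symmetry: left and right tips identical for the symmetric design
  expect_equal(a[["tip_left"]], a[["tip_right"]])
  # mirror equivariance on an asymmetric mask: extra blob on the left
  m2 <- m
  m2$pixels[200:210, 30:40] <- TRUE
  p2 <- partition_regions(m2, d, 0.3)
  p2m <- partition_regions(mirror_grid(m2), d, 0.3)
  a2 <- region_areas(p2); a2m <- region_areas(p2m)
  expect_equal(a2m[["tip_left"]], a2[["tip_right"]])
  expect_equal(a2m[["tip_right"]], a2[["tip_left"]])
  expect_equal(a2m[["tip_stem"]], a2[["tip_stem"]])
  expect_equal(a2m[["trunk"]], a2[["trunk"]])
})

test_that("partition edge cases: small tip fraction, empty mask, frame mismatch", {
  d <- y_design()
  m <- rasterize_design(d, 8)
  tiny <- partition_regions(m, d, 1e-6)
  a <- region_areas(tiny)
  # tip_fraction -> 0 limit: the tip zone shrinks to the three end caps
  # (pixels whose nearest skeleton point is the free endpoint itself)
  expect_lt(a[["tips"]], 1.05 * 3 * pi * 50^2 / 2)
  expect_gt(a[["tips"]], 0.90 * 3 * pi * 50^2 / 2)
  expect_equal(a[["trunk"]], sum(m$pixels) * 64 - a[["tips"]])
  empty <- image_grid(matrix(FALSE, 10, 10), 8)
  expect_error(partition_regions(empty, d), "empty")
  off <- image_grid(m$pixels, m$pixel_size, origin = m$origin + c(9000, 0))
  expect_error(partition_regions(off, d), "register_mask")
  expect_error(partition_regions(m, d, tip_fraction = 1), "tip_fraction")
})

test_that("partition agrees with the brute-force nearest-skeleton oracle", {
  d <- y_design(500, 400, 70, 100)
  m <- rasterize_design(d, 10, margin = 120)
  # blob appended beyond the stem's free endpoint must be tip_stem
  sk <- design_skeleton(d)
  gx <- bpq:::grid_x(m); gy <- bpq:::grid_y(m)
  bi <- which.min(abs(gy - (sk["stem", "y1"] + 60)))
  bj <- which.min(abs(gx - sk["stem", "x1"]))
  m$pixels[(bi - 3):(bi + 3), (bj - 3):(bj + 3)] <- TRUE
  part <- partition_regions(m, d, 0.3)
  expect_true(all(part$labels[(bi - 3):(bi + 3), (bj - 3):(bj + 3)] == 2L))
  oracle <- brute_partition_codes(m, d, 0.3)
  mismatch <- mean(part$labels[m$pixels] != oracle[m$pixels])
  expect_lt(mismatch, 0.01)  # only quantized region-boundary pixels may differ
})

test_that("outline lengths match closed form, symmetry and the line-walking oracle", {
  # solid disk: perimeter within 2% of 2*pi*r
  n <- 101L; ctr <- 51; r <- 30
  disk <- outer(1:n, 1:n, function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
  lab <- matrix(0L, n, n); lab[disk] <- 1L
  len <- bpq:::perimeter_by_label(disk, lab, 2)
  expect_equal(len[["trunk"]], 2 * pi * r * 2, tolerance = 0.02)
  # agreement with the brute-force line-walking implementation
  blob <- random_blob_mask(64, 64, seed = 42)
  labb <- matrix(0L, 64, 64); labb[blob] <- 1L
  expect_equal(bpq:::perimeter_by_label(blob, labb, 1.5)[["trunk"]],
               brute_perimeter(blob, 1.5), tolerance = 1e-12)
  # symmetric Y: left and right tip outlines equal; per-group accessor works
  d <- y_design()
  m <- rasterize_design(d, 4)
  part <- partition_regions(m, d, 0.3)
  lens <- outline_lengths(part, m)
  expect_equal(lens[["tip_left"]], lens[["tip_right"]], tolerance = 0.01)
  expect_equal(outline_length(part, m, "tips"),
               mean(lens[c("tip_stem", "tip_left", "tip_right")]))
  expect_equal(outline_length(part, m, "trunk"), lens[["trunk"]])
  expect_error(outline_lengths(part, matrix(FALSE, nrow(m$pixels),
                                            ncol(m$pixels))), "empty")
})

test_that("register_mask recovers identity, translation and rotation", {
  d <- y_design()
  m <- rasterize_design(d, 8)
  tr <- register_mask(m, d)
  expect_lt(abs(tr$rotation_deg), 1)
  expect_lt(max(abs(tr$translation_um)), 8)
  # translation by (+50, -30) px is recovered as (-50, +30) px
  shifted <- image_grid(m$pixels, m$pixel_size,
                        origin = m$origin + c(50, -30) * m$pixel_size)
  tr2 <- register_mask(shifted, d)
  expect_equal(tr2$translation_um / m$pixel_size, c(-50, 30), tolerance = 0.05)
  # rotation by 15 degrees is recovered as -15 +- 1
  rot <- apply_rigid(m, list(rotation_deg = 15, translation_um = c(0, 0),
                             mask_centroid = bpq:::mask_axis(m)$centroid))
  tr3 <- register_mask(rot, d)
  expect_equal(tr3$rotation_deg, -15, tolerance = 1 / 15)
  # near-isotropic mask has no principal axis
  blob <- image_grid(outer(1:80, 1:80, function(i, j)
    (i - 40)^2 + (j - 40)^2 <= 25^2), 8)
  expect_error(register_mask(blob, d), "principal axis")
})
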