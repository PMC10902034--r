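#' Ground-truth parameters of a synthetic culture scene
#'
#' The generator emulates the measured features of the 3D-bioprinted
#' cultures with known ground truth: region-dependent radial growth of the
#' printed stroke (tips bulge more than the trunk), outline protrusions
#' (invasions) placed with region-dependent probability, nuclei with
#' region-specific Ki67-positive fractions, and a planted dead-cell
#' fraction. Defaults represent a day-14 culture of the non-cancerous
#' cell line; [dcis_scene_params()] switches the invasion placement to the
#' trunk-weighted pattern of the DCIS-like line, and [day3_scene_params()]
#' gives the near-design day-3 state used for growth-expansion analyses.
#'
#' @param design a [y_design()].
#' @param day culture day (bookkeeping only).
#' @param pixel_size um/px of the rendered scene (default 4).
#' @param tip_fraction tip-region fraction used for the ground-truth label
#'   map (default 0.3).
#' @param growth_factor_tip_stem,growth_factor_tip_branch,growth_factor_trunk
#'   radial dilation of the stroke half-width per region, >= 1; 1 leaves
#'   the printed design unchanged.
#' @param ki67_fraction named fractions in `[0, 1]` for `tip_stem`,
#'   `tip_left`, `tip_right`, `trunk`.
#' @param nuclei_density nuclei per um^2 of culture area.
#' @param dead_fraction planted fraction of PI-positive (dead) nuclei.
#' @param protrusion_count number of invasive protrusions.
#' @param protrusion_region_weights named probabilities over `tips` and
#'   `trunk` for protrusion placement (must sum to 1).
#' @param protrusion_length_mean mean protrusion length, um.
#' @param protrusion_width protrusion tube width, um.
#' @param margin rendered margin around the design, um.
#' @param seed integer RNG seed.
#' @return a `scene_params` list.
#' @export
scene_params <- function(design = y_design(), day = 14, pixel_size = 4,
                         tip_fraction = 0.3,
                         growth_factor_tip_stem = 1.9,
                         growth_factor_tip_branch = 1.7,
                         growth_factor_trunk = 1.3,
                         ki67_fraction = c(tip_stem = 0.45, tip_left = 0.28,
                                           tip_right = 0.28, trunk = 0.10),
                         nuclei_density = 0.004, dead_fraction = 0.03,
                         protrusion_count = 12,
                         protrusion_region_weights = c(tips = 0.5, trunk = 0.5),
                         protrusion_length_mean = 60, protrusion_width = 20,
                         margin = 300, seed = 1) {
  stopifnot(inherits(design, "y_design"))
  g <- c(growth_factor_tip_stem, growth_factor_tip_branch, growth_factor_trunk)
  if (any(g < 1)) stop("growth factors must be >= 1", call. = FALSE)
  req <- c("tip_stem", "tip_left", "tip_right", "trunk")
  if (!all(req %in% names(ki67_fraction)))
    stop("`ki67_fraction` must name ", paste(req, collapse = ", "), call. = FALSE)
  if (any(ki67_fraction < 0 | ki67_fraction > 1))
    stop("`ki67_fraction` values must lie in [0, 1]", call. = FALSE)
  if (dead_fraction < 0 || dead_fraction > 1)
    stop("`dead_fraction` must lie in [0, 1]", call. = FALSE)
  w <- protrusion_region_weights
  if (!all(c("tips", "trunk") %in% names(w)) || abs(sum(w) - 1) > 1e-9)
    stop("`protrusion_region_weights` must name tips/trunk and sum to 1",
         call. = FALSE)
  structure(list(design = design, day = day, pixel_size = pixel_size,
                 tip_fraction = tip_fraction,
                 growth_factor_tip_stem = growth_factor_tip_stem,
                 growth_factor_tip_branch = growth_factor_tip_branch,
                 growth_factor_trunk = growth_factor_trunk,
                 ki67_fraction = ki67_fraction[req],
                 nuclei_density = nuclei_density,
                 dead_fraction = dead_fraction,
                 protrusion_count = protrusion_count,
                 protrusion_region_weights = w[c("tips", "trunk")],
                 protrusion_length_mean = protrusion_length_mean,
                 protrusion_width = protrusion_width,
                 margin = margin, seed = seed),
            class = "scene_params")
}

#' @rdname scene_params
#' @param ... overrides passed on to [scene_params()].
#' @export
dcis_scene_params <- function(...) {
  defaults <- list(protrusion_region_weights = c(tips = 0.2, trunk = 0.8),
                   protrusion_count = 16)
  do.call(scene_params, modifyList(defaults, list(...)))
}

#' @rdname scene_params
#' @export
viability_scene_params <- function(...) {
  # freshly printed culture (day 0): undilated design, no invasions, sparse
  # well-separated cells whose PI status can be scored per nucleus
  defaults <- list(day = 0, growth_factor_tip_stem = 1,
                   growth_factor_tip_branch = 1, growth_factor_trunk = 1,
                   protrusion_count = 0, nuclei_density = 0.002,
                   dead_fraction = 0.03)
  do.call(scene_params, modifyList(defaults, list(...)))
}

#' @rdname scene_params
#' @export
day3_scene_params <- function(...) {
  defaults <- list(day = 3, growth_factor_tip_stem = 1.1,
                   growth_factor_tip_branch = 1.1, growth_factor_trunk = 1.1,
                   protrusion_count = 0,
                   ki67_fraction = c(tip_stem = 0.6, tip_left = 0.45,
                                     tip_right = 0.45, trunk = 0.25))
  do.call(scene_params, modifyList(defaults, list(...)))
}

# per-pixel region code (0 never occurs: every pixel is assigned to its
# nearest segment) following the same tip rule as partition_regions()
.region_code_field <- function(grid, design, tip_fraction) {
  xs <- grid_x(grid); ys <- grid_y(grid)
  nr <- nrow(grid$pixels); nc <- ncol(grid$pixels)
  px <- rep(xs, each = nr)  # column-major expansion
  py <- rep(ys, times = nc)
  ns <- nearest_segment(px, py, design)
  in_tip <- (ns$seg_len - ns$arc) < tip_fraction * ns$seg_len & !ns$tie
  code <- ifelse(in_tip, .TIP_CODES[ns$seg], .LABELS[["trunk"]])
  list(code = matrix(code, nr, nc), dist = matrix(ns$dist, nr, nc))
}

# stamp unit-peak Gaussian spots (sigma um) at world coords into a matrix
.stamp_spots <- function(grid, xy, sigma = 3, reach = 3) {
  img <- matrix(0, nrow(grid$pixels), ncol(grid$pixels))
  if (!nrow(xy)) return(img)
  ps <- grid$pixel_size
  r <- ceiling(reach * sigma / ps)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  nr <- nrow(img); nc <- ncol(img)
  for (i in seq_len(nrow(xy))) {
    ci0 <- (xy[i, 1] - grid$origin[1]) / ps + 1
    ri0 <- (grid$origin[2] - xy[i, 2]) / ps + 1
    ri <- round(ri0) + off$dr; ci <- round(ci0) + off$dc
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    d2 <- ((ri - ri0)^2 + (ci - ci0)^2) * ps^2
    v <- exp(-d2 / (2 * sigma^2))
    idx <- cbind(ri[ok], ci[ok])
    img[idx] <- img[idx] + v[ok]
  }
  img
}

#' Generate a synthetic culture scene
#'
#' Deterministic for a given seed. Construction: the design is rasterized;
#' each pixel's stroke half-width is scaled by its region's growth factor
#' (distance-to-skeleton thresholding, so a growth factor of 1 reproduces
#' the rasterized design exactly); invasive protrusions are grown as
#' persistent random-walk tubes seeded on the culture outline with
#' region-weighted placement; nuclei are scattered inside the mask at the
#' requested density and rendered as Gaussian spots (sigma 3 um) into
#' DAPI, Ki67 and PI channels with 2% additive Gaussian background.
#'
#' @param params a [scene_params()].
#' @return a `synthetic_scene`: `culture_mask`, `dapi`, `ki67`, `pi`
#'   (`image_grid`s), `labels` (ground-truth region code matrix) and
#'   `ground_truth` (planted region areas, Ki67 fractions, invasion areas,
#'   viability, nuclei table).
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  base <- rasterize_design(p$design, p$pixel_size, p$margin)
  rc <- .region_code_field(base, p$design, p$tip_fraction)
  gmap <- c(p$growth_factor_trunk, p$growth_factor_tip_stem,
            p$growth_factor_tip_branch, p$growth_factor_tip_branch)
  # codes: trunk=1, tip_stem=2, tip_left=3, tip_right=4
  gfac <- matrix(gmap[rc$code], nrow(rc$code), ncol(rc$code))
  grown <- rc$dist <= gfac * p$design$stroke_width / 2
  ps <- p$pixel_size
  nr <- nrow(grown); nc <- ncol(grown)

  with_seed(p$seed, {
    mask <- grown
    invasion_px <- c(tips = 0, trunk = 0)
    if (p$protrusion_count > 0) {
      # outline pixels of the grown culture (4-neighbour boundary)
      inner <- shift_mat(grown * 1L, 1, 0) & shift_mat(grown * 1L, -1, 0) &
               shift_mat(grown * 1L, 0, 1) & shift_mat(grown * 1L, 0, -1)
      outline <- which(grown & !inner)
      o_ri <- (outline - 1L) %% nr + 1L; o_ci <- (outline - 1L) %/% nr + 1L
      o_grp <- ifelse(rc$code[outline] %in% .TIP_CODES, "tips", "trunk")
      rad_px <- p$protrusion_width / 2 / ps
      r <- ceiling(rad_px)
      disk <- expand.grid(dr = -r:r, dc = -r:r)
      disk <- disk[disk$dr^2 + disk$dc^2 <= rad_px^2 + 1e-9, ]
      xs <- grid_x(base); ys <- grid_y(base)
      # region weights act per unit outline: each outline pixel's chance of
      # seeding a protrusion is proportional to its group's weight, so
      # equal weights mean uniform seeding along the whole outline
      w_px <- ifelse(o_grp == "tips", p$protrusion_region_weights[["tips"]],
                     p$protrusion_region_weights[["trunk"]])
      for (k in seq_len(p$protrusion_count)) {
        j <- sample(length(outline), 1, prob = w_px)
        grp <- o_grp[j]
        pos <- c(xs[o_ci[j]], ys[o_ri[j]])
        ns <- nearest_segment(pos[1], pos[2], p$design)
        dir <- pos - .skeleton_point(p$design, ns$seg, ns$arc)
        dir <- dir / max(sqrt(sum(dir^2)), 1e-9)
        len <- max(10, rnorm(1, p$protrusion_length_mean,
                             p$protrusion_length_mean / 4))
        n_steps <- max(1L, round(len / 10))
        for (s in seq_len(n_steps)) {
          th <- runif(1, 0, 2 * pi)
          dir <- 0.8 * dir + 0.2 * c(cos(th), sin(th))
          dir <- dir / sqrt(sum(dir^2))
          pos <- pos + 10 * dir
          ci0 <- round((pos[1] - base$origin[1]) / ps) + 1L
          ri0 <- round((base$origin[2] - pos[2]) / ps) + 1L
          ri <- ri0 + disk$dr; ci <- ci0 + disk$dc
          ok <- ri >= 1L & ri <= nr & ci >= 1L & ci <= nc
          idx <- cbind(ri[ok], ci[ok])
          new_px <- !mask[idx]
          outside <- new_px & !grown[idx]
          invasion_px[grp] <- invasion_px[grp] + sum(outside)
          mask[idx] <- TRUE
        }
      }
    }

    area_um2 <- sum(mask) * ps^2
    n_nuclei <- round(p$nuclei_density * area_um2)
    if (n_nuclei < 1)
      stop("nuclei_density yields zero nuclei for this culture area",
           call. = FALSE)
    fg_idx <- which(mask)
    pick <- sample(fg_idx, n_nuclei, replace = n_nuclei > length(fg_idx))
    ri <- (pick - 1L) %% nr + 1L; ci <- (pick - 1L) %/% nr + 1L
    nx <- grid_x(base)[ci] + runif(n_nuclei, -ps / 2, ps / 2)
    ny <- grid_y(base)[ri] - runif(n_nuclei, -ps / 2, ps / 2)
    ncode <- rc$code[pick]
    region <- names(.LABELS)[match(ncode, .LABELS)]
    ki67_pos <- rbinom(n_nuclei, 1, p$ki67_fraction[region]) == 1
    dead <- rbinom(n_nuclei, 1, p$dead_fraction) == 1

    noise <- function() matrix(rnorm(nr * nc, 0, 0.02), nr, nc)
    dapi <- .stamp_spots(base, cbind(nx, ny)) + noise()
    ki67 <- .stamp_spots(base, cbind(nx, ny)[ki67_pos, , drop = FALSE]) + noise()
    pi_ch <- .stamp_spots(base, cbind(nx, ny)[dead, , drop = FALSE]) + noise()

    labels <- rc$code * mask
    px2 <- ps^2
    areas <- vapply(.LABELS[-1], function(k) sum(labels == k) * px2, numeric(1))
    ki67_true <- vapply(split(ki67_pos, region), mean, numeric(1))
    grp <- ifelse(ncode %in% .TIP_CODES, "tips", "trunk")
    ki67_true_grp <- vapply(split(ki67_pos, grp), mean, numeric(1))
    structure(list(
      nuclei = data.frame(x = nx, y = ny, region = region,
                          ki67 = ki67_pos, dead = dead),
      culture_mask = grid_like(base, mask),
      dapi = grid_like(base, dapi),
      ki67 = grid_like(base, ki67),
      pi = grid_like(base, pi_ch),
      labels = labels,
      ground_truth = list(
        region_areas_um2 = c(areas, tips = sum(areas[c("tip_stem", "tip_left", "tip_right")])),
        ki67_fraction = ki67_true,
        ki67_fraction_group = ki67_true_grp,
        invasion_area_um2 = invasion_px * px2,
        n_nuclei = n_nuclei,
        n_dead = sum(dead),
        viability_percent = 100 * (1 - mean(dead))),
      params = p), class = "synthetic_scene")
  })
}

# world coordinates of the skeleton point at arc position `arc` (um from
# the branch point) along segment `seg`
.skeleton_point <- function(design, seg, arc) {
  sk <- design_skeleton(design)
  s <- sk[seg, ]
  u <- c(s["x1"] - s["x0"], s["y1"] - s["y0"]) / s["length"]
  c(s["x0"], s["y0"]) + arc * u
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> day %g, %d x %d px @ %g um/px, %d nuclei, viability %.1f%%\n",
              x$params$day, nrow(x$labels), ncol(x$labels),
              x$params$pixel_size, x$ground_truth$n_nuclei,
              x$ground_truth$viability_percent))
  invisible(x)
}

#' Generate a day-3 / day-14 timecourse pair
#'
#' Both scenes share the design, grid and seed; growth is monotone by
#' construction (every day-14 growth factor must be at least its day-3
#' counterpart, and the day-14 mask is united with the day-3 mask so
#' protrusions present early never leave the late mask).
#'
#' @param params_day3,params_day14 [scene_params()] sharing design,
#'   pixel size and seed.
#' @return list of two `synthetic_scene`s named `day3` and `day14`.
#' @export
generate_timecourse <- function(params_day3 = day3_scene_params(),
                                params_day14 = scene_params()) {
  p3 <- params_day3; p14 <- params_day14
  stopifnot(inherits(p3, "scene_params"), inherits(p14, "scene_params"))
  if (!identical(p3$design, p14$design))
    stop("timecourse scenes must share one design", call. = FALSE)
  if (p3$pixel_size != p14$pixel_size || p3$seed != p14$seed ||
      p3$margin != p14$margin)
    stop("timecourse scenes must share pixel size, margin and seed",
         call. = FALSE)
  for (f in c("growth_factor_tip_stem", "growth_factor_tip_branch",
              "growth_factor_trunk"))
    if (p14[[f]] < p3[[f]])
      stop("day-14 ", f, " is smaller than day-3: growth must be monotone",
           call. = FALSE)
  s3 <- generate_scene(p3)
  s14 <- generate_scene(p14)
  m <- as_mask(s14$culture_mask) | as_mask(s3$culture_mask)
  s14$culture_mask <- grid_like(s14$culture_mask, m)
  fill <- m & s14$labels == 0L
  s14$labels[fill] <- s3$labels[fill]
  px2 <- p14$pixel_size^2
  areas <- vapply(.LABELS[-1], function(k) sum(s14$labels == k) * px2, numeric(1))
  s14$ground_truth$region_areas_um2 <-
    c(areas, tips = sum(areas[c("tip_stem", "tip_left", "tip_right")]))
  list(day3 = s3, day14 = s14)
}

#' Write a scene to a directory of plain-text images
#'
#' The mask and label map go to PGM, the intensity channels to 16-bit
#' scaled PGM, and the ground truth to a JSON sidecar.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pgm(scene$culture_mask, file.path(dir, "mask.pgm"), maxval = 1)
  write_pgm(grid_like(scene$culture_mask, scene$labels),
            file.path(dir, "labels.pgm"), maxval = 4)
  for (ch in c("dapi", "ki67", "pi")) {
    g <- scene[[ch]]
    v <- pmax(g$pixels, 0)
    scl <- grid_like(g, round(v / max(v, 1e-9) * 65535))
    write_pgm(scl, file.path(dir, paste0(ch, ".pgm")), maxval = 65535)
  }
  gt <- scene$ground_truth
  gt$params <- scene$params[setdiff(names(scene$params), "design")]
  gt$design <- unclass(scene$params$design)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
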