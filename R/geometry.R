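#' Parametric Y-shaped structure design
#'
#' The printable structure is a Y: a stem plus two branches meeting at a
#' branch point, printed as strokes of constant width. The default
#' reproduces the published design: 100 um stroke (the minimum nozzle
#' size) and a 60 degree angle between the branches; segment lengths of
#' 1000 um are a documented assumption since the print figure states no
#' lengths. The stem runs along +y from the branch point; the branches are
#' mirror-symmetric about the stem axis, each at `branch_angle / 2` from
#' it on the -y side.
#'
#' @param stem_length,branch_length segment lengths in micrometres (> 0).
#' @param branch_angle angle between the two branches, degrees, in (0, 180).
#' @param stroke_width printed stroke width in micrometres (> 0).
#' @param branch_point world (x, y) of the branch point in micrometres.
#' @return A `y_design` object.
#' @export
#' @examples
#' d <- y_design()
#' design_skeleton(d)
y_design <- function(stem_length = 1000, branch_length = 1000,
                     branch_angle = 60, stroke_width = 100,
                     branch_point = c(0, 0)) {
  for (nm in c("stem_length", "branch_length", "stroke_width")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a single positive number", nm), call. = FALSE)
  }
  if (!is.numeric(branch_angle) || length(branch_angle) != 1L ||
      branch_angle <= 0 || branch_angle >= 180)
    stop("`branch_angle` must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  if (length(branch_point) != 2L || !is.numeric(branch_point))
    stop("`branch_point` must be a numeric (x, y) pair", call. = FALSE)
  structure(list(stem_length = stem_length, branch_length = branch_length,
                 branch_angle = branch_angle, stroke_width = stroke_width,
                 branch_point = as.numeric(branch_point)),
            class = "y_design")
}

#' @export
print.y_design <- function(x, ...) {
  cat(sprintf(paste0("<y_design> stem %g um, branches %g um @ %g deg, ",
                     "stroke %g um, branch point (%g, %g)\n"),
              x$stem_length, x$branch_length, x$branch_angle,
              x$stroke_width, x$branch_point[1], x$branch_point[2]))
  invisible(x)
}

#' Skeleton segments of a design
#'
#' @param design a `y_design`.
#' @return 3 x 5 numeric matrix, rows `stem`, `left`, `right`; columns
#'   `x0, y0` (branch point), `x1, y1` (free endpoint), `length` (um).
#' @export
design_skeleton <- function(design) {
  stopifnot(inherits(design, "y_design"))
  bp <- design$branch_point
  half <- design$branch_angle / 2 * pi / 180
  ends <- rbind(
    stem  = bp + c(0, design$stem_length),
    left  = bp + design$branch_length * c(-sin(half), -cos(half)),
    right = bp + design$branch_length * c(sin(half), -cos(half)))
  cbind(x0 = bp[1], y0 = bp[2], x1 = ends[, 1], y1 = ends[, 2],
        length = c(design$stem_length, design$branch_length,
                   design$branch_length))
}

# distance and arc position of points to one segment; t in [0, L] measured
# from the branch-point end
.seg_dist <- function(px, py, seg) {
  vx <- seg["x1"] - seg["x0"]; vy <- seg["y1"] - seg["y0"]
  L2 <- vx * vx + vy * vy
  t <- pmin(pmax(((px - seg["x0"]) * vx + (py - seg["y0"]) * vy) / L2, 0), 1)
  dx <- px - (seg["x0"] + t * vx); dy <- py - (seg["y0"] + t * vy)
  list(dist = sqrt(dx * dx + dy * dy), t = t * seg["length"])
}

# per-pixel nearest-segment info for arbitrary world coordinates
nearest_segment <- function(px, py, design) {
  sk <- design_skeleton(design)
  ds <- lapply(seq_len(3), function(k) .seg_dist(px, py, sk[k, ]))
  dmat <- cbind(ds[[1]]$dist, ds[[2]]$dist, ds[[3]]$dist)
  tmat <- cbind(ds[[1]]$t, ds[[2]]$t, ds[[3]]$t)
  dmin <- pmin(dmat[, 1], dmat[, 2], dmat[, 3])
  seg <- max.col(-dmat, ties.method = "first")
  tie <- rowSums(dmat <= dmin + 1e-9) > 1L
  list(dist = dmin, seg = seg, tie = tie,
       arc = tmat[cbind(seq_along(px), seg)],
       seg_len = sk[, "length"][seg])
}

#' Rasterize a design to a binary mask
#'
#' Foreground pixels are those whose center lies within `stroke_width / 2`
#' of the skeleton polyline (round caps). The grid is laid out so that
#' pixel *edges* fall on multiples of `pixel_size` in design coordinates;
#' with the stem on a coordinate axis this centers the stroke on a pixel
#' boundary and makes the measured stroke width unbiased.
#'
#' @param design a `y_design`.
#' @param pixel_size um per pixel; must be at most `stroke_width / 4` so
#'   the stroke is resolvable.
#' @param margin extra world space (um) around the skeleton bounding box.
#' @return binary `image_grid`.
#' @export
rasterize_design <- function(design, pixel_size = 4, margin = 200) {
  stopifnot(inherits(design, "y_design"))
  if (pixel_size > design$stroke_width / 4)
    stop(sprintf("pixel_size %g um too coarse for a %g um stroke (need <= stroke_width/4)",
                 pixel_size, design$stroke_width), call. = FALSE)
  sk <- design_skeleton(design)
  pad <- design$stroke_width / 2 + margin
  xlim <- range(c(sk[, "x0"], sk[, "x1"])) + c(-pad, pad)
  ylim <- range(c(sk[, "y0"], sk[, "y1"])) + c(-pad, pad)
  ps <- pixel_size
  x0 <- floor(xlim[1] / ps) * ps; x1 <- ceiling(xlim[2] / ps) * ps
  y0 <- floor(ylim[1] / ps) * ps; y1 <- ceiling(ylim[2] / ps) * ps
  xs <- seq(x0 + ps / 2, x1 - ps / 2, by = ps)
  ys <- seq(y1 - ps / 2, y0 + ps / 2, by = -ps)
  px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
  ns <- nearest_segment(px, py, design)
  fg <- matrix(ns$dist <= design$stroke_width / 2, nrow = length(ys))
  image_grid(fg, ps, c(xs[1], ys[1]))
}

.LABELS <- c(background = 0L, trunk = 1L, tip_stem = 2L, tip_left = 3L,
             tip_right = 4L)
.TIP_CODES <- c(2L, 3L, 4L)

#' Partition a culture mask into tip and trunk sub-regions
#'
#' Every foreground pixel is assigned to the skeleton segment whose
#' nearest point is closest; if that nearest point lies within
#' `tip_fraction` of the segment length from the segment's free endpoint
#' the pixel belongs to that segment's tip region (`tip_stem`,
#' `tip_left`, `tip_right`), otherwise to the `trunk`. Pixels equidistant
#' between segments (the branch-point neighbourhood) are always trunk, so
#' ties never inflate tip areas.
#'
#' @param mask binary `image_grid`, registered to the design frame.
#' @param design a `y_design` in the same world frame as `mask`.
#' @param tip_fraction fraction of each segment counted as its tip,
#'   in (0, 1).
#' @return A `labeled_partition`: integer label image plus metadata.
#' @export
partition_regions <- function(mask, design, tip_fraction = 0.3) {
  stopifnot(is_image_grid(mask), inherits(design, "y_design"))
  if (!(tip_fraction > 0 && tip_fraction < 1))
    stop("`tip_fraction` must lie strictly between 0 and 1", call. = FALSE)
  m <- as_mask(mask)
  if (!any(m)) stop("mask is empty: nothing to partition", call. = FALSE)
  # frame sanity: the branch point must fall inside the mask bounding box
  xs <- grid_x(mask); ys <- grid_y(mask)
  idx <- which(m)
  ri <- (idx - 1L) %% nrow(m) + 1L; ci <- (idx - 1L) %/% nrow(m) + 1L
  bb_x <- range(xs[ci]); bb_y <- range(ys[ri])
  bp <- design$branch_point
  slack <- 0.25 * (design$stem_length + design$branch_length)
  if (bp[1] < bb_x[1] - slack || bp[1] > bb_x[2] + slack ||
      bp[2] < bb_y[1] - slack || bp[2] > bb_y[2] + slack)
    stop("design and mask frames do not overlap; run register_mask() first",
         call. = FALSE)
  ns <- nearest_segment(xs[ci], ys[ri], design)
  in_tip <- (ns$seg_len - ns$arc) < tip_fraction * ns$seg_len & !ns$tie
  lab <- matrix(0L, nrow(m), ncol(m))
  lab[idx] <- ifelse(in_tip, .TIP_CODES[ns$seg], .LABELS[["trunk"]])
  structure(list(labels = lab, pixel_size = mask$pixel_size,
                 origin = mask$origin, design = design,
                 tip_fraction = tip_fraction, label_codes = .LABELS),
            class = "labeled_partition")
}

#' @export
print.labeled_partition <- function(x, ...) {
  n <- vapply(.LABELS[-1], function(k) sum(x$labels == k), integer(1))
  cat(sprintf("<labeled_partition> %d x %d px, %.3g um/px; tip_fraction %.2f\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size, x$tip_fraction))
  print(n)
  invisible(x)
}

#' Region areas of a partition
#'
#' @param partition a `labeled_partition`.
#' @param mask optional binary mask restricting the count (defaults to the
#'   whole partition foreground).
#' @return named vector of areas in um^2 for `trunk`, `tip_stem`,
#'   `tip_left`, `tip_right`, plus `tips` (their pooled sum).
#' @export
region_areas <- function(partition, mask = NULL) {
  lab <- partition$labels
  if (!is.null(mask)) lab <- lab * as_mask(mask)
  px2 <- partition$pixel_size^2
  a <- vapply(.LABELS[-1], function(k) sum(lab == k) * px2, numeric(1))
  c(a, tips = sum(a[c("tip_stem", "tip_left", "tip_right")]))
}

# group -> label codes
group_codes <- function(group) {
  switch(group, tips = .TIP_CODES, trunk = .LABELS[["trunk"]],
         stop("unknown region group: ", group, call. = FALSE))
}

# --- perimeter -------------------------------------------------------------

# Per-label Crofton (4-direction line-intercept) perimeter of `mask`,
# attributing each boundary crossing to the partition label of its
# foreground pixel. Returns lengths in um, named by sub-region. The
# 4-direction estimator is used instead of raw marching-squares polygon
# length because the latter overestimates smooth boundaries by ~6%.
perimeter_by_label <- function(mask, labels, pixel_size) {
  m <- as_mask(mask)
  # pad so that the image border counts as background
  pm <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
  pm[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  pl <- matrix(0L, nrow(pm), ncol(pm))
  pl[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- labels
  acc <- numeric(max(.LABELS) + 1L)
  dirs <- list(c(1L, 0L, 1), c(0L, 1L, 1),
               c(1L, 1L, 1 / sqrt(2)), c(1L, -1L, 1 / sqrt(2)))
  nr <- nrow(pm); nc <- ncol(pm)
  for (d in dirs) {
    dr <- d[[1]]; dc <- d[[2]]; w <- d[[3]]
    r1 <- seq_len(nr - abs(dr)); c1 <- seq_len(nc - abs(dc))
    r2 <- r1 + abs(dr)
    if (dc >= 0) { ca <- c1; cb <- c1 + dc } else { ca <- c1 - dc; cb <- c1 }
    a <- pm[r1, ca, drop = FALSE]; b <- pm[r2, cb, drop = FALSE]
    trans <- a != b
    if (!any(trans)) next
    la <- pl[r1, ca, drop = FALSE]; lb <- pl[r2, cb, drop = FALSE]
    fg_lab <- ifelse(a, la, lb)[trans]
    cnt <- tabulate(fg_lab + 1L, nbins = length(acc))
    acc <- acc + w * cnt
  }
  len <- (pi / 8) * acc * pixel_size
  names(len) <- names(.LABELS)[match(seq_along(acc) - 1L, .LABELS)]
  len[-1]  # drop 'background' (transitions on unlabeled fg, normally none)
}

#' Outline length of the main structure within a region group
#'
#' Perimeter of `main_mask` measured with a 4-direction line-intercept
#' (Crofton) estimator and attributed per sub-region by the partition
#' label of each boundary pixel. For `group = "tips"` the *mean* over the
#' three tip sub-regions is returned (matching the averaging used when
#' normalizing invasion areas); for `"trunk"` the trunk outline length.
#'
#' @param partition a `labeled_partition`.
#' @param main_mask binary `image_grid`/matrix, a subset of the partition
#'   foreground.
#' @param group `"tips"` or `"trunk"`.
#' @return outline length in micrometres.
#' @seealso [outline_lengths()] for the per-sub-region values.
#' @export
outline_length <- function(partition, main_mask, group = c("tips", "trunk")) {
  group <- match.arg(group)
  len <- outline_lengths(partition, main_mask)
  if (group == "trunk") unname(len[["trunk"]])
  else mean(len[c("tip_stem", "tip_left", "tip_right")])
}

#' @rdname outline_length
#' @export
outline_lengths <- function(partition, main_mask) {
  stopifnot(inherits(partition, "labeled_partition"))
  m <- as_mask(main_mask)
  if (!any(m)) stop("main_mask is empty", call. = FALSE)
  if (any(m & partition$labels == 0L))
    stop("main_mask has foreground outside the partition support", call. = FALSE)
  perimeter_by_label(m, partition$labels, partition$pixel_size)
}

# --- registration ----------------------------------------------------------

# principal axis (unit vector) and centroid of a mask's foreground, in
# world coordinates
mask_axis <- function(mask) {
  m <- as_mask(mask)
  idx <- which(m)
  ri <- (idx - 1L) %% nrow(m) + 1L; ci <- (idx - 1L) %/% nrow(m) + 1L
  pts <- cbind(grid_x(mask)[ci], grid_y(mask)[ri])
  ctr <- colMeans(pts)
  pc <- prcomp(pts, center = TRUE, scale. = FALSE)
  list(centroid = ctr, axis = pc$rotation[, 1],
       anisotropy = pc$sdev[1] / max(pc$sdev[2], 1e-12))
}

#' Rigid registration of a mask to a design
#'
#' Estimates the rigid transform (rotation + translation, no scaling:
#' pixel size is metadata) aligning the mask's centroid and principal axis
#' to those of the rasterized design. The 180-degree ambiguity of the
#' principal axis is resolved by choosing the candidate with the smaller
#' symmetric-difference area against the design raster.
#'
#' @param mask binary `image_grid`.
#' @param design a `y_design`.
#' @return list with `rotation_deg`, `translation_um` (applied after
#'   rotating about the mask centroid), `mask_centroid`, `design_centroid`,
#'   and `apply(mask)` is available via [apply_rigid()].
#' @export
register_mask <- function(mask, design) {
  stopifnot(is_image_grid(mask), inherits(design, "y_design"))
  if (!any(as_mask(mask))) stop("mask is empty", call. = FALSE)
  ref <- rasterize_design(design, mask$pixel_size)
  ma <- mask_axis(mask); da <- mask_axis(ref)
  if (ma$anisotropy < 1.1)
    stop("mask has no well-defined principal axis (near-isotropic); ",
         "supply a manual transform", call. = FALSE)
  base <- atan2(da$axis[2], da$axis[1]) - atan2(ma$axis[2], ma$axis[1])
  cand <- c(base, base + pi)
  score <- vapply(cand, function(th) {
    tr <- list(rotation_deg = th * 180 / pi,
               translation_um = da$centroid - ma$centroid,
               mask_centroid = ma$centroid)
    reg <- apply_rigid(mask, tr, ref)
    sum(xor(as_mask(reg), as_mask(ref)))
  }, numeric(1))
  th <- cand[which.min(score)]
  th <- atan2(sin(th), cos(th))  # wrap to (-pi, pi]
  list(rotation_deg = th * 180 / pi,
       translation_um = da$centroid - ma$centroid,
       mask_centroid = ma$centroid, design_centroid = da$centroid)
}

#' Apply a rigid transform to a mask
#'
#' Resamples `mask` (nearest neighbour) onto `target` after rotating by
#' `transform$rotation_deg` about `transform$mask_centroid` and
#' translating by `transform$translation_um`.
#'
#' @param mask binary `image_grid`.
#' @param transform as returned by [register_mask()].
#' @param target `image_grid` defining the output frame (default: same
#'   grid as `mask`).
#' @return binary `image_grid` on the target grid.
#' @export
apply_rigid <- function(mask, transform, target = mask) {
  m <- as_mask(mask)
  th <- transform$rotation_deg * pi / 180
  ctr <- transform$mask_centroid
  tx <- transform$translation_um
  xs <- grid_x(target); ys <- grid_y(target)
  gx <- rep(xs, each = length(ys)); gy <- rep(ys, times = length(xs))
  # inverse map: target point -> mask frame
  ux <- gx - ctr[1] - tx[1]; uy <- gy - ctr[2] - tx[2]
  mx <- cos(-th) * ux - sin(-th) * uy + ctr[1]
  my <- sin(-th) * ux + cos(-th) * uy + ctr[2]
  ci <- round((mx - mask$origin[1]) / mask$pixel_size) + 1L
  ri <- round((mask$origin[2] - my) / mask$pixel_size) + 1L
  ok <- ri >= 1L & ri <= nrow(m) & ci >= 1L & ci <= ncol(m)
  out <- rep(FALSE, length(gx))
  out[ok] <- m[cbind(ri[ok], ci[ok])]
  grid_like(target, matrix(out, nrow = length(ys)))
}

# --- raster measurements ---------------------------------------------------

#' Measure stroke width and branch angle from a rasterized mask
#'
#' `measure_stroke_width` thins the mask to its skeleton and returns twice
#' the median Euclidean distance from skeleton pixels to the background,
#' in micrometres. `measure_branch_angle` locates the skeleton branch
#' point, splits the skeleton into arms, fits a principal direction to
#' each arm, and returns the angle (degrees) between the two most acute
#' arms, i.e. the inter-branch angle of a Y.
#'
#' @param mask binary `image_grid`.
#' @return stroke width in um / branch angle in degrees.
#' @export
measure_stroke_width <- function(mask) {
  m <- as_mask(mask)
  if (!any(m)) stop("mask is empty", call. = FALSE)
  sk <- skeletonize_mask(m)
  d <- distance_transform(m, "background")
  2 * median(d[sk]) * (if (is_image_grid(mask)) mask$pixel_size else 1)
}

#' @rdname measure_stroke_width
#' @export
measure_branch_angle <- function(mask) {
  m <- as_mask(mask)
  if (!any(m)) stop("mask is empty", call. = FALSE)
  sk <- skeletonize_mask(m)
  edt <- distance_transform(m, "background")
  half_w <- median(edt[sk])  # px
  # branch point: the junction is the locally thickest point of the Y, so
  # take the skeleton pixel with the largest clearance to the background
  # (robust against spurious junction pixels on thinning staircases)
  dsk <- edt
  dsk[!sk] <- -Inf
  bpix <- which.max(dsk)
  bp <- c((bpix - 1L) %% nrow(m) + 1L, (bpix - 1L) %/% nrow(m) + 1L)
  # strip the junction neighbourhood, leaving three arms
  idx <- which(sk)
  sri <- (idx - 1L) %% nrow(m) + 1L; sci <- (idx - 1L) %/% nrow(m) + 1L
  keep <- (sri - bp[1])^2 + (sci - bp[2])^2 > (3 * half_w)^2
  arms <- matrix(FALSE, nrow(m), ncol(m))
  arms[idx[keep]] <- TRUE
  lab <- label_components(arms, 8)
  sizes <- tabulate(lab[lab > 0L])
  if (length(sizes) < 3L) stop("could not isolate three skeleton arms", call. = FALSE)
  top3 <- order(sizes, decreasing = TRUE)[1:3]
  dirs <- vapply(top3, function(k) {
    pid <- which(lab == k)
    pr <- (pid - 1L) %% nrow(m) + 1L; pc <- (pid - 1L) %/% nrow(m) + 1L
    v <- prcomp(cbind(pr, pc))$rotation[, 1]
    ctr <- c(mean(pr), mean(pc)) - bp
    if (sum(v * ctr) < 0) v <- -v
    v
  }, numeric(2))
  ang <- function(u, v) acos(pmin(pmax(sum(u * v), -1), 1)) * 180 / pi
  pairs <- combn(3, 2)
  angles <- apply(pairs, 2, function(p) ang(dirs[, p[1]], dirs[, p[2]]))
  min(angles)
}
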