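#' Segment a culture image
#'
#' Thresholds a transmitted-light or fluorescence image into a foreground
#' mask. The threshold is Otsu's by default (the published workflow does
#' not state its segmentation algorithm) or a fixed value; `polarity`
#' selects whether the culture is brighter or darker than the background.
#' Enclosed holes smaller than `fill_hole_px` pixels are filled.
#'
#' @param image `image_grid` (or numeric matrix).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold threshold value when `method = "fixed"`.
#' @param polarity `"bright"`: foreground above threshold; `"dark"`: below.
#' @param fill_hole_px holes smaller than this many pixels are filled.
#' @return binary `image_grid` (or matrix, matching the input).
#' @export
segment_culture <- function(image, method = c("otsu", "fixed"),
                            threshold = NULL,
                            polarity = c("bright", "dark"),
                            fill_hole_px = 100) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  px <- as_pixels(image)
  thr <- if (method == "otsu") otsu_threshold(px) else {
    if (is.null(threshold)) stop("fixed method needs `threshold`", call. = FALSE)
    threshold
  }
  m <- if (polarity == "bright") px > thr else px < thr
  fill_holes(restore_mask(image, m), fill_hole_px)
}

.REPORT_REGIONS <- c("trunk", "tip_stem", "tip_left", "tip_right", "tips")

# area per reporting row (sub-regions + pooled tips) of mask within labels
.region_area_rows <- function(mask, partition) {
  lab <- partition$labels
  m <- as_mask(mask)
  px2 <- partition$pixel_size^2
  a <- vapply(.LABELS[-1], function(k) sum(m & lab == k) * px2, numeric(1))
  c(a, tips = sum(a[c("tip_stem", "tip_left", "tip_right")]))
}

#' Growth expansion between two timepoints
#'
#' Per sub-region and per group, the day-14 over day-3 area ratio of the
#' superimposed, segmented culture masks -- the "relative change in
#' culture area" readout. Regions with zero day-3 area get `NA` ratios
#' and a warning.
#'
#' @param mask_d3,mask_d14 binary `image_grid`s on the same grid,
#'   registered to the partition frame.
#' @param partition a [partition_regions()] result covering both masks.
#' @return a `growth_report` data frame: region, areas (um^2),
#'   `expansion_ratio` (day14/day3) and `percent_change`.
#' @export
growth_expansion <- function(mask_d3, mask_d14, partition) {
  stopifnot(inherits(partition, "labeled_partition"))
  if (is_image_grid(mask_d3) && is_image_grid(mask_d14) &&
      !same_grid(mask_d3, mask_d14))
    stop("day-3 and day-14 masks are on different grids", call. = FALSE)
  a3 <- .region_area_rows(mask_d3, partition)
  a14 <- .region_area_rows(mask_d14, partition)
  ratio <- ifelse(a3 > 0, a14 / a3, NA_real_)
  if (any(is.na(ratio)))
    warning("zero day-3 area in region(s): ",
            paste(names(ratio)[is.na(ratio)], collapse = ", "),
            "; expansion undefined there", call. = FALSE)
  out <- data.frame(region = .REPORT_REGIONS,
                    area_day3_um2 = unname(a3[.REPORT_REGIONS]),
                    area_day14_um2 = unname(a14[.REPORT_REGIONS]),
                    expansion_ratio = unname(ratio[.REPORT_REGIONS]))
  out$percent_change <- 100 * (out$expansion_ratio - 1)
  class(out) <- c("growth_report", "data.frame")
  out
}

#' Extract the invasion area by morphological opening
#'
#' Reproduces the published invasion extraction: the segmented culture is
#' opened with a disk (radius 30 px for day-14 images, 20 px for day-10
#' images in the original Fiji workflow), which erases protrusions
#' narrower than twice the radius; the largest connected component of the
#' opening is kept as the main structure (a reproducible surrogate for
#' the manual erasing of leftovers), and the invasion mask is the
#' remainder of the original foreground, with components smaller than
#' `min_component` pixels discarded as noise.
#'
#' @param mask segmented binary `image_grid`.
#' @param opening_radius disk radius in pixels (>= 1).
#' @param min_component discard invasion components smaller than this
#'   (pixels).
#' @return an `invasion_masks` list: `main_mask`, `invasion_mask`,
#'   `discarded_px`, `opening_radius`, `min_component`.
#' @export
extract_invasion <- function(mask, opening_radius = 30, min_component = 10) {
  if (opening_radius < 1) stop("`opening_radius` must be >= 1", call. = FALSE)
  m <- as_mask(mask)
  if (!any(m)) stop("mask is empty", call. = FALSE)
  opened <- binary_opening(m, opening_radius)
  if (!any(opened))
    stop("opening removed the whole structure: radius ", opening_radius,
         " px exceeds the structure half-width", call. = FALSE)
  main <- largest_component(opened)
  invasion_raw <- m & !main
  invasion <- discard_small(invasion_raw, min_component)
  structure(list(main_mask = restore_mask(mask, main),
                 invasion_mask = restore_mask(mask, invasion),
                 discarded_px = sum(invasion_raw) - sum(invasion),
                 opening_radius = opening_radius,
                 min_component = min_component),
            class = "invasion_masks")
}

#' Per-region invasion quantification
#'
#' Assigns every invasion pixel to the region group (`tips` or `trunk`)
#' of the nearest outline pixel of the main structure -- invasions begin
#' at and cross the main outline, so the outline, not the sub-region
#' area, is the natural reference -- and normalizes each group's invasion
#' area by the group's total outline length (the three tip outlines
#' pooled), i.e. by the length of boundary from which invasions in that
#' group could have originated.
#'
#' @param invasion_mask,main_mask binary masks on the partition grid
#'   (typically from [extract_invasion()], or an `invasion_masks` object
#'   passed as `invasion_mask` with `main_mask` missing).
#' @param partition a `labeled_partition`.
#' @return an `invasion_report` data frame with one row per group:
#'   `invasion_area_um2`, `outline_length_um`, `normalized_invasion`
#'   (um^2/um), plus attributes `main_area_um2`.
#' @export
invasion_per_region <- function(invasion_mask, main_mask = NULL, partition) {
  if (inherits(invasion_mask, "invasion_masks")) {
    main_mask <- invasion_mask$main_mask
    invasion_mask <- invasion_mask$invasion_mask
  }
  stopifnot(inherits(partition, "labeled_partition"))
  main <- as_mask(main_mask); inv <- as_mask(invasion_mask)
  if (!any(main)) stop("main mask is empty", call. = FALSE)
  # outline pixels of the main structure (4-neighbour boundary)
  inner <- shift_mat(main * 1L, 1, 0) & shift_mat(main * 1L, -1, 0) &
           shift_mat(main * 1L, 0, 1) & shift_mat(main * 1L, 0, -1)
  outline <- main & !inner
  if (!any(outline)) stop("main structure has no outline", call. = FALSE)
  tip_outline <- outline & matrix(partition$labels %in% .TIP_CODES,
                                  nrow(outline), ncol(outline))
  trunk_outline <- outline & partition$labels == .LABELS[["trunk"]]
  px2 <- partition$pixel_size^2
  area <- c(tips = 0, trunk = 0)
  if (any(inv)) {
    d_tip <- if (any(tip_outline)) cpp_edt_sq(tip_outline) else
      matrix(Inf, nrow(outline), ncol(outline))
    d_trunk <- if (any(trunk_outline)) cpp_edt_sq(trunk_outline) else
      matrix(Inf, nrow(outline), ncol(outline))
    to_tip <- d_tip[inv] < d_trunk[inv]  # ties go to trunk
    area <- c(tips = sum(to_tip), trunk = sum(!to_tip)) * px2
  }
  len <- outline_lengths(partition, main)
  # normalize by the group's total outline length (all three tip outlines
  # pooled), the same length over which invasions could have originated
  olen <- c(tips = sum(len[c("tip_stem", "tip_left", "tip_right")]),
            trunk = unname(len[["trunk"]]))
  out <- data.frame(group = c("tips", "trunk"),
                    invasion_area_um2 = unname(area[c("tips", "trunk")]),
                    outline_length_um = unname(olen[c("tips", "trunk")]))
  out$normalized_invasion <- out$invasion_area_um2 / out$outline_length_um
  attr(out, "main_area_um2") <- sum(main) * px2
  class(out) <- c("invasion_report", "data.frame")
  out
}

#' Ki67 proliferation ratio per region
#'
#' Segments the DAPI and Ki67 maximum-projection channels and reports, per
#' sub-region and pooled group, the ratio of Ki67-positive nuclear area to
#' total nuclear area. One common threshold -- Otsu's on the DAPI channel
#' by default -- is applied to both channels, so equally bright nuclei
#' contribute equal segmented areas in either channel and a blank Ki67
#' channel yields a zero ratio; the Ki67 mask is additionally intersected
#' with the DAPI mask so the ratio stays in `[0, 1]`.
#'
#' @param dapi,ki67 co-registered `image_grid` channels on the partition
#'   grid.
#' @param partition a `labeled_partition`.
#' @param method `"otsu"` (threshold derived from DAPI) or `"fixed"`.
#' @param threshold threshold value when `method = "fixed"`.
#' @return a `proliferation_report` data frame: region, `dapi_area_um2`,
#'   `ki67_area_um2`, `ratio` (`NA` where the region has no DAPI signal).
#' @export
ki67_ratio <- function(dapi, ki67, partition, method = c("otsu", "fixed"),
                       threshold = NULL) {
  stopifnot(inherits(partition, "labeled_partition"))
  method <- match.arg(method)
  thr <- if (method == "otsu") otsu_threshold(as_pixels(dapi)) else {
    if (is.null(threshold)) stop("fixed method needs `threshold`", call. = FALSE)
    threshold
  }
  dm <- as_pixels(dapi) > thr
  km <- as_pixels(ki67) > thr
  km <- km & dm
  d_area <- .region_area_rows(dm, partition)
  k_area <- .region_area_rows(km, partition)
  ratio <- ifelse(d_area > 0, k_area / d_area, NA_real_)
  out <- data.frame(region = .REPORT_REGIONS,
                    dapi_area_um2 = unname(d_area[.REPORT_REGIONS]),
                    ki67_area_um2 = unname(k_area[.REPORT_REGIONS]),
                    ratio = unname(ratio[.REPORT_REGIONS]))
  class(out) <- c("proliferation_report", "data.frame")
  out
}

#' Viability from DAPI and propidium-iodide channels
#'
#' Detects nuclei as local intensity maxima of the DAPI channel above a
#' threshold, scores each nucleus PI-positive when the PI signal at its
#' position exceeds `pi_threshold`, and reports
#' `100 * (1 - n_PI / n_nuclei)`. With unit-peak channels (as produced by
#' [generate_scene()]) the default absolute PI threshold of 0.5 separates
#' a labelled nucleus from background noise.
#'
#' @param dapi,pi co-registered `image_grid` channels.
#' @param dapi_threshold nuclei detection threshold (default: Otsu).
#' @param pi_threshold PI positivity threshold at the nucleus position.
#' @return a `viability_report`: list with `n_nuclei`, `n_pi_positive`,
#'   `viability_percent`.
#' @export
viability <- function(dapi, pi, dapi_threshold = NULL, pi_threshold = 0.5) {
  d <- as_pixels(dapi); p <- as_pixels(pi)
  stopifnot(all(dim(d) == dim(p)))
  thr <- dapi_threshold %||% otsu_threshold(d)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
               c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  is_max <- d > thr
  for (o in offs) is_max <- is_max & d > shift_mat(d, o[1], o[2])
  n <- sum(is_max)
  if (n == 0L) stop("no nuclei detected in the DAPI channel", call. = FALSE)
  n_pi <- sum(p[is_max] > pi_threshold)
  structure(list(n_nuclei = n, n_pi_positive = n_pi,
                 viability_percent = 100 * (1 - n_pi / n)),
            class = "viability_report")
}

#' @export
print.viability_report <- function(x, ...) {
  cat(sprintf("<viability_report> %d nuclei, %d PI+, viability %.1f%%\n",
              x$n_nuclei, x$n_pi_positive, x$viability_percent))
  invisible(x)
}

#' Confluence time series normalized to the 0-h timepoint
#'
#' @param frames list of binary masks (or images segmented with Otsu),
#'   one per timepoint.
#' @param times timepoints in hours; strictly increasing, starting at 0.
#' @return a `confluence_series` data frame: `time_h`, `confluence`
#'   (foreground fraction), `normalized` (relative to t = 0).
#' @export
confluence_series <- function(frames, times) {
  if (!length(frames)) stop("need at least one frame", call. = FALSE)
  if (length(times) != length(frames) || times[1] != 0 ||
      any(diff(times) <= 0))
    stop("`times` must be strictly increasing and start at 0", call. = FALSE)
  conf <- vapply(frames, function(f) {
    px <- as_pixels(f)
    m <- if (is.logical(px)) px else as_mask(segment_culture(px))
    mean(m)
  }, numeric(1))
  if (conf[1] == 0)
    stop("zero confluence at t = 0: normalization undefined", call. = FALSE)
  out <- data.frame(time_h = times, confluence = conf,
                    normalized = conf / conf[1])
  class(out) <- c("confluence_series", "data.frame")
  out
}
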