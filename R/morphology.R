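#' Euclidean distance transform
#'
#' Exact distance (in pixels) from every pixel to the nearest pixel of the
#' reference set. The compiled backend implements the two-pass
#' lower-envelope algorithm, so run time is linear in the pixel count.
#'
#' @param mask binary `image_grid` or logical matrix.
#' @param to `"foreground"`: distance to the nearest foreground pixel;
#'   `"background"`: distance to the nearest background pixel, where
#'   everything outside the image also counts as background.
#' @return numeric matrix of distances in pixel units.
#' @export
distance_transform <- function(mask, to = c("foreground", "background")) {
  to <- match.arg(to)
  m <- as_mask(mask)
  if (to == "foreground") return(sqrt(cpp_edt_sq(m)))
  d <- sqrt(cpp_edt_sq(!m))
  # pixels beyond the image edge are background too
  nr <- nrow(m); nc <- ncol(m)
  border <- outer(pmin(seq_len(nr), nr + 1L - seq_len(nr)),
                  pmin(seq_len(nc), nc + 1L - seq_len(nc)), pmin)
  pmin(d, border)
}

# disk membership test: squared distance vs squared radius, inclusive
.r2 <- function(radius) radius * radius + 1e-9

#' Binary morphology with a disk structuring element
#'
#' Erosion, dilation, and opening with the Euclidean disk of the given
#' radius (in pixels), computed through the exact distance transform:
#' erosion keeps foreground pixels farther than `radius` from any
#' background pixel (the image border counts as background), dilation adds
#' pixels within `radius` of the foreground. `binary_opening` is erosion
#' followed by dilation and removes any foreground feature narrower than
#' `2 * radius`.
#'
#' @param mask binary `image_grid` or logical matrix.
#' @param radius disk radius in pixels (>= 0).
#' @return object of the same kind as `mask` (grid in, grid out).
#' @export
binary_erosion <- function(mask, radius) {
  stopifnot(radius >= 0)
  m <- as_mask(mask)
  keep <- m & (distance_transform(m, "background")^2 > .r2(radius))
  restore_mask(mask, keep)
}

#' @rdname binary_erosion
#' @export
binary_dilation <- function(mask, radius) {
  stopifnot(radius >= 0)
  m <- as_mask(mask)
  grown <- m | (cpp_edt_sq(m) <= .r2(radius))
  restore_mask(mask, grown)
}

#' @rdname binary_erosion
#' @export
binary_opening <- function(mask, radius) {
  binary_dilation(binary_erosion(mask, radius), radius)
}

restore_mask <- function(template, m) {
  if (is_image_grid(template)) grid_like(template, m) else m
}

#' Connected components and derived filters
#'
#' `label_components` labels connected foreground components (raster-scan
#' numbering); `largest_component` keeps only the biggest one;
#' `discard_small` drops components below a pixel-count threshold;
#' `fill_holes` fills enclosed background holes smaller than `max_hole`
#' pixels.
#'
#' @param mask binary `image_grid` or logical matrix.
#' @param connectivity 4 or 8 (default 8 for foreground).
#' @param min_px minimum component size (pixels) to keep.
#' @param max_hole holes with strictly fewer pixels than this are filled.
#' @return `label_components` returns an integer matrix; the others return
#'   an object of the same kind as `mask`.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  cpp_label(as_mask(mask), as.integer(connectivity))
}

#' @rdname label_components
#' @export
largest_component <- function(mask, connectivity = 8) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(restore_mask(mask, as_mask(mask)))
  sizes <- tabulate(lab[lab > 0L])
  restore_mask(mask, lab == which.max(sizes))
}

#' @rdname label_components
#' @export
discard_small <- function(mask, min_px, connectivity = 8) {
  lab <- label_components(mask, connectivity)
  m <- as_mask(mask)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    m <- lab > 0L & sizes[pmax(lab, 1L)] >= min_px
    dim(m) <- dim(lab)
  }
  restore_mask(mask, m)
}

#' @rdname label_components
#' @export
fill_holes <- function(mask, max_hole = 100) {
  m <- as_mask(mask)
  lab <- cpp_label(!m, 4L)  # background components, 4-connected
  if (max(lab) > 0L) {
    border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    sizes <- tabulate(lab[lab > 0L])
    fill_ids <- setdiff(which(sizes < max_hole), border_labels)
    if (length(fill_ids)) m[lab %in% fill_ids] <- TRUE
  }
  restore_mask(mask, m)
}

#' Otsu threshold
#'
#' Classic between-class-variance maximizing threshold on a 256-bin
#' histogram of the input values.
#'
#' @param x numeric matrix, `image_grid`, or vector; must not be constant.
#' @return threshold value; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(x) {
  v <- as.numeric(if (is_image_grid(x)) x$pixels else x)
  rng <- range(v)
  if (!is.finite(diff(rng)) || diff(rng) == 0)
    stop("otsu_threshold: image is constant, no threshold exists", call. = FALSE)
  nb <- 256L
  h <- tabulate(pmin(nb, 1L + floor((v - rng[1]) / diff(rng) * nb)), nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nb))
  mu_t <- mu[nb]
  bcv <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  bcv[!is.finite(bcv)] <- 0
  k <- which.max(bcv)
  rng[1] + k / nb * diff(rng)
}

# shift a matrix by (dr, dc) with zero padding
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

#' Topological skeleton by thinning
#'
#' Zhang-Suen iterative thinning of a binary mask down to a 1-pixel-wide
#' 8-connected skeleton. Used to measure stroke width and branch angles of
#' rasterized designs.
#'
#' @param mask binary `image_grid` or logical matrix.
#' @return logical matrix (same dims) marking skeleton pixels.
#' @export
skeletonize_mask <- function(mask) {
  m <- as_mask(mask) * 1L
  # neighbours clockwise from north: P2..P9
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P <- lapply(offs, function(o) shift_mat(m, o[1], o[2]))
      B <- Reduce(`+`, P)
      ring <- c(P, P[1])
      A <- Reduce(`+`, lapply(seq_len(8), function(k) (ring[[k]] == 0L) & (ring[[k + 1]] == 1L)))
      if (step == 1) {
        cond <- P[[1]] * P[[3]] * P[[5]] == 0L & P[[3]] * P[[5]] * P[[7]] == 0L
      } else {
        cond <- P[[1]] * P[[3]] * P[[7]] == 0L & P[[1]] * P[[5]] * P[[7]] == 0L
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & cond
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}
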