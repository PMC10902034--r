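# Independent brute-force oracles. These deliberately avoid the package's
# computational routes (distance transforms, projection formulas, 2x2
# counting): they implement the defining operation directly.

# binary erosion by explicit structuring-element shifts (border = background)
brute_erode <- function(m, radius) {
  r <- ceiling(radius)
  keep <- m
  for (dr in -r:r) for (dc in -r:r) {
    if (dr * dr + dc * dc > radius * radius + 1e-9) next
    shifted <- matrix(FALSE, nrow(m), ncol(m))
    rs <- seq_len(nrow(m)) + dr; cs <- seq_len(ncol(m)) + dc
    rok <- rs >= 1 & rs <= nrow(m); cok <- cs >= 1 & cs <= ncol(m)
    shifted[rok, cok] <- m[rs[rok], cs[cok]]
    keep <- keep & shifted
  }
  keep
}

brute_dilate <- function(m, radius) {
  r <- ceiling(radius)
  acc <- m
  for (dr in -r:r) for (dc in -r:r) {
    if (dr * dr + dc * dc > radius * radius + 1e-9) next
    shifted <- matrix(FALSE, nrow(m), ncol(m))
    rs <- seq_len(nrow(m)) + dr; cs <- seq_len(ncol(m)) + dc
    rok <- rs >= 1 & rs <= nrow(m); cok <- cs >= 1 & cs <= ncol(m)
    shifted[rok, cok] <- m[rs[rok], cs[cok]]
    acc <- acc | shifted
  }
  acc
}

brute_open <- function(m, radius) brute_dilate(brute_erode(m, radius), radius)

# squared distance to the nearest TRUE pixel by direct search
brute_edt_sq <- function(m) {
  out <- matrix(Inf, nrow(m), ncol(m))
  feat <- which(m, arr.ind = TRUE)
  if (!nrow(feat)) return(out)
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    out[i, j] <- min((feat[, 1] - i)^2 + (feat[, 2] - j)^2)
  }
  out
}

# Crofton perimeter by literally walking every sampling line in the four
# directions and counting boundary crossings (outside the image = bg)
brute_perimeter <- function(m, pixel_size = 1) {
  nr <- nrow(m); nc <- ncol(m)
  crossings_along <- function(vals) {
    v <- c(FALSE, vals, FALSE)
    sum(v[-1] != v[-length(v)])
  }
  t_rows <- sum(vapply(seq_len(nr), function(i) crossings_along(m[i, ]), numeric(1)))
  t_cols <- sum(vapply(seq_len(nc), function(j) crossings_along(m[, j]), numeric(1)))
  diag_vals <- function(flip) {
    mm <- if (flip) m[, rev(seq_len(nc)), drop = FALSE] else m
    tot <- 0
    for (k in (1 - nr):(nc - 1)) {
      i <- seq_len(nr); j <- i + k
      ok <- j >= 1 & j <= nc
      if (!any(ok)) next
      tot <- tot + crossings_along(mm[cbind(i[ok], j[ok])])
    }
    tot
  }
  (pi / 8) * (t_rows + t_cols + (diag_vals(FALSE) + diag_vals(TRUE)) / sqrt(2)) *
    pixel_size
}

# nearest-skeleton-point region assignment by dense sampling of the
# skeleton polyline (0.25 px steps), independent of the projection formula
brute_partition_codes <- function(mask, design, tip_fraction) {
  sk <- design_skeleton(design)
  pts <- list()
  for (k in 1:3) {
    n <- ceiling(sk[k, "length"] / (0.25 * mask$pixel_size))
    tt <- seq(0, 1, length.out = n + 1)
    pts[[k]] <- cbind(seg = k,
                      x = sk[k, "x0"] + tt * (sk[k, "x1"] - sk[k, "x0"]),
                      y = sk[k, "y0"] + tt * (sk[k, "y1"] - sk[k, "y0"]),
                      arc = tt * sk[k, "length"],
                      len = sk[k, "length"])
  }
  pts <- do.call(rbind, pts)
  m <- mask$pixels
  lab <- matrix(0L, nrow(m), ncol(m))
  xs <- bpq:::grid_x(mask); ys <- bpq:::grid_y(mask)
  tip_codes <- c(2L, 3L, 4L)
  for (idx in which(m)) {
    i <- (idx - 1) %% nrow(m) + 1; j <- (idx - 1) %/% nrow(m) + 1
    d2 <- (pts[, "x"] - xs[j])^2 + (pts[, "y"] - ys[i])^2
    best <- which.min(d2)
    near <- which(d2 <= d2[best] + 1e-6)
    segs <- unique(pts[near, "seg"])
    in_tip <- (pts[best, "len"] - pts[best, "arc"]) <
      tip_fraction * pts[best, "len"]
    lab[idx] <- if (length(segs) > 1 || !in_tip) 1L else tip_codes[segs[1]]
  }
  lab
}

as_mask_px <- function(x) bpq:::as_mask(x)

# mirror a symmetric-grid mask about the stem (x = 0) axis
mirror_cols <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

mirror_grid <- function(grid) bpq:::grid_like(grid, mirror_cols(grid$pixels))

# random blobby binary mask (a few dilated seed points), seeded
random_blob_mask <- function(nr, nc, n_seeds = 4, radius = 6, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(FALSE, nr, nc)
    m[cbind(sample(nr, n_seeds), sample(nc, n_seeds))] <- TRUE
    brute_dilate(m, radius)
  })
}
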