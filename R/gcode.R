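#' Well layout for printing
#'
#' A layout places one or more Y-designs at planar offsets inside a well
#' and records the print parameters. The default mirrors the published
#' protocol: four Y-shaped structures per well, printed at 1 mm/s under
#' 5 mbar pneumatic pressure from a 3e6 cells/ml suspension.
#'
#' @param designs list of `y_design` objects.
#' @param offsets list/matrix of planar (x, y) offsets in um, one per design.
#' @param print_speed print speed in mm/s.
#' @param pressure pneumatic pressure in mbar.
#' @param cell_density cell suspension density, cells/ml.
#' @return a `well_layout`.
#' @export
well_layout <- function(designs, offsets, print_speed = 1, pressure = 5,
                        cell_density = 3e6) {
  if (!length(designs)) stop("layout needs at least one design", call. = FALSE)
  stopifnot(all(vapply(designs, inherits, logical(1), "y_design")))
  offsets <- if (is.matrix(offsets)) lapply(seq_len(nrow(offsets)), function(i) offsets[i, ])
             else offsets
  stopifnot(length(offsets) == length(designs))
  structure(list(designs = designs, offsets = lapply(offsets, as.numeric),
                 print_speed = print_speed, pressure = pressure,
                 cell_density = cell_density),
            class = "well_layout")
}

#' @rdname well_layout
#' @param design the design replicated at every position.
#' @param n number of structures (default 4 per well).
#' @param spacing grid spacing between structure origins, um; must exceed
#'   the design footprint so rasterized structures do not overlap.
#' @export
default_well_layout <- function(design = y_design(), n = 4, spacing = 3200) {
  ext <- 2 * (max(design$stem_length, design$branch_length) +
              design$stroke_width / 2)
  if (spacing <= ext)
    stop("spacing ", spacing, " um gives overlapping footprints", call. = FALSE)
  side <- ceiling(sqrt(n))
  offs <- lapply(seq_len(n) - 1L,
                 function(k) c((k %% side) * spacing, (k %/% side) * spacing))
  well_layout(rep(list(design), n), offs)
}

#' @export
print.well_layout <- function(x, ...) {
  cat(sprintf("<well_layout> %d structures, %g mm/s, %g mbar, %.3g cells/ml\n",
              length(x$designs), x$print_speed, x$pressure, x$cell_density))
  invisible(x)
}

# skeleton toolpath of one structure (um), in print order:
# stem tip -> branch point -> left tip, travel, branch point -> right tip
structure_path <- function(design, offset = c(0, 0)) {
  sk <- design_skeleton(design)
  shift <- function(p) p + offset
  list(draw1 = rbind(shift(sk["stem", c("x1", "y1")]),
                     shift(sk["stem", c("x0", "y0")]),
                     shift(sk["left", c("x1", "y1")])),
       draw2 = rbind(shift(sk["right", c("x0", "y0")]),
                     shift(sk["right", c("x1", "y1")])))
}

#' Emit a G-code toolpath for a well layout
#'
#' Produces plain-text RepRap-dialect G-code: for every structure a `G0`
#' travel to the stem tip followed by chained `G1` draw moves tracing the
#' stem, then the left branch, then (after a travel back to the branch
#' point) the right branch -- the print order of the published design.
#' Every `G1` carries the feed word `F = print_speed * 60` (mm/min; 1 mm/s
#' gives `F60`). The pneumatic pressure is recorded as a comment since
#' RepRap G-code has no pressure word. Coordinates are millimetres.
#'
#' @param layout a `well_layout`.
#' @param z_height print height in mm.
#' @return a single string of G-code text.
#' @export
emit_gcode <- function(layout, z_height = 0) {
  stopifnot(inherits(layout, "well_layout"))
  if (!length(layout$designs)) stop("empty layout", call. = FALSE)
  feed <- layout$print_speed * 60
  fmt <- function(cmd, p, f = NULL)
    sprintf("%s X%.4f Y%.4f Z%.4f%s", cmd, p[1] / 1000, p[2] / 1000, z_height,
            if (is.null(f)) "" else sprintf(" F%g", f))
  out <- c("; bpq toolpath",
           sprintf("; print_speed_mm_per_s: %g", layout$print_speed),
           sprintf("; pressure_mbar: %g", layout$pressure),
           sprintf("; cell_density_cells_per_ml: %g", layout$cell_density),
           "G21 ; millimetres", "G90 ; absolute coordinates")
  for (i in seq_along(layout$designs)) {
    path <- structure_path(layout$designs[[i]], layout$offsets[[i]])
    out <- c(out, sprintf("; structure %d", i),
             fmt("G0", path$draw1[1, ]),
             fmt("G1", path$draw1[2, ], feed),
             fmt("G1", path$draw1[3, ], feed),
             fmt("G0", path$draw2[1, ]),
             fmt("G1", path$draw2[2, ], feed))
  }
  paste(out, collapse = "\n")
}

#' Parse a G-code toolpath
#'
#' Reads `G0`/`G1` motion commands with `X`/`Y` words, splitting polylines
#' at `G0` travels. Unknown words are skipped with a single warning.
#'
#' @param text G-code text (single string or character vector of lines).
#' @return list with `polylines` (list of n x 2 matrices, mm) and `feed`
#'   (last seen feed, mm/min, or `NA`).
#' @export
parse_gcode <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  polylines <- list(); current <- NULL
  pos <- c(NA_real_, NA_real_); feed <- NA_real_
  unknown <- character(0)
  n_motion <- 0L
  for (ln in lines) {
    words <- strsplit(ln, "[[:space:]]+")[[1]]
    cmd <- toupper(words[1])
    if (!cmd %in% c("G0", "G1", "G00", "G01", "G21", "G90")) {
      unknown <- c(unknown, cmd)
      next
    }
    if (cmd %in% c("G21", "G90")) next
    x <- pos[1]; y <- pos[2]
    for (w in words[-1]) {
      key <- toupper(substr(w, 1, 1))
      val <- suppressWarnings(as.numeric(substr(w, 2, nchar(w))))
      if (key == "X") x <- val else if (key == "Y") y <- val
      else if (key == "F") feed <- val
      else if (key != "Z") unknown <- c(unknown, key)
    }
    pos <- c(x, y)
    n_motion <- n_motion + 1L
    if (cmd %in% c("G0", "G00")) {
      if (!is.null(current) && nrow(current) > 1L)
        polylines <- c(polylines, list(current))
      current <- matrix(pos, ncol = 2)
    } else {
      if (is.null(current)) current <- matrix(pos, ncol = 2)
      else current <- rbind(current, pos)
    }
  }
  if (!is.null(current) && nrow(current) > 1L)
    polylines <- c(polylines, list(current))
  if (n_motion == 0L)
    stop("no motion commands (G0/G1) found in G-code input", call. = FALSE)
  if (length(unknown))
    warning("ignored unknown G-code words: ",
            paste(unique(unknown), collapse = ", "), call. = FALSE)
  polylines <- lapply(polylines, function(p) {
    dimnames(p) <- list(NULL, c("x", "y")); p
  })
  list(polylines = polylines, feed = feed)
}
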