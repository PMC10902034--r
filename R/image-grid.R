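#' Image grid
#'
#' A light container pairing a 2D pixel array with its physical pixel size
#' and the world coordinate of the first pixel center. Rows run top to
#' bottom (decreasing world y), columns left to right (increasing world x),
#' matching the usual microscopy image convention.
#'
#' @param pixels numeric, integer or logical matrix (non-empty).
#' @param pixel_size pixel edge length in micrometres (> 0).
#' @param origin length-2 numeric: world (x, y) in micrometres of the center
#'   of pixel `[1, 1]` (top-left).
#' @return An `image_grid` object.
#' @export
image_grid <- function(pixels, pixel_size, origin = c(0, 0)) {
  if (!is.matrix(pixels) || nrow(pixels) == 0L || ncol(pixels) == 0L)
    stop("`pixels` must be a non-empty matrix", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  if (length(origin) != 2L || !is.numeric(origin))
    stop("`origin` must be a numeric length-2 vector", call. = FALSE)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 origin = as.numeric(origin)),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d px, %.3g um/px, origin (%.4g, %.4g) um\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              x$origin[1], x$origin[2]))
  invisible(x)
}

#' @export
dim.image_grid <- function(x) dim(x$pixels)

is_image_grid <- function(x) inherits(x, "image_grid")

# Replace the pixel array, keeping geometry.
grid_like <- function(grid, pixels) {
  image_grid(pixels, grid$pixel_size, grid$origin)
}

# World x of every column / world y of every row (pixel centers, um).
grid_x <- function(grid) grid$origin[1] + (seq_len(ncol(grid$pixels)) - 1L) * grid$pixel_size
grid_y <- function(grid) grid$origin[2] - (seq_len(nrow(grid$pixels)) - 1L) * grid$pixel_size

# Coerce image_grid | matrix -> plain matrix.
as_pixels <- function(x) {
  if (is_image_grid(x)) x$pixels else if (is.matrix(x)) x else
    stop("expected an image_grid or a matrix", call. = FALSE)
}

# Logical foreground from a mask-like input (>0 counts as foreground).
as_mask <- function(x) {
  px <- as_pixels(x)
  if (is.logical(px)) px else px > 0
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$pixels), dim(b$pixels)) &&
    abs(a$pixel_size - b$pixel_size) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

#' Read and write portable graymap (PGM, plain `P2`) images
#'
#' Plain-text image I/O used for masks, label maps and scaled intensity
#' channels; the text variant keeps all fixtures human-readable and
#' version-controllable. `pixel_size` and `origin` are stored in a comment
#' line so that grids round-trip.
#'
#' @param grid an `image_grid` with non-negative integer pixels.
#' @param path file path.
#' @param maxval maximum gray value declared in the header.
#' @return `read_pgm` returns an `image_grid`; `write_pgm` returns `path`
#'   invisibly.
#' @export
write_pgm <- function(grid, path, maxval = NULL) {
  px <- as_pixels(grid)
  if (is.logical(px)) px <- px * 1L
  px <- round(px)
  if (any(px < 0)) stop("PGM pixels must be non-negative", call. = FALSE)
  if (is.null(maxval)) maxval <- max(1, max(px))
  ps <- if (is_image_grid(grid)) grid$pixel_size else 1
  org <- if (is_image_grid(grid)) grid$origin else c(0, 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2",
               sprintf("# bpq pixel_size=%.10g origin=%.10g,%.10g", ps, org[1], org[2]),
               sprintf("%d %d", ncol(px), nrow(px)),
               sprintf("%d", maxval)), con)
  write.table(px, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || trimws(lines[1]) != "P2")
    stop("not a plain (P2) PGM file: ", path, call. = FALSE)
  ps <- 1; org <- c(0, 0)
  meta <- grep("^# bpq pixel_size=", lines, value = TRUE)
  if (length(meta)) {
    m <- regmatches(meta[1],
      regexec("pixel_size=([-0-9.eE+]+) origin=([-0-9.eE+]+),([-0-9.eE+]+)", meta[1]))[[1]]
    ps <- as.numeric(m[2]); org <- as.numeric(m[3:4])
  }
  body <- lines[!startsWith(trimws(lines), "#")][-1]  # drop "P2" and comments
  nums <- scan(text = paste(body, collapse = "\n"), quiet = TRUE)
  nc <- nums[1]; nr <- nums[2]
  px <- matrix(as.integer(nums[-(1:3)]), nrow = nr, ncol = nc, byrow = TRUE)
  image_grid(px, ps, org)
}
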