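#' Hertz force for spherical indentation
#'
#' Contact force of a rigid sphere of radius `R` indenting an elastic
#' half-space by `delta`:
#' `F = (4/3) * E / (1 - nu^2) * sqrt(R) * delta^(3/2)`.
#' All quantities are SI (m, N, Pa).
#'
#' @param delta indentation depth(s), m, non-negative.
#' @param E Young's modulus, Pa (> 0).
#' @param nu Poisson's ratio in `[0, 0.5]`; 0.5 (incompressible) is the
#'   value used for soft hydrogels.
#' @param R indenter (bead) radius, m (> 0).
#' @return force in N, vectorized over `delta`.
#' @export
#' @examples
#' hertz_force(1e-6, E = 100, nu = 0.5, R = 2.25e-6)  # 2.667e-10 N
hertz_force <- function(delta, E, nu = 0.5, R) {
  if (any(delta < 0)) stop("`delta` must be non-negative", call. = FALSE)
  if (!is.numeric(E) || E <= 0) stop("`E` must be positive", call. = FALSE)
  if (nu < 0 || nu > 0.5) stop("`nu` must lie in [0, 0.5]", call. = FALSE)
  if (R <= 0) stop("`R` must be positive", call. = FALSE)
  (4 / 3) * E / (1 - nu^2) * sqrt(R) * delta^1.5
}

#' One AFM approach curve
#'
#' @param delta indentation depths, m; non-negative, strictly increasing,
#'   at least 10 samples.
#' @param force measured forces, N; same length as `delta`.
#' @param bead_radius indenter radius, m.
#' @param metadata free-form list (region id, grid position, repeat ...).
#' @return an `indentation_curve`.
#' @export
indentation_curve <- function(delta, force, bead_radius, metadata = list()) {
  if (length(delta) != length(force))
    stop("`delta` and `force` must have equal length", call. = FALSE)
  if (length(delta) < 10L)
    stop("an indentation curve needs at least 10 samples", call. = FALSE)
  if (any(delta < 0) || any(diff(delta) <= 0))
    stop("`delta` must be non-negative and strictly increasing", call. = FALSE)
  if (bead_radius <= 0) stop("`bead_radius` must be positive", call. = FALSE)
  structure(list(delta = as.numeric(delta), force = as.numeric(force),
                 bead_radius = bead_radius, metadata = metadata),
            class = "indentation_curve")
}

#' @export
print.indentation_curve <- function(x, ...) {
  cat(sprintf("<indentation_curve> %d pts, delta <= %.3g m, F <= %.3g N, R = %.3g m\n",
              length(x$delta), max(x$delta), max(x$force), x$bead_radius))
  invisible(x)
}

#' AFM sampling plan
#'
#' The published measurement plan indents each gel in `n_regions` regions,
#' each sampled on a `grid_side x grid_side` point grid spanning
#' `span x span` um^2 with `repeats` indentations per location; the
#' defaults give the 3 x 5 x 5 x 3 = 225 curves per gel of the protocol.
#'
#' @param n_regions number of regions.
#' @param grid_side points per grid edge.
#' @param span grid edge length, um.
#' @param repeats indentations per grid point.
#' @return a `sampling_plan`: data frame of (region, x_um, y_um, rep) with
#'   attribute `total`.
#' @export
build_plan <- function(n_regions = 3, grid_side = 5, span = 100, repeats = 3) {
  stopifnot(n_regions >= 1, grid_side >= 1, span > 0, repeats >= 1)
  coord <- if (grid_side == 1) span / 2 else seq(0, span, length.out = grid_side)
  plan <- expand.grid(rep = seq_len(repeats), y_um = coord, x_um = coord,
                      region = seq_len(n_regions))[, 4:1]
  rownames(plan) <- NULL
  structure(plan, total = nrow(plan), class = c("sampling_plan", "data.frame"))
}

#' Generate synthetic Hertz indentation curves
#'
#' Samples each curve's indentation depth uniformly from 0 to the depth at
#' which the Hertz force reaches `max_force`, evaluates the Hertz model,
#' and adds i.i.d. Gaussian force noise with standard deviation
#' `noise_sd * max_force`. One curve is produced per row of `plan`, with
#' the plan row recorded in the curve metadata. Deterministic for a given
#' seed.
#'
#' @param E_true ground-truth Young's modulus, Pa.
#' @param nu Poisson's ratio (default 0.5).
#' @param bead_radius bead radius, m (default 2.25e-6: a 4.5 um bead).
#' @param max_force force setpoint, N (default 4e-9: 4 nN).
#' @param n_points samples per curve.
#' @param plan a [build_plan()] sampling plan (default: 225 curves).
#' @param noise_sd Gaussian force noise as a fraction of `max_force`.
#' @param seed integer RNG seed.
#' @return list of [indentation_curve()] objects, length `nrow(plan)`.
#' @export
generate_afm_curves <- function(E_true, nu = 0.5, bead_radius = 2.25e-6,
                                max_force = 4e-9, n_points = 200,
                                plan = build_plan(), noise_sd = 0.05,
                                seed = 1) {
  if (E_true <= 0) stop("`E_true` must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (max_force <= 0 || bead_radius <= 0)
    stop("`max_force` and `bead_radius` must be positive", call. = FALSE)
  delta_max <- (3 * max_force * (1 - nu^2) / (4 * E_true * sqrt(bead_radius)))^(2 / 3)
  delta <- seq(0, delta_max, length.out = n_points)
  f0 <- hertz_force(delta, E_true, nu, bead_radius)
  with_seed(seed, {
    lapply(seq_len(nrow(plan)), function(i) {
      noise <- rnorm(n_points, 0, noise_sd * max_force)
      indentation_curve(delta, f0 + noise, bead_radius,
                        metadata = as.list(plan[i, ]))
    })
  })
}

#' Fit the Hertz model to an indentation curve
#'
#' Least-squares fit of Young's modulus `E` and a contact-point offset
#' `delta0`, modelling `F = hertz(max(delta - delta0, 0))`. The problem is
#' separable: for fixed `delta0` the optimal `E` is a closed-form linear
#' least-squares solution, so `delta0` is found by deterministic
#' golden-section search over `[0, 0.9 * max(delta)]` (with the boundary
#' `delta0 = 0` also evaluated exactly). Points above `max_force` are
#' excluded from the fit. The fit is flagged non-converged when the
#' relative residual `sqrt(rss / sum(F^2))` exceeds 20%.
#'
#' @param curve an [indentation_curve()].
#' @param nu Poisson's ratio (default 0.5).
#' @param max_force fit range cap, N (default 4e-9).
#' @return a `hertz_fit`: list with `E` (Pa), `delta0` (m), `rss` (N^2),
#'   `converged`, `n_used`.
#' @export
fit_hertz <- function(curve, nu = 0.5, max_force = 4e-9) {
  stopifnot(inherits(curve, "indentation_curve"))
  keep <- curve$force <= max_force
  d <- curve$delta[keep]; f <- curve$force[keep]
  pref <- (4 / 3) * sqrt(curve$bead_radius) / (1 - nu^2)
  obj <- function(d0) {
    x <- pref * pmax(d - d0, 0)^1.5
    sxx <- sum(x * x)
    E <- if (sxx > 0) max(sum(f * x) / sxx, 0) else 0
    list(E = E, rss = sum((f - E * x)^2))
  }
  if (length(d) < 10L || sum(d > 0) < 10L)
    stop("fewer than 10 usable points above contact", call. = FALSE)
  up <- 0.9 * max(d)
  opt <- optimize(function(d0) obj(d0)$rss, c(0, up), tol = max(d) * 1e-7)
  cand <- list(c(d0 = 0, rss = obj(0)$rss),
               c(d0 = opt$minimum, rss = opt$objective))
  best <- cand[[which.min(vapply(cand, `[`, numeric(1), "rss"))]]
  d0 <- unname(best["d0"])
  if (sum(d > d0) < 10L)
    stop("fewer than 10 points above the fitted contact point", call. = FALSE)
  fit <- obj(d0)
  rel <- sqrt(fit$rss / max(sum(f^2), .Machine$double.xmin))
  structure(list(E = fit$E, delta0 = d0, rss = fit$rss,
                 converged = is.finite(fit$E) && fit$E > 0 && rel <= 0.2,
                 n_used = length(d)),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("<hertz_fit> E = %.4g Pa, delta0 = %.3g m, rss = %.3g N^2, %s\n",
              x$E, x$delta0, x$rss,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Gaussian summary of fitted moduli
#'
#' Mean and standard deviation of Young's modulus over converged fits,
#' with a Shapiro-Wilk normality check mirroring the published analysis
#' (moduli were summarized as mean +/- SD after confirming a Gaussian
#' distribution). A warning is raised when normality is rejected at
#' p <= 0.05.
#'
#' @param fits list of `hertz_fit` objects.
#' @return a `modulus_summary`: list with `mean`, `sd` (Pa), `n`,
#'   `normality_p` (NA when the test is undefined, e.g. identical values).
#' @export
summarize_modulus <- function(fits) {
  stopifnot(is.list(fits))
  E <- vapply(fits, function(f) {
    stopifnot(inherits(f, "hertz_fit"))
    if (isTRUE(f$converged)) f$E else NA_real_
  }, numeric(1))
  E <- E[!is.na(E)]
  if (length(E) < 3L)
    stop("need at least 3 converged fits to summarize", call. = FALSE)
  p <- tryCatch(shapiro.test(E)$p.value, error = function(e) NA_real_)
  if (!is.na(p) && p <= 0.05)
    warning(sprintf("modulus sample departs from normality (Shapiro-Wilk p = %.3g); mean +/- SD may be misleading", p),
            call. = FALSE)
  structure(list(mean = mean(E), sd = sd(E), n = length(E), normality_p = p),
            class = "modulus_summary")
}

#' @export
print.modulus_summary <- function(x, ...) {
  cat(sprintf("<modulus_summary> E = %.4g +/- %.3g Pa (n = %d, Shapiro-Wilk p = %.3g)\n",
              x$mean, x$sd, x$n, x$normality_p))
  invisible(x)
}

#' Read and write indentation curves as CSV
#'
#' One tidy CSV holds all curves: columns `curve_id`, `delta_m`,
#' `force_N`, plus a JSON sidecar (`<path>.json`) with bead radius and
#' per-curve metadata.
#'
#' @param curves list of `indentation_curve` objects.
#' @param path CSV file path.
#' @return `read_indentation_csv` returns a list of curves;
#'   `write_indentation_csv` returns `path` invisibly.
#' @export
write_indentation_csv <- function(curves, path) {
  df <- do.call(rbind, lapply(seq_along(curves), function(i) {
    data.frame(curve_id = i, delta_m = curves[[i]]$delta,
               force_N = curves[[i]]$force)
  }))
  write.csv(df, path, row.names = FALSE)
  meta <- list(bead_radius_m = curves[[1]]$bead_radius,
               metadata = lapply(curves, `[[`, "metadata"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_indentation_csv
#' @export
read_indentation_csv <- function(path) {
  df <- read.csv(path)
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json")) else list(bead_radius_m = NA)
  R <- as.numeric(meta$bead_radius_m)
  lapply(split(df, df$curve_id), function(d) {
    i <- d$curve_id[1]
    md <- if (length(meta$metadata) >= i) meta$metadata[[i]] else list()
    indentation_curve(d$delta_m, d$force_N, R, metadata = md)
  })
}
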