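#' Unpolarized Fresnel power coefficients
#'
#' Mean of the s- and p-polarized Fresnel power reflectances at a planar
#' interface, with the refraction angle from Snell's law. Beyond the
#' critical angle (when `n1 > n2`) the interface totally reflects.
#'
#' @param incidence_angle angle of incidence in degrees, in \[0, 90\].
#' @param n1 refractive index of the incidence medium (>= 1).
#' @param n2 refractive index of the far medium (>= 1).
#' @return A list with `R`, `T = 1 - R`, `refraction_angle` (degrees, `NA`
#'   under total internal reflection) and logical `tir`.
#' @examples
#' fresnel_unpolarized(0, 1, 1.4)$R      # ((1.4-1)/(1.4+1))^2
#' fresnel_unpolarized(50, 1.4, 1)$tir   # beyond the critical angle
#' @export
fresnel_unpolarized <- function(incidence_angle, n1, n2) {
  if (!is.finite(incidence_angle) || incidence_angle < 0 ||
      incidence_angle > 90) {
    stop("incidence_angle must lie in [0, 90] degrees")
  }
  if (n1 < 1 || n2 < 1) stop("refractive indices must be >= 1")
  ti <- incidence_angle * pi / 180
  sint <- n1 / n2 * sin(ti)
  if (sint >= 1) {
    return(list(R = 1, T = 0, refraction_angle = NA_real_, tir = TRUE))
  }
  cosi <- cos(ti)
  cost <- sqrt(1 - sint^2)
  rs <- (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost)
  rp <- (n2 * cosi - n1 * cost) / (n2 * cosi + n1 * cost)
  R <- 0.5 * (rs^2 + rp^2)
  list(R = R, T = 1 - R, refraction_angle = asin(sint) * 180 / pi,
       tir = FALSE)
}

#' Intersect a single ray with a profile height field
#'
#' First intersection of a ray with the piecewise-linear sampled profile,
#' strictly ahead of the origin (beyond a small epsilon); x is wrapped
#' periodically. A ray leaving the slab above `max(h)` (upward) or below
#' `min(h)` (downward) returns a no-hit.
#'
#' @param profile a [build_profile()] object.
#' @param origin numeric `c(x, z)` in micrometres.
#' @param direction numeric 2-vector (normalised internally).
#' @param eps self-intersection guard distance (micrometres).
#' @return A list with `hit` (logical) and, when hit, the intersection
#'   `x`, `z`, ray parameter `t`, upward unit `normal` and the local
#'   `incidence_deg`.
#' @export
intersect_height_field <- function(profile, origin, direction, eps = 1e-6) {
  stopifnot(inherits(profile, "surface_profile"))
  d <- as.numeric(direction)
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) stop("direction must be non-zero")
  d <- d / nrm
  intersect_polyline_cpp(profile$h, profile$dx, min(profile$h) - 1e-9,
                         max(profile$h) + 1e-9, origin[1], origin[2],
                         d[1], d[2], eps, 1e6)
}

#' Monte Carlo scattering simulation on a surface profile
#'
#' Launches parallel rays at incidence angle `theta_i` onto the profile,
#' from the air side (`mode = "reflection"`) or from inside the medium
#' (`mode = "transmission"`). At every surface hit the ray splits
#' deterministically into a reflected and a refracted child weighted by the
#' local unpolarized Fresnel coefficients (the refracted child is omitted
#' under total internal reflection); children re-intersect the height field
#' until they escape or fall below the power cutoff / bounce limit.
#' Monte Carlo randomness enters only through the seeded uniform launch
#' positions over one macro period.
#'
#' Escaped power is binned by signed global exit angle. `R` is the power
#' returned to the source side and `T` the power delivered across the
#' surface, so under air-side illumination `R` is the diffuse reflectance
#' (air to medium) and under medium-side illumination `T` is the diffuse
#' transmittance (medium to air).
#'
#' @param profile a [build_profile()] object.
#' @param theta_i incidence angle in degrees, `0 <= theta_i < 90`.
#' @param mode `"reflection"` (illuminated from air, above) or
#'   `"transmission"` (illuminated from inside the medium, below).
#' @param n_outside refractive index above the surface (default air, 1).
#' @param n_inside refractive index below the surface; defaults to the
#'   profile's `params$n`.
#' @param ray_count number of launched rays (>= 1).
#' @param seed integer seed for the launch positions.
#' @param max_depth maximum number of surface interactions per branch.
#' @param power_cutoff branch termination threshold as a fraction of one
#'   launched ray's power; terminated power is reported as `residual`.
#' @param bin_width angular bin width in degrees for the distributions.
#' @return An object of class `scatter_result`: `reflection_distribution`
#'   and `transmission_distribution` ([bin_exit_rays()] objects for the
#'   source and far side), `R`, `T`, `residual`, `theta_i`, `mode`,
#'   `ray_count`, `seed` and bounce statistics, plus the raw exit records.
#' @examples
#' flat <- build_profile(surface_params(100, 0, 0, 0, 1), 1, 256)
#' res <- simulate_scattering(flat, 45, "reflection", ray_count = 100, seed = 1)
#' res$R  # unpolarized Fresnel reflectance at 45 degrees
#' @export
simulate_scattering <- function(profile, theta_i,
                                mode = c("reflection", "transmission"),
                                n_outside = 1.0, n_inside = NULL,
                                ray_count = 1e5, seed = 1L, max_depth = 20L,
                                power_cutoff = 1e-4, bin_width = 1) {
  stopifnot(inherits(profile, "surface_profile"))
  mode <- match.arg(mode)
  if (!is.finite(theta_i) || theta_i < 0 || theta_i >= 90) {
    stop("theta_i must lie in [0, 90) degrees")
  }
  if (any(!is.finite(profile$h))) stop("profile heights must be finite")
  if (ray_count < 1) stop("ray_count must be >= 1")
  if (is.null(n_inside)) n_inside <- profile$params$n

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  launch_x <- runif(ray_count, 0, profile$period)

  raw <- trace_rays_cpp(profile$h, profile$dx, profile$zmin - 1e-9,
                        profile$zmax + 1e-9, launch_x, theta_i,
                        mode == "reflection", n_outside, n_inside,
                        as.integer(max_depth), power_cutoff, 1e-6, 2e6)
  up_power <- sum(raw$up_power)
  down_power <- sum(raw$down_power)
  up_dist <- bin_exit_rays(raw$up_angle, raw$up_power, bin_width,
                           side = if (mode == "reflection") "reflection"
                                  else "transmission")
  down_dist <- bin_exit_rays(raw$down_angle, raw$down_power, bin_width,
                             side = if (mode == "reflection") "transmission"
                                    else "reflection")
  if (mode == "reflection") {
    R <- up_power; T <- down_power
    refl_dist <- up_dist; trans_dist <- down_dist
  } else {
    R <- down_power; T <- up_power
    refl_dist <- down_dist; trans_dist <- up_dist
  }
  structure(list(
    reflection_distribution = refl_dist,
    transmission_distribution = trans_dist,
    R = R, T = T, residual = raw$residual, lost = raw$lost,
    theta_i = theta_i, mode = mode, ray_count = ray_count, seed = seed,
    n_outside = n_outside, n_inside = n_inside,
    n_hits = raw$n_hits, n_traced = raw$n_traced, deepest = raw$deepest,
    exit_up = data.frame(angle = raw$up_angle, power = raw$up_power),
    exit_down = data.frame(angle = raw$down_angle, power = raw$down_power)),
    class = "scatter_result")
}

#' @export
print.scatter_result <- function(x, ...) {
  cat(sprintf(
    "Scattering run (%s mode, theta_i = %g deg, %d rays, seed %d)\n",
    x$mode, x$theta_i, x$ray_count, x$seed))
  cat(sprintf("  R = %.6f  T = %.6f  residual = %.3g\n", x$R, x$T, x$residual))
  cat(sprintf("  %d surface hits, %d branches, deepest split %d\n",
              x$n_hits, x$n_traced, x$deepest))
  invisible(x)
}

#' Export a scattering run
#'
#' Writes the angular distributions as CSV (`theta_deg, power_per_degree`)
#' and the run summary as JSON.
#'
#' @param result a `scatter_result`.
#' @param dist_path,summary_path output file paths (`NULL` skips a file).
#' @return Invisibly, the paths written.
#' @export
write_scatter_result <- function(result, dist_path = NULL,
                                 summary_path = NULL) {
  stopifnot(inherits(result, "scatter_result"))
  written <- character(0)
  if (!is.null(dist_path)) {
    rd <- result$reflection_distribution
    td <- result$transmission_distribution
    df <- rbind(
      data.frame(side = rd$side, theta_deg = rd$theta,
                 power_per_degree = rd$intensity),
      data.frame(side = td$side, theta_deg = td$theta,
                 power_per_degree = td$intensity))
    write.csv(df, dist_path, row.names = FALSE)
    written <- c(written, dist_path)
  }
  if (!is.null(summary_path)) {
    jsonlite::write_json(
      list(mode = result$mode, theta_i_deg = result$theta_i, R = result$R,
           T = result$T, residual = result$residual,
           ray_count = result$ray_count, seed = result$seed,
           n_outside = result$n_outside, n_inside = result$n_inside),
      summary_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, summary_path)
  }
  invisible(written)
}
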