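#' Direct-path translucency component
#'
#' Angle average, over incidence angles 0 to 90 degrees inside the skin, of
#' the probability that internally reflected light crosses the textured
#' surface along its direct path: `<(1 - R(theta_i)) * T(theta_i')>`, where
#' `theta_i' = asin(sin(theta_i) / n_rel)` is the refraction angle inside
#' the medium (Snell's law, relative index `n_rel`, default skin 1.4).
#'
#' @param u_ratio SMT ripple aspect ratio `u_w/u_h`.
#' @param step quadrature step in degrees (default 0.01).
#' @param n_rel relative refractive index used for the refraction angle.
#' @param R_fun,T_fun reflectance/transmittance models, functions of
#'   `(theta_i, u_ratio)`; default the published closed forms.
#' @return The direct translucency component, a fraction.
#' @export
translucency_direct <- function(u_ratio, step = 0.01, n_rel = 1.4,
                                R_fun = reflectance_model,
                                T_fun = transmittance_model) {
  if (u_ratio <= 0) stop("u_ratio must be > 0")
  if (step <= 0 || step > 0.1) stop("step must be in (0, 0.1] degrees")
  theta <- seq(0, 90, by = step)
  if (theta[length(theta)] < 90) theta <- c(theta, 90)
  theta_p <- asin(pmin(1, sin(theta * pi / 180) / n_rel)) * 180 / pi
  y <- (1 - R_fun(theta, u_ratio)) * T_fun(theta_p, u_ratio)
  sum(diff(theta) * (y[-1] + y[-length(y)]) / 2) / 90
}

#' Diffuse-path translucency component
#'
#' Product of the two separate angle averages `<1 - R>` and `<T>`: the
#' internally scattered light is assumed isotropic, so escape through the
#' texture decouples from the arrival direction.
#'
#' @inheritParams translucency_direct
#' @return The diffuse translucency component, a fraction.
#' @export
translucency_diffuse <- function(u_ratio, step = 0.01,
                                 R_fun = reflectance_model,
                                 T_fun = transmittance_model) {
  if (u_ratio <= 0) stop("u_ratio must be > 0")
  one_minus_R <- function(theta_i, u) 1 - R_fun(theta_i, u)
  angle_average(one_minus_R, u_ratio, step = step) *
    angle_average(T_fun, u_ratio, step = step)
}

#' Total translucency index
#'
#' Affine mix of the diffuse and direct components,
#' `tau = eta * tau_diffuse + (1 - eta) * tau_direct`, where `eta` is the
#' fraction of the internally reflected light that is diffusely scattered.
#' `eta` is an input: the single-layer surface model provides no estimator
#' for the diffuse fraction.
#'
#' @param eta diffuse mixing ratio, in \[0, 1\].
#' @inheritParams translucency_direct
#' @return An object of class `translucency_result` with `tau_direct`,
#'   `tau_diffuse`, `tau`, `eta`, `u_ratio` and the quadrature `step`.
#' @examples
#' translucency_index(0.5, 11.8)
#' @export
translucency_index <- function(eta, u_ratio, step = 0.01, n_rel = 1.4,
                               R_fun = reflectance_model,
                               T_fun = transmittance_model) {
  if (!is.finite(eta) || eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  td <- translucency_direct(u_ratio, step = step, n_rel = n_rel,
                            R_fun = R_fun, T_fun = T_fun)
  tf <- translucency_diffuse(u_ratio, step = step, R_fun = R_fun,
                             T_fun = T_fun)
  structure(list(tau_direct = td, tau_diffuse = tf,
                 tau = eta * tf + (1 - eta) * td, eta = eta,
                 u_ratio = u_ratio, step = step),
            class = "translucency_result")
}

#' @export
print.translucency_result <- function(x, ...) {
  cat(sprintf(
    "Translucency index at u_w/u_h = %g, eta = %g:\n", x$u_ratio, x$eta))
  cat(sprintf("  tau_direct = %.5f  tau_diffuse = %.5f  tau = %.5f\n",
              x$tau_direct, x$tau_diffuse, x$tau))
  invisible(x)
}
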