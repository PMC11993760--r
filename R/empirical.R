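#' Empirical model coefficient tables
#'
#' The published constants of the closed-form models linking the texture
#' ratios `u_w/u_h` (ripple period over height) and `W_V/W` (sulcus width
#' over macro period) to the Gaussian lobe amplitude and width and to the
#' reflectance/transmittance sigmoids. Every model function accepts a
#' `coef` argument defaulting to these values, so alternative calibrations
#' (e.g. refits against this package's own tracer, or corrections of
#' suspected misprints) can be supplied without code changes.
#'
#' @return A named list of coefficient vectors:
#'   \describe{
#'     \item{amp_reflection}{`a, b, c` in `A/I_s = (a + b*wv)*u + c`.}
#'     \item{width_reflection}{`a, b, c` in `1/sigma = (a + b*wv)*u + c`.}
#'     \item{amp_transmission}{`a, b, c` in
#'       `A/I_s = (1 - wv) * ((a*cos(t) + b)*u + c*(1 - cos(t)))`.}
#'     \item{width_transmission}{`w, a, b, c` in
#'       `1/sigma = (1 + w*wv) * ((a*cos(t) + b)*u + c*(1 - cos(t)))`.}
#'     \item{reflectance}{`p1, p2, k1, k2, c1, c2` in
#'       `R = 1 - (p1 + p2/u) / (1 + exp((k1 + k2/u)*(t - (c1 + c2/u))))`.}
#'     \item{transmittance}{`p1, p2, k1, k2, c1, c2` in
#'       `T = (p1 + p2/u) / (1 + exp((k1 + k2/u)*(t - (c1 + c2/u))))`.}
#'   }
#' @export
smt_constants <- function() {
  list(
    amp_reflection = c(a = 0.0023, b = -0.0016, c = -0.00029),
    width_reflection = c(a = 0.006, b = -0.0007, c = -0.009),
    amp_transmission = c(a = 0.028, b = -0.0196, c = 0.0493),
    width_transmission = c(w = -0.71, a = 0.089, b = -0.0604, c = 0.23),
    reflectance = c(p1 = 0.00016, p2 = 0.97, k1 = 0.11, k2 = -0.26,
                    c1 = 87.44, c2 = 107.15),
    transmittance = c(p1 = 0.94, p2 = -0.44, k1 = 0.32, k2 = -2.00,
                      c1 = 44.28, c2 = 61.57))
}

check_ratio_inputs <- function(u_ratio, wv_ratio) {
  if (any(u_ratio <= 0)) stop("u_ratio must be > 0")
  if (any(wv_ratio < 0 | wv_ratio >= 1)) stop("wv_ratio must lie in [0, 1)")
  if (any(u_ratio < 9 | u_ratio > 39)) {
    warning("u_ratio outside the calibrated range of the skin ensemble")
  }
  invisible(NULL)
}

#' Closed-form diffuse-reflection lobe amplitude
#'
#' Empirical linear model for the Gaussian lobe amplitude of diffuse
#' reflection: `A = I_s * ((a + b * wv_ratio) * u_ratio + c)`, with the
#' published constants (see [smt_constants()]).
#'
#' @param u_ratio SMT ripple aspect ratio `u_w/u_h` (> 0).
#' @param wv_ratio macro texture ratio `W_V/W`, in \[0, 1).
#' @param I_s total scattering intensity normalisation (same units as `A`).
#' @param coef coefficient vector `c(a, b, c)`.
#' @return Amplitude in the units of `I_s`.
#' @examples
#' amp_reflection_model(25, 0.11)  # 0.05281
#' @export
amp_reflection_model <- function(u_ratio, wv_ratio, I_s = 1,
                                 coef = smt_constants()$amp_reflection) {
  check_ratio_inputs(u_ratio, wv_ratio)
  I_s * ((coef[["a"]] + coef[["b"]] * wv_ratio) * u_ratio + coef[["c"]])
}

#' Closed-form diffuse-reflection lobe width
#'
#' Empirical model for the Gaussian lobe width of diffuse reflection:
#' `sigma = 1 / ((a + b * wv_ratio) * u_ratio + c)` degrees. The width is
#' undefined where the bracket is non-positive.
#'
#' @inheritParams amp_reflection_model
#' @param coef coefficient vector `c(a, b, c)`.
#' @return Lobe width in degrees.
#' @export
width_reflection_model <- function(u_ratio, wv_ratio,
                                   coef = smt_constants()$width_reflection) {
  check_ratio_inputs(u_ratio, wv_ratio)
  inv <- (coef[["a"]] + coef[["b"]] * wv_ratio) * u_ratio + coef[["c"]]
  if (any(inv <= 0)) {
    stop("undefined width: the linear bracket is non-positive")
  }
  1 / inv
}

#' Closed-form diffuse-transmission lobe amplitude and width
#'
#' Empirical models for the Gaussian lobe of diffuse transmission (light
#' crossing the surface from the medium into air), which gain a
#' `cos(theta_i)` dependence from the change of media:
#' `A = I_s * (1 - wv) * ((a*cos(t) + b)*u + c*(1 - cos(t)))` and
#' `sigma = 1 / ((1 + w*wv) * ((a*cos(t) + b)*u + c*(1 - cos(t))))`.
#'
#' @inheritParams amp_reflection_model
#' @param theta_i incidence angle inside the medium, degrees.
#' @param coef coefficient vector (see [smt_constants()]).
#' @return Amplitude in the units of `I_s`, or width in degrees.
#' @export
amp_transmission_model <- function(u_ratio, wv_ratio, theta_i, I_s = 1,
                                   coef = smt_constants()$amp_transmission) {
  check_ratio_inputs(u_ratio, wv_ratio)
  ct <- cos(theta_i * pi / 180)
  I_s * (1 - wv_ratio) *
    ((coef[["a"]] * ct + coef[["b"]]) * u_ratio + coef[["c"]] * (1 - ct))
}

#' @rdname amp_transmission_model
#' @export
width_transmission_model <- function(u_ratio, wv_ratio, theta_i,
                                     coef = smt_constants()$width_transmission) {
  check_ratio_inputs(u_ratio, wv_ratio)
  ct <- cos(theta_i * pi / 180)
  inv <- (1 + coef[["w"]] * wv_ratio) *
    ((coef[["a"]] * ct + coef[["b"]]) * u_ratio + coef[["c"]] * (1 - ct))
  if (any(inv <= 0)) {
    stop("undefined width: the bracket is non-positive")
  }
  1 / inv
}

#' Empirical diffuse reflectance sigmoid
#'
#' Closed-form reflectance of diffuse reflection (air to medium) versus
#' incidence angle and SMT ratio:
#' `R = 1 - (p1 + p2/u) / (1 + exp((k1 + k2/u) * (t - (c1 + c2/u))))`.
#'
#' @param theta_i incidence angle in degrees, in \[0, 90\]; vectorised.
#' @param u_ratio SMT ripple aspect ratio `u_w/u_h`.
#' @param coef coefficient vector (see [smt_constants()]).
#' @return Reflectance fraction(s).
#' @examples
#' reflectance_model(0, 25)  # about 0.9610
#' @export
reflectance_model <- function(theta_i, u_ratio,
                              coef = smt_constants()$reflectance) {
  if (any(theta_i < 0 | theta_i > 90)) stop("theta_i must lie in [0, 90]")
  k <- coef[["k1"]] + coef[["k2"]] / u_ratio
  ctr <- coef[["c1"]] + coef[["c2"]] / u_ratio
  1 - (coef[["p1"]] + coef[["p2"]] / u_ratio) /
    (1 + exp(k * (theta_i - ctr)))
}

#' Empirical diffuse transmittance sigmoid
#'
#' Closed-form transmittance of diffuse transmission (medium to air) versus
#' incidence angle inside the medium and SMT ratio:
#' `T = (p1 + p2/u) / (1 + exp((k1 + k2/u) * (t - (c1 + c2/u))))`.
#'
#' @inheritParams reflectance_model
#' @return Transmittance fraction(s).
#' @examples
#' transmittance_model(0, 11.8)  # about 0.902
#' @export
transmittance_model <- function(theta_i, u_ratio,
                                coef = smt_constants()$transmittance) {
  if (any(theta_i < 0 | theta_i > 90)) stop("theta_i must lie in [0, 90]")
  k <- coef[["k1"]] + coef[["k2"]] / u_ratio
  ctr <- coef[["c1"]] + coef[["c2"]] / u_ratio
  (coef[["p1"]] + coef[["p2"]] / u_ratio) /
    (1 + exp(k * (theta_i - ctr)))
}

#' Average a model over all incidence angles
#'
#' Unweighted mean of a closed-form model over incidence angles 0 to 90
#' degrees (uniform angular weighting), by composite trapezoid quadrature.
#'
#' @param model a function of `(theta_i, u_ratio, ...)`, e.g.
#'   [reflectance_model()] or [transmittance_model()].
#' @param u_ratio SMT ripple aspect ratio passed to the model.
#' @param step quadrature step in degrees (<= 0.1; default 0.01).
#' @param ... further arguments passed to `model`.
#' @return The angle-averaged model value.
#' @examples
#' angle_average(transmittance_model, 11.8)  # about 0.495
#' @export
angle_average <- function(model, u_ratio, step = 0.01, ...) {
  if (step <= 0 || step > 0.1) stop("step must be in (0, 0.1] degrees")
  theta <- seq(0, 90, by = step)
  if (theta[length(theta)] < 90) theta <- c(theta, 90)
  y <- model(theta, u_ratio, ...)
  sum(diff(theta) * (y[-1] + y[-length(y)]) / 2) / 90
}

#' Spearman rank correlation
#'
#' Rank correlation with mid-ranks for ties. The p-value uses the
#' t-distribution approximation; for `n <= 10` an exact two-sided
#' permutation p-value (enumerating all distinct rank arrangements) is
#' available.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exact use the exact permutation null (requires `n <= 10`).
#' @return A list with `rho`, `p_value`, `n` and `method`.
#' @export
spearman_rank <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("rank correlation undefined for constant input")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (exact) {
    if (n > 10) stop("exact permutation p-value limited to n <= 10")
    p <- spearman_perm_pvalue_cpp(rx, ry, rho)
    return(list(rho = rho, p_value = p, n = n, method = "exact permutation"))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = rho, p_value = unname(ct$p.value), n = n,
       method = "t approximation")
}

#' Simulated parametric sweep over texture ratios
#'
#' Runs the Monte Carlo tracer over a grid of `(u_ratio, wv_ratio,
#' theta_i)` points, fits the Gaussian lobe on the relevant hemisphere of
#' each run, and tabulates the fitted amplitude/width with the simulated
#' reflectance or transmittance. Concrete geometries are derived from the
#' ratios with the sulcus width, sulcus depth and ripple height held fixed:
#' `W = W_V / wv_ratio` (or a ripple-free-equivalent period when
#' `wv_ratio = 0`) and `u_w = u_ratio * u_h`.
#'
#' @param u_ratio,wv_ratio,theta_i grid values (crossed).
#' @param mode `"reflection"` or `"transmission"`.
#' @param u_h ripple height held fixed across the sweep (micrometres).
#' @param H sulcus depth (micrometres).
#' @param W_V sulcus width (micrometres).
#' @param n refractive index of the medium.
#' @param ray_count rays per grid point.
#' @param seed base seed; each grid point uses `seed + point index`.
#' @param bin_width angular bin width (degrees).
#' @param n_periods macro periods per profile.
#' @return A data.frame of class `smt_sweep` with one row per grid point:
#'   the grid values, fitted `A`, `mu`, `sigma`, `goodness`, normalised
#'   amplitude `A_norm = A / I_s` (with `I_s` the total lobe power),
#'   simulated `R`, `T` and `residual`.
#' @export
run_sweep <- function(u_ratio, wv_ratio = 0.11, theta_i = 45,
                      mode = c("reflection", "transmission"), u_h = 2,
                      H = 20, W_V = 40, n = 1.40, ray_count = 1e5,
                      seed = 1L, bin_width = 1, n_periods = 2L) {
  mode <- match.arg(mode)
  grid <- expand.grid(u_ratio = u_ratio, wv_ratio = wv_ratio,
                      theta_i = theta_i, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    u_w <- g$u_ratio * u_h
    W <- if (g$wv_ratio > 0) W_V / g$wv_ratio else W_V + 8 * u_w
    p <- surface_params(W = W, H = H, W_V = if (g$wv_ratio > 0) W_V else 0,
                        u_h = u_h, u_w = u_w, n = n)
    prof <- build_profile(p, n_periods = n_periods)
    res <- simulate_scattering(prof, g$theta_i, mode, ray_count = ray_count,
                               seed = seed + i, bin_width = bin_width)
    dist <- if (mode == "reflection") res$reflection_distribution
            else res$transmission_distribution
    fit <- fit_gaussian(dist)
    I_s <- dist$total_power
    rows[[i]] <- data.frame(
      u_ratio = g$u_ratio, wv_ratio = g$wv_ratio, theta_i = g$theta_i,
      mode = mode, A = fit$A, mu = fit$mu, sigma = fit$sigma,
      goodness = fit$goodness, A_norm = fit$A / I_s, I_s = I_s,
      R = res$R, T = res$T, residual = res$residual)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("smt_sweep", "data.frame")
  out
}

#' Fit the linear amplitude/width forms to sweep records
#'
#' Least-squares fit of the empirical linear family
#' `value = (a + b * wv_ratio) * u_ratio + c` to a sweep table, with
#' `value` the normalised lobe amplitude (`response = "amplitude"`) or the
#' reciprocal lobe width (`response = "width"`). When the sweep holds
#' `wv_ratio` fixed, the interaction coefficient `b` is not identifiable
#' and is dropped.
#'
#' @param records a sweep data.frame from [run_sweep()], or any data.frame
#'   with columns `u_ratio`, `wv_ratio` and either `A_norm` or `sigma`.
#' @param response `"amplitude"` or `"width"`.
#' @return A list with `coef` (`a`, `b`, `c`; `b` is `NA` when dropped),
#'   `r_squared` and the underlying `lm` fit.
#' @export
fit_linear_form <- function(records, response = c("amplitude", "width")) {
  response <- match.arg(response)
  if (length(unique(records$u_ratio)) < 4) {
    stop("need >= 4 distinct u_ratio values")
  }
  value <- if (response == "amplitude") records$A_norm else 1 / records$sigma
  d <- data.frame(value = value, u = records$u_ratio,
                  uwv = records$u_ratio * records$wv_ratio)
  vary_wv <- length(unique(records$wv_ratio)) > 1
  fit <- if (vary_wv) lm(value ~ u + uwv, data = d) else
    lm(value ~ u, data = d)
  cf <- coef(fit)
  if (any(!is.finite(cf))) stop("rank-deficient design")
  ss_tot <- sum((d$value - mean(d$value))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else NA_real_
  list(coef = c(a = unname(cf["u"]),
                b = if (vary_wv) unname(cf["uwv"]) else NA_real_,
                c = unname(cf["(Intercept)"])),
       r_squared = r2, fit = fit)
}

#' Fit the reflectance/transmittance sigmoid family to records
#'
#' Least-squares fit of the six-constant sigmoid family (plateau pair,
#' steepness pair, centre pair, each affine in `1/u_ratio`) to simulated
#' reflectance or transmittance records across incidence angles and SMT
#' ratios. The published constants serve as starting values.
#'
#' @param records data.frame with columns `theta_i`, `u_ratio` and `value`
#'   (the simulated `R` for reflection mode or `T` for transmission mode).
#' @param mode `"reflection"` (fits `1 - sigmoid`) or `"transmission"`
#'   (fits the bare sigmoid).
#' @return A list with the fitted `coef` (named `p1, p2, k1, k2, c1, c2`),
#'   `rss` and the `nls` fit object.
#' @export
fit_sigmoid_form <- function(records, mode = c("reflection", "transmission")) {
  mode <- match.arg(mode)
  if (length(unique(records$u_ratio)) < 2) {
    stop("need >= 2 distinct u_ratio values")
  }
  start <- as.list(if (mode == "reflection") smt_constants()$reflectance
                   else smt_constants()$transmittance)
  form <- if (mode == "reflection") {
    value ~ 1 - (p1 + p2 / u_ratio) /
      (1 + exp((k1 + k2 / u_ratio) * (theta_i - (c1 + c2 / u_ratio))))
  } else {
    value ~ (p1 + p2 / u_ratio) /
      (1 + exp((k1 + k2 / u_ratio) * (theta_i - (c1 + c2 / u_ratio))))
  }
  fit <- minpack.lm::nlsLM(form, data = records, start = start,
                           control = minpack.lm::nls.lm.control(
                             ftol = 1e-14, ptol = 1e-14, maxiter = 500))
  list(coef = coef(fit), rss = sum(residuals(fit)^2), fit = fit)
}

#' Export a sweep table as CSV
#'
#' @param sweep a sweep data.frame from [run_sweep()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}
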