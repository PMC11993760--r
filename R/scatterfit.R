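#' Bin exit-ray records into an angular distribution
#'
#' Conservative binning of escaped-ray records onto a uniform angular grid
#' over \[-90, 90\] degrees: the summed binned power equals the summed
#' record power exactly. Intensity is reported as power per degree.
#'
#' @param angles exit angles in degrees, within \[-90, 90\].
#' @param powers non-negative powers, same length as `angles`.
#' @param bin_width bin width in degrees; 180 must be a multiple of it.
#' @param side `"reflection"` or `"transmission"` hemisphere label.
#' @return An object of class `angular_distribution`: bin centre vector
#'   `theta`, `intensity` (power per degree), `bin_width`, `total_power`
#'   and `side`.
#' @examples
#' d <- bin_exit_rays(c(-45, 45), c(0.5, 0.5), 1)
#' d$total_power
#' @export
bin_exit_rays <- function(angles, powers, bin_width = 1,
                          side = c("reflection", "transmission")) {
  side <- match.arg(side)
  if (bin_width <= 0 || abs(180 / bin_width - round(180 / bin_width)) > 1e-9) {
    stop("bin_width must divide 180 degrees")
  }
  angles <- as.numeric(angles)
  powers <- as.numeric(powers)
  if (length(angles) != length(powers)) stop("angles/powers length mismatch")
  if (length(angles) && (min(angles) < -90 || max(angles) > 90)) {
    stop("angles must lie in [-90, 90] degrees")
  }
  if (length(powers) && min(powers) < 0) stop("powers must be >= 0")
  nb <- as.integer(round(180 / bin_width))
  centers <- -90 + (seq_len(nb) - 0.5) * bin_width
  power <- numeric(nb)
  if (length(angles)) {
    idx <- pmin(nb, pmax(1L, as.integer(floor((angles + 90) / bin_width)) + 1L))
    agg <- rowsum(powers, group = idx)
    power[as.integer(rownames(agg))] <- agg[, 1]
  }
  structure(list(theta = centers, intensity = power / bin_width,
                 bin_width = bin_width, total_power = sum(power),
                 side = side),
            class = "angular_distribution")
}

#' Construct an angular distribution from binned values
#'
#' @param theta uniform bin centres in degrees.
#' @param intensity power per degree in each bin, >= 0.
#' @param side hemisphere label.
#' @return An `angular_distribution` object.
#' @export
angular_distribution <- function(theta, intensity,
                                 side = c("reflection", "transmission")) {
  side <- match.arg(side)
  if (length(theta) < 2) stop("need at least two bins")
  bw <- diff(theta)
  if (max(abs(bw - bw[1])) > 1e-9) stop("bin widths must be uniform")
  if (any(intensity < 0)) stop("intensity must be >= 0")
  structure(list(theta = theta, intensity = intensity, bin_width = bw[1],
                 total_power = sum(intensity) * bw[1], side = side),
            class = "angular_distribution")
}

#' @export
print.angular_distribution <- function(x, ...) {
  cat(sprintf(
    "Angular distribution (%s side): %d bins of %g deg, total power %.6g\n",
    x$side, length(x$theta), x$bin_width, x$total_power))
  invisible(x)
}

#' @export
plot.angular_distribution <- function(x, ...) {
  graphics::plot(x$theta, x$intensity, type = "h",
                 xlab = "scattering angle (deg)",
                 ylab = "power per degree", ...)
  invisible(x)
}

#' Fit a Gaussian radiance lobe to an angular distribution
#'
#' Nonlinear least squares of `A * exp(-(theta - mu)^2 / (2 * sigma^2))` to
#' the binned intensities. Initialisation: `A` at the maximum intensity,
#' `mu` at the argmax bin (or `fix_center`), `sigma` at the power-weighted
#' standard deviation of the bin centres. Zero-power bins take part in the
#' fit (they constrain the width); an isolated specular spike more than
#' 100 times its neighbours can optionally be excluded.
#'
#' @param distribution an `angular_distribution`.
#' @param fix_center optional centre angle in degrees; when given, `mu` is
#'   held fixed and only `A` and `sigma` are fitted.
#' @param exclude_spike drop a single dominant specular-spike bin before
#'   fitting (default `FALSE`).
#' @return An object of class `gaussian_fit`: `A`, `mu`, `sigma` (degrees),
#'   `goodness` (coefficient of determination against the fitted bins) and
#'   a `poor` flag for goodness below 0.2.
#' @export
fit_gaussian <- function(distribution, fix_center = NULL,
                         exclude_spike = FALSE) {
  stopifnot(inherits(distribution, "angular_distribution"))
  theta <- distribution$theta
  y <- distribution$intensity
  nz <- sum(y > 0)
  if (nz < 5) {
    stop("degenerate fit: fewer than 5 nonzero bins in the distribution")
  }
  if (max(y) * distribution$bin_width / distribution$total_power > 0.999) {
    stop("degenerate fit: single-bin specular spike carries all the power")
  }
  if (exclude_spike) {
    i <- which.max(y)
    nb <- y[pmax(1, i - 1)] + y[pmin(length(y), i + 1)] - y[i] * 0
    neigh <- max(y[setdiff(c(i - 1, i + 1), c(0, length(y) + 1))])
    if (neigh > 0 && y[i] > 100 * neigh) {
      theta <- theta[-i]
      y <- y[-i]
    }
  }
  w <- pmax(y, 0)
  mbar <- sum(w * theta) / sum(w)
  s0 <- sqrt(sum(w * (theta - mbar)^2) / sum(w))
  s0 <- min(max(s0, distribution$bin_width / 2), 90)
  A0 <- max(y)
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                     maxiter = 500)
  dat <- data.frame(theta = theta, y = y)
  fit <- if (is.null(fix_center)) {
    mu0 <- theta[which.max(y)]
    try(minpack.lm::nlsLM(
      y ~ A * exp(-(theta - mu)^2 / (2 * sigma^2)), data = dat,
      start = list(A = A0, mu = mu0, sigma = s0),
      lower = c(A = 0, mu = -90, sigma = distribution$bin_width / 100),
      upper = c(A = Inf, mu = 90, sigma = 1e4), control = ctrl),
      silent = TRUE)
  } else {
    mu_fixed <- fix_center
    try(minpack.lm::nlsLM(
      y ~ A * exp(-(theta - mu_fixed)^2 / (2 * sigma^2)), data = dat,
      start = list(A = A0, sigma = s0),
      lower = c(A = 0, sigma = distribution$bin_width / 100),
      upper = c(A = Inf, sigma = 1e4), control = ctrl), silent = TRUE)
  }
  if (inherits(fit, "try-error")) {
    # fall back to moment estimates, flagged as a non-converged fit
    out <- list(A = A0, mu = if (is.null(fix_center)) mbar else fix_center,
                sigma = s0, goodness = 0, poor = TRUE, converged = FALSE)
    class(out) <- "gaussian_fit"
    return(out)
  }
  cf <- coef(fit)
  yhat <- predict(fit)
  ss_tot <- sum((y - mean(y))^2)
  goodness <- if (ss_tot <= .Machine$double.eps * max(1, sum(y^2))) 0 else
    1 - sum((y - yhat)^2) / ss_tot
  out <- list(A = unname(cf["A"]),
              mu = if (is.null(fix_center)) unname(cf["mu"]) else fix_center,
              sigma = unname(cf["sigma"]),
              goodness = goodness, poor = goodness < 0.2, converged = TRUE)
  class(out) <- "gaussian_fit"
  out
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf(
    "Gaussian lobe fit: A = %.5g, mu = %.4g deg, sigma = %.4g deg (R2 = %.4f%s)\n",
    x$A, x$mu, x$sigma, x$goodness, if (x$poor) ", poor" else ""))
  invisible(x)
}

#' Serialise a Gaussian fit to JSON
#'
#' @param fit a `gaussian_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gaussian_fit <- function(fit, path) {
  stopifnot(inherits(fit, "gaussian_fit"))
  jsonlite::write_json(list(A = fit$A, mu_deg = fit$mu, sigma_deg = fit$sigma,
                            goodness = fit$goodness),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
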