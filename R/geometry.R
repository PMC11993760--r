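#' Surface topography parameter set
#'
#' Bundles the five lengths describing one period of the equivalent 2D skin
#' surface model together with the refractive index of the medium below the
#' surface. The macro texture is a periodic groove (sulcus cutis) of width
#' `W_V` and depth `H` cut into a flat ridge (crista cutis) plateau repeating
#' with period `W`; the subvisible micro texture (SMT) is a train of
#' half-ellipse ripple bumps of peak-to-valley height `u_h` and period `u_w`
#' carried on the ridge plateau.
#'
#' @param W macro spatial period (micrometres).
#' @param H sulcus depth (micrometres).
#' @param W_V sulcus width (micrometres); must be smaller than `W`.
#' @param u_h SMT ripple height, peak-to-valley (micrometres).
#' @param u_w SMT ripple period (micrometres); when the ripple is active
#'   (`u_h > 0`) it must fit on the ridge, `u_w <= W - W_V`.
#' @param n refractive index of the medium below the surface (>= 1);
#'   1.40 for skin, 1.49 for PMMA.
#' @return An object of class `surface_params` (a named list).
#' @examples
#' surface_params(W = 240.8, H = 17.9, W_V = 40, u_h = 2.1, u_w = 53.4)
#' @export
surface_params <- function(W, H, W_V, u_h, u_w, n = 1.40) {
  vals <- c(W = W, H = H, W_V = W_V, u_h = u_h, u_w = u_w)
  if (any(!is.finite(c(vals, n)))) stop("all parameters must be finite")
  if (any(vals < 0)) stop("all lengths must be >= 0")
  if (W <= 0) stop("W must be > 0")
  if (W_V >= W) stop("W_V must be smaller than the period W")
  if (u_h > 0 && u_w > 0 && u_w > W - W_V) {
    stop("ripple period u_w must not exceed the ridge width W - W_V")
  }
  if (n < 1) stop("refractive index n must be >= 1")
  structure(list(W = W, H = H, W_V = W_V, u_h = u_h, u_w = u_w, n = n),
            class = "surface_params")
}

#' @export
print.surface_params <- function(x, ...) {
  cat("Surface parameters (um): W =", x$W, " H =", x$H, " W_V =", x$W_V,
      " u_h =", x$u_h, " u_w =", x$u_w, "| n =", x$n, "\n")
  invisible(x)
}

# Analytic height of one period, vectorised. Crista reference plane at h = 0:
# the sulcus is a half-ellipse groove on [0, W_V] reaching -H at its centre
# (two quarter-ellipse walls, vertical at the rim), the ridge [W_V, W)
# carries half-ellipse ripple bumps of height u_h and base u_w starting at
# the sulcus edge; a partial bump may be truncated at the far edge.
profile_height_fun <- function(params, x) {
  W <- params$W; WV <- params$W_V; H <- params$H
  uh <- params$u_h; uw <- params$u_w
  xm <- x %% W
  h <- numeric(length(xm))
  if (WV > 0 && H > 0) {
    i <- xm < WV
    u <- 2 * xm[i] / WV - 1
    h[i] <- -H * sqrt(pmax(0, 1 - u * u))
  }
  if (uh > 0) {
    i <- xm >= WV
    s <- (xm[i] - WV) %% uw
    v <- 2 * s / uw - 1
    h[i] <- uh * sqrt(pmax(0, 1 - v * v))
  }
  h
}

# Analytic slope dh/dx; vertical wall tangents give large finite slopes.
profile_slope_fun <- function(params, x) {
  W <- params$W; WV <- params$W_V; H <- params$H
  uh <- params$u_h; uw <- params$u_w
  xm <- x %% W
  s_out <- numeric(length(xm))
  if (WV > 0 && H > 0) {
    i <- xm < WV
    u <- 2 * xm[i] / WV - 1
    s_out[i] <- 2 * H * u / (WV * sqrt(pmax(1 - u * u, 1e-30)))
  }
  if (uh > 0) {
    i <- xm >= WV
    s <- (xm[i] - WV) %% uw
    v <- 2 * s / uw - 1
    s_out[i] <- -2 * uh * v / (uw * sqrt(pmax(1 - v * v, 1e-30)))
  }
  s_out
}

#' Build the equivalent 2D surface profile
#'
#' Samples the piecewise-analytic periodic height function defined by a
#' [surface_params()] set onto a uniform grid suitable for ray tracing.
#' Setting `u_h = 0` yields a smooth macro-only profile; `H = 0` and
#' `u_h = 0` yield a flat surface.
#'
#' @param params a [surface_params()] object.
#' @param n_periods number of macro periods to sample (>= 1). The tracer
#'   wraps the profile periodically, so small values suffice.
#' @param samples_per_period number of grid samples per macro period. The
#'   default resolves the ripple with at least 40 samples per `u_w` and the
#'   sulcus walls with at least 200 samples across `W_V`.
#' @return An object of class `surface_profile`: the sample grid (`x`, `h`),
#'   grid spacing `dx`, macro `period`, analytic height bounds
#'   (`zmin = -H`, `zmax = u_h`) and the generating parameters.
#' @examples
#' p <- surface_params(W = 200, H = 20, W_V = 20, u_h = 2, u_w = 20, n = 1.49)
#' prof <- build_profile(p, n_periods = 2)
#' range(prof$h)
#' @export
build_profile <- function(params, n_periods = 1, samples_per_period = NULL) {
  stopifnot(inherits(params, "surface_params"))
  if (params$u_h > 0 && params$u_w <= 0) {
    stop("u_w = 0 with u_h > 0: ripple period undefined")
  }
  n_periods <- as.integer(n_periods)
  if (n_periods < 1) stop("n_periods must be >= 1")
  W <- params$W
  if (is.null(samples_per_period)) {
    dx_t <- W / 512
    if (params$u_h > 0) dx_t <- min(dx_t, params$u_w / 40)
    if (params$H > 0 && params$W_V > 0) dx_t <- min(dx_t, params$W_V / 200)
    samples_per_period <- min(50000L, as.integer(ceiling(W / dx_t)))
  }
  samples_per_period <- as.integer(samples_per_period)
  if (params$u_h > 0 && samples_per_period < ceiling(20 * W / params$u_w)) {
    stop("samples_per_period too small: u_w must span >= 20 samples")
  }
  m <- samples_per_period * n_periods
  dx <- W / samples_per_period
  x <- (seq_len(m) - 1) * dx
  h <- profile_height_fun(params, x)
  structure(list(x = x, h = h, dx = dx, period = W, n_periods = n_periods,
                 length = W * n_periods, zmin = -params$H, zmax = params$u_h,
                 params = params),
            class = "surface_profile")
}

#' @export
print.surface_profile <- function(x, ...) {
  cat("Surface profile:", x$n_periods, "period(s) of", x$period,
      "um,", length(x$h), "samples (dx =", signif(x$dx, 4), "um), height in [",
      signif(min(x$h), 4), ",", signif(max(x$h), 4), "] um\n")
  invisible(x)
}

#' Query the analytic height and outward normal of a profile
#'
#' Evaluates the continuous height function (and its upward unit normal) at
#' arbitrary positions; both are periodic in the macro period.
#'
#' @param profile a [build_profile()] object.
#' @param x positions (micrometres), any length.
#' @return A data.frame with columns `x`, `h`, `nx`, `nz` (unit normal).
#' @export
profile_height <- function(profile, x) {
  stopifnot(inherits(profile, "surface_profile"))
  h <- profile_height_fun(profile$params, x)
  s <- profile_slope_fun(profile$params, x)
  nn <- sqrt(1 + s * s)
  data.frame(x = x, h = h, nx = -s / nn, nz = 1 / nn)
}

# Sub-sample refinement of a valley floor on [lo, hi] (raw indices into h).
# Where two convex ripple bumps meet, the profile has a sqrt-shaped cusp and
# the sampled minimum overshoots the true floor by O(sqrt(dx)). Fit
# h(x) = c + aL*sqrt(x0 - x) + aR*sqrt(x - x0) on a few samples around the
# minimum, scanning the cusp position x0; the offset c estimates the floor.
# Falls back to the sampled minimum when the model fits poorly or is
# implausible (negative flank slopes, floor above the sampled minimum).
refine_valley <- function(h, lo, hi) {
  idx <- lo:hi
  vm <- idx[which.min(h[idx])]
  vmin <- h[vm]
  iL <- seq.int(max(lo, vm - 4L), vm - 1L)
  iR <- seq.int(vm + 1L, min(hi, vm + 4L))
  if (vm - 1L < lo || vm + 1L > hi || length(iL) < 2 || length(iR) < 2) {
    return(vmin)
  }
  pts <- c(iL, vm, iR)
  y <- h[pts]
  best_rss <- Inf
  best_c <- vmin
  for (x0 in seq(vm - 1, vm + 1, length.out = 21)) {
    X <- cbind(1, sqrt(pmax(0, x0 - pts)), sqrt(pmax(0, pts - x0)))
    fit <- tryCatch(stats::.lm.fit(X, y), error = function(e) NULL)
    if (is.null(fit)) next
    cf <- fit$coefficients
    if (any(!is.finite(cf)) || cf[2] < 0 || cf[3] < 0) next
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) {
      best_rss <- rss
      best_c <- cf[1]
    }
  }
  if (best_c > vmin) return(vmin)
  max(best_c, vmin - (max(y) - vmin))  # guard against wild extrapolation
}

# Local maxima of a numeric vector with a prominence filter. Returns indices.
find_peaks <- function(h, prominence = 0) {
  n <- length(h)
  if (n < 3) return(integer(0))
  cand <- which(h[2:(n - 1)] > h[1:(n - 2)] & h[2:(n - 1)] >= h[3:n]) + 1L
  if (prominence <= 0 || length(cand) == 0) return(cand)
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    lmin <- h[i]; j <- i
    while (j > 1 && h[j] <= h[i]) { lmin <- min(lmin, h[j]); j <- j - 1 }
    if (j == 1) lmin <- min(lmin, h[1])
    rmin <- h[i]; j <- i
    while (j < n && h[j] <= h[i]) { rmin <- min(rmin, h[j]); j <- j + 1 }
    if (j == n) rmin <- min(rmin, h[n])
    keep[k] <- (h[i] - max(lmin, rmin)) >= prominence
  }
  cand[keep]
}

#' Estimate surface parameters from a measured cross-section
#'
#' Inverts [build_profile()]: given a sampled height cross-section, detects
#' sulcus grooves and ridge plateaus and estimates the five topography
#' parameters. Sulcus runs are detected as contiguous samples deeper than
#' `sulcus_frac` of the robust (1st-99th percentile) height range; each run's
#' edges are then refined outward to the shallow crossing at `edge_frac` of
#' its depth so that the full groove width is recovered for steep elliptical
#' walls. On the ridge runs, SMT ripple peaks are local maxima passing a
#' prominence filter (`prominence_frac` of the local ridge amplitude), after
#' optional light smoothing and optional moving-median detrending.
#'
#' @param h numeric vector of heights (micrometres) at uniform spacing, or a
#'   `surface_profile`, or a two-column data.frame `(x, h)`.
#' @param spacing sample spacing (micrometres); taken from the profile or
#'   data.frame when omitted.
#' @param sulcus_frac detection threshold as a fraction of the robust height
#'   range (default 0.5).
#' @param edge_frac depth fraction at which refined sulcus edges are placed
#'   (default 0.02).
#' @param prominence_frac minimum peak prominence as a fraction of the local
#'   ridge amplitude (default 0.1).
#' @param smooth_window odd number of samples for a running-mean pre-smooth
#'   of the ridge heights before peak detection (default 5; 1 disables).
#' @param detrend_window optional moving-median window (micrometres) removed
#'   from ridge heights before peak detection; use about three expected
#'   ripple periods when the ridge top is not flat. `NULL` (default) skips
#'   detrending.
#' @return A list of class `surface_params_estimate` with elements `W`, `H`,
#'   `W_V`, `u_h`, `u_w` (NA when undetectable), `n_sulci`, `n_peaks`.
#' @examples
#' p <- surface_params(W = 200, H = 20, W_V = 20, u_h = 2, u_w = 20, n = 1.49)
#' prof <- build_profile(p, n_periods = 4)
#' parameterize_profile(prof)
#' @export
parameterize_profile <- function(h, spacing = NULL, sulcus_frac = 0.5,
                                 edge_frac = 0.02, prominence_frac = 0.1,
                                 smooth_window = 5, detrend_window = NULL) {
  if (inherits(h, "surface_profile")) {
    spacing <- h$dx
    h <- h$h
  } else if (is.data.frame(h)) {
    if (is.null(spacing)) spacing <- diff(h[[1]])[1]
    h <- h[[2]]
  }
  if (is.null(spacing) || spacing <= 0) stop("uniform spacing > 0 required")
  h <- as.numeric(h)
  n <- length(h)
  if (n < 16) stop("cross-section too short")

  out <- list(W = NA_real_, H = NA_real_, W_V = NA_real_,
              u_h = NA_real_, u_w = NA_real_, n_sulci = 0L, n_peaks = 0L)
  rng <- quantile(h, c(0.01, 0.99), names = FALSE, type = 7)
  span <- rng[2] - rng[1]
  crista_idx <- seq_len(n)
  baseline_used <- NA_real_

  if (span > 0) {
    deep <- h < rng[2] - sulcus_frac * span
    runs <- rle(deep)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    core_s <- starts[runs$values]
    core_e <- ends[runs$values]
    keep <- (core_e - core_s + 1L) >= 3L
    core_s <- core_s[keep]; core_e <- core_e[keep]
    if (length(core_s) > 0) {
      baseline <- NA_real_
      depths <- numeric(0)
      # exclusion zones around cores for a clean ridge-baseline estimate
      margin <- pmax(3L, as.integer(ceiling(0.15 * (core_e - core_s + 1L))))
      excl <- rep(FALSE, n)
      for (k in seq_along(core_s)) {
        excl[max(1L, core_s[k] - margin[k]):min(n, core_e[k] + margin[k])] <- TRUE
      }
      if (any(!excl)) {
        baseline <- quantile(h[!excl], 0.02, names = FALSE, type = 7)
        depths <- baseline - vapply(seq_along(core_s), function(k) {
          min(h[core_s[k]:core_e[k]])
        }, numeric(1))
        # a real sulcus is much deeper than the ridge's own ripple spread;
        # otherwise the "grooves" are just ripple valleys (no macro texture)
        ridge_spread <- diff(quantile(h[!excl], c(0.05, 0.98), names = FALSE))
        if (mean(depths) <= 3 * ridge_spread) {
          core_s <- integer(0)
        }
      }
      if (length(core_s) > 0 && is.finite(baseline)) {
        baseline_used <- baseline
        # refine run edges outward to the shallow-depth crossing
        ref_s <- core_s; ref_e <- core_e
        for (k in seq_along(core_s)) {
          lev <- baseline - edge_frac * depths[k]
          i <- core_s[k]
          while (i > 1 && h[i - 1] < lev) i <- i - 1L
          ref_s[k] <- i
          i <- core_e[k]
          while (i < n && h[i + 1] < lev) i <- i + 1L
          ref_e[k] <- i
        }
        widths <- (ref_e - ref_s + 1L) * spacing
        centers <- (ref_s + ref_e) / 2 * spacing
        out$n_sulci <- length(core_s)
        out$H <- mean(depths)
        out$W_V <- mean(widths)
        if (length(centers) >= 2) out$W <- mean(diff(sort(centers)))
        crista <- rep(TRUE, n)
        for (k in seq_along(ref_s)) {
          crista[max(1L, ref_s[k] - 2L):min(n, ref_e[k] + 2L)] <- FALSE
        }
        crista_idx <- which(crista)
      }
    }
  }

  # SMT estimation on ridge runs
  if (length(crista_idx) >= 8) {
    # contiguous ridge segments
    brk <- c(0L, which(diff(crista_idx) != 1L), length(crista_idx))
    spacings <- c(); amps <- c(); valleys <- c(); npk <- 0L
    for (k in seq_len(length(brk) - 1L)) {
      seg <- crista_idx[(brk[k] + 1L):brk[k + 1L]]
      if (length(seg) < 8) next
      hs <- h[seg]
      if (!is.null(detrend_window)) {
        w <- max(3L, as.integer(round(detrend_window / spacing)))
        if (w %% 2L == 0L) w <- w + 1L
        if (w < length(hs)) hs <- hs - runmed(hs, w)
      }
      if (smooth_window > 1 && length(hs) > smooth_window) {
        kern <- rep(1 / smooth_window, smooth_window)
        hs <- as.numeric(stats::filter(hs, kern, sides = 2))
        ok <- !is.na(hs)
        hs <- hs[ok]; seg <- seg[ok]
      }
      amp_loc <- max(hs) - min(hs)
      if (amp_loc <= 0) next
      pk <- find_peaks(hs, prominence = prominence_frac * amp_loc)
      npk <- npk + length(pk)
      if (length(pk) >= 2) {
        spacings <- c(spacings, diff(seg[pk]) * spacing)
        for (j in seq_len(length(pk) - 1L)) {
          valley <- refine_valley(h, seg[pk[j]], seg[pk[j + 1L]])
          valleys <- c(valleys, valley)
          amps <- c(amps, mean(h[seg[pk[c(j, j + 1L)]]]) - valley)
        }
      }
    }
    out$n_peaks <- npk
    if (npk >= 3 && length(spacings) > 0) {
      out$u_w <- mean(spacings)
      out$u_h <- mean(amps)
      # the refined ripple valleys sit on the crista reference plane and
      # locate it better than the initial low-quantile baseline
      if (!is.na(out$H) && !is.na(baseline_used) && length(valleys) > 0) {
        out$H <- out$H + (mean(valleys) - baseline_used)
      }
    }
  }
  class(out) <- "surface_params_estimate"
  out
}

#' @export
print.surface_params_estimate <- function(x, ...) {
  cat("Estimated surface parameters (um):\n")
  cat("  macro:", if (is.na(x$W)) "not detected" else
    paste0("W = ", signif(x$W, 4), ", H = ", signif(x$H, 4),
           ", W_V = ", signif(x$W_V, 4), " (", x$n_sulci, " sulci)"), "\n")
  cat("  SMT:  ", if (is.na(x$u_w)) "not detected" else
    paste0("u_h = ", signif(x$u_h, 4), ", u_w = ", signif(x$u_w, 4),
           " (", x$n_peaks, " peaks)"), "\n")
  invisible(x)
}

#' Generate a synthetic height map
#'
#' Extrudes the analytic profile along y on a regular lattice and adds
#' independent Gaussian height noise, emulating a laser-microscope scan of
#' the modelled surface. Reproducible for a given seed.
#'
#' @param params a [surface_params()] object.
#' @param extent `c(x, y)` extent in micrometres; x must span at least one
#'   macro period.
#' @param spacing pixel spacing (micrometres), > 0.
#' @param noise_sd standard deviation of additive height noise (micrometres).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return An object of class `height_map`: list with matrix `z` (rows = y)
#'   and `spacing`.
#' @export
synth_height_map <- function(params, extent, spacing, noise_sd = 0,
                             seed = NULL) {
  stopifnot(inherits(params, "surface_params"))
  if (spacing <= 0) stop("spacing must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(extent) != 2 || any(extent <= 0)) stop("extent must be c(x, y) > 0")
  if (extent[1] < params$W) stop("x extent must span >= 1 macro period")
  nx <- as.integer(floor(extent[1] / spacing))
  ny <- as.integer(floor(extent[2] / spacing))
  x <- (seq_len(nx) - 1) * spacing
  row_h <- profile_height_fun(params, x)
  z <- matrix(rep(row_h, each = ny), nrow = ny)
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      }, add = TRUE)
      set.seed(seed)
    }
    z <- z + matrix(rnorm(nx * ny, sd = noise_sd), nrow = ny)
  }
  structure(list(z = z, spacing = spacing), class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat("Height map:", nrow(x$z), "x", ncol(x$z), "pixels at",
      x$spacing, "um/pixel\n")
  invisible(x)
}

#' Read and write height maps
#'
#' CSV maps are plain numeric matrices (row-major) preceded by a comment
#' header line `# spacing_um=<value>`. TIFF maps are single-channel 32-bit
#' float grids holding heights in micrometres directly (requires the `tiff`
#' package; spacing is supplied by the caller on read).
#'
#' @param map a `height_map` object.
#' @param path file path; format chosen by extension (`.csv` or `.tif`).
#' @param spacing pixel spacing in micrometres, required when reading TIFF.
#' @return `read_height_map` returns a `height_map`; `write_height_map`
#'   returns `path` invisibly.
#' @export
write_height_map <- function(map, path) {
  stopifnot(inherits(map, "height_map"))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required for TIFF output")
    }
    # heights normalised to [0, 1] (TIFF grey levels); the physical range
    # and pixel spacing travel in a JSON sidecar next to the image
    zmin <- min(map$z)
    zmax <- max(map$z)
    zn <- if (zmax > zmin) (map$z - zmin) / (zmax - zmin)
          else matrix(0, nrow(map$z), ncol(map$z))
    tiff::writeTIFF(zn, path, bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(list(spacing_um = map$spacing, zmin_um = zmin,
                              zmax_um = zmax),
                         paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# spacing_um=%.10g", map$spacing), con)
    write.table(format(map$z, digits = 10, trim = TRUE), con, sep = ",",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_height_map
#' @export
read_height_map <- function(path, spacing = NULL) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required for TIFF input")
    }
    z <- tiff::readTIFF(path, as.is = FALSE)
    meta_path <- paste0(path, ".meta.json")
    if (file.exists(meta_path)) {
      meta <- jsonlite::read_json(meta_path)
      if (is.null(spacing)) spacing <- meta$spacing_um
      z <- z * (meta$zmax_um - meta$zmin_um) + meta$zmin_um
    }
    if (is.null(spacing)) stop("spacing must be given when reading TIFF")
    if (length(dim(z)) == 3) z <- z[, , 1]
    z <- matrix(as.numeric(z), nrow = nrow(z))
    return(structure(list(z = z, spacing = spacing), class = "height_map"))
  }
  first <- readLines(path, n = 1)
  sp <- as.numeric(sub("^#\\s*spacing_um=", "", first))
  if (!is.finite(sp)) stop("missing '# spacing_um=' header")
  z <- as.matrix(read.csv(path, header = FALSE, comment.char = "#"))
  dimnames(z) <- NULL
  structure(list(z = z, spacing = sp), class = "height_map")
}

#' Export a profile cross-section as CSV
#'
#' @param profile a `surface_profile`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "surface_profile"))
  write.csv(data.frame(x_um = profile$x, h_um = profile$h), path,
            row.names = FALSE)
  invisible(path)
}
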