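test_that("closed forms agree with independent one-line evaluations", {
  set.seed(1)
  for (i in 1:100) {
    u <- runif(1, 10, 38)
    wv <- runif(1, 0, 0.5)
    th <- runif(1, 0, 90)
    Is <- runif(1, 0.5, 2)
    ct <- cos(th * pi / 180)
    expect_equal(suppressWarnings(amp_reflection_model(u, wv, Is)),
                 Is * ((0.0023 - 0.0016 * wv) * u - 0.00029),
                 tolerance = 1e-12)
    expect_equal(suppressWarnings(width_reflection_model(u, wv)),
                 1 / ((0.006 - 0.0007 * wv) * u - 0.009), tolerance = 1e-12)
    expect_equal(suppressWarnings(amp_transmission_model(u, wv, th, Is)),
                 Is * (1 - wv) * ((0.028 * ct - 0.0196) * u +
                                    0.0493 * (1 - ct)), tolerance = 1e-12)
    expect_equal(
      reflectance_model(th, u),
      1 - (0.00016 + 0.97 / u) /
        (1 + exp((0.11 - 0.26 / u) * (th - (87.44 + 107.15 / u)))),
      tolerance = 1e-12)
    expect_equal(
      transmittance_model(th, u),
      (0.94 - 0.44 / u) /
        (1 + exp((0.32 - 2.00 / u) * (th - (44.28 + 61.57 / u)))),
      tolerance = 1e-12)
  }
  # width model for transmission, checked at a representative point
  ct <- cos(45 * pi / 180)
  expect_equal(width_transmission_model(25, 0.11, 45),
               1 / ((1 - 0.71 * 0.11) *
                      ((0.089 * ct - 0.0604) * 25 + 0.23 * (1 - ct))),
               tolerance = 1e-12)
})

test_that("hand-evaluated reference points of the closed forms", {
  expect_equal(amp_reflection_model(25, 0.11), 0.05281, tolerance = 1e-9)
  expect_equal(width_reflection_model(25, 0.11), 7.190365, tolerance = 1e-6)
  expect_equal(amp_transmission_model(25, 0.11, 45), 0.0172788,
               tolerance = 1e-6)
  expect_equal(reflectance_model(0, 25), 0.9610442, tolerance = 1e-6)
  expect_equal(transmittance_model(0, 11.8), 0.9021872, tolerance = 1e-6)
  expect_lt(transmittance_model(90, 11.8), 0.01)
})

test_that("structural properties of the closed forms", {
  u <- seq(10, 38, by = 2)
  # amplitude linear in I_s
  expect_equal(suppressWarnings(amp_reflection_model(25, 0.11, I_s = 2)),
               2 * amp_reflection_model(25, 0.11, I_s = 1))
  # amplitude vanishes at the root of the linear bracket
  wv <- 0.2
  u0 <- 0.00029 / (0.0023 - 0.0016 * wv)
  expect_equal(suppressWarnings(amp_reflection_model(u0, wv)), 0,
               tolerance = 1e-12)
  # 1/sigma affine and sigma strictly decreasing in u_ratio
  s <- suppressWarnings(width_reflection_model(u, 0.11))
  expect_true(all(diff(s) < 0))
  expect_lt(max(abs(diff(diff(1 / s)))), 1e-12)
  # transmission amplitude vanishes when the sulcus fills the period
  expect_equal(suppressWarnings(amp_transmission_model(20, 1 - 1e-12, 30)),
               0, tolerance = 1e-9)
  # sigmoids monotone in incidence angle
  th <- seq(0, 90, by = 1)
  expect_true(all(diff(reflectance_model(th, 25)) >= 0))
  expect_true(all(diff(transmittance_model(th, 11.8)) <= 0))
  # large-u limit of the reflectance numerator
  expect_equal(1 - reflectance_model(0, 1e9),
               0.00016 / (1 + exp(0.11 * (0 - 87.44))), tolerance = 1e-5)
})

test_that("angle averaging is exact for constants and reproduces references", {
  cmod <- function(theta_i, u_ratio) rep(0.37, length(theta_i))
  expect_equal(angle_average(cmod, 5), 0.37, tolerance = 1e-14)
  expect_equal(angle_average(transmittance_model, 11.8), 0.495,
               tolerance = 0.005)
  expect_equal(angle_average(transmittance_model, 25), 0.479,
               tolerance = 0.005)
  # averaged transmittance strictly decreasing across the sample range
  u <- c(11.8, 15.2, 21.9, 25)
  avg <- vapply(u, function(ui) angle_average(transmittance_model, ui),
                numeric(1))
  expect_true(all(diff(avg) < 0))
  # averaged reflectance increasing (trend of the printed model)
  avg_r <- vapply(u, function(ui) angle_average(reflectance_model, ui),
                  numeric(1))
  expect_true(all(diff(avg_r) > 0))
  expect_error(angle_average(cmod, 5, step = 0.5), "step")
})

test_that("Spearman rank correlation matches brute-force mid-ranks", {
  expect_equal(spearman_rank(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(spearman_rank(1:5, c(10, 8, 6, 4, 2))$rho, -1)
  # 6-point set with one tie against explicit mid-rank computation
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 4, 6, 7)
  rx <- rank(x)
  ry <- rank(y)
  rho_bf <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  s <- spearman_rank(x, y)
  expect_equal(s$rho, rho_bf, tolerance = 1e-12)
  expect_true(s$p_value > 0 && s$p_value < 1)
  # exact permutation p-value: strictly monotone 4-vector has p = 2/4! * 2
  se <- spearman_rank(1:4, c(3, 5, 7, 9), exact = TRUE)
  expect_equal(se$rho, 1)
  expect_equal(se$p_value, 2 / 24, tolerance = 1e-12)
  expect_error(spearman_rank(1:5, rep(2, 5)), "constant")
  expect_error(spearman_rank(1:2, 1:2), "at least 3")
})

test_that("linear-form refit recovers generating coefficients exactly", {
  grid <- expand.grid(u_ratio = c(10, 14, 18, 22, 26, 30),
                      wv_ratio = c(0.05, 0.11, 0.2, 0.3))
  grid$A_norm <- (0.0023 - 0.0016 * grid$wv_ratio) * grid$u_ratio - 0.00029
  grid$sigma <- 1 / ((0.006 - 0.0007 * grid$wv_ratio) * grid$u_ratio - 0.009)
  fitA <- fit_linear_form(grid, "amplitude")
  expect_equal(unname(fitA$coef["a"]), 0.0023, tolerance = 1e-6)
  expect_equal(unname(fitA$coef["b"]), -0.0016, tolerance = 1e-6)
  expect_equal(unname(fitA$coef["c"]), -0.00029, tolerance = 1e-6)
  fitS <- fit_linear_form(grid, "width")
  expect_equal(unname(fitS$coef["a"]), 0.006, tolerance = 1e-6)
  expect_equal(unname(fitS$coef["b"]), -0.0007, tolerance = 1e-6)
  expect_equal(unname(fitS$coef["c"]), -0.009, tolerance = 1e-6)
  expect_error(fit_linear_form(grid[grid$u_ratio == 10, ], "amplitude"),
               ">= 4")
})

test_that("sigmoid-family refit recovers generating constants", {
  grid <- expand.grid(theta_i = seq(0, 90, by = 5),
                      u_ratio = c(11.8, 15.2, 21.9, 25))
  grid$value <- transmittance_model(grid$theta_i, grid$u_ratio)
  fit <- fit_sigmoid_form(grid, "transmission")
  expect_equal(unname(fit$coef), unname(smt_constants()$transmittance),
               tolerance = 1e-4)
  grid$value <- reflectance_model(grid$theta_i, grid$u_ratio)
  fit <- fit_sigmoid_form(grid, "reflection")
  expect_equal(unname(fit$coef), unname(smt_constants()$reflectance),
               tolerance = 1e-4)
})

test_that("simulated sweep shows the published parametric structure", {
  sw <- run_sweep(u_ratio = c(12, 15, 19, 25), wv_ratio = 0.11,
                  theta_i = 45, mode = "reflection", ray_count = 2e4,
                  seed = 1)
  expect_equal(nrow(sw), 4)
  # width decreases, normalised amplitude increases with the SMT ratio
  expect_true(all(diff(sw$sigma) < 0))
  expect_true(all(diff(sw$A_norm) > 0))
  lin <- fit_linear_form(sw, "width")
  expect_gt(lin$r_squared, 0.9)
  expect_gt(lin$coef["a"], 0)
  expect_lte(spearman_rank(sw$u_ratio, sw$sigma)$rho, -0.9)
})

test_that("macro-texture influence on the lobe is weaker than the SMT's", {
  sw_u <- run_sweep(u_ratio = c(12, 25), wv_ratio = 0.11, theta_i = 45,
                    ray_count = 2e4, seed = 21)
  sw_wv <- run_sweep(u_ratio = 19, wv_ratio = c(0.08, 0.3), theta_i = 45,
                     ray_count = 2e4, seed = 31)
  rel_change <- function(v) abs(diff(v)) / mean(v)
  expect_gt(rel_change(sw_u$sigma), rel_change(sw_wv$sigma))
  expect_gt(rel_change(sw_u$A_norm), rel_change(sw_wv$A_norm))
})
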