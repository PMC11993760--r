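test_that("flat and degenerate limits of the profile builder", {
  flat <- flat_profile()
  expect_true(all(flat$h == 0))
  # macro only, no ripple: smooth groove, bounded by [-H, 0]
  p <- surface_params(W = 200, H = 10, W_V = 30, u_h = 0, u_w = 0)
  prof <- build_profile(p, 1, 1000)
  expect_lte(max(prof$h), 0)
  expect_gte(min(prof$h), -10)
  # invalid combinations are rejected
  expect_error(build_profile(surface_params(100, 5, 10, 1, 0), 1, 1000),
               "ripple period undefined")
  expect_error(surface_params(W = 100, H = 5, W_V = 100, u_h = 0, u_w = 0),
               "W_V")
  expect_error(surface_params(W = 100, H = 5, W_V = 10, u_h = 1, u_w = 95),
               "u_w")
})

test_that("sample 2 profile has the tabulated period and depth range", {
  p <- table1_presets()$sample2
  prof <- build_profile(p, 1)
  expect_equal(prof$period, 240.8)
  # groove reaches -H; ripple tops reach +u_h above the crista plane
  expect_equal(min(prof$h), -17.9, tolerance = 1e-3)
  expect_equal(max(prof$h), 2.1, tolerance = 1e-3)
  expect_equal(max(prof$h) - min(prof$h), 17.9 + 2.1, tolerance = 1e-3)
})

test_that("ripple maxima per period match a brute-force extremum scan", {
  for (nm in c("sample1", "sample2", "sb6")) {
    p <- table1_presets()[[nm]]
    prof <- build_profile(p, 1)
    h <- prof$h
    n <- length(h)
    # brute-force scan for strict local maxima above the crista plane
    is_max <- h[2:(n - 1)] > h[1:(n - 2)] & h[2:(n - 1)] >= h[3:n] &
      h[2:(n - 1)] > p$u_h / 2
    n_max <- sum(is_max)
    expected <- floor((p$W - p$W_V) / p$u_w)
    expect_gte(n_max, expected)
    expect_lte(n_max, expected + 1)
  }
})

test_that("profile is periodic and height-bounded", {
  p <- table1_presets()$sample1
  prof <- build_profile(p, 2)
  x <- seq(0, p$W, length.out = 501)
  q1 <- profile_height(prof, x)
  q2 <- profile_height(prof, x + p$W)
  expect_lt(max(abs(q1$h - q2$h)), 1e-9)
  expect_true(all(prof$h <= p$u_h + 1e-12))
  expect_true(all(prof$h >= -p$H - p$u_h - 1e-12))
  # normals are unit length
  nn <- sqrt(q1$nx^2 + q1$nz^2)
  expect_lt(max(abs(nn - 1)), 1e-12)
})

test_that("scaling all lengths scales the height function pointwise", {
  p <- table1_presets()$sample3
  cs <- 2.5
  ps <- surface_params(W = cs * p$W, H = cs * p$H, W_V = cs * p$W_V,
                       u_h = cs * p$u_h, u_w = cs * p$u_w, n = p$n)
  prof1 <- build_profile(p, 1)
  prof2 <- build_profile(ps, 1)
  x <- seq(0.1, p$W - 0.1, length.out = 400)
  h1 <- profile_height(prof1, x)$h
  h2 <- profile_height(prof2, cs * x)$h
  expect_equal(h2, cs * h1, tolerance = 1e-12)
})

test_that("noise-free round trip recovers all parameters within 5%", {
  for (nm in c("sample1", "sample2", "sample3", "sample4", "sb6")) {
    p <- table1_presets()[[nm]]
    est <- parameterize_profile(build_profile(p, n_periods = 4))
    for (f in c("W", "H", "W_V", "u_h", "u_w")) {
      expect_lt(abs(est[[f]] - p[[f]]) / p[[f]], 0.05,
                label = sprintf("%s / %s relative error", nm, f))
    }
  }
})

test_that("pure ripple train is parameterized without a false sulcus", {
  p <- surface_params(W = 300, H = 0, W_V = 0, u_h = 2, u_w = 30)
  est <- parameterize_profile(build_profile(p, n_periods = 3))
  expect_identical(est$n_sulci, 0L)
  expect_true(is.na(est$W))
  expect_lt(abs(est$u_h - 2) / 2, 0.05)
  expect_lt(abs(est$u_w - 30) / 30, 0.05)
})

test_that("flat input yields absent parameters without crashing", {
  est <- parameterize_profile(rep(0, 400), spacing = 1)
  expect_true(is.na(est$u_w))
  expect_true(is.na(est$W))
  expect_identical(est$n_peaks, 0L)
})

test_that("synthetic height maps are deterministic and extrude the profile", {
  p <- table1_presets()$sb6
  hm0 <- synth_height_map(p, extent = c(400, 20), spacing = 1, noise_sd = 0)
  # noise-free: every row equals the sampled profile
  row <- profile_height(build_profile(p, 2), (seq_len(400) - 1) * 1)$h
  expect_equal(hm0$z[5, ], row, tolerance = 1e-12)
  hm1 <- synth_height_map(p, extent = c(400, 20), spacing = 1,
                          noise_sd = 0.2, seed = 7)
  hm2 <- synth_height_map(p, extent = c(400, 20), spacing = 1,
                          noise_sd = 0.2, seed = 7)
  expect_identical(hm1$z, hm2$z)
  expect_error(synth_height_map(p, c(400, 20), spacing = 0), "spacing")
  expect_error(synth_height_map(p, c(100, 20), spacing = 1), "extent")
})

test_that("noisy central row still recovers the ripple period within 10%", {
  p <- table1_presets()$sample2
  hm <- synth_height_map(p, extent = c(708, 40), spacing = 0.5,
                         noise_sd = 0.05 * p$u_h, seed = 11)
  est <- parameterize_profile(hm$z[20, ], spacing = 0.5)
  expect_lt(abs(est$u_w - p$u_w) / p$u_w, 0.10)
})

test_that("height maps round-trip through CSV and TIFF", {
  hm <- synth_height_map(table1_presets()$sb6, extent = c(300, 12),
                         spacing = 1, noise_sd = 0.3, seed = 3)
  f_csv <- tempfile(fileext = ".csv")
  write_height_map(hm, f_csv)
  back <- read_height_map(f_csv)
  expect_equal(back$spacing, 1)
  expect_lt(max(abs(back$z - hm$z)), 1e-8)
  skip_if_not_installed("tiff")
  f_tif <- tempfile(fileext = ".tif")
  write_height_map(hm, f_tif)
  back2 <- read_height_map(f_tif)
  expect_lt(max(abs(back2$z - hm$z)), 1e-5)
  expect_equal(back2$spacing, 1)
})
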