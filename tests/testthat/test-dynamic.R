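test_that("temporal STD matches closed forms", {
  meta <- tiny_meta(4, 2)
  # constant series -> 0
  stk <- raw_stack(array(5, c(4, 2, 2)), meta)
  expect_equal(temporal_std(stk), matrix(0, 2, 2))
  # alternating +a/-a around an offset: sample SD = a sqrt(T/(T-1))
  a <- 3
  series <- 10 + rep(c(a, -a), 2)
  stk2 <- raw_stack(array(rep(series, 4), c(4, 2, 2)), meta)
  expect_equal(temporal_std(stk2), matrix(a * sqrt(4 / 3), 2, 2),
               tolerance = 1e-12)
  # full-period sinusoid: RMS a/sqrt(2), within 1% for T = 500
  stk3 <- tone_stack(freq = 10, amplitude = 2, n_frames = 500, fps = 500)
  expect_equal(max(abs(temporal_std(stk3) - 2 / sqrt(2))) / (2 / sqrt(2)),
               0, tolerance = 0.01)
  # single-frame acquisitions are rejected upstream, at the metadata level
  expect_error(tiny_meta(1, 2), class = "dffocm_parameter_error")
})

test_that("STD map is invariant to a per-pixel temporal constant", {
  set.seed(9)
  meta <- tiny_meta(32, 4)
  frames <- array(runif(32 * 16, 10, 20), c(32, 4, 4))
  shift <- matrix(runif(16, 0, 50), 4, 4)
  shifted <- frames + rep(as.vector(shift), each = 32)
  expect_equal(temporal_std(raw_stack(frames, meta)),
               temporal_std(raw_stack(shifted, meta)), tolerance = 1e-9)
})

test_that("pixel spectrum satisfies Parseval and isolates pure tones", {
  # constant stack: all AC bins zero
  cube0 <- pixel_spectrum(raw_stack(array(3, c(16, 2, 2)), tiny_meta(16, 2)))
  expect_equal(max(cube0$magnitudes[-1, , ]), 0)
  expect_equal(cube0$freqs, seq(0, 250, by = 500 / 16))
  # unit cosine at exact bin k: all AC power in bin k, magnitude = RMS
  k <- 5
  stk <- tone_stack(freq = k * 500 / 64, amplitude = 1, n_frames = 64)
  cube <- pixel_spectrum(stk)
  pw <- cube$magnitudes[, 1, 1]^2
  expect_equal(pw[k + 1], 0.5, tolerance = 1e-10)
  expect_equal(sum(pw[-1]) - pw[k + 1], 0, tolerance = 1e-10)
  # white noise: sum of one-sided AC power = population variance
  set.seed(21)
  frames <- array(rexp(128 * 9, 1 / 50), c(128, 3, 3))
  stkn <- raw_stack(frames, tiny_meta(128, 3))
  cuben <- pixel_spectrum(stkn)
  for (i in 1:3) for (j in 1:3) {
    x <- frames[, i, j]
    v_pop <- var(x) * 127 / 128
    expect_equal(sum(cuben$magnitudes[-1, i, j]^2) / v_pop, 1,
                 tolerance = 1e-10)
  }
})

test_that("band integration respects bin membership and edge rules", {
  stk <- tone_stack(freq = 150, amplitude = 1, n_frames = 500)
  cube <- pixel_spectrum(stk)
  maps <- integrate_bands(cube, band_definition(), quantity = "power")
  expect_equal(max(maps$low), 0, tolerance = 1e-20)
  expect_equal(max(maps$mid), 0, tolerance = 1e-20)
  expect_gt(min(maps$high), 0.49)
  # a tone exactly at a shared edge belongs to the upper band
  stk_edge <- tone_stack(freq = 100, amplitude = 1, n_frames = 500)
  maps_edge <- integrate_bands(pixel_spectrum(stk_edge), band_definition(),
                               quantity = "power")
  expect_equal(max(maps_edge$mid), 0, tolerance = 1e-20)
  expect_gt(min(maps_edge$high), 0.49)
  # a tone at Nyquist is captured by a band closing at Nyquist
  stk_nyq <- tone_stack(freq = 250, amplitude = 1, n_frames = 500)
  maps_nyq <- integrate_bands(pixel_spectrum(stk_nyq), band_definition(),
                              quantity = "power")
  expect_gt(min(maps_nyq$high), 0.9)  # Nyquist bin power = a^2 (not a^2/2)
  # empty band warns and returns zeros
  cube16 <- pixel_spectrum(raw_stack(array(rnorm(16 * 4)^2, c(16, 2, 2)),
                                     tiny_meta(16, 2)))
  expect_warning(
    m <- integrate_bands(cube16, band_definition(c(1, 3, 100, 250))),
    class = "dffocm_warning")
  expect_equal(max(m$low), 0)
})

test_that("bands tiling (0, Nyquist] conserve total AC power", {
  set.seed(5)
  frames <- array(runif(256 * 16, 100, 200), c(256, 4, 4))
  stk <- raw_stack(frames, tiny_meta(256, 4))
  cube <- pixel_spectrum(stk)
  maps <- integrate_bands(cube, band_definition(c(1e-9, 3, 100, 250)),
                          quantity = "power")
  total <- maps$low + maps$mid + maps$high
  v_pop <- apply(frames, c(2, 3), function(x) var(x) * 255 / 256)
  expect_equal(total, v_pop, tolerance = 1e-10)
})

test_that("raising drive amplitude strictly raises the containing band power", {
  powers <- vapply(c(5, 10, 20, 40), function(a) {
    stk <- simulate_stack(driven_spec(20, amplitude = a, n_frames = 256))
    maps <- integrate_bands(pixel_spectrum(stk), quantity = "power")
    mean(maps$mid)
  }, numeric(1))
  expect_true(all(diff(powers) > 0))
})

test_that("percentile stretch saturates and zeroes the configured fractions", {
  m <- matrix(seq_len(200 * 200), 200, 200)  # strictly increasing, distinct
  maps <- list(low = m, mid = m, high = m)
  rgb <- render_rgb(maps, render_config())
  for (ch in 1:3) {
    v <- rgb[ch, , ]
    expect_equal(sum(v == 1) / length(v), 0.01)
    expect_equal(sum(v == 0) / length(v), 0.01)
  }
  expect_true(all(rgb >= 0 & rgb <= 1))
})

test_that("rendering is scale-invariant well above the log epsilon", {
  set.seed(8)
  m <- matrix(rexp(64 * 64) + 1, 64, 64)
  maps1 <- list(low = m, mid = 2 * m, high = 5 * m)
  maps10 <- lapply(maps1, function(x) 10 * x)
  cfg <- render_config(log_epsilon = 1e-20)
  expect_equal(render_rgb(maps10, cfg), render_rgb(maps1, cfg),
               tolerance = 1e-9)
})

test_that("degenerate channels render all-zero with a warning", {
  z <- matrix(0, 8, 8)
  m <- matrix(seq_len(64), 8, 8)
  expect_warning(rgb <- render_rgb(list(low = z, mid = m, high = m),
                                   render_config()),
                 class = "dffocm_warning")
  expect_equal(max(rgb[3, , ]), 0)
  expect_gt(max(rgb[2, , ]), 0)
})

test_that("driven regions adopt their band's colour in the full pipeline", {
  fx <- three_region_spec(n = 32)
  img <- dynamic_pipeline(simulate_stack(fx$spec))
  dominant <- c("B", "G", "R")  # low, mid, high drive
  for (r in 1:3) {
    mask <- fx$regions == r
    means <- vapply(1:3, function(ch) mean(img$rgb[ch, , ][mask]), numeric(1))
    expect_equal(c("R", "G", "B")[which.max(means)], dominant[r])
  }
})

test_that("the pipeline is deterministic and black for static samples", {
  bands4 <- band_definition(c(4, 20, 100, 250))  # resolvable on short stacks
  fx <- three_region_spec(n = 16, n_frames = 128)
  stk <- simulate_stack(fx$spec)
  img1 <- dynamic_pipeline(stk, bands4)
  img2 <- dynamic_pipeline(stk, bands4)
  expect_identical(img1$rgb, img2$rgb)
  expect_identical(img1$std_map, img2$std_map)

  static_spec <- simulation_spec(
    meta = tiny_meta(64, 8),
    dynamics = scatterer_dynamics(static_reflectivity = 0.2),
    shot_noise = FALSE)
  img0 <- dynamic_pipeline(simulate_stack(static_spec), bands4)
  expect_equal(max(img0$std_map), 0)
  expect_equal(max(img0$rgb), 0)
})

test_that("mean spectrum averages pixel spectra arithmetically", {
  stk <- tone_stack(freq = 50, amplitude = 1, n_frames = 64, n = 2)
  cube <- pixel_spectrum(stk)
  ms <- mean_spectrum(cube)
  expect_equal(ms$magnitude, cube$magnitudes[, 1, 1], tolerance = 1e-12)
  # two pixels, one silent: mean is half the active spectrum
  frames <- stk$frames
  frames[, 1, 1] <- mean(frames[, 1, 1])
  frames[, 2, 1] <- mean(frames[, 2, 1])
  frames[, 1, 2] <- mean(frames[, 1, 2])
  cube2 <- pixel_spectrum(raw_stack(frames, stk$meta))
  ms2 <- mean_spectrum(cube2)
  expect_equal(ms2$magnitude[-1], cube$magnitudes[-1, 1, 1] / 4,
               tolerance = 1e-12)
})

test_that("volumes assemble with correct orthogonal projections", {
  fx <- three_region_spec(n = 16, n_frames = 128)
  img <- dynamic_pipeline(simulate_stack(fx$spec),
                          band_definition(c(4, 20, 100, 250)))
  zero_img <- img
  zero_img$rgb <- array(0, dim(img$rgb))
  # single image: projections equal the image
  v1 <- assemble_volume(list(img), z_step = 1)
  expect_equal(dim(v1$volume), c(3, 1, 16, 16))
  expect_equal(v1$xy, img$rgb)
  # second all-zero image: max projection still equals the first
  v2 <- assemble_volume(list(img, zero_img), z_step = 1)
  expect_equal(v2$xy, img$rgb)
  # a bright layer at known z appears at that row of the XZ projection
  v3 <- assemble_volume(list(zero_img, img, zero_img), z_step = 0.5)
  expect_equal(v3$xz[1, 2, ], apply(img$rgb[1, , ], 2, max))
  expect_equal(max(v3$xz[, c(1, 3), ]), 0)
  expect_error(assemble_volume(list()), class = "dffocm_structural_error")
})
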