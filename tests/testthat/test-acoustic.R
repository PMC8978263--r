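make_point_slice <- function(n = 96, sp = 0.3, src = NULL, sigma = 0.3,
                             c0 = 1500, rho0 = 1000) {
  cx <- (seq_len(n) - 0.5) * sp
  X <- matrix(cx, n, n)
  Z <- matrix(cx, n, n, byrow = TRUE)
  if (is.null(src)) src <- c(n * sp / 2, n * sp / 2)
  p0 <- exp(-((X - src[1])^2 + (Z - src[2])^2) / (2 * sigma^2))
  makeAcousticSlice(p0, matrix(c0, n, n), matrix(rho0, n, n), sp)
}

test_that("slices extracted from 3-D volumes equal direct 2-D construction", {
  sp <- 0.5
  grid <- GridSpec(c(12, 7, 12), sp)
  scene <- list(
    Structure("sphere", list(center = c(3, 1.75, 3), radius = 1.2),
              tissueLibrary("blood"), 2),
    Structure("background", composition = tissueLibrary("water")))
  vols <- createModelBasedVolume(scene, grid, 800)
  sl <- extractSlice(vols, NULL)            # mid-plane y index 4
  expect_equal(sl@sos, as.matrix(vols@sos[, 4, ]))
  expect_equal(dim(sl@p0), c(12L, 12L))
  # homogeneous background away from the sphere
  expect_equal(sl@sos[10, 10], mixComposition(tissueLibrary("water"),
                                              800)$sos)
  # the sphere cross-section appears as a disk of blood sound speed
  blood_sos <- mixComposition(tissueLibrary("blood"), 800)$sos
  expect_true(any(abs(sl@sos - blood_sos) < 1))
  expect_error(extractSlice(vols, NULL, y_index = 99), "range")
})

test_that("zero initial pressure stays zero and propagation is linear", {
  sl <- make_point_slice(48, 0.4)
  z <- sl
  z@p0 <- matrix(0, 48, 48)
  pr0 <- kspacePropagate(z, 30, sensors = cbind(5, 5))
  expect_true(all(pr0$sensor_data == 0))
  expect_true(all(pr0$p_final == 0))

  pr1 <- kspacePropagate(sl, 30, sensors = cbind(5, 5))
  sl2 <- sl
  sl2@p0 <- sl@p0 * 3.5
  pr2 <- kspacePropagate(sl2, 30, sensors = cbind(5, 5))
  expect_equal_tol(pr2$sensor_data, 3.5 * pr1$sensor_data,
                   1e-10 * max(abs(pr1$sensor_data)))
})

test_that("arrival times respect geometry: symmetry and ordering", {
  n <- 96; sp <- 0.3
  sl <- make_point_slice(n, sp)
  ctr <- n * sp / 2
  sens <- rbind(c(ctr - 6, ctr), c(ctr + 6, ctr),  # equidistant pair
                c(ctr, ctr - 4), c(ctr, ctr - 10)) # closer vs farther
  pr <- kspacePropagate(sl, 220, sensors = sens)
  expect_equal_tol(pr$sensor_data[1, ], pr$sensor_data[2, ],
                   1e-5 * max(abs(pr$sensor_data[1, ])))
  peak <- apply(pr$sensor_data, 1, which.max)
  expect_lt(peak[3], peak[4])
  expect_error(kspacePropagate(sl, 10, sensors = cbind(1e3, 0)), "outside")
})

test_that("the envelope peak of a recorded pulse arrives at distance over speed", {
  n <- 128; sp <- 0.3
  sl <- make_point_slice(n, sp, src = c(n * sp / 2, 8), sigma = sp)
  d_mm <- 12
  pr <- kspacePropagate(sl, 260, sensors = cbind(n * sp / 2, 8 + d_mm))
  env <- as.vector(envelopeDetect(matrix(pr$sensor_data[1, ], 1)))
  t_peak <- which.max(env) * pr$dt
  t_true <- d_mm * 1e-3 / 1500
  expect_lte(abs(t_peak - t_true), pr$dt)
})

test_that("refining the grid moves the envelope arrival by less than one coarse step", {
  arrival <- function(n, sp) {
    sl <- make_point_slice(n, sp, src = c(n * sp / 2, 6), sigma = 0.45)
    pr <- kspacePropagate(sl, round(180 * 0.3 / sp),
                          sensors = cbind(n * sp / 2, 16))
    env <- as.vector(envelopeDetect(matrix(pr$sensor_data[1, ], 1)))
    list(t = which.max(env) * pr$dt, dt = pr$dt)
  }
  coarse <- arrival(72, 0.3)
  fine <- arrival(144, 0.15)
  expect_lt(abs(fine$t - coarse$t), coarse$dt)
})

test_that("field energy is conserved before the wavefront reaches the boundary", {
  sl <- make_point_slice(100, 0.3)
  pr <- kspacePropagate(sl, 120, record_energy = TRUE)
  e <- pr$energy
  # after the initial potential/kinetic equilibration, drift < 1%
  expect_lt((max(e[10:110]) - min(e[10:110])) / e[10], 0.01)
})

test_that("reciprocity: swapping source and receiver gives the same arrival", {
  n <- 96; sp <- 0.3
  a <- c(9, 9); b <- c(18, 16)
  arr <- function(src, rec) {
    sl <- make_point_slice(n, sp, src = src, sigma = sp)
    pr <- kspacePropagate(sl, 220, sensors = rbind(rec))
    env <- as.vector(envelopeDetect(matrix(pr$sensor_data[1, ], 1)))
    which.max(env)
  }
  expect_lte(abs(arr(a, b) - arr(b, a)), 1)
})

test_that("CFL violations are refused and the PML suppresses wrap-around", {
  sl <- make_point_slice(48, 0.4)
  dt_max <- 0.3 * 0.4e-3 / 1500
  expect_error(kspacePropagate(sl, 10, dt = dt_max * 2), "CFL")

  # long run: wrap-around through the periodic FFT boundary would revisit
  # the center with O(1) amplitude; the PML keeps it small
  pr <- kspacePropagate(sl, 500, sensors = cbind(9.6, 9.6))
  s <- abs(pr$sensor_data[1, ])
  expect_lt(max(s[300:500]), 0.05 * max(s))
})

test_that("recordTimeSeries matches inline sensor recording", {
  n <- 48; sp <- 0.4
  sl <- make_point_slice(n, sp)
  det <- buildLinearArray(5, 1.5, center_mm = c(n * sp / 2, 0, 3))
  pr <- kspacePropagate(sl, 60, record_fields = TRUE,
                        sensors = elementPositions(
                          DeviceTwin(det, IlluminationGeometry("pencil"))
                        )[, c(1, 3)])
  ts <- recordTimeSeries(pr$fields, pr$dt, sl, det)
  expect_equal(ts@signals, pr$sensor_data, tolerance = 1e-12)
  expect_equal(ts@dt, pr$dt)
  det_out <- buildLinearArray(3, 1.5, center_mm = c(90, 0, 3))
  expect_error(recordTimeSeries(pr$fields, pr$dt, sl, det_out), "outside")
})

test_that("the attenuation filter scales tones by the analytic factor", {
  fs <- 40e6
  tt <- (0:2047) / fs
  tone <- sin(2 * pi * 5e6 * tt)
  ts <- new("TimeSeriesData", signals = rbind(tone, tone), dt = 1 / fs,
            t0 = 0, positions = matrix(0, 2, 3), soundSpeed = 1500)
  out <- applyAttenuation(ts, 0.5, 20)   # 0.5 dB/cm/MHz over 2 cm
  gain <- max(abs(out@signals[1, 200:1800])) /
    max(abs(ts@signals[1, 200:1800]))
  expect_lt(abs(gain - 10^(-0.25)) / 10^(-0.25), 0.01)

  expect_equal(applyAttenuation(ts, 0, 20)@signals, ts@signals)
  expect_error(applyAttenuation(ts, -1, 20), ">= 0")

  # monotonicity: a larger alpha never increases any frequency magnitude
  w1 <- abs(stats::fft(applyAttenuation(ts, 0.3, 20)@signals[1, ]))
  w2 <- abs(stats::fft(applyAttenuation(ts, 0.9, 20)@signals[1, ]))
  expect_true(all(w2 <= w1 + 1e-9 * max(w1)))
})
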