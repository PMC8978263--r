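# shared fixture builders; everything is generated in code at test time

# small homogeneous background volume
tiny_volumes <- function(shape = c(15, 15, 20), spacing = 0.5,
                         tissue = "background", wavelengths = 800) {
  grid <- GridSpec(shape, spacing)
  bg <- Structure("background", composition = tissueLibrary(tissue))
  createModelBasedVolume(list(bg), grid, wavelengths)
}

# point-absorber scene: voxel-scale blood sphere over a water background
point_scene <- function(extent = c(17, 3, 17), spacing = 0.35,
                        depth = 6, radius = spacing) {
  ctr <- round(extent / spacing / 2) * spacing
  target <- c(ctr[1], ctr[2], depth)
  list(target = target,
       structures = list(
         Structure("sphere", list(center = target, radius = radius),
                   tissueLibrary("blood", oxygenation = 0.9), priority = 2),
         Structure("background", composition = tissueLibrary("water"))))
}

# analytic detector data for a point source: gaussian pulses delayed by the
# exact time of flight (no solver involved)
analytic_point_ts <- function(src = c(8, 8), n_elem = 32, pitch = 0.5,
                              c0 = 1500, dt = 2.5e-8, n_t = 1200,
                              sigma_t = 1e-7, amp = 1) {
  ex <- (seq_len(n_elem) - (n_elem + 1) / 2) * pitch + src[1]
  pos <- cbind(ex, 0, 0)
  tt <- (seq_len(n_t) - 1) * dt
  sig <- matrix(0, n_elem, n_t)
  for (i in seq_len(n_elem)) {
    tau <- sqrt((ex[i] - src[1])^2 + src[2]^2) * 1e-3 / c0
    sig[i, ] <- amp * exp(-(tt - tau)^2 / (2 * sigma_t^2))
  }
  new("TimeSeriesData", signals = sig, dt = dt, t0 = 0, positions = pos,
      soundSpeed = c0)
}

# argmax of an image in world coordinates (mm)
image_argmax <- function(img) {
  px <- abs(pixels(img))
  am <- which(px == max(px), arr.ind = TRUE)[1, ]
  c(img@origin[1] + (am[1] - 0.5) * img@spacing,
    img@origin[2] + (am[2] - 0.5) * img@spacing)
}

expect_equal_tol <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("max |diff| = %.3g (tol %.3g)",
                              max(abs(object - expected)), tol))
}
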