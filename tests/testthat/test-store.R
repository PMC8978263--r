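test_that("numeric fields round-trip bitwise through the store", {
  st <- createStore(tempfile(fileext = ".h5"))
  x <- array(rnorm(210), dim = c(5, 6, 7))
  saveField(st, "mua", x, 800)
  expect_identical(loadField(st, "mua", 800), x)
  v <- rnorm(9)
  saveField(st, "sos", array(v, c(3, 3, 1)))
  expect_identical(as.vector(loadField(st, "sos")), v)
})

test_that("the wavelength schema is enforced on save and load", {
  st <- createStore(tempfile(fileext = ".h5"))
  saveField(st, "sos", array(1500, c(2, 2, 2)))
  saveField(st, "mua", array(0.1, c(2, 2, 2)), 800)
  expect_silent(loadField(st, "sos"))               # no wavelength needed
  expect_error(loadField(st, "mua"), "wavelength")  # wavelength required
  expect_error(saveField(st, "phi", array(1, c(2, 2))), "wavelength")
  expect_error(loadField(st, "rho"), "available")
  expect_false(fieldExists(st, "mua", 700))
  expect_true(fieldExists(st, "mua", 800))
})

test_that("repacking compresses without changing any value", {
  st <- createStore(tempfile(fileext = ".h5"))
  x <- array(rep(rnorm(10), 500), dim = c(50, 100))
  saveField(st, "p0", x, 750)
  .h5_write_str <- get(".h5_write_str", asNamespace("pasim"))
  .h5_write_str(st@path, "/pipeline", c("volume", "optical"))
  before <- storePayload(st@path, "/")
  repackStore(st@path, level = 6)
  after <- storePayload(st@path, "/")
  expect_identical(before, after)
})

test_that("IPASC-style export round-trips signals and metadata", {
  sig <- matrix(rnorm(64 * 200), 64, 200)
  ts <- new("TimeSeriesData", signals = sig, dt = 2.5e-8, t0 = 0,
            positions = cbind(seq_len(64), 0, 0), soundSpeed = 1540)
  dev <- devicePreset("linear_probe")
  f <- tempfile(fileext = ".h5")
  exportIpasc(ts, dev, meta = list(wavelengths_nm = 800), path = f)
  r <- importIpasc(f)
  expect_identical(r@signals, sig)
  expect_equal(1 / r@dt, 1 / ts@dt)
  expect_equal(r@soundSpeed, 1540)
  expect_equal(as.numeric(pasim:::.h5_read_num(f, "/meta_data/sampling_rate_hz")),
               1 / ts@dt)
})

mini_sim <- function(output, seed = 1, wavelengths = 800,
                     algorithm = "das", extra = NULL, n_photons = 2000) {
  extent <- c(8, 3, 8)
  scene <- list(
    Structure("sphere", list(center = c(4, 1.5, 4), radius = 0.8),
              tissueLibrary("blood", oxygenation = 0.8), priority = 2),
    Structure("background", composition = tissueLibrary("water")))
  device <- DeviceTwin(
    buildLinearArray(16, 0.4, center_mm = c(4, 1.5, 0.5)),
    IlluminationGeometry("slit", origin_mm = c(4, 1.5, 0), length_mm = 5),
    fov_mm = rbind(c(1, 0, 1), c(7, 3, 7)))
  settings <- paSettings(
    general = list(spacing_mm = 0.5, wavelengths_nm = wavelengths,
                   volume_extent_mm = extent, rng_seed = seed,
                   output_path = output),
    volume_creation = list(scene = scene),
    optical = list(n_photons = n_photons),
    acoustic = list(),
    noise = list(model = "gaussian", params = list(std = 1e-4)),
    reconstruction = list(algorithm = algorithm),
    linear_unmixing = list(source_field = "p0"))
  pipeline <- c(list(pipelineElement("volume_creation"),
                     pipelineElement("optical"),
                     pipelineElement("acoustic"),
                     pipelineElement("noise"),
                     pipelineElement("reconstruction")), extra)
  suppressMessages(runSimulation(pipeline, settings, device))
  list(settings = settings, device = device)
}

test_that("the orchestrator writes the full hierarchical layout per wavelength", {
  out <- tempfile(fileext = ".h5")
  mini_sim(out, wavelengths = c(700, 800, 900))
  top <- pasim:::.h5_ls(out, "/")
  expect_setequal(top$name, c("Settings", "Device", "Simulations",
                              "pipeline"))
  # one fluence dataset per wavelength
  expect_setequal(pasim:::.h5_ls(out, "/Simulations/phi")$name,
                  c("700", "800", "900"))
  expect_setequal(pasim:::.h5_ls(out, "/Simulations/p0recon")$name,
                  c("700", "800", "900"))
  # wavelength-independent grids stored once (datasets, not groups)
  ls_sim <- pasim:::.h5_ls(out, "/Simulations")
  for (f in c("sos", "rho", "alpha", "gamma", "so2", "segmentation"))
    expect_false(ls_sim$is_group[ls_sim$name == f])
  expect_equal(pasim:::.h5_read_str(out, "/pipeline"),
               c("volume_creation", "optical", "acoustic", "noise",
                 "reconstruction"))
})

test_that("configuration errors name the offending element; empty pipelines fail", {
  dev <- devicePreset("linear_probe")
  s <- paSettings(general = list(spacing_mm = 0.5, wavelengths_nm = 800,
                                 volume_extent_mm = c(5, 5, 5)))
  expect_error(runSimulation(list(), s, dev), "empty")
  expect_error(
    runSimulation(list(pipelineElement("optical")), s, dev),
    "optical")
  expect_warning(
    paSettings(general = list(spacing_mm = 0.5, wavelengths_nm = 800,
                              volume_extent_mm = c(5, 5, 5),
                              typo_tag = 1)),
    "typo_tag")
  expect_error(paSettings(general = list(spacing_mm = -1,
                                         wavelengths_nm = 800)),
               "spacing")
})

test_that("identical seeds give identical payloads; different seeds differ", {
  o1 <- tempfile(fileext = ".h5"); o2 <- tempfile(fileext = ".h5")
  o3 <- tempfile(fileext = ".h5")
  mini_sim(o1, seed = 7)
  mini_sim(o2, seed = 7)
  mini_sim(o3, seed = 8)
  p1 <- storePayload(o1); p2 <- storePayload(o2); p3 <- storePayload(o3)
  expect_identical(serialize(p1, NULL), serialize(p2, NULL))
  expect_false(identical(p1[["/Simulations/phi/800"]],
                         p3[["/Simulations/phi/800"]]))
})

test_that("elements are exchangeable without touching other settings", {
  # swapping DAS for time reversal and moving the noise element must not
  # raise schema errors or require other sub-trees to change
  o1 <- tempfile(fileext = ".h5")
  expect_no_error(mini_sim(o1, algorithm = "time_reversal"))
  extent <- c(8, 3, 8)
  scene <- list(
    Structure("sphere", list(center = c(4, 1.5, 4), radius = 0.8),
              tissueLibrary("blood"), priority = 2),
    Structure("background", composition = tissueLibrary("water")))
  device <- DeviceTwin(
    buildLinearArray(16, 0.4, center_mm = c(4, 1.5, 0.5)),
    IlluminationGeometry("slit", origin_mm = c(4, 1.5, 0), length_mm = 5),
    fov_mm = rbind(c(1, 0, 1), c(7, 3, 7)))
  settings <- paSettings(
    general = list(spacing_mm = 0.5, wavelengths_nm = 800,
                   volume_extent_mm = extent, rng_seed = 1,
                   output_path = tempfile(fileext = ".h5")),
    volume_creation = list(scene = scene),
    optical = list(n_photons = 2000),
    acoustic = list(),
    noise = list(model = "gaussian", params = list(std = 1e-4)),
    reconstruction = list(algorithm = "das"))
  # noise placed on p0 before the acoustic stage instead of after it
  settings$noise$target_field <- "p0"
  pipeline <- list(pipelineElement("volume_creation"),
                   pipelineElement("optical"),
                   pipelineElement("noise"),
                   pipelineElement("acoustic"),
                   pipelineElement("reconstruction"))
  expect_no_error(suppressMessages(
    runSimulation(pipeline, settings, device)))
})

test_that("forward results feed several reconstructions without re-running", {
  out <- tempfile(fileext = ".h5")
  ctx <- mini_sim(out)
  st <- openStore(out)
  ts_sig1 <- loadField(st, "time_series", 800)
  # run a second reconstruction element against the same store
  runner <- get(".elem_reconstruction", asNamespace("pasim"))
  runner(st, list(algorithm = "dmas"), ctx$settings, ctx$device, 800, 1)
  expect_identical(loadField(st, "time_series", 800), ts_sig1)
  expect_true(fieldExists(st, "p0recon", 800))
})

test_that("multispectral elements run once after the wavelength loop", {
  out <- tempfile(fileext = ".h5")
  mini_sim(out, wavelengths = c(750, 850),
           extra = list(pipelineElement("linear_unmixing")))
  st <- openStore(out)
  expect_true(pasim:::.h5_exists(out, "/Simulations/unmixing/so2"))
  so2 <- loadField(st, "unmixing/so2")
  # the blood sphere region should unmix to a defined saturation
  expect_true(any(is.finite(so2)))
  expect_true(all(so2[is.finite(so2)] >= 0 & so2[is.finite(so2)] <= 1))
})

test_that("random scenes are reproducible, sized as requested, and diverse", {
  s1 <- generateRandomScene(5)
  s2 <- generateRandomScene(5)
  expect_equal(length(s1$structures), length(s2$structures))
  p1 <- vapply(s1$structures, function(x) x@priority, numeric(1))
  expect_identical(lapply(s1$structures, function(x) x@params),
                   lapply(s2$structures, function(x) x@params))

  s3 <- generateRandomScene(1, ranges = list(n_vessels = c(3, 3),
                                             radius_mm = c(0.5, 2),
                                             depth_mm = c(3, 12),
                                             so2 = c(0, 1),
                                             skin_amplitude_mm = c(0, 1)))
  n_tubes <- sum(vapply(s3$structures, function(x)
    x@kind == "elliptical_tube", logical(1)))
  expect_equal(n_tubes, 3)

  # 12 seeds give pairwise distinct vessel position sets
  key <- vapply(1:12, function(s) {
    sc <- generateRandomScene(s)
    paste(round(unlist(lapply(sc$structures, function(x)
      x@params$start)), 6), collapse = ",")
  }, character(1))
  expect_equal(length(unique(key)), 12L)

  expect_error(generateRandomScene(1, ranges = list(n_vessels = c(3, 1))),
               "min")
})
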