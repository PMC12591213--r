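test_that("a single straight fiber has textbook channel features", {
  r <- single_fiber_image(40, 4, theta = 0)
  v <- extract_features(r$image, intermediates = TRUE)
  expect_identical(unname(v["NumberOfFibers_mature"]), 1)
  expect_identical(unname(v["Branchpoints_mature"]), 0)
  expect_identical(unname(v["EulerNumber_mature"]), 1)
  expect_gte(unname(v["Persistence_mature"]), 0.95)
  expect_equal(unname(v["AngleRandomness_mature"]), 0, tolerance = 1e-6)
  expect_gt(unname(v["Eccentricity_mature"]), 0.99)  # elongated object
  expect_true(all(v[paste0(c("Brightness", "NumberOfFibers", "FiberLength"),
                           "_immature")] == 0))
})

test_that("angle randomness follows the doubled-angle resultant", {
  # two parallel horizontal fibers: zero circular variance
  par2 <- rbind(
    data.frame(x = 30, y = 16, theta = 0, length = 40, width = 3,
               waviness = 0, stain = "mature", fragments = 1L),
    data.frame(x = 30, y = 44, theta = 0, length = 40, width = 3,
               waviness = 0, stain = "mature", fragments = 1L))
  r <- render_fibers(par2, pixel_size = 0.5, field = c(60, 60), noise_sd = 0)
  v <- extract_features(r$image)
  expect_lt(unname(v["AngleRandomness_mature"]), 0.02)

  # orthogonal equal-length fibers: doubled angles cancel, variance 1
  orth <- rbind(
    data.frame(x = 16, y = 16, theta = 0, length = 24, width = 3,
               waviness = 0, stain = "mature", fragments = 1L),
    data.frame(x = 44, y = 44, theta = pi / 2, length = 24, width = 3,
               waviness = 0, stain = "mature", fragments = 1L))
  r <- render_fibers(orth, pixel_size = 0.5, field = c(60, 60), noise_sd = 0)
  v <- extract_features(r$image)
  expect_equal(unname(v["AngleRandomness_mature"]), 1, tolerance = 0.05)
})

test_that("feature vectors have exactly 26 entries in canonical order", {
  sim <- simulate_image("control", seed = 21, field_px = c(96, 96))
  v <- extract_features(sim$image)
  expect_length(v, 26L)
  expect_identical(names(v), ecm_feature_names())
  expect_identical(names(v)[1:13],
                   paste0(names(v)[14:26] |> sub("_immature", "", x = _),
                          "_mature"))
  # determinism for a fixed image and configuration
  expect_identical(v, extract_features(sim$image))
})

test_that("a blank image yields the all-zero feature vector", {
  blank <- array(1, dim = c(48, 48, 3))
  v <- extract_features(blank, pixel_size = 0.5)
  expect_identical(unname(v), rep(0, 26))
  m <- fiber_metrics(blank, pixel_size = 0.5)
  expect_equal(unname(m["porosity_pct"]), 100)
  expect_equal(unname(m["fiber_length_um"]), 0)
})

test_that("bounded features stay in [0, 1] and counts are integers", {
  for (s in 1:3) {
    v <- extract_features(simulate_image("degradation", seed = 500 + s,
                                         field_px = c(128, 128))$image)
    bounded <- paste0(rep(c("Persistence", "AngleRandomness", "Extent",
                            "Solidity", "Eccentricity"), 2),
                      rep(c("_mature", "_immature"), each = 5))
    expect_true(all(v[bounded] >= 0 & v[bounded] <= 1))
    counts <- paste0(rep(c("NumberOfFibers", "Branchpoints"), 2),
                     rep(c("_mature", "_immature"), each = 2))
    expect_true(all(v[counts] == round(v[counts]) & v[counts] >= 0))
    expect_true(v["EulerNumber_mature"] == round(v["EulerNumber_mature"]))
  }
})

test_that("the Euler number matches the flood-fill oracle", {
  set.seed(14)
  for (i in 1:6) {
    mask <- matrix(runif(30 * 30) < 0.4, 30, 30)
    expect_equal(fibroscore:::euler_number(mask), oracle_euler(mask))
  }
  ring <- matrix(FALSE, 12, 12); ring[3:9, 3:9] <- TRUE; ring[5:7, 5:7] <- FALSE
  expect_equal(fibroscore:::euler_number(ring), 0)   # 1 component, 1 hole
})

test_that("adding one distant fiber increments NumberOfFibers and EulerNumber", {
  one <- data.frame(x = 25, y = 25, theta = 0.2, length = 30, width = 3,
                    waviness = 0, stain = "mature", fragments = 1L)
  two <- rbind(one, data.frame(x = 75, y = 75, theta = 1.2, length = 30,
                               width = 3, waviness = 0, stain = "mature",
                               fragments = 1L))
  v1 <- extract_features(render_fibers(one, pixel_size = 0.5,
                                       field = c(100, 100), noise_sd = 0)$image)
  v2 <- extract_features(render_fibers(two, pixel_size = 0.5,
                                       field = c(100, 100), noise_sd = 0)$image)
  expect_identical(v2["NumberOfFibers_mature"] - v1["NumberOfFibers_mature"],
                   c(NumberOfFibers_mature = 1))
  expect_identical(v2["EulerNumber_mature"] - v1["EulerNumber_mature"],
                   c(EulerNumber_mature = 1))
})

test_that("porosity and fiber-area fraction are exactly complementary", {
  for (s in 1:4) {
    sim <- simulate_image("control", seed = 600 + s, field_px = c(96, 96))
    m <- fiber_metrics(sim$image)
    # recompute the union mask through the exported stage functions
    ch <- deconvolve_stains(rgb_to_od(sim$image))
    masks <- lapply(list(ch$mature, ch$immature), function(x) {
      select_fibers(binarize_channel(pmax(wiener_denoise(x), 0)))
    })
    union <- masks[[1]] | masks[[2]]
    expect_equal(unname(m["porosity_pct"]) / 100 + mean(union), 1,
                 tolerance = 1e-12)
  }
})

test_that("preset contrasts are recovered by the morphometry", {
  # deposition: longer, thicker, more aligned than control (mature channel)
  fc <- preset_features("control", 3, 700)
  fd <- preset_features("deposition", 3, 800)
  expect_gt(mean(fd[, "FiberLength_mature"]), mean(fc[, "FiberLength_mature"]))
  expect_gt(mean(fd[, "FiberWidth_mature"]), mean(fc[, "FiberWidth_mature"]))
  expect_lt(mean(fd[, "AngleRandomness_mature"]),
            mean(fc[, "AngleRandomness_mature"]))
  # degradation: shorter fibers, higher porosity in the simple metrics
  mc <- sapply(1:3, function(i) fiber_metrics(simulate_image("control",
    seed = 700 + i)$image))
  mg <- sapply(1:3, function(i) fiber_metrics(simulate_image("degradation",
    seed = 900 + i)$image))
  expect_lt(mean(mg["fiber_length_um", ]), mean(mc["fiber_length_um", ]))
  expect_gt(mean(mg["porosity_pct", ]), mean(mc["porosity_pct", ]))
})
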