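test_that("presets encode the three ECM states with the required orderings", {
  ctrl <- fiber_preset("control")
  dep <- fiber_preset("deposition")
  deg <- fiber_preset("degradation")
  # deposition dominates control in length, width, alignment, mature fraction
  expect_gt(dep$length_mu, ctrl$length_mu)
  expect_gt(dep$width_mu, ctrl$width_mu)
  expect_gt(dep$kappa, ctrl$kappa)
  expect_gt(dep$p_mature, ctrl$p_mature)
  expect_gt(dep$rate, ctrl$rate)
  # degradation: shorter, more fragmented, less mature, sparser
  expect_lt(deg$length_mu, ctrl$length_mu)
  expect_gt(deg$fragments_mean, 1)
  expect_lt(deg$p_mature, ctrl$p_mature)
  expect_lt(deg$rate, ctrl$rate)
  expect_error(fiber_preset("xyz"), "unknown preset")
  expect_error(fiber_preset("xyz"), "control")  # lists the valid names
})

test_that("gradient presets interpolate linearly between control and deposition", {
  ctrl <- fiber_preset("control")
  dep <- fiber_preset("deposition")
  expect_equal(unclass(gradient_preset(0))[names(ctrl) != "name"],
               unclass(ctrl)[names(ctrl) != "name"], ignore_attr = TRUE)
  expect_equal(unclass(gradient_preset(1))[names(dep) != "name"],
               unclass(dep)[names(dep) != "name"], ignore_attr = TRUE)
  mid <- gradient_preset(0.5)
  expect_equal(mid$length_mu, (ctrl$length_mu + dep$length_mu) / 2)
  expect_equal(mid$kappa, (ctrl$kappa + dep$kappa) / 2)
  expect_error(gradient_preset(-0.1), "\\[0, 1\\]")
  expect_error(gradient_preset(1.5), "\\[0, 1\\]")
})

test_that("fiber sampling is reproducible and honors the Poisson rate", {
  p <- fiber_preset("control")
  a <- sample_fibers(p, seed = 11)
  b <- sample_fibers(p, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(a$length > 0), all(a$width > 0))
  expect_true(all(a$theta >= 0 & a$theta < pi))
  expect_true(all(a$fragments >= 1L))

  p0 <- p; p0$rate <- 0
  expect_identical(nrow(sample_fibers(p0, seed = 1)), 0L)

  # Poisson moment oracle: mean count over 1000 seeded draws near the rate
  counts <- vapply(seq_len(1000), function(s) {
    nrow(sample_fibers(p, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(counts) - p$rate), 3 * sqrt(p$rate / 1000))
})

test_that("axial von Mises orientations concentrate with kappa", {
  set.seed(5)
  th_lo <- fibroscore:::rvonmises_axial(2000, 0, 0.3)
  th_hi <- fibroscore:::rvonmises_axial(2000, 0, 4)
  circvar <- function(th) 1 - Mod(mean(exp(2i * th)))
  expect_gt(circvar(th_lo), circvar(th_hi))
  expect_true(all(th_lo >= 0 & th_lo < pi))
})

test_that("rendering an empty field gives a uniform image with 100% porosity", {
  fib <- data.frame(x = numeric(0), y = numeric(0), theta = numeric(0),
                    length = numeric(0), width = numeric(0),
                    waviness = numeric(0), stain = character(0),
                    fragments = integer(0))
  r <- render_fibers(fib, pixel_size = 0.5, field = c(32, 32), noise_sd = 0)
  expect_true(all(r$image == 1))
  expect_equal(r$truth$summaries$porosity_pct, 100)
  expect_equal(r$truth$summaries$n_fibers, 0L)
})

test_that("a single mature fiber yields one connected component in its channel", {
  r <- single_fiber_image(40, 4, theta = 0.4)
  od <- rgb_to_od(r$image, I0 = 1)
  ch <- deconvolve_stains(od)
  expect_equal(oracle_components(ch$mature > 0.5), 1L)
  expect_equal(oracle_components(ch$immature > 0.5), 0L)
})

test_that("rendered stroke thickness matches the requested width", {
  # width 4 um at 0.5 um/px -> 8 +/- 1 px by distance transform
  r <- single_fiber_image(40, 4, theta = 0)
  mask <- deconvolve_stains(rgb_to_od(r$image, I0 = 1))$mature > 0.5
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
  expect_lt(abs(2 * max(dm) - 8), 1 + 1e-9)
})

test_that("simulation is bit-identical under a fixed (preset, seed, size)", {
  a <- simulate_image("degradation", seed = 3, field_px = c(96, 96))
  b <- simulate_image("degradation", seed = 3, field_px = c(96, 96))
  expect_identical(a$image, b$image)
  expect_identical(a$truth$fibers, b$truth$fibers)
  c <- simulate_image("degradation", seed = 4, field_px = c(96, 96))
  expect_false(identical(a$image, c$image))
})

test_that("ground-truth summaries are self-consistent with the fiber table", {
  sim <- simulate_image("control", seed = 8, field_px = c(128, 128))
  fib <- sim$truth$fibers
  s <- sim$truth$summaries
  expect_identical(s$n_fibers, nrow(fib))
  expect_equal(s$mean_length, mean(fib$length))
  expect_equal(s$mean_width, mean(fib$width))
  expect_equal(s$orientation_circvar, 1 - Mod(mean(exp(2i * fib$theta))))
  area <- fib$length * fib$width
  expect_equal(s$porosity_pct, 100 * max(0, 1 - sum(area) / (64 * 64)))
  expect_equal(s$mature_area_fraction,
               sum(area[fib$stain == "mature"]) / sum(area))
})

test_that("fibers outside the field are clipped without error", {
  fib <- data.frame(x = -30, y = 16, theta = 0, length = 20, width = 3,
                    waviness = 0, stain = "mature", fragments = 1L)
  r <- render_fibers(fib, pixel_size = 0.5, field = c(32, 32), noise_sd = 0)
  expect_true(all(r$image == 1))  # entirely outside: nothing drawn
})

test_that("fragmented fibers render as multiple pieces", {
  frag <- data.frame(x = 48, y = 48, theta = 0, length = 60, width = 3,
                     waviness = 0, stain = "mature", fragments = 3L)
  r <- single_fiber_image(60, 3)
  rf <- render_fibers(frag, pixel_size = 0.5, field = c(96, 96), noise_sd = 0)
  n1 <- oracle_components(deconvolve_stains(rgb_to_od(r$image, I0 = 1))$mature > 0.5)
  n3 <- oracle_components(deconvolve_stains(rgb_to_od(rf$image, I0 = 1))$mature > 0.5)
  expect_identical(n1, 1L)
  expect_identical(n3, 3L)
})
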