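#' Canonical fiber-morphology class presets
#'
#' Returns the generative parameters for one of the three extracellular-matrix
#' states emulated by the synthetic image generator: \code{"control"}
#' (homeostatic dermis: moderate fiber length and width, weak alignment),
#' \code{"deposition"} (fibrosis-like: longer, thicker fibers, strongly
#' aligned along the stretch axis, mature/red-stain dominant) and
#' \code{"degradation"} (aging-like: sparse, short, fragmented, disorganized
#' fibers with a higher immature/green fraction).
#'
#' Length and width are log-normal on the micrometre scale: \code{length_mu}
#' and \code{width_mu} are medians in um, \code{length_sdlog} and
#' \code{width_sdlog} are standard deviations on the log scale. Axial fiber
#' orientations follow a von Mises distribution on doubled angles with
#' concentration \code{kappa} about the stretch axis (the image x axis).
#' \code{rate} is the expected number of fibers per field, \code{p_mature}
#' the probability that a fiber carries the mature (red) stain,
#' \code{fragments_mean} the mean number of pieces each fiber is broken into,
#' \code{waviness_mean} the mean bend amplitude as a fraction of fiber length
#' and \code{noise_sd} the Gaussian background noise in optical-density units.
#'
#' @param name one of \code{"control"}, \code{"deposition"},
#'   \code{"degradation"}.
#' @return an object of class \code{"fiber_preset"}: a named list of
#'   generative parameters.
#' @examples
#' fiber_preset("control")
#' fiber_preset("deposition")$length_mu   # longer than control
#' @seealso [sample_fibers()], [simulate_image()], [gradient_preset()]
#' @export
fiber_preset <- function(name) {
  presets <- list(
    control = list(
      name = "control", rate = 60,
      length_mu = 40, length_sdlog = 0.4,
      width_mu = 3, width_sdlog = 0.2,
      kappa = 0.5, p_mature = 0.7,
      fragments_mean = 1, waviness_mean = 0.05,
      noise_sd = 0.02
    ),
    deposition = list(
      name = "deposition", rate = 90,
      length_mu = 80, length_sdlog = 0.4,
      width_mu = 5, width_sdlog = 0.2,
      kappa = 4, p_mature = 0.85,
      fragments_mean = 1, waviness_mean = 0.02,
      noise_sd = 0.02
    ),
    degradation = list(
      name = "degradation", rate = 50,
      length_mu = 15, length_sdlog = 0.4,
      width_mu = 2.5, width_sdlog = 0.2,
      kappa = 0.3, p_mature = 0.5,
      fragments_mean = 3, waviness_mean = 0.10,
      noise_sd = 0.02
    )
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets)) {
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid names are: ", paste(names(presets), collapse = ", "))
  }
  structure(presets[[name]], class = "fiber_preset")
}

#' @export
print.fiber_preset <- function(x, ...) {
  cat("Fiber preset '", x$name, "'\n", sep = "")
  num <- x[vapply(x, is.numeric, logical(1))]
  cat(paste0("  ", format(names(num), width = 14), " ",
             vapply(num, format, character(1))), sep = "\n")
  invisible(x)
}

# numeric generative parameters shared by all presets (interpolation axis)
.preset_numeric_fields <- c(
  "rate", "length_mu", "length_sdlog", "width_mu", "width_sdlog",
  "kappa", "p_mature", "fragments_mean", "waviness_mean", "noise_sd"
)

#' Interpolated preset along the control-to-deposition axis
#'
#' Linearly interpolates every numeric generative parameter between the
#' control preset (\code{t = 0}) and the deposition/fibrosis preset
#' (\code{t = 1}), giving a one-parameter family of morphologies spanning the
#' homeostatic-to-fibrotic score axis (0 to +1).
#'
#' @param t interpolation coordinate in \[0, 1\].
#' @return a \code{"fiber_preset"} with \code{name = "gradient"} and
#'   attribute \code{t}.
#' @examples
#' gradient_preset(0.5)$length_mu  # midpoint of 40 and 80
#' @export
gradient_preset <- function(t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > 1) {
    stop("t must be a single number in [0, 1]")
  }
  a <- fiber_preset("control")
  b <- fiber_preset("deposition")
  out <- a
  for (f in .preset_numeric_fields) out[[f]] <- (1 - t) * a[[f]] + t * b[[f]]
  out$name <- "gradient"
  attr(out, "t") <- t
  out
}

# von Mises sampler, Best & Fisher (1979) rejection scheme.
# Written here because no circular-statistics sampler ships with the
# declared dependencies; kappa = 0 falls back to the uniform circle.
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(ok)) {
      th <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
      take <- min(sum(ok), n - got)
      out[got + seq_len(take)] <- mu + th[seq_len(take)]
      got <- got + take
    }
  }
  out %% (2 * pi)
}

# axial orientations in [0, pi): von Mises on doubled angles about axis mu0
rvonmises_axial <- function(n, mu0 = 0, kappa = 1) {
  (rvonmises(n, 2 * mu0, kappa) / 2) %% pi
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Sample a random fiber population from a preset
#'
#' Draws a Poisson number of fibers (expectation \code{preset$rate} per
#' field) and, for each fiber, an anchor point uniform over the field, an
#' axial orientation (von Mises on doubled angles about the x axis), a
#' log-normal contour length and stroke width, a stain class
#' (mature/immature), a fragment count (\code{1 + Poisson}) and an
#' exponential waviness. The anchor is the midpoint of the fiber chord.
#'
#' @param preset a \code{"fiber_preset"} or a preset name.
#' @param field field size in um, \code{c(width, height)}.
#' @param seed optional integer; when given, sampling is reproducible and the
#'   caller's RNG state is left untouched.
#' @return a data.frame of class \code{"fiber_set"} with columns \code{x},
#'   \code{y} (um), \code{theta} (radians in \[0, pi)), \code{length},
#'   \code{width} (um), \code{waviness}, \code{stain}
#'   (\code{"mature"}/\code{"immature"}) and \code{fragments}; attributes
#'   \code{field}, \code{preset}, \code{seed}.
#' @examples
#' f <- sample_fibers("control", seed = 1)
#' nrow(f)
#' @export
sample_fibers <- function(preset, field = c(256, 256), seed = NULL) {
  if (is.character(preset)) preset <- fiber_preset(preset)
  stopifnot(is.numeric(field), length(field) == 2L, all(field > 0))
  fib <- with_seed(seed, {
    n <- stats::rpois(1L, preset$rate)
    data.frame(
      x = stats::runif(n, 0, field[1]),
      y = stats::runif(n, 0, field[2]),
      theta = rvonmises_axial(n, 0, preset$kappa),
      length = stats::rlnorm(n, log(preset$length_mu), preset$length_sdlog),
      width = stats::rlnorm(n, log(preset$width_mu), preset$width_sdlog),
      waviness = pmin(0.25, stats::rexp(n, 1 / max(preset$waviness_mean, 1e-9))),
      stain = ifelse(stats::runif(n) < preset$p_mature, "mature", "immature"),
      fragments = 1L + stats::rpois(n, max(preset$fragments_mean - 1, 0)),
      stringsAsFactors = FALSE
    )
  })
  structure(fib, field = field, preset = preset$name, seed = seed,
            class = c("fiber_set", "data.frame"))
}
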