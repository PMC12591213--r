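# Fiber rasterizer: anti-aliased constant-width strokes in optical-density
# space (peak OD 1, saturating where fibers overlap -- birefringence signal
# does not stack like absorbing dye), converted to RGB transmittance
# through the stain basis (Beer-Lambert), i.e. the inverse of the
# deconvolution model.

# centreline polyline of one fiber: chord along theta with one sinusoidal
# bend of amplitude waviness * length; rescaled so arc length == length
fiber_polyline <- function(x, y, theta, length, waviness, n_pts = 33L) {
  u <- c(cos(theta), sin(theta))
  v <- c(-sin(theta), cos(theta))
  amp <- waviness * length
  tt <- seq(0, 1, length.out = n_pts)
  L0 <- length
  for (i in 1:3) {
    px <- x + (tt - 0.5) * L0 * u[1] + amp * sin(pi * tt) * v[1]
    py <- y + (tt - 0.5) * L0 * u[2] + amp * sin(pi * tt) * v[2]
    arc <- sum(sqrt(diff(px)^2 + diff(py)^2))
    if (abs(arc - length) < 1e-9 * length) break
    L0 <- L0 * length / arc
  }
  cbind(x = px, y = py)
}

# parameter sub-intervals drawn for a fiber broken into k fragments:
# each k-th slot keeps its central 70%, leaving visible gaps
fragment_windows <- function(k) {
  if (k <= 1L) return(cbind(0, 1))
  j <- seq_len(k)
  cbind((j - 1 + 0.15) / k, (j - 0.15) / k)
}

# accumulate the anti-aliased coverage of one stroke into `od` (H x W,
# rows = y). Coverage ramps linearly over one pixel at the stroke border.
rasterize_stroke <- function(od, pts, width, pixel_size) {
  h <- nrow(od); w <- ncol(od)
  half <- width / 2
  margin <- half + 1.5 * pixel_size
  # fiber-local coverage on the stroke's bounding box
  c0 <- max(1L, floor((min(pts[, 1]) - margin) / pixel_size) + 1L)
  c1 <- min(w, ceiling((max(pts[, 1]) + margin) / pixel_size))
  r0 <- max(1L, floor((min(pts[, 2]) - margin) / pixel_size) + 1L)
  r1 <- min(h, ceiling((max(pts[, 2]) + margin) / pixel_size))
  if (c0 > c1 || r0 > r1) return(od)  # entirely outside the field: clipped
  nr <- r1 - r0 + 1L; nc <- c1 - c0 + 1L
  dmin <- matrix(Inf, nr, nc)
  xs <- (seq.int(c0, c1) - 0.5) * pixel_size
  ys <- (seq.int(r0, r1) - 0.5) * pixel_size
  for (s in seq_len(nrow(pts) - 1L)) {
    ax <- pts[s, 1]; ay <- pts[s, 2]
    bx <- pts[s + 1L, 1]; by <- pts[s + 1L, 2]
    sc0 <- max(1L, floor((min(ax, bx) - margin - (c0 - 1) * pixel_size) / pixel_size) + 1L)
    sc1 <- min(nc, ceiling((max(ax, bx) + margin - (c0 - 1) * pixel_size) / pixel_size))
    sr0 <- max(1L, floor((min(ay, by) - margin - (r0 - 1) * pixel_size) / pixel_size) + 1L)
    sr1 <- min(nr, ceiling((max(ay, by) + margin - (r0 - 1) * pixel_size) / pixel_size))
    if (sc0 > sc1 || sr0 > sr1) next
    px <- xs[sc0:sc1]; py <- ys[sr0:sr1]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    X <- matrix(px, length(py), length(px), byrow = TRUE)
    Y <- matrix(py, length(py), length(px))
    if (len2 < 1e-12) {
      d <- sqrt((X - ax)^2 + (Y - ay)^2)
    } else {
      tproj <- pmin(1, pmax(0, ((X - ax) * dx + (Y - ay) * dy) / len2))
      d <- sqrt((X - (ax + tproj * dx))^2 + (Y - (ay + tproj * dy))^2)
    }
    blk <- dmin[sr0:sr1, sc0:sc1, drop = FALSE]
    dmin[sr0:sr1, sc0:sc1] <- pmin(blk, d)
  }
  cov <- pmin(1, pmax(0, (half - dmin) / pixel_size + 0.5))
  od[r0:r1, c0:c1] <- pmax(od[r0:r1, c0:c1], cov)
  od
}

# analytic ground-truth summaries recomputed from the fiber table alone
truth_summaries <- function(fibers, field = attr(fibers, "field")) {
  n <- nrow(fibers)
  if (n == 0L) {
    return(list(n_fibers = 0L, mean_length = 0, mean_width = 0,
                orientation_circvar = 0, porosity_pct = 100,
                mature_area_fraction = 0))
  }
  area <- fibers$length * fibers$width
  rbar <- Mod(mean(exp(2i * fibers$theta)))
  list(
    n_fibers = n,
    mean_length = mean(fibers$length),
    mean_width = mean(fibers$width),
    orientation_circvar = 1 - rbar,
    # overlap-free approximation: covered area = sum(length x width)
    porosity_pct = 100 * max(0, 1 - sum(area) / prod(field)),
    mature_area_fraction = sum(area[fibers$stain == "mature"]) / sum(area)
  )
}

#' Render a fiber population into a synthetic birefringence-style RGB image
#'
#' Each fiber is drawn as an anti-aliased constant-width stroke (peak optical
#' density 1) into the OD plane of its stain class; fragmented fibers are
#' drawn with gaps. The two stain OD planes are mixed through the
#' (row-normalized) stain basis, Gaussian noise of standard deviation
#' \code{noise_sd} is added in OD space, and the result is converted to RGB
#' transmittance \code{I = 10^(-OD)} clipped to \[0, 1\]. Fibers extending
#' beyond the field are silently clipped at the border.
#'
#' @param fibers a \code{"fiber_set"} (see [sample_fibers()]) or data.frame
#'   with the same columns.
#' @param pixel_size pixel size in um/px.
#' @param field field size in um \code{c(width, height)}; defaults to the
#'   \code{field} attribute of \code{fibers}.
#' @param basis 3x3 stain absorbance basis, rows = (mature, immature,
#'   residual); see [psr_basis()].
#' @param noise_sd Gaussian OD noise standard deviation.
#' @param seed optional seed for the noise draw.
#' @return a list with elements \code{image} (H x W x 3 transmittance array
#'   in \[0, 1\], attributes \code{pixel_size}, \code{preset}, \code{seed})
#'   and \code{truth} (class \code{"fiber_truth"}: the fiber table plus
#'   analytic summaries).
#' @examples
#' f <- sample_fibers("control", field = c(64, 64), seed = 1)
#' img <- render_fibers(f, pixel_size = 0.5, noise_sd = 0)$image
#' range(img)
#' @export
render_fibers <- function(fibers, pixel_size = 0.5, field = NULL,
                          basis = psr_basis(), noise_sd = 0, seed = NULL) {
  stopifnot(pixel_size > 0)
  if (is.null(field)) field <- attr(fibers, "field")
  if (is.null(field)) stop("field size must be given when `fibers` carries no field attribute")
  w <- as.integer(round(field[1] / pixel_size))
  h <- as.integer(round(field[2] / pixel_size))
  od <- list(mature = matrix(0, h, w), immature = matrix(0, h, w))
  if (nrow(fibers) > 0) {
    for (i in seq_len(nrow(fibers))) {
      pts <- fiber_polyline(fibers$x[i], fibers$y[i], fibers$theta[i],
                            fibers$length[i], fibers$waviness[i])
      win <- fragment_windows(fibers$fragments[i])
      tt <- seq(0, 1, length.out = nrow(pts))
      ch <- fibers$stain[i]
      for (j in seq_len(nrow(win))) {
        keep <- tt >= win[j, 1] & tt <= win[j, 2]
        if (sum(keep) < 2L) next
        od[[ch]] <- rasterize_stroke(od[[ch]], pts[keep, , drop = FALSE],
                                     fibers$width[i], pixel_size)
      }
    }
  }
  M <- normalize_basis(basis)
  od_rgb <- outer(od$mature, M[1, ]) + outer(od$immature, M[2, ])
  if (noise_sd > 0) {
    od_rgb <- od_rgb + with_seed(seed, array(stats::rnorm(length(od_rgb), 0, noise_sd),
                                             dim = dim(od_rgb)))
  }
  img <- array(pmin(1, pmax(0, 10^(-od_rgb))), dim = c(h, w, 3))
  attr(img, "pixel_size") <- pixel_size
  attr(img, "preset") <- attr(fibers, "preset")
  attr(img, "seed") <- seed
  truth <- structure(list(fibers = as.data.frame(fibers),
                          summaries = truth_summaries(fibers, field)),
                     class = "fiber_truth")
  list(image = img, truth = truth)
}

#' @export
print.fiber_truth <- function(x, ...) {
  s <- x$summaries
  cat("Ground truth:", s$n_fibers, "fibers | mean length",
      signif(s$mean_length, 4), "um | mean width", signif(s$mean_width, 4),
      "um | porosity", signif(s$porosity_pct, 4), "%\n")
  invisible(x)
}

#' Simulate one ground-truthed synthetic image from a preset
#'
#' Convenience wrapper chaining [sample_fibers()] and [render_fibers()]
#' under a single seed, so that identical \code{(preset, seed, field)} give
#' bit-identical images.
#'
#' @param preset preset name or \code{"fiber_preset"} object.
#' @param seed integer seed (optional but recommended).
#' @param pixel_size um per pixel.
#' @param field_px field size in pixels \code{c(width, height)}.
#' @param noise_sd OD noise; defaults to the preset's value.
#' @return as [render_fibers()]: \code{list(image, truth)}.
#' @examples
#' sim <- simulate_image("degradation", seed = 7, field_px = c(96, 96))
#' sim$truth
#' @export
simulate_image <- function(preset = "control", seed = NULL, pixel_size = 0.5,
                           field_px = c(512, 512), noise_sd = NULL) {
  if (is.character(preset)) preset <- fiber_preset(preset)
  if (is.null(noise_sd)) noise_sd <- preset$noise_sd
  field <- field_px * pixel_size
  with_seed(seed, {
    fib <- sample_fibers(preset, field = field, seed = NULL)
    render_fibers(fib, pixel_size = pixel_size, basis = psr_basis(),
                  noise_sd = noise_sd, seed = NULL)
  })
}

#' Simulate a batch of images along the control-to-deposition gradient
#'
#' Generates \code{n} seeded images from the interpolated preset
#' [gradient_preset()] at coordinate \code{t}.
#'
#' @param t gradient coordinate in \[0, 1\] (0 = control, 1 = deposition).
#' @param n number of images.
#' @param seed base seed; image i uses \code{seed + i - 1}.
#' @inheritParams simulate_image
#' @return list of \code{n} \code{list(image, truth)} elements.
#' @export
gradient_series <- function(t, n = 5, seed = 1, pixel_size = 0.5,
                            field_px = c(512, 512)) {
  preset <- gradient_preset(t)
  lapply(seq_len(n), function(i) {
    simulate_image(preset, seed = seed + i - 1L, pixel_size = pixel_size,
                   field_px = field_px)
  })
}
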