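# Independent reference implementations used as oracles. These are written
# naively (loops, recursion-free flood fill) on purpose: they must not share
# code paths with the package.

# sliding-window adaptive Wiener filter, recomputed pixel by pixel with
# reflected borders
oracle_wiener <- function(x, window = 3L) {
  half <- (window - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  reflect <- function(i, n) {
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  m <- matrix(0, nr, nc); v <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      rs <- reflect(r + (-half:half), nr)
      cs <- reflect(c + (-half:half), nc)
      w <- x[rs, cs]
      m[r, c] <- mean(w)
      v[r, c] <- mean(w^2) - mean(w)^2
    }
  }
  noise <- mean(v)
  out <- m + ifelse(v > 0, pmax(0, v - noise) / v, 0) * (x - m)
  out
}

# iterative flood fill (8- or 4-connectivity) component count
oracle_components <- function(mask, conn = 8L) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nlab <- 0L
  offs <- if (conn == 8L) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    nlab <- nlab + 1L
    queue <- start
    lab[start] <- nlab
    while (length(queue) > 0L) {
      p <- queue[1]; queue <- queue[-1]
      r <- ((p - 1L) %% nrow(mask)) + 1L
      c <- ((p - 1L) %/% nrow(mask)) + 1L
      for (o in offs) {
        rr <- r + o[1]; cc <- c + o[2]
        if (rr < 1L || rr > nrow(mask) || cc < 1L || cc > ncol(mask)) next
        q <- (cc - 1L) * nrow(mask) + rr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- nlab
          queue <- c(queue, q)
        }
      }
    }
  }
  nlab
}

# Euler number oracle: 8-connected components minus 4-connected interior
# holes, both by flood fill
oracle_euler <- function(mask) {
  comps <- oracle_components(mask, conn = 8L)
  # pad so the outer background is a single 4-connected component
  bg <- !rbind(FALSE, cbind(FALSE, mask, FALSE), FALSE)
  holes <- oracle_components(bg, conn = 4L) - 1L
  comps - holes
}

# one straight fiber rendered at a given geometry, zero noise
single_fiber_image <- function(length, width, theta = 0, field = c(96, 96),
                               pixel_size = 0.5, stain = "mature",
                               waviness = 0) {
  fib <- data.frame(x = field[1] / 2, y = field[2] / 2, theta = theta,
                    length = length, width = width, waviness = waviness,
                    stain = stain, fragments = 1L, stringsAsFactors = FALSE)
  render_fibers(fib, pixel_size = pixel_size, field = field, noise_sd = 0)
}

# feature matrix for n seeded images of one preset
preset_features <- function(preset, n, seed0, field_px = c(512, 512)) {
  t(vapply(seq_len(n), function(i) {
    extract_features(simulate_image(preset, seed = seed0 + i,
                                    field_px = field_px)$image)
  }, numeric(26)))
}
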