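# Color deconvolution (Ruifrok & Johnston style): per-pixel linear unmixing
# of the optical-density vector into stain contributions.

#' Picrosirius-red stain absorbance basis
#'
#' The published absorbance vectors used for birefringent picrosirius-red
#' images: mature (red) collagen = \code{[1 0 0]}, immature (green) collagen
#' = \code{[0 1 0]}, residual = \code{[1 1 1]}. Rows are unit-normalized
#' before inversion by [deconvolve_stains()].
#'
#' @return a 3x3 numeric matrix with rownames
#'   \code{c("mature", "immature", "residual")} and colnames
#'   \code{c("R", "G", "B")}.
#' @examples
#' psr_basis()
#' @export
psr_basis <- function() {
  m <- rbind(mature = c(1, 0, 0), immature = c(0, 1, 0), residual = c(1, 1, 1))
  colnames(m) <- c("R", "G", "B")
  m
}

# unit-normalize rows; error on degenerate (all-zero row or singular) bases
normalize_basis <- function(basis) {
  basis <- as.matrix(basis)
  if (!all(dim(basis) == c(3L, 3L)) || !is.numeric(basis)) {
    stop("stain basis must be a numeric 3x3 matrix")
  }
  nrm <- sqrt(rowSums(basis^2))
  if (any(nrm < 1e-12)) stop("degenerate stain basis: all-zero row")
  m <- basis / nrm
  if (rcond(m) < 1e-10) stop("degenerate stain basis: not invertible")
  if (is.null(rownames(m))) rownames(m) <- c("mature", "immature", "residual")
  m
}

#' Convert an RGB transmittance image to optical density
#'
#' Beer-Lambert preprocessing for color deconvolution:
#' \code{OD = -log10(I / I0)} per channel, where \code{I0} is the incident
#' (background) intensity. Intensities are floored at \code{I0 / 65536} so
#' zero-valued pixels stay finite; values above \code{I0} clamp to OD 0.
#'
#' @param image H x W x 3 array of transmittance values in \[0, 1\].
#' @param I0 background intensity, one value per channel (length 1 or 3).
#'   Default: the per-channel 99th percentile of the image, a robust
#'   white-point estimate.
#' @return H x W x 3 array of non-negative optical densities, with the
#'   \code{I0} used stored as an attribute.
#' @examples
#' img <- array(1, dim = c(4, 4, 3))
#' range(rgb_to_od(img, I0 = 1))  # blank field -> OD 0
#' @export
rgb_to_od <- function(image, I0 = NULL) {
  stopifnot(is.array(image), length(dim(image)) == 3L, dim(image)[3] == 3L)
  nbad <- sum(!is.finite(image))
  if (nbad > 0) stop("image contains ", nbad, " non-finite pixel values")
  if (is.null(I0)) {
    I0 <- apply(image, 3, stats::quantile, probs = 0.99, names = FALSE)
    I0[I0 <= 0] <- 1
  }
  if (length(I0) == 1L) I0 <- rep(I0, 3L)
  stopifnot(length(I0) == 3L, all(I0 > 0))
  od <- image
  for (k in 1:3) {
    I <- pmax(image[, , k], I0[k] / 65536)
    od[, , k] <- pmax(0, -log10(I / I0[k]))
  }
  attr(od, "I0") <- I0
  attr(od, "pixel_size") <- attr(image, "pixel_size")
  od
}

#' Unmix an optical-density image into per-stain channels
#'
#' Per-pixel linear deconvolution: with stain basis rows normalized to unit
#' length, the stain amounts at a pixel solve
#' \code{OD = amounts \%*\% basis}. Negative amounts (noise, colors outside
#' the stain gamut) are clipped to zero; the clipped mass is recorded.
#'
#' @param od H x W x 3 optical-density array (see [rgb_to_od()]).
#' @param basis 3x3 stain absorbance matrix, one stain per row; rows are
#'   unit-normalized internally. Default [psr_basis()].
#' @return an object of class \code{"stain_channels"}: a list with H x W
#'   matrices \code{mature}, \code{immature}, \code{residual}, the normalized
#'   \code{basis}, and \code{clipped_mass} (total negative amount clipped).
#' @examples
#' od <- array(0, dim = c(2, 2, 3)); od[1, 1, ] <- c(1, 0, 0)
#' ch <- deconvolve_stains(od)
#' ch$mature[1, 1]  # pure mature-stain pixel -> amount 1
#' @export
deconvolve_stains <- function(od, basis = psr_basis()) {
  stopifnot(is.array(od), length(dim(od)) == 3L, dim(od)[3] == 3L)
  M <- normalize_basis(basis)
  d <- dim(od)
  flat <- matrix(od, nrow = d[1] * d[2], ncol = 3L)
  amounts <- flat %*% solve(M)
  clipped <- -sum(amounts[amounts < 0])
  amounts[amounts < 0] <- 0
  out <- list(
    mature = matrix(amounts[, 1], d[1], d[2]),
    immature = matrix(amounts[, 2], d[1], d[2]),
    residual = matrix(amounts[, 3], d[1], d[2]),
    basis = M,
    I0 = attr(od, "I0"),
    clipped_mass = clipped
  )
  structure(out, class = "stain_channels",
            pixel_size = attr(od, "pixel_size"))
}

#' @export
print.stain_channels <- function(x, ...) {
  cat("Stain channels ", nrow(x$mature), "x", ncol(x$mature),
      " (mature / immature / residual), clipped OD mass ",
      signif(x$clipped_mass, 3), "\n", sep = "")
  invisible(x)
}
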