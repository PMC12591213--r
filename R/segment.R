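# Binarization and morphological selection of fiber-shaped objects.

#' Binarize a stain channel
#'
#' Thresholds the channel at a fixed fraction of its maximum (the default
#' global-threshold binarization), or by Otsu's method on the normalized
#' channel. An all-zero channel yields an empty mask.
#'
#' @param x numeric matrix, finite and non-negative.
#' @param threshold fraction of the channel maximum in (0, 1); ignored for
#'   \code{method = "otsu"}.
#' @param method \code{"fixed"} (default) or \code{"otsu"}.
#' @return logical matrix of the same dimensions.
#' @examples
#' binarize_channel(matrix(c(0.2, 0.8), 2, 2) * 5, threshold = 0.5)
#' @export
binarize_channel <- function(x, threshold = 0.5, method = c("fixed", "otsu")) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (any(!is.finite(x)) || any(x < 0)) stop("channel must be finite and non-negative")
  method <- match.arg(method)
  mx <- max(x)
  if (mx == 0) return(matrix(FALSE, nrow(x), ncol(x)))
  norm <- x / mx
  if (method == "otsu") {
    threshold <- EBImage::otsu(EBImage::Image(norm))
  } else if (!is.numeric(threshold) || length(threshold) != 1L ||
             threshold <= 0 || threshold >= 1) {
    stop("threshold must be a single value in (0, 1)")
  }
  norm > threshold
}

# linear structuring element of odd length at 0/45/90/135 degrees
# (built directly: not all angles of the EBImage line brush are usable)
line_brush <- function(len, angle) {
  k <- switch(as.character(angle),
    "0"   = matrix(1, 1, len),
    "90"  = matrix(1, len, 1),
    "45"  = diag(len)[, len:1, drop = FALSE],
    "135" = diag(len),
    stop("unsupported line angle: ", angle)
  )
  storage.mode(k) <- "integer"
  k
}

#' Morphological selection of fiber-shaped objects
#'
#' Keeps elongated structures and drops specks: the union over four
#' orientations (0, 45, 90, 135 degrees) of morphological opening with a
#' linear structuring element, followed by a single closing with a
#' diamond-shaped element to bridge small gaps. Objects smaller than every
#' structuring element are removed.
#'
#' @param mask logical matrix.
#' @param line_length length of the linear structuring element in pixels
#'   (odd, >= 1).
#' @param diamond_radius radius of the diamond element in pixels (>= 1).
#' @return logical matrix; always a subset of the diamond-closing of the
#'   input.
#' @export
select_fibers <- function(mask, line_length = 5L, diamond_radius = 1L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  line_length <- as.integer(line_length)
  diamond_radius <- as.integer(diamond_radius)
  if (line_length < 1L || diamond_radius < 1L) stop("structuring element sizes must be >= 1")
  if (!any(mask)) return(mask)
  if (line_length %% 2L == 0L) line_length <- line_length + 1L
  img <- EBImage::Image(mask * 1)
  opened <- matrix(FALSE, nrow(mask), ncol(mask))
  for (ang in c(0, 45, 90, 135)) {
    k <- line_brush(line_length, ang)
    op <- EBImage::opening(img, k)
    opened <- opened | (EBImage::imageData(op) > 0.5)
  }
  dsize <- 2L * diamond_radius + 1L
  kd <- EBImage::makeBrush(dsize, shape = "diamond")
  closed <- EBImage::closing(EBImage::Image(opened * 1), kd)
  EBImage::imageData(closed) > 0.5
}
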