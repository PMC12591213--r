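# The 13-per-channel collagen ultrastructure parameters and the full
# 26-entry feature vector.

.channel_feature_names <- c(
  "Brightness", "NumberOfFibers", "FiberLength", "FiberWidth",
  "Persistence", "AngleRandomness", "Branchpoints", "EulerNumber",
  "Extent", "Perimeter", "Solidity", "Eccentricity", "EquivalentDiameter"
)

#' Canonical names of the 26 collagen ultrastructure parameters
#'
#' Thirteen parameters per stain channel, mature (red) channel first:
#' Brightness (mean OD over the mask), NumberOfFibers (skeleton connected
#' components), FiberLength (mean segment geodesic length, um), FiberWidth
#' (2 x mean distance-transform value along the skeleton, um), Persistence
#' (length-weighted mean segment straightness, chord/geodesic),
#' AngleRandomness (length-weighted circular variance of doubled axial
#' orientations), Branchpoints (merged junction count), EulerNumber
#' (components minus holes of the mask), and the area-weighted mean region
#' properties Extent, Perimeter (um), Solidity, Eccentricity,
#' EquivalentDiameter (um).
#'
#' @return character vector of length 26 in canonical order.
#' @examples
#' ecm_feature_names()
#' @export
ecm_feature_names <- function() {
  c(paste0(.channel_feature_names, "_mature"),
    paste0(.channel_feature_names, "_immature"))
}

# convex hull area of a pixel set, using the 4 corners of each pixel so that
# single-pixel and collinear components get their true covered area
convex_area_px <- function(r, c_) {
  pr <- c(r - 0.5, r - 0.5, r + 0.5, r + 0.5)
  pc <- c(c_ - 0.5, c_ + 0.5, c_ - 0.5, c_ + 0.5)
  h <- grDevices::chull(pc, pr)
  x <- pc[h]; y <- pr[h]
  n <- length(h)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# area-weighted mean region properties over 8-connected mask components
region_props <- function(mask, pixel_size) {
  labels <- label_components(mask, conn = 8L)
  nlab <- max(labels)
  if (nlab == 0L) {
    return(c(Extent = 0, Perimeter = 0, Solidity = 0, Eccentricity = 0,
             EquivalentDiameter = 0))
  }
  per_px <- EBImage::computeFeatures.shape(labels)[, "s.perimeter"]
  idx <- which(mask)
  nr <- nrow(mask)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  lab <- labels[idx]
  props <- vapply(seq_len(nlab), function(l) {
    sel <- lab == l
    r <- rows[sel]; c_ <- cols[sel]
    a <- length(r)
    extent <- a / ((max(r) - min(r) + 1) * (max(c_) - min(c_) + 1))
    solidity <- min(1, a / max(convex_area_px(r, c_), a))
    # eccentricity from central second moments
    mu20 <- stats::var(c_) * (a - 1) / a
    mu02 <- stats::var(r) * (a - 1) / a
    if (a == 1L) { mu20 <- 0; mu02 <- 0; mu11 <- 0 } else {
      mu11 <- stats::cov(c_, r) * (a - 1) / a
    }
    common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
    l1 <- (mu20 + mu02 + common) / 2
    l2 <- (mu20 + mu02 - common) / 2
    ecc <- if (l1 > 0) sqrt(pmax(0, 1 - l2 / l1)) else 0
    eqd <- sqrt(4 * a / pi) * pixel_size
    c(a, extent, solidity, ecc, eqd)
  }, numeric(5))
  areas <- props[1, ]
  w <- areas / sum(areas)
  c(Extent = sum(w * props[2, ]),
    Perimeter = sum(w * per_px * pixel_size),
    Solidity = sum(w * props[3, ]),
    Eccentricity = sum(w * props[4, ]),
    EquivalentDiameter = sum(w * props[5, ]))
}

#' Compute the 13 ultrastructure parameters of one stain channel
#'
#' See [ecm_feature_names()] for the definitions. An empty mask returns all
#' zeros by convention.
#'
#' @param graph a \code{"skeleton_graph"} from [skeletonize_network()].
#' @param mask the binary fiber mask the graph was derived from.
#' @param channel the optical-density channel (same dimensions).
#' @param pixel_size um per pixel.
#' @return named numeric vector of length 13.
#' @export
channel_features <- function(graph, mask, channel, pixel_size = graph$pixel_size) {
  stopifnot(all(dim(mask) == graph$dim), all(dim(channel) == dim(mask)))
  out <- stats::setNames(numeric(13L), .channel_feature_names)
  if (!any(mask)) return(out)
  out["Brightness"] <- mean(channel[mask])
  n_comp <- max(label_components(graph$skeleton, conn = 8L))
  out["NumberOfFibers"] <- n_comp
  seg <- graph$segments
  if (nrow(seg) > 0L) {
    # mean skeleton length per connected fiber structure: the companion of
    # NumberOfFibers (= components); raw inter-junction segment means would
    # measure crossing spacing, not fiber length, once the network is dense
    out["FiberLength"] <- sum(seg$geodesic_um) / n_comp
    w <- seg$geodesic_um
    pos <- w > 0
    if (any(pos)) {
      out["Persistence"] <- sum(w[pos] * (seg$chord_um[pos] / seg$geodesic_um[pos])) / sum(w[pos])
      z <- sum(w[pos] * exp(2i * seg$orientation[pos])) / sum(w[pos])
      out["AngleRandomness"] <- 1 - Mod(z)
    }
  }
  dist <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
  skpx <- which(graph$skeleton)
  if (length(skpx) > 0L) out["FiberWidth"] <- 2 * mean(dist[skpx]) * pixel_size
  out["Branchpoints"] <- count_branchpoints(graph)
  out["EulerNumber"] <- euler_number(mask)
  rp <- region_props(mask, pixel_size)
  out[names(rp)] <- rp
  out
}

# default processing configuration for the channel pipeline
default_config <- function() {
  list(threshold = 0.5, binarize_method = "fixed", wiener_window = 3L,
       line_length = 5L, diamond_radius = 1L, basis = psr_basis(), I0 = NULL)
}

# run one OD channel through denoise -> binarize -> select -> skeletonize
process_channel <- function(channel, pixel_size, config = default_config()) {
  den <- wiener_denoise(channel, config$wiener_window)
  den <- pmax(den, 0)  # integral-image roundoff can leave ~ -1e-16
  mask <- binarize_channel(den, threshold = config$threshold,
                           method = config$binarize_method)
  mask <- select_fibers(mask, config$line_length, config$diamond_radius)
  graph <- skeletonize_network(mask, pixel_size)
  list(channel = den, mask = mask, graph = graph)
}

#' Extract the 26-entry collagen ultrastructure feature vector
#'
#' The full morphometry pipeline on an RGB image: optical-density conversion,
#' stain deconvolution, then per stain channel adaptive Wiener denoising,
#' binarization at a fraction of the channel maximum, morphological fiber
#' selection, skeletonization and parameter measurement. The mature-channel
#' parameters come first, then the immature-channel parameters, in the order
#' of [ecm_feature_names()].
#'
#' @param image H x W x 3 RGB transmittance array in \[0, 1\] (e.g. from
#'   [simulate_image()] or [read_rgb_image()]).
#' @param pixel_size um per pixel; defaults to the image's
#'   \code{pixel_size} attribute, else 0.5.
#' @param config named list overriding entries of the default configuration:
#'   \code{threshold} (0.5), \code{binarize_method} ("fixed"),
#'   \code{wiener_window} (3), \code{line_length} (5),
#'   \code{diamond_radius} (1), \code{basis} ([psr_basis()]), \code{I0}.
#' @param intermediates if TRUE, attach the per-channel masks and skeleton
#'   graphs as an attribute.
#' @return named numeric vector of length 26.
#' @examples
#' sim <- simulate_image("control", seed = 1, field_px = c(96, 96))
#' v <- extract_features(sim$image)
#' length(v)
#' @export
extract_features <- function(image, pixel_size = NULL, config = list(),
                             intermediates = FALSE) {
  if (is.null(pixel_size)) pixel_size <- attr(image, "pixel_size") %||% 0.5
  cfg <- utils::modifyList(default_config(), config)
  od <- rgb_to_od(image, I0 = cfg$I0)
  ch <- deconvolve_stains(od, basis = cfg$basis)
  pm <- process_channel(ch$mature, pixel_size, cfg)
  pi_ <- process_channel(ch$immature, pixel_size, cfg)
  fm <- channel_features(pm$graph, pm$mask, pm$channel, pixel_size)
  fi <- channel_features(pi_$graph, pi_$mask, pi_$channel, pixel_size)
  out <- stats::setNames(c(fm, fi), ecm_feature_names())
  if (intermediates) attr(out, "intermediates") <- list(mature = pm, immature = pi_)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simplified clinical morphometry: mean fiber length and porosity
#'
#' The reduced human-sample workflow: both stain masks are merged, porosity
#' is the percentage of non-fiber pixels, and mean fiber length is the mean
#' geodesic length of the merged network's skeleton segments, calibrated to
#' micrometres.
#'
#' @inheritParams extract_features
#' @return named numeric vector: \code{fiber_length_um}, \code{porosity_pct}.
#' @examples
#' sim <- simulate_image("control", seed = 1, field_px = c(96, 96))
#' fiber_metrics(sim$image)
#' @export
fiber_metrics <- function(image, pixel_size = NULL, config = list()) {
  if (is.null(pixel_size)) pixel_size <- attr(image, "pixel_size") %||% 0.5
  cfg <- utils::modifyList(default_config(), config)
  od <- rgb_to_od(image, I0 = cfg$I0)
  ch <- deconvolve_stains(od, basis = cfg$basis)
  pm <- process_channel(ch$mature, pixel_size, cfg)
  pi_ <- process_channel(ch$immature, pixel_size, cfg)
  mask <- pm$mask | pi_$mask
  graph <- skeletonize_network(mask, pixel_size)
  len <- if (nrow(graph$segments) > 0L) mean(graph$segments$geodesic_um) else 0
  c(fiber_length_um = len, porosity_pct = 100 * mean(!mask))
}
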