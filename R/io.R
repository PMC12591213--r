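# Readers and writers: RGB images (PNG/TIFF), feature and score CSVs,
# model JSON.

#' Read an 8- or 16-bit RGB image
#'
#' Reads a PNG or TIFF file and returns an H x W x 3 array normalized to
#' \[0, 1\]; an alpha channel, if present, is discarded. Grayscale images
#' are rejected (the deconvolution pipeline requires RGB).
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return numeric array H x W x 3 with attribute \code{bit_depth}.
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    bits <- attr(img, "bit.depth") %||% 8L
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(img, "bits.per.sample") %||% 8L
  } else {
    stop("unsupported format '", ext, "': expected png, tif or tiff")
  }
  if (length(dim(img)) != 3L || dim(img)[3] < 3L) {
    stop("RGB required: '", path, "' is not a 3-channel image")
  }
  img <- img[, , 1:3, drop = FALSE]
  attr(img, "bit_depth") <- as.integer(bits)
  img
}

#' Write an RGB transmittance array to a TIFF or PNG file
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param path output path (.tif/.tiff/.png).
#' @param bits bits per sample (8 or 16).
#' @return the path, invisibly.
#' @export
write_rgb_image <- function(image, path, bits = 8L) {
  stopifnot(is.array(image), length(dim(image)) == 3L)
  img <- pmin(1, pmax(0, image))
  attributes(img) <- list(dim = dim(image))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits))
  } else {
    stop("unsupported format '", ext, "'")
  }
  invisible(path)
}

#' Write / read a feature table as CSV
#'
#' The CSV has an \code{id} column, an optional \code{group} column, then
#' the 26 canonical feature columns in order.
#'
#' @param x matrix or data.frame of feature vectors with canonical column
#'   names; row names (or an \code{id} column) become the id.
#' @param path output CSV path.
#' @param group optional character vector of group labels.
#' @return \code{write_features}: the path, invisibly.
#'   \code{read_features}: a data.frame with \code{id} (and \code{group} if
#'   present) plus the 26 feature columns.
#' @export
write_features <- function(x, path, group = NULL) {
  x <- as.data.frame(as.matrix(x))
  missing <- setdiff(ecm_feature_names(), names(x))
  if (length(missing) > 0L) {
    stop("feature table is missing column(s): ", paste(missing, collapse = ", "))
  }
  out <- data.frame(id = rownames(x) %||% as.character(seq_len(nrow(x))),
                    stringsAsFactors = FALSE)
  if (nrow(x) > 0L && is.null(rownames(x))) out$id <- as.character(seq_len(nrow(x)))
  if (!is.null(group)) out$group <- as.character(group)
  out <- cbind(out, x[, ecm_feature_names(), drop = FALSE])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(ecm_feature_names(), names(df))
  if (length(missing) > 0L) {
    stop("feature CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Write turnover scores as CSV
#'
#' @param scores numeric vector of scores.
#' @param path output CSV path.
#' @param id sample ids (default sequence).
#' @param group optional group labels.
#' @return the path, invisibly.
#' @export
write_scores <- function(scores, path, id = NULL, group = NULL) {
  out <- data.frame(id = id %||% as.character(seq_along(scores)),
                    score = as.numeric(scores), stringsAsFactors = FALSE)
  if (!is.null(group)) out$group <- as.character(group)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a fitted turnover model as JSON
#'
#' Full-precision JSON round trip: a restored model reproduces scores
#' bit-identically.
#'
#' @param model an \code{"ecm_turnover"} model.
#' @param path JSON file path.
#' @return \code{write_model}: the path, invisibly. \code{read_model}: the
#'   restored \code{"ecm_turnover"} model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ecm_turnover"))
  payload <- list(
    class = "ecm_turnover",
    anchors = as.list(model$anchors),
    scaler = list(center = as.list(model$scaler$center),
                  scale = as.list(model$scaler$scale),
                  dropped = model$scaler$dropped),
    selected = model$selected,
    coefficients = as.list(model$coefficients),
    fitted = model$fitted,
    group = model$group,
    scores = model$scores,
    lambda = model$lambda,
    nfolds = model$nfolds,
    seed = model$seed,
    rule = model$rule
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$class, "ecm_turnover")) stop("not a serialized ecm_turnover model")
  structure(list(
    scaler = list(center = unlist(p$scaler$center),
                  scale = unlist(p$scaler$scale),
                  dropped = as.character(unlist(p$scaler$dropped))),
    selected = as.character(unlist(p$selected)),
    coefficients = unlist(p$coefficients),
    fitted = as.numeric(p$fitted),
    group = as.character(p$group),
    scores = as.numeric(p$scores),
    anchors = unlist(p$anchors),
    lambda = p$lambda, nfolds = p$nfolds, seed = p$seed, rule = p$rule,
    call = NULL
  ), class = "ecm_turnover")
}

#' Write a decoupling report as JSON
#'
#' @param x an \code{"expansion_index"} object.
#' @param path JSON file path.
#' @return the path, invisibly.
#' @export
write_decoupling_report <- function(x, path) {
  stopifnot(inherits(x, "expansion_index"))
  payload <- list(
    ref_day = x$ref_day, delta = x$delta,
    decoupling_day = if (is.na(x$decoupling_day)) NULL else x$decoupling_day,
    series = x$series
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns", null = "null")
  invisible(path)
}
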