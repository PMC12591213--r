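# The ECM turnover scoring model: cross-validated LASSO feature selection
# on the 26 ultrastructure parameters, followed by an anchored ordinary
# least-squares score calibrated so that the non-stretched control group
# maps to 0 and the fibrosis group (the deposition gold standard) to 1.
# Scores below 0 read as net collagen degradation.

#' Standardize a feature matrix against a calibration subset
#'
#' Columns are z-scored with the mean and standard deviation of the
#' reference (calibration) rows only, so that scoring held-out groups does
#' not leak their statistics into the scale. Columns with zero variance on
#' the reference rows are dropped with a warning and recorded.
#'
#' @param x numeric matrix or data.frame (samples x features).
#' @param reference integer or logical index of the calibration rows;
#'   default all rows.
#' @return list with \code{scaled} (matrix over all rows, dropped columns
#'   removed) and \code{scaler} (list: center, scale, dropped).
#' @export
standardize_features <- function(x, reference = seq_len(nrow(x))) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  ref <- x[reference, , drop = FALSE]
  if (nrow(ref) == 0L) stop("calibration subset is empty")
  center <- colMeans(ref)
  scale <- apply(ref, 2, stats::sd)
  if (nrow(ref) == 1L) scale[] <- 0
  dropped <- colnames(x)[scale == 0 | !is.finite(scale)]
  if (length(dropped) == ncol(x)) stop("all columns have zero variance on the calibration rows")
  if (length(dropped) > 0L) {
    warning("dropping zero-variance column(s): ", paste(dropped, collapse = ", "))
  }
  keep <- setdiff(colnames(x), dropped)
  scaled <- sweep(sweep(x[, keep, drop = FALSE], 2, center[keep]),
                  2, scale[keep], "/")
  list(scaled = scaled,
       scaler = list(center = center[keep], scale = scale[keep],
                     dropped = dropped))
}

#' LASSO feature selection with seeded k-fold cross-validation
#'
#' Runs \code{glmnet::cv.glmnet} (squared-error loss) over a log-spaced
#' lambda grid of 100 values from the largest gradient
#' \code{max(abs(crossprod(X, y))) / n} down four decades, with seeded fold
#' assignment, and keeps the features with
#' nonzero coefficients at the one-standard-error lambda (or the CV-minimum
#' lambda if \code{rule = "min"}).
#'
#' @param x standardized numeric matrix (samples x features).
#' @param y numeric 0/1 anchor labels, one per row of \code{x}.
#' @param nfolds number of CV folds (default 10).
#' @param seed optional seed for the fold assignment.
#' @param rule \code{"1se"} (default) or \code{"min"}.
#' @return list with \code{selected} (character vector, possibly empty),
#'   \code{lambda} (chosen value), \code{lambda_grid}, \code{cv} (the
#'   \code{cv.glmnet} object), \code{nfolds}, \code{seed}, \code{rule}.
#' @export
lasso_select <- function(x, y, nfolds = 10L, seed = NULL, rule = c("1se", "min")) {
  x <- as.matrix(x)
  rule <- match.arg(rule)
  if (length(unique(y)) < 2L) stop("labels must contain both classes (0 and 1)")
  n <- nrow(x)
  if (n < nfolds) stop("n (", n, ") < folds (", nfolds, "); use a smaller k")
  lambda_max <- max(abs(crossprod(x, y - mean(y)))) / n
  grid <- exp(seq(log(lambda_max), log(lambda_max * 1e-4), length.out = 100L))
  foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), n)))
  cv <- glmnet::cv.glmnet(x, y, family = "gaussian", lambda = grid,
                          foldid = foldid, standardize = FALSE)
  lambda <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
  beta <- as.matrix(stats::coef(cv, s = lambda))[-1, 1]
  selected <- names(beta)[beta != 0]
  if (length(selected) == 0L) {
    warning("LASSO selected no features at the chosen lambda; model will be intercept-only")
  }
  list(selected = selected, lambda = lambda, lambda_grid = grid, cv = cv,
       nfolds = nfolds, seed = seed, rule = rule)
}

#' Anchored linear scoring model on selected features
#'
#' Ordinary least squares of the 0/1 anchor labels on the selected
#' (standardized) features plus an intercept. Collinear columns are dropped
#' and the model refit. Used by [ecm_turnover()]; exposed for direct use.
#'
#' @param x standardized feature matrix of the calibration samples.
#' @param y 0/1 anchor labels.
#' @param selected character vector of column names to use; empty gives an
#'   intercept-only model with a warning.
#' @return list with \code{coefficients} (named, first element
#'   \code{"(Intercept)"}), \code{fitted}, \code{selected} (after any
#'   collinearity drops).
#' @export
fit_turnover <- function(x, y, selected) {
  x <- as.matrix(x)
  if (length(selected) == 0L) {
    warning("empty selection: fitting an intercept-only model")
    co <- c("(Intercept)" = mean(y))
    return(list(coefficients = co, fitted = rep(mean(y), length(y)),
                selected = character(0)))
  }
  xs <- x[, selected, drop = FALSE]
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, xs), y)
  co <- fit$coefficients
  if (anyNA(co)) {
    keep <- setdiff(names(co)[!is.na(co)], "(Intercept)")
    message("dropping collinear column(s): ",
            paste(setdiff(selected, keep), collapse = ", "))
    return(fit_turnover(x, y, keep))
  }
  list(coefficients = co, fitted = as.numeric(cbind(1, xs) %*% co),
       selected = selected)
}

#' Fit the anchored ECM turnover scoring model
#'
#' The headline fitting function. Calibration uses only the two anchor
#' groups: samples in \code{control} receive label 0 (homeostatic) and
#' samples in \code{fibrosis} label 1 (pathological deposition); all other
#' groups are scored but never fitted. Features are standardized on the
#' calibration rows, informative parameters are selected by seeded
#' cross-validated LASSO, and an ordinary least-squares model on the
#' selected features yields the score. Scores near 0 indicate homeostatic
#' collagen morphology, near +1 fibrotic deposition, and negative values
#' net degradation.
#'
#' @param x numeric matrix or data.frame of feature vectors (samples x 26,
#'   columns named as [ecm_feature_names()]).
#' @param group character (or factor) group label per row.
#' @param control,fibrosis the two anchor group labels.
#' @param nfolds CV folds for the LASSO (default 10).
#' @param seed seed for the CV fold assignment.
#' @param rule lambda rule, \code{"1se"} (default) or \code{"min"}.
#' @return object of class \code{"ecm_turnover"}: list with \code{scaler},
#'   \code{selected}, \code{coefficients}, \code{fitted} (calibration
#'   samples), \code{scores} (all samples), \code{group}, \code{lambda},
#'   \code{lambda_grid}, \code{nfolds}, \code{seed}, \code{rule},
#'   \code{anchors}, \code{call}.
#' @seealso [predict.ecm_turnover()], [write_model()]
#' @examples
#' \donttest{
#' feats <- rbind(
#'   t(sapply(1:8, function(i)
#'     extract_features(simulate_image("control", seed = i,
#'                                     field_px = c(128, 128))$image))),
#'   t(sapply(1:8, function(i)
#'     extract_features(simulate_image("deposition", seed = 100 + i,
#'                                     field_px = c(128, 128))$image))))
#' grp <- rep(c("control", "fibrosis"), each = 8)
#' fit <- ecm_turnover(feats, grp, nfolds = 4, seed = 1)
#' summary(fit)
#' }
#' @export
ecm_turnover <- function(x, group, control = "control", fibrosis = "fibrosis",
                         nfolds = 10L, seed = NULL, rule = c("1se", "min")) {
  rule <- match.arg(rule)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- ecm_feature_names()[seq_len(ncol(x))]
  group <- as.character(group)
  stopifnot(length(group) == nrow(x))
  calib <- group %in% c(control, fibrosis)
  if (!any(group == control) || !any(group == fibrosis)) {
    stop("both anchor groups ('", control, "', '", fibrosis, "') must be present")
  }
  y <- as.numeric(group[calib] == fibrosis)
  std <- standardize_features(x, reference = which(calib))
  sel <- lasso_select(std$scaled[calib, , drop = FALSE], y,
                      nfolds = nfolds, seed = seed, rule = rule)
  fit <- fit_turnover(std$scaled[calib, , drop = FALSE], y, sel$selected)
  obj <- structure(list(
    scaler = std$scaler,
    selected = fit$selected,
    coefficients = fit$coefficients,
    fitted = fit$fitted,
    group = group,
    anchors = c(control = control, fibrosis = fibrosis),
    lambda = sel$lambda, lambda_grid = sel$lambda_grid,
    nfolds = nfolds, seed = seed, rule = rule,
    call = match.call()
  ), class = "ecm_turnover")
  obj$scores <- predict(obj, x)
  obj
}

#' Score feature vectors with a fitted turnover model
#'
#' @param object an \code{"ecm_turnover"} model.
#' @param newdata named numeric vector (one sample) or matrix/data.frame
#'   with named columns; must contain every selected feature.
#' @param ... unused.
#' @return numeric vector of scores (unbounded; 0 = homeostatic anchor,
#'   1 = fibrosis anchor, negative = net degradation).
#' @export
predict.ecm_turnover <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  newdata <- as.matrix(newdata)
  sel <- object$selected
  if (length(sel) == 0L) {
    return(rep(unname(object$coefficients["(Intercept)"]), nrow(newdata)))
  }
  missing <- setdiff(sel, colnames(newdata))
  if (length(missing) > 0L) {
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  }
  z <- sweep(sweep(newdata[, sel, drop = FALSE], 2, object$scaler$center[sel]),
             2, object$scaler$scale[sel], "/")
  as.numeric(object$coefficients["(Intercept)"] + z %*% object$coefficients[sel])
}

#' @export
print.ecm_turnover <- function(x, ...) {
  cat("ECM turnover scoring model\n")
  cat("  anchors: ", x$anchors["control"], " = 0, ", x$anchors["fibrosis"],
      " = 1\n", sep = "")
  cat("  selected features (", length(x$selected), " of ",
      length(x$scaler$center), "): ",
      paste(x$selected, collapse = ", "), "\n", sep = "")
  cat("  lambda = ", signif(x$lambda, 4), " (", x$rule, " rule, ",
      x$nfolds, "-fold CV)\n", sep = "")
  invisible(x)
}

#' @export
summary.ecm_turnover <- function(object, ...) {
  by_group <- tapply(object$scores, object$group, mean)
  out <- list(model = object, group_means = by_group,
              coefficients = object$coefficients)
  class(out) <- "summary.ecm_turnover"
  out
}

#' @export
print.summary.ecm_turnover <- function(x, ...) {
  print(x$model)
  cat("  coefficients:\n")
  print(signif(x$coefficients, 4))
  cat("  mean score by group:\n")
  print(signif(x$group_means, 4))
  invisible(x)
}

#' @export
coef.ecm_turnover <- function(object, ...) object$coefficients

#' @export
fitted.ecm_turnover <- function(object, ...) object$fitted

#' @export
residuals.ecm_turnover <- function(object, ...) {
  calib <- object$group %in% object$anchors
  y <- as.numeric(object$group[calib] == object$anchors["fibrosis"])
  y - object$fitted
}

#' Strip chart of scores by group for a fitted turnover model
#' @param x an \code{"ecm_turnover"} model.
#' @param ... passed to \code{stripchart}.
#' @export
plot.ecm_turnover <- function(x, ...) {
  grp <- factor(x$group)
  graphics::stripchart(split(x$scores, grp), vertical = TRUE, pch = 16,
                       method = "jitter", ylab = "ECM turnover score", ...)
  graphics::abline(h = c(0, 1), lty = 3, col = "grey40")
  means <- tapply(x$scores, grp, mean)
  graphics::points(seq_along(means), means, pch = 3, cex = 1.5, col = "red3")
  invisible(x)
}

#' UMAP embedding of a feature matrix
#'
#' Two-dimensional UMAP of (optionally standardized) feature vectors, the
#' quality-control view of group separation in ultrastructure space.
#'
#' @param x numeric matrix or data.frame (samples x features).
#' @param n_neighbors UMAP neighbor count (default 15).
#' @param min_dist UMAP minimum embedding distance (default 0.1).
#' @param seed seed; the embedding is deterministic for a fixed seed.
#' @param scale z-score columns first (zero-variance columns dropped).
#' @return n x 2 matrix of coordinates with attributes \code{n_neighbors},
#'   \code{min_dist}, \code{seed}.
#' @export
embed_features <- function(x, n_neighbors = 15L, min_dist = 0.1, seed = NULL,
                           scale = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < n_neighbors + 1L) {
    stop("need at least n_neighbors + 1 = ", n_neighbors + 1L, " samples, got ", nrow(x))
  }
  if (scale) x <- suppressWarnings(standardize_features(x))$scaled
  emb <- with_seed(seed, uwot::umap(x, n_neighbors = n_neighbors,
                                    min_dist = min_dist, n_threads = 1,
                                    n_sgd_threads = 0))
  dimnames(emb) <- list(rownames(x), c("UMAP1", "UMAP2"))
  attr(emb, "n_neighbors") <- n_neighbors
  attr(emb, "min_dist") <- min_dist
  attr(emb, "seed") <- seed
  emb
}
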