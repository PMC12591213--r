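# synthetic separable feature matrices (no images: model mechanics only)
toy_features <- function(n_per = 20, seed = 1, shift = 3) {
  set.seed(seed)
  p <- 26L
  x <- matrix(rnorm(2 * n_per * p), 2 * n_per, p,
              dimnames = list(NULL, ecm_feature_names()))
  grp <- rep(c("control", "fibrosis"), each = n_per)
  x[grp == "fibrosis", 1:3] <- x[grp == "fibrosis", 1:3] + shift
  list(x = x, group = grp)
}

test_that("standardization uses calibration statistics and drops constants", {
  d <- toy_features(15, seed = 2)
  ref <- 1:10
  out <- standardize_features(d$x, reference = ref)
  expect_equal(unname(colMeans(out$scaled[ref, ])), rep(0, 26),
               tolerance = 1e-9)
  expect_equal(unname(apply(out$scaled[ref, ], 2, sd)), rep(1, 26),
               tolerance = 1e-9)

  x2 <- d$x; x2[, 5] <- 7  # constant column
  expect_warning(out2 <- standardize_features(x2, reference = ref),
                 "zero-variance")
  expect_identical(out2$scaler$dropped, ecm_feature_names()[5])
  expect_false(ecm_feature_names()[5] %in% colnames(out2$scaled))

  x3 <- matrix(1, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(standardize_features(x3), "all columns")

  # a column equal to its own mean maps to zero
  x4 <- d$x; x4[ref, 2] <- mean(x4[ref, 2])
  expect_warning(out4 <- standardize_features(x4, reference = ref), "zero-variance")
  expect_false(ecm_feature_names()[2] %in% colnames(out4$scaled))
})

test_that("the LASSO path vanishes at lambda_max and meets OLS at lambda 0", {
  d <- toy_features(30, seed = 3)
  std <- standardize_features(d$x, reference = seq_len(nrow(d$x)))
  y <- as.numeric(d$group == "fibrosis")
  sel <- lasso_select(std$scaled, y, nfolds = 5, seed = 1)
  # largest grid value is max|X'(y - ybar)|/n: the whole path starts empty
  beta_top <- sel$cv$glmnet.fit$beta[, 1]
  expect_true(all(beta_top == 0))
  expect_true(all(sel$selected %in% ecm_feature_names()))

  # lambda = 0 equals the normal-equations solution
  xs <- std$scaled[, 1:5]
  fit0 <- glmnet::glmnet(xs, y, lambda = 0, thresh = 1e-14)
  xd <- cbind(1, xs)
  beta_ols <- solve(crossprod(xd), crossprod(xd, y))
  expect_lt(max(abs(as.numeric(coef(fit0)) - as.numeric(beta_ols))), 1e-6)
})

test_that("a planted informative feature is recovered", {
  set.seed(4)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 26), n, 26, dimnames = list(NULL, ecm_feature_names()))
  x[, 7] <- y + rnorm(n, 0, 0.1)
  std <- standardize_features(x)
  sel <- lasso_select(std$scaled, y, nfolds = 10, seed = 9)
  expect_true(ecm_feature_names()[7] %in% sel$selected)

  expect_error(lasso_select(std$scaled, rep(1, n)), "both classes")
  both <- c(1:3, 31:33)   # both classes present but n < folds
  expect_error(lasso_select(std$scaled[both, ], y[both], nfolds = 10),
               "smaller k")
})

test_that("the anchored linear fit matches the normal equations", {
  d <- toy_features(25, seed = 5)
  std <- standardize_features(d$x)
  y <- as.numeric(d$group == "fibrosis")
  sel_names <- ecm_feature_names()[1:4]
  fit <- fit_turnover(std$scaled, y, sel_names)
  xd <- cbind(1, std$scaled[, sel_names])
  beta <- solve(crossprod(xd), crossprod(xd, y))
  expect_equal(unname(fit$coefficients), as.numeric(beta), tolerance = 1e-9)
  # balanced labels: OLS with intercept -> mean fitted value 1/2
  expect_equal(mean(fit$fitted), 0.5, tolerance = 1e-9)

  # a perfectly predictive feature reproduces the labels
  x1 <- std$scaled
  x1[, 1] <- y
  fit1 <- fit_turnover(x1, y, ecm_feature_names()[1])
  expect_equal(fit1$fitted, y, tolerance = 1e-9)

  # collinear columns are dropped and the model refit
  x2 <- std$scaled
  x2[, 2] <- 2 * x2[, 1]
  expect_message(fit2 <- fit_turnover(x2, y, ecm_feature_names()[1:2]),
                 "collinear")
  expect_length(fit2$selected, 1L)

  expect_warning(fit3 <- fit_turnover(std$scaled, y, character(0)),
                 "intercept-only")
  expect_equal(unname(fit3$coefficients), mean(y))
})

test_that("the fitted scoring model anchors control at 0 and fibrosis at 1", {
  d <- toy_features(25, seed = 6)
  fit <- ecm_turnover(d$x, d$group, nfolds = 5, seed = 1)
  expect_s3_class(fit, "ecm_turnover")
  mc <- mean(fit$scores[d$group == "control"])
  mf <- mean(fit$scores[d$group == "fibrosis"])
  expect_lt(abs(mc - 0), 0.1)
  expect_lt(abs(mf - 1), 0.1)
  # scoring a stored calibration sample reproduces its fitted value
  expect_equal(predict(fit, d$x), fit$fitted, tolerance = 1e-9)
  expect_equal(fit$scores, fit$fitted, tolerance = 1e-9)
  # identical feature vectors give identical scores
  expect_identical(predict(fit, d$x[c(1, 1), ])[1],
                   predict(fit, d$x[c(1, 1), ])[2])
  # missing selected feature names are reported
  expect_error(predict(fit, d$x[, -match(fit$selected[1], colnames(d$x))]),
               fit$selected[1])
  # residuals/fitted accessors are consistent
  y <- as.numeric(d$group == "fibrosis")
  expect_equal(residuals(fit), y - fitted(fit))
})

test_that("model serialization round-trips scores bit-identically", {
  d <- toy_features(20, seed = 7)
  fit <- ecm_turnover(d$x, d$group, nfolds = 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_identical(predict(back, d$x), predict(fit, d$x))
  expect_identical(back$coefficients, fit$coefficients)
  expect_identical(back$selected, fit$selected)
})

test_that("UMAP embeddings have one row per sample and preserve structure", {
  d <- toy_features(30, seed = 8, shift = 6)
  emb <- embed_features(d$x, n_neighbors = 10, seed = 5)
  expect_identical(dim(emb), c(60L, 2L))
  expect_identical(emb, embed_features(d$x, n_neighbors = 10, seed = 5))
  expect_error(embed_features(d$x[1:5, ], n_neighbors = 15), "n_neighbors")

  # duplicated input rows embed to near-coincident points
  xdup <- rbind(d$x, d$x[1, , drop = FALSE])
  e2 <- embed_features(xdup, n_neighbors = 10, seed = 5)
  d_dup <- sqrt(sum((e2[61, ] - e2[1, ])^2))
  spread <- max(dist(e2))
  expect_lt(d_dup, 0.05 * spread)

  # three well-separated classes keep positive silhouette in 2-D
  set.seed(11)
  x3 <- rbind(matrix(rnorm(20 * 26, 0), 20),
              matrix(rnorm(20 * 26, 8), 20),
              matrix(rnorm(20 * 26, -8), 20))
  colnames(x3) <- ecm_feature_names()
  lab <- rep(1:3, each = 20)
  e3 <- embed_features(x3, n_neighbors = 10, seed = 6)
  sil <- cluster::silhouette(lab, dist(e3))
  expect_gt(mean(sil[, "sil_width"]), 0)
})
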