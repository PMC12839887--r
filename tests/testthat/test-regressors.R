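# The three regression back ends and their shared plumbing.

make_linear_table <- function(n = 120, seed = 21, noise = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * 13), n, 13)
  colnames(X) <- feature_names()
  beta <- seq(-1, 1, length.out = 13)
  y <- 5 + X %*% beta + rnorm(n, sd = noise)
  tab <- data.frame(X)
  tab$q1_mv <- as.numeric(y)
  tab$q2_mv <- as.numeric(2 * y - 3)
  tab$sigma_p <- NA_real_
  attr(tab, "beta") <- beta
  tab
}

test_that("metrics follow their definitions", {
  expect_equal(unname(metrics_regression(c(3, 4), c(3, 4))[1:3]), c(0, 0, 1))
  m <- metrics_regression(c(0, 0), c(3, 4))
  expect_equal(m[["rmse"]], sqrt(12.5))
  expect_equal(m[["mae"]], 3.5)
  obs <- c(1, 2, 3, 6)
  m0 <- metrics_regression(rep(mean(obs), 4), obs)
  expect_equal(m0[["r2"]], 0)
  expect_error(metrics_regression(c(1, 2), c(5, 5)), "zero target variance")
  expect_error(metrics_regression(NA_real_, NA_real_), "no unmasked")
})

test_that("standardization is an exact affine pair fitted on the train split", {
  tab <- make_linear_table(50)
  X <- as.matrix(tab[, feature_names()])
  std <- fit_standardizer(X, rows = 1:30)
  expect_equal(unstandardize(standardize(X, std), std), X,
               tolerance = 1e-12)
  expect_equal(colMeans(standardize(X, std)[1:30, ]), rep(0, 13),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("splits stratify by family and folds partition the rows", {
  fam <- rep(c("BQ", "NQ", "AQ", "misc"), times = c(40, 30, 20, 10))
  sp <- make_split(100, 0.2, fam, seed = 3)
  expect_equal(sort(c(sp$train, sp$validation)), 1:100)
  expect_equal(as.integer(table(fam[sp$validation])[c("BQ", "NQ")]),
               c(8L, 6L))
  folds <- make_folds(100, 5, fam, seed = 3)
  all_val <- sort(unlist(lapply(folds, `[[`, "validation")))
  expect_equal(all_val, 1:100)
})

test_that("ordinary least squares recovers exact and planted maps", {
  tab <- make_linear_table(100, noise = 0)
  fit <- ita_fit(tab, targets = c("q1_mv", "q2_mv"), method = "lr",
                 seed = 2)
  expect_s3_class(fit, "ita_fit_lr")
  expect_equal(unname(coef(fit)[-1, "q1_mv"]), attr(tab, "beta"),
               tolerance = 1e-8)
  expect_equal(fit$report$r2, rep(1, 4), tolerance = 1e-10)

  # planted noisy map: recovery within 3 standard errors (OLS theory)
  tabn <- make_linear_table(500, seed = 8, noise = 2)
  lmfit <- lm(reformulate(feature_names(), "q1_mv"), tabn)
  est <- summary(lmfit)$coefficients[-1, ]
  expect_lt(max(abs(est[, "Estimate"] - attr(tabn, "beta")) /
                  est[, "Std. Error"]), 3)

  # collinear design errors out naming the duplicated column
  bad <- tab
  bad$S_S <- bad$I_F
  expect_error(ita_fit(bad, targets = "q1_mv", method = "lr"),
               "collinear")
})

test_that("a target with no labels is dropped with a warning", {
  tab <- make_linear_table(60)
  expect_warning(fit <- ita_fit(tab, method = "lr", seed = 2),
                 "sigma_p")
  expect_identical(fit$targets, c("q1_mv", "q2_mv"))
})

test_that("zero-epoch MLP reports its de-standardized initialization", {
  tab <- make_linear_table(60)
  fit <- ita_fit(tab, targets = "q1_mv", method = "mlp", seed = 4,
                 epochs = 0)
  params0 <- itaml:::.with_seed(4, itaml:::.mlp_init(13, 6L, 1L))
  Xs <- standardize(as.matrix(tab[, feature_names()]), fit$xstd)
  manual <- unstandardize(itaml:::.mlp_forward(params0, Xs)$yhat, fit$ystd)
  expect_equal(unname(predict(fit)), unname(manual), tolerance = 1e-12)
})

test_that("masked rows contribute zero gradient to their head", {
  set.seed(9)
  X <- matrix(rnorm(20 * 4), 20, 4)
  Y <- cbind(rnorm(20), rnorm(20))
  M <- matrix(TRUE, 20, 2)
  M[1:10, 2] <- FALSE
  params <- itaml:::.mlp_init(4, 3L, 2L)
  fw <- itaml:::.mlp_forward(params, X)
  l <- itaml:::.masked_mse(fw$yhat, Y, M)
  expect_equal(l$dy[1:10, 2], rep(0, 10))
  # perturbing a masked label leaves the loss unchanged
  Y2 <- Y; Y2[3, 2] <- Y2[3, 2] + 100
  expect_equal(itaml:::.masked_mse(fw$yhat, Y2, M)$loss, l$loss)
})

test_that("MLP fits are bitwise reproducible for a fixed seed", {
  tab <- make_linear_table(80)
  f1 <- ita_fit(tab, targets = "q1_mv", method = "mlp", seed = 11,
                epochs = 50)
  f2 <- ita_fit(tab, targets = "q1_mv", method = "mlp", seed = 11,
                epochs = 50)
  expect_identical(f1$report, f2$report)
  expect_identical(predict(f1), predict(f2))
})

test_that("VQC fits are reproducible and reduce to an affine map at zero angles", {
  tab <- make_linear_table(40)
  f1 <- ita_fit(tab, targets = "q1_mv", method = "vqc", seed = 12,
                epochs = 3, n_qubits = 4L, encoder_hidden = 6L)
  f2 <- ita_fit(tab, targets = "q1_mv", method = "vqc", seed = 12,
                epochs = 3, n_qubits = 4L, encoder_hidden = 6L)
  expect_identical(f1$report, f2$report)

  # degenerate-circuit limit: with no entangling layer the readout is the
  # cosine of each embedding angle, so the model is an affine map of
  # cos-embedded encoder features; training then converges on a linear map
  fit0 <- ita_fit(tab, targets = "q1_mv", method = "vqc", seed = 12,
                  epochs = 0, n_qubits = 4L, encoder_hidden = 6L,
                  layers = 0L, warm_start_head = FALSE)
  Xs <- standardize(as.matrix(tab[, feature_names()]), fit0$xstd)
  fw <- itaml:::.vqc_forward(fit0$params, Xs)
  expect_equal(fw$Z, cos(t(fw$ANG)), tolerance = 1e-12)
  tab_big <- make_linear_table(150)
  fit_lin <- ita_fit(tab_big, targets = "q1_mv", method = "vqc", seed = 12,
                     epochs = 500, lr_rate = 0.05, n_qubits = 4L,
                     encoder_hidden = 6L, layers = 0L)
  expect_gt(fit_lin$report$r2[fit_lin$report$set == "validation"], 0.97)
})

test_that("the trained mean-model de-standardizes to the training mean", {
  tab <- make_linear_table(60)
  fit <- ita_fit(tab, targets = "q1_mv", method = "mlp", seed = 5,
                 epochs = 0)
  # zero out the network: predictions are the standardized-space zero,
  # i.e. the training-target mean in original units
  p0 <- lapply(fit$params, function(p) p * 0)
  Xs <- standardize(as.matrix(tab[, feature_names()]), fit$xstd)
  pred <- unstandardize(itaml:::.mlp_forward(p0, Xs)$yhat, fit$ystd)
  expect_equal(unname(pred[, 1]),
               rep(mean(tab$q1_mv[fit$split$train]), nrow(tab)),
               tolerance = 1e-8)
})

test_that("fit objects expose the standard S3 surface", {
  tab <- make_linear_table(60)
  fit <- ita_fit(tab, targets = c("q1_mv", "q2_mv"), method = "lr", seed = 2)
  expect_output(print(fit), "ordinary least squares")
  expect_output(summary(fit), "validation")
  r <- residuals(fit)
  expect_equal(dim(r), c(60L, 2L))
  expect_equal(r[1, 1], tab$q1_mv[1] - predict(fit)[1, 1])
  ev <- evaluate_fit(fit, tab)
  expect_equal(ev$r2, c(1, 1), tolerance = 1e-10)
})
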