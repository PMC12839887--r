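## Front-door fitting function and S3 methods for the three regression back
## ends.  All three share the interface: a descriptor table, 13 feature
## columns, up to three target columns (first/second redox potential in mV,
## Hammett sigma_p) with explicit-NA missingness, a single stratified
## train/validation split, and reports in original units.

#' Fit a property-prediction model on a descriptor table
#'
#' Methods:
#' \describe{
#'   \item{`"lr"`}{ordinary least squares per target (baseline).}
#'   \item{`"mlp"`}{multilayer perceptron, one hidden layer of 6 rectified
#'     units by default, multitask output with masked MSE loss, full-batch
#'     Adam with reduce-on-plateau scheduling.}
#'   \item{`"vqc"`}{hybrid model: two-layer classical encoder (13 -> 16 ->
#'     12), 12-qubit angle-embedded variational circuit with 2 entangling
#'     layers, Pauli-Z readout, affine head; trained end-to-end for 200
#'     epochs by default with exact adjoint circuit gradients.}
#' }
#' Features and targets are standardized on the training split only (not
#' for `"lr"`); predictions and metrics are reported in original units.
#'
#' @param data data frame holding feature and target columns.
#' @param features feature column names (default [feature_names()], the 11
#'   ITA descriptors plus HOMO and LUMO).
#' @param targets target column names; rows with `NA` are masked out of the
#'   loss for that target only.
#' @param method `"lr"`, `"mlp"` or `"vqc"`.
#' @param split `list(train, validation)` row indices; default a stratified
#'   80/20 split by `data$family` (plain random split if absent).
#' @param seed RNG seed controlling initialization and the default split.
#' @param epochs training epochs (`mlp` 2000, `vqc` 200; ignored by `lr`).
#' @param lr_rate optimizer learning rate (default 1e-3).
#' @param hidden hidden-layer widths of the MLP (default 6).
#' @param encoder_hidden width of the VQC encoder hidden layer (default 16).
#' @param n_qubits,layers circuit width and entangling depth (12, 2).
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (`mlp` 100; `vqc` `Inf`).
#' @param plateau_factor,plateau_patience reduce-on-plateau schedule:
#'   multiply the rate by `plateau_factor` after `plateau_patience` epochs
#'   without validation improvement (defaults 0.5 and 10).
#' @param warm_start_head deterministic least-squares initialization of the
#'   VQC head (default `TRUE`).
#' @return an object of class `c("ita_fit_<method>", "ita_fit")` with
#'   `report` (per-target train/validation RMSE/MAE/R^2 in original units),
#'   `history` (loss trajectory), and everything `predict()` needs.
#' @seealso [predict.ita_fit()], [evaluate_fit()], [metrics_regression()]
#' @export
ita_fit <- function(data, features = feature_names(),
                    targets = c("q1_mv", "q2_mv", "sigma_p"),
                    method = c("lr", "mlp", "vqc"),
                    split = NULL, seed = 1, epochs = NULL, lr_rate = 1e-3,
                    hidden = 6L, encoder_hidden = 16L, n_qubits = 12L,
                    layers = 2L, early_stop_patience = NULL,
                    plateau_factor = 0.5, plateau_patience = 10L,
                    warm_start_head = TRUE) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data), all(features %in% names(data)),
            all(targets %in% names(data)))
  X <- as.matrix(data[, features, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing values in feature columns")
  Y <- as.matrix(data[, targets, drop = FALSE])
  storage.mode(Y) <- "double"
  M <- !is.na(Y)
  dead <- colSums(M) == 0
  if (any(dead)) {
    warning("target(s) with no labels excluded: ",
            paste(targets[dead], collapse = ", "))
    targets <- targets[!dead]
    Y <- Y[, !dead, drop = FALSE]
    M <- M[, !dead, drop = FALSE]
  }
  if (!length(targets)) stop("no target with at least one label")
  if (is.null(split)) {
    strat <- if ("family" %in% names(data)) data$family
    split <- make_split(nrow(data), 0.2, strat, seed)
  }
  fit <- switch(method,
    lr = .fit_lr(X, Y, M, split, features, targets),
    mlp = .fit_mlp(X, Y, M, split, seed, epochs %||% 2000L, lr_rate,
                   hidden, early_stop_patience %||% 100L,
                   plateau_factor, plateau_patience),
    vqc = .fit_vqc(X, Y, M, split, seed, epochs %||% 200L, lr_rate,
                   encoder_hidden, n_qubits, layers,
                   early_stop_patience %||% Inf, warm_start_head,
                   plateau_factor, plateau_patience))
  fit$method <- method
  fit$features <- features
  fit$targets <- targets
  fit$split <- split
  fit$seed <- seed
  fit$X <- X; fit$Y <- Y; fit$M <- M
  fit$report <- .fit_report(fit$fitted, Y, M, split, targets)
  class(fit) <- c(paste0("ita_fit_", method), "ita_fit")
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fit_report <- function(fitted, Y, M, split, targets) {
  out <- do.call(rbind, lapply(c("train", "validation"), function(set) {
    rows <- split[[set]]
    do.call(rbind, lapply(seq_along(targets), function(t) {
      obs <- ifelse(M[rows, t], Y[rows, t], NA_real_)
      if (all(is.na(obs))) {
        return(data.frame(target = targets[t], set = set, rmse = NA_real_,
                          mae = NA_real_, r2 = NA_real_, n = 0L))
      }
      m <- tryCatch(metrics_regression(fitted[rows, t], obs),
                    error = function(e) c(rmse = NA_real_, mae = NA_real_,
                                          r2 = NA_real_, n = sum(!is.na(obs))))
      data.frame(target = targets[t], set = set, rmse = m[["rmse"]],
                 mae = m[["mae"]], r2 = m[["r2"]], n = as.integer(m[["n"]]))
    }))
  }))
  rownames(out) <- NULL
  out
}

.fit_lr <- function(X, Y, M, split, features, targets) {
  Xd <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(Xd[split$train, , drop = FALSE])
  if (qrd$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qrd$pivot[(qrd$rank + 1):ncol(Xd)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coefs <- matrix(NA_real_, ncol(Xd), ncol(Y),
                  dimnames = list(colnames(Xd), targets))
  for (t in seq_len(ncol(Y))) {
    rows <- intersect(split$train, which(M[, t]))
    if (length(rows) < 2) stop("fewer than 2 labelled training rows for ",
                               targets[t])
    coefs[, t] <- stats::lm.fit(Xd[rows, , drop = FALSE], Y[rows, t])$coefficients
  }
  list(coefficients = coefs, fitted = Xd %*% coefs, history = NULL)
}

.fit_mlp <- function(X, Y, M, split, seed, epochs, lr_rate, hidden,
                     early_stop_patience, plateau_factor = 0.5,
                     plateau_patience = 10L) {
  xstd <- fit_standardizer(X, split$train)
  ystd <- fit_standardizer(Y, split$train, M)
  Xs <- standardize(X, xstd)
  Ys <- standardize(Y, ystd)
  Ys[!M] <- 0
  params <- .with_seed(seed, .mlp_init(ncol(X), hidden, ncol(Y)))
  history <- NULL
  if (epochs > 0) {
    tr <- .train_loop(params, .mlp_forward, .mlp_backward,
                      Xs[split$train, , drop = FALSE],
                      Ys[split$train, , drop = FALSE],
                      M[split$train, , drop = FALSE],
                      Xs[split$validation, , drop = FALSE],
                      Ys[split$validation, , drop = FALSE],
                      M[split$validation, , drop = FALSE],
                      epochs, lr_rate, plateau_factor = plateau_factor,
                      plateau_patience = plateau_patience,
                      early_stop_patience = early_stop_patience)
    params <- tr$params
    history <- tr$history
  }
  fitted <- unstandardize(.mlp_forward(params, Xs)$yhat, ystd)
  list(params = params, xstd = xstd, ystd = ystd, hidden = hidden,
       fitted = fitted, history = history)
}

.fit_vqc <- function(X, Y, M, split, seed, epochs, lr_rate, encoder_hidden,
                     n_qubits, layers, early_stop_patience, warm_start_head,
                     plateau_factor = 0.5, plateau_patience = 10L) {
  xstd <- fit_standardizer(X, split$train)
  ystd <- fit_standardizer(Y, split$train, M)
  Xs <- standardize(X, xstd)
  Ys <- standardize(Y, ystd)
  Ys[!M] <- 0
  params <- .with_seed(seed, .vqc_init(ncol(X), encoder_hidden, n_qubits,
                                       layers, ncol(Y)))
  if (warm_start_head) {
    params <- .vqc_warm_start_head(params, Xs[split$train, , drop = FALSE],
                                   Ys[split$train, , drop = FALSE],
                                   M[split$train, , drop = FALSE])
  }
  history <- NULL
  if (epochs > 0) {
    tr <- .train_loop(params, .vqc_forward, .vqc_backward,
                      Xs[split$train, , drop = FALSE],
                      Ys[split$train, , drop = FALSE],
                      M[split$train, , drop = FALSE],
                      Xs[split$validation, , drop = FALSE],
                      Ys[split$validation, , drop = FALSE],
                      M[split$validation, , drop = FALSE],
                      epochs, lr_rate, plateau_factor = plateau_factor,
                      plateau_patience = plateau_patience,
                      early_stop_patience = early_stop_patience)
    params <- tr$params
    history <- tr$history
  }
  fitted <- unstandardize(.vqc_forward(params, Xs)$yhat, ystd)
  list(params = params, xstd = xstd, ystd = ystd,
       n_qubits = n_qubits, layers = layers,
       encoder_hidden = encoder_hidden, fitted = fitted, history = history)
}

#' Predict from a fitted model
#'
#' @param object an [ita_fit()] object.
#' @param newdata data frame with the feature columns; defaults to the
#'   training table.
#' @param ... unused.
#' @return matrix (rows x targets) of predictions in original units.
#' @export
predict.ita_fit <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$X else {
    as.matrix(newdata[, object$features, drop = FALSE])
  }
  storage.mode(X) <- "double"
  out <- switch(object$method,
    lr = cbind(1, X) %*% object$coefficients,
    mlp = unstandardize(
      .mlp_forward(object$params, standardize(X, object$xstd))$yhat,
      object$ystd),
    vqc = unstandardize(
      .vqc_forward(object$params, standardize(X, object$xstd))$yhat,
      object$ystd))
  colnames(out) <- object$targets
  out
}

#' Evaluate a fitted model on a labelled table
#'
#' @param object an [ita_fit()] object.
#' @param data data frame with feature and target columns.
#' @return per-target metrics data frame (original units).
#' @export
evaluate_fit <- function(object, data) {
  pred <- predict(object, data)
  out <- do.call(rbind, lapply(seq_along(object$targets), function(t) {
    obs <- data[[object$targets[t]]]
    m <- metrics_regression(pred[, t], obs)
    data.frame(target = object$targets[t], rmse = m[["rmse"]],
               mae = m[["mae"]], r2 = m[["r2"]], n = as.integer(m[["n"]]))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.ita_fit <- function(x, ...) {
  lab <- switch(x$method, lr = "ordinary least squares",
                mlp = "multilayer perceptron",
                vqc = "hybrid variational-quantum-circuit model")
  cat("<ita_fit> ", lab, "\n", sep = "")
  cat("  features: ", length(x$features), "; targets: ",
      paste(x$targets, collapse = ", "), "\n", sep = "")
  cat("  split: ", length(x$split$train), " train / ",
      length(x$split$validation), " validation; seed ", x$seed, "\n",
      sep = "")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ita_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    n <- nrow(object$history)
    cat("  trained ", n, " epochs; final masked-MSE (std. units): train ",
        signif(object$history[n, 1], 4), ", validation ",
        signif(object$history[n, 2], 4), "\n", sep = "")
  }
  invisible(object)
}

#' @export
coef.ita_fit <- function(object, ...) {
  if (object$method == "lr") object$coefficients else object$params
}

#' @export
residuals.ita_fit <- function(object, ...) {
  r <- object$Y - predict(object)
  r[!object$M] <- NA_real_
  r
}

#' @export
plot.ita_fit <- function(x, ...) {
  pred <- predict(x)
  nt <- length(x$targets)
  op <- graphics::par(mfrow = c(1, nt))
  on.exit(graphics::par(op))
  for (t in seq_len(nt)) {
    obs <- ifelse(x$M[, t], x$Y[, t], NA_real_)
    in_val <- seq_len(nrow(x$Y)) %in% x$split$validation
    graphics::plot(obs, pred[, t], col = ifelse(in_val, 2, 1),
                   pch = ifelse(in_val, 17, 1),
                   xlab = paste("observed", x$targets[t]),
                   ylab = "predicted", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
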