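## Metrics, standardization, and train/validation splitting shared by the
## three regression back ends.

#' Regression metrics over unmasked pairs
#'
#' @param pred predictions.
#' @param obs observations; `NA`s (and `NA` predictions) are masked out.
#' @return named vector `c(rmse, mae, r2, n)`; R^2 = 1 - SSE/SST.
#' @export
metrics_regression <- function(pred, obs) {
  ok <- !is.na(obs) & !is.na(pred)
  if (!any(ok)) stop("no unmasked prediction/observation pairs")
  e <- pred[ok] - obs[ok]
  sst <- sum((obs[ok] - mean(obs[ok]))^2)
  if (sst == 0) stop("zero target variance: R^2 undefined")
  c(rmse = sqrt(mean(e^2)), mae = mean(abs(e)),
    r2 = 1 - sum(e^2) / sst, n = sum(ok))
}

#' Fit a standardizer on training rows
#'
#' @param x numeric matrix.
#' @param rows rows to fit on (training split).
#' @param mask optional logical matrix; `FALSE` entries are ignored.
#' @return list with per-column `mean` and `sd` (zero spread maps to sd 1).
#' @export
fit_standardizer <- function(x, rows = seq_len(nrow(x)), mask = NULL) {
  x <- as.matrix(x)
  m <- numeric(ncol(x)); s <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    v <- x[rows, j]
    if (!is.null(mask)) v <- v[mask[rows, j]]
    v <- v[!is.na(v)]
    m[j] <- if (length(v)) mean(v) else 0
    s[j] <- if (length(v) > 1) stats::sd(v) else 1
    if (!is.finite(s[j]) || s[j] == 0) s[j] <- 1
  }
  list(mean = m, sd = s)
}

#' Apply / invert a standardizer (exact affine pair)
#' @param x matrix.
#' @param std a [fit_standardizer()] result.
#' @return standardized (or de-standardized) matrix; `NA`s pass through.
#' @export
standardize <- function(x, std) {
  sweep(sweep(as.matrix(x), 2, std$mean, "-"), 2, std$sd, "/")
}

#' @rdname standardize
#' @export
unstandardize <- function(x, std) {
  sweep(sweep(as.matrix(x), 2, std$sd, "*"), 2, std$mean, "+")
}

#' Single stratified train/validation split
#'
#' @param n number of rows.
#' @param validation_frac fraction held out (default 0.2).
#' @param stratify optional factor of length `n` (e.g. molecular family);
#'   the hold-out fraction is taken within each level.
#' @param seed RNG seed.
#' @return list with integer vectors `train` and `validation`.
#' @export
make_split <- function(n, validation_frac = 0.2, stratify = NULL, seed = 1) {
  stopifnot(n >= 2, validation_frac > 0, validation_frac < 1)
  rs <- .with_seed(seed, {
    if (is.null(stratify)) {
      val <- sort(sample.int(n, max(1L, round(validation_frac * n))))
    } else {
      stopifnot(length(stratify) == n)
      val <- sort(unlist(lapply(split(seq_len(n), stratify), function(ii) {
        if (length(ii) < 2) return(integer(0))
        sample(ii, max(1L, round(validation_frac * length(ii))))
      }), use.names = FALSE))
    }
    val
  })
  list(train = setdiff(seq_len(n), rs), validation = rs)
}

#' k-fold cross-validation folds
#'
#' @inheritParams make_split
#' @param k number of folds (default 5).
#' @return list of `k` splits, each a `list(train, validation)`.
#' @export
make_folds <- function(n, k = 5, stratify = NULL, seed = 1) {
  stopifnot(n >= k, k >= 2)
  fold_of <- .with_seed(seed, {
    f <- integer(n)
    if (is.null(stratify)) {
      f <- sample(rep_len(seq_len(k), n))
    } else {
      for (ii in split(seq_len(n), stratify)) {
        f[ii] <- sample(rep_len(seq_len(k), length(ii)))
      }
    }
    f
  })
  lapply(seq_len(k), function(j) {
    list(train = which(fold_of != j), validation = which(fold_of == j))
  })
}

# evaluate an expression with a local RNG seed, restoring global state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}
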