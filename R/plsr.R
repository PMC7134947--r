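# PLSR trait models: NIPALS PLS1 on mean-centered (unscaled) spectra, latent
# variables selected at the minimum leave-one-out PRESS RMSE, resampling
# validation statistics, and variable-importance-in-projection scores.

#' Fit a PLSR trait model
#'
#' NIPALS PLS1 on mean-centered, unscaled data (reflectance bands share
#' units, so no variance scaling is applied). For every candidate latent
#' variable count `1..max_lv` the leave-one-out predicted residual sum of
#' squares (PRESS) is computed, each fold re-centered and refit; the
#' selected count minimizes the PRESS RMSE, with ties broken toward fewer
#' components (parsimony).
#'
#' @param X `n x p` spectra matrix; columns are the retained (masked)
#'   wavelength bands, column names are wavelengths in nm.
#' @param y Length-`n` trait vector.
#' @param max_lv Largest candidate component count
#'   (default `min(15, n - 2)`).
#' @param trait_name Stored on the model for reporting.
#' @return An object of class `plsr_model`: `n_lv`, `x_mean`/`y_mean`
#'   centering terms, `weights` (W), `x_loadings` (P), `y_loadings` (q),
#'   `coefficients` (the per-band linear model at the selected rank),
#'   `press_curve` (LOO PRESS RMSE per candidate count), `vip`,
#'   `wavelength_grid`, `trait_name`, `r2_train`.
#' @export
fit_plsr <- function(X, y, max_lv = NULL, trait_name = "trait") {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 4) stop("too few samples: PLSR needs n >= 4", call. = FALSE)
  if (length(y) != n) stop("X and y sizes differ", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported", call. = FALSE)
  if (stats::var(y) == 0) stop("degenerate target: y is constant", call. = FALSE)
  if (is.null(max_lv)) max_lv <- min(15L, n - 2L)
  max_lv <- min(max_lv, n - 2L, p)

  press <- .pls1_press_cpp(X, y, max_lv)
  press_rmse <- sqrt(press / n)
  n_lv <- which.min(press_rmse)  # first minimum: ties toward fewer LVs

  fit <- .pls1_fit_cpp(X, y, n_lv)
  if (fit$ncomp < 1) stop("PLS extracted no components (X'y vanished)", call. = FALSE)
  n_lv <- min(n_lv, fit$ncomp)
  W <- fit$W; P <- fit$P; q <- drop(fit$q); tt <- drop(fit$tt)
  coefficients <- drop(W %*% solve(t(P) %*% W, matrix(q, ncol = 1L)))

  model <- structure(
    list(n_lv = as.integer(n_lv), x_mean = drop(fit$x_mean), y_mean = fit$y_mean,
         weights = W, x_loadings = P, y_loadings = q, tt = tt,
         coefficients = coefficients, press_curve = press_rmse,
         wavelength_grid = colnames(X), trait_name = trait_name,
         n = n, p = p),
    class = "plsr_model")
  model$vip <- vip_scores(model)
  yhat <- predict(model, X)
  model$r2_train <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  model
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %s: %d samples x %d bands, %d latent variable(s)\n",
              x$trait_name, x$n, x$p, x$n_lv))
  cat(sprintf("  train R2 %.3f | PRESS RMSE at selection %.4g\n",
              x$r2_train, x$press_curve[x$n_lv]))
  invisible(x)
}

#' Predict traits from spectra
#'
#' `yhat = y_mean + (x - x_mean) . coefficients`. The spectra must sit on
#' the model's wavelength grid; no silent interpolation is performed.
#'
#' @param object A `plsr_model`.
#' @param newdata `m x p` spectra matrix (or single spectrum vector).
#' @param ... Unused.
#' @return Length-`m` trait predictions.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) {
    stop("wavelength alignment error: model has ", object$p,
         " bands, spectra have ", ncol(newdata), call. = FALSE)
  }
  if (!is.null(colnames(newdata)) && !is.null(object$wavelength_grid) &&
      !identical(colnames(newdata), object$wavelength_grid)) {
    stop("wavelength alignment error: band names differ from the model grid",
         call. = FALSE)
  }
  drop(object$y_mean + sweep(newdata, 2L, object$x_mean) %*% object$coefficients)
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt( p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a )` over
#' the selected components, with `SSY_a = q_a^2 t_a't_a` the y-variance
#' captured by component `a`. The scores satisfy `sum_j VIP_j^2 = p`.
#'
#' @param model A fitted `plsr_model`.
#' @return Per-band non-negative importance scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsr_model"))
  a <- model$n_lv
  W <- model$weights[, seq_len(a), drop = FALSE]
  ssy <- (model$y_loadings[seq_len(a)]^2) * model$tt[seq_len(a)]
  if (sum(ssy) <= 0) stop("undefined VIP: no explained y-variance", call. = FALSE)
  wnorm2 <- colSums(W^2)
  frac <- sweep(W^2, 2L, wnorm2, `/`)  # (w_ja/||w_a||)^2
  sqrt(model$p * drop(frac %*% ssy) / sum(ssy))
}

#' Resampling validation of a PLSR model
#'
#' Repeats `n_resamples` random train/test splits. Each training fold
#' re-runs the full latent-variable selection (leave-one-out PRESS on the
#' fold only), fits at the selected count and predicts its hold-outs. Each
#' sample's reported prediction is the mean over all resamples in which it
#' was held out, and the cross-validated statistics compare those mean
#' predictions with the observations: `r2_cv` (1 - SSres/SStot), `rmse`,
#' `rmse_pct = 100 rmse / (max(y) - min(y))` and `bias = mean(pred - obs)`.
#' `r2_train` and the reported component count come from the full-data fit.
#'
#' @param X,y Spectra matrix and trait vector as in [fit_plsr()].
#' @param n_resamples Number of random resamples (default 1000).
#' @param holdout_fraction Fraction of samples held out per resample.
#' @param max_lv Candidate component cap, as in [fit_plsr()].
#' @param seed Integer RNG seed (splits are deterministic given it).
#' @param trait_name Reporting label.
#' @return A list of class `plsr_cv`: `stats` (data.frame with `r2_train`,
#'   `r2_cv`, `rmse`, `rmse_pct`, `bias`, `n_lv`), `predictions` (per-sample
#'   mean held-out prediction; NA when never held out, with a coverage
#'   warning), `lv_selected` (per-resample counts), `model` (full-data fit).
#' @export
resample_validate <- function(X, y, n_resamples = 1000, holdout_fraction = 0.2,
                              max_lv = NULL, seed = 1, trait_name = "trait") {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  n_test <- max(1L, floor(n * holdout_fraction))
  if (n - n_test < 4) stop("holdout too large: training folds need >= 4 samples",
                           call. = FALSE)
  if (is.null(max_lv)) max_lv <- min(15L, n - 2L)
  max_lv <- min(max_lv, n - n_test - 2L, ncol(X))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  splits <- vapply(seq_len(n_resamples), function(i) sample.int(n, n_test),
                   integer(n_test))
  splits <- matrix(splits, nrow = n_test)

  res <- .pls1_resample_cpp(X, y, splits, max_lv)
  cnt <- drop(res$count)
  preds <- drop(res$pred_sum)
  preds[cnt > 0] <- preds[cnt > 0] / cnt[cnt > 0]
  preds[cnt == 0] <- NA_real_
  if (any(cnt == 0)) {
    warning(sum(cnt == 0), " sample(s) never held out; omitted from CV statistics")
  }
  ok <- cnt > 0
  rmse <- sqrt(mean((preds[ok] - y[ok])^2))
  stats_df <- data.frame(
    trait = trait_name,
    r2_train = NA_real_,
    r2_cv = 1 - sum((y[ok] - preds[ok])^2) / sum((y[ok] - mean(y[ok]))^2),
    rmse = rmse,
    rmse_pct = rmse_percent(rmse, y),
    bias = mean(preds[ok] - y[ok]),
    n_lv = NA_integer_
  )
  model <- fit_plsr(X, y, max_lv = max_lv, trait_name = trait_name)
  stats_df$r2_train <- model$r2_train
  stats_df$n_lv <- model$n_lv
  if (stats_df$r2_cv > stats_df$r2_train) {
    warning("CV R2 exceeds training R2; inspect the resampling setup")
  }
  structure(list(stats = stats_df, predictions = preds,
                 lv_selected = drop(res$lv_selected), model = model),
            class = "plsr_cv")
}

#' @export
print.plsr_cv <- function(x, ...) {
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Range-normalized RMSE in percent
#'
#' `100 * rmse / (max(y) - min(y))`: the reporting convention that relates
#' a trait's RMSE to its observed range.
#'
#' @param rmse Root mean square error in trait units.
#' @param y Observed trait values (only their range is used).
#' @return RMSE as a percentage of the observed range.
#' @export
rmse_percent <- function(rmse, y) {
  rng <- max(y) - min(y)
  if (rng <= 0) stop("observed trait range is zero", call. = FALSE)
  100 * rmse / rng
}

#' Serialize / restore a PLSR model as JSON
#'
#' @param model A `plsr_model`.
#' @param path Output/input JSON path.
#' @return `path` (write) or the restored `plsr_model` (read).
#' @export
write_plsr_model <- function(model, path) {
  stopifnot(inherits(model, "plsr_model"))
  obj <- unclass(model)
  # matrices stored flat (column-major) with explicit dims
  for (f in c("weights", "x_loadings")) {
    obj[[f]] <- list(dim = dim(obj[[f]]), values = as.vector(obj[[f]]))
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_plsr_model
#' @export
read_plsr_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("weights", "x_loadings")) {
    obj[[f]] <- matrix(obj[[f]]$values, obj[[f]]$dim[1L], obj[[f]]$dim[2L])
  }
  obj$n_lv <- as.integer(obj$n_lv)
  structure(obj, class = "plsr_model")
}
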