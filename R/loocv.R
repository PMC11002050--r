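# Leave-one-out cross-validation for selecting the number of PLS components.

#' Select the number of PLS components by leave-one-out cross-validation
#'
#' For each candidate component count `A` in `1..A_max` and each training
#' sample `i`, the model is refit on the remaining `n - 1` samples --
#' re-deriving the spectral pre-treatment and the centering inside the fold,
#' so the held-out sample never leaks into them -- and sample `i` is
#' predicted. The mean squared error between predicted and actual
#' concentrations (on the original concentration scale) is aggregated over
#' all folds, and the selected `A*` is the smallest count attaining the
#' minimum MSE (ties, within a relative slack of `1e-8` of the curve's
#' range, break toward fewer components).
#'
#' Each fold is fit once with the largest candidate count; predictions for
#' smaller counts fall out of the nested score recursion. If a fold's rank
#' is exhausted below `A_max`, its last achievable prediction is carried
#' forward and the result is flagged as capped, with a warning.
#'
#' @param X raw training spectra (samples x channels) when
#'   `preprocess = TRUE`, otherwise already pre-treated spectra.
#' @param Y response vector or matrix, mg g\eqn{^{-1}}.
#' @param A_max largest candidate component count (default 20).
#' @param preprocess logical; refit [fit_preprocess()] within every fold
#'   (default `TRUE`).
#' @return An object of class `cv_result`: `mse` (named curve over
#'   `1..A_max`), `A_star`, `A_max`, `capped` and `n_folds`.
#' @export
loocv_select <- function(X, Y, A_max = 20L, preprocess = TRUE) {
  assert_matrix_like(X, "X")
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  assert_matrix_like(Y, "Y")
  n <- nrow(X)
  if (n < 3) stop_nutrispec("LOOCV needs at least 3 training samples")
  if (A_max < 1) stop_nutrispec("A_max must be >= 1")
  A_max <- as.integer(min(A_max, n - 2L, ncol(X)))

  sq_err <- matrix(0, n, A_max)
  capped <- FALSE
  for (i in seq_len(n)) {
    X_in <- X[-i, , drop = FALSE]
    X_out <- X[i, , drop = FALSE]
    if (preprocess) {
      st <- fit_preprocess(X_in)
      X_in <- apply_preprocess(X_in, st)
      X_out <- apply_preprocess(X_out, st)
    }
    y_in <- Y[-i, , drop = FALSE]
    x_center <- colMeans(X_in)
    y_center <- colMeans(y_in)
    core <- nipals_core(sweep(X_in, 2, x_center, "-"),
                        sweep(y_in, 2, y_center, "-"), A_max,
                        strict = FALSE)
    A_eff <- ncol(core$W)
    if (A_eff == 0L) {
      stop_nutrispec("no PLS component is extractable in a fold")
    }
    if (A_eff < A_max) capped <- TRUE
    x <- as.vector(X_out) - x_center
    yhat <- y_center
    for (a in seq_len(A_max)) {
      if (a <= A_eff) {
        t_a <- sum(x * core$W[, a])
        x <- x - t_a * core$P[, a]
        yhat <- yhat + t_a * core$Q[, a]
      }
      sq_err[i, a] <- mean((yhat - Y[i, ])^2)
    }
  }
  if (capped) {
    warning("LOOCV: rank exhausted below A_max in at least one fold; ",
            "curve capped at the fold rank", call. = FALSE)
  }
  mse <- colMeans(sq_err)
  names(mse) <- seq_len(A_max)
  slack <- 1e-8 * diff(range(mse))
  A_star <- which(mse <= min(mse) + slack)[1]
  structure(
    list(mse = mse, A_star = as.integer(A_star), A_max = A_max,
         capped = capped, n_folds = n),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> LOOCV over %d folds, A* = %d (MSE %.4g)\n",
              x$n_folds, x$A_star, x$mse[x$A_star]))
  invisible(x)
}
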