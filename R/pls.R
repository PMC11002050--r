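# NIPALS partial least squares regression.
#
# The bilinear model is X = T P' + Fx and Y = U Q' + Fy on centered data,
# with the original-space regression Y = X B + E assembled from
# B = W (P' W)^{-1} Q'. Components are extracted sequentially with
# X-deflation; for a single response the inner iteration closes in one pass.

# Core NIPALS loop on centered matrices; returns weights/scores/loadings.
# Rank exhaustion (deflated X, or X-Y covariance, numerically zero relative
# to its initial scale) errors in strict mode with the achievable maximum,
# and truncates the decomposition otherwise.
nipals_core <- function(Xc, Yc, A, tol = 1e-10, max_iter = 500L,
                        strict = TRUE) {
  n <- nrow(Xc)
  p <- ncol(Xc)
  m <- ncol(Yc)
  W <- matrix(0, p, A)
  P <- matrix(0, p, A)
  Q <- matrix(0, m, A)
  Tm <- matrix(0, n, A)
  Um <- matrix(0, n, A)
  fx0 <- sum(Xc^2)
  fy0 <- sum(Yc^2)
  a_done <- 0L
  for (a in seq_len(A)) {
    exhausted <- sum(Xc^2) < 1e-24 * fx0 || sum(Yc^2) < 1e-24 * fy0
    if (!exhausted) {
      u <- Yc[, which.max(colSums(Yc^2)), drop = FALSE]
      w0 <- sqrt(sum(crossprod(Xc, u)^2))
      exhausted <- w0^2 < 1e-24 * fx0 * sum(u^2)
    }
    if (exhausted) {
      if (strict) {
        stop_nutrispec(sprintf(
          "X/Y covariance exhausted at component %d; maximum achievable is %d",
          a, a - 1L))
      }
      break
    }
    w_old <- rep(0, p)
    for (iter in seq_len(max_iter)) {
      w <- crossprod(Xc, u)
      w <- w / sqrt(sum(w^2))
      t_vec <- Xc %*% w
      tt <- sum(t_vec^2)
      q <- crossprod(Yc, t_vec) / tt
      if (m == 1L) break
      u <- Yc %*% q / sum(q^2)
      if (sqrt(sum((w - w_old)^2)) < tol) break
      w_old <- w
    }
    u <- if (sum(q^2) > 0) Yc %*% q / sum(q^2) else u
    p_vec <- crossprod(Xc, t_vec) / tt
    Xc <- Xc - t_vec %*% t(p_vec)
    Yc <- Yc - t_vec %*% t(q)
    W[, a] <- w
    P[, a] <- p_vec
    Q[, a] <- q
    Tm[, a] <- t_vec
    Um[, a] <- u
    a_done <- a
  }
  keep <- seq_len(a_done)
  list(W = W[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
       Q = Q[, keep, drop = FALSE], T = Tm[, keep, drop = FALSE],
       U = Um[, keep, drop = FALSE], Fx = Xc, Fy_deflated = Yc)
}

#' Fit a PLS regression by NIPALS
#'
#' Decomposes centered spectra `X` and responses `Y` into `A` latent
#' components (`X = T P' + Fx`, `Y = U Q' + Fy`) and assembles the
#' original-space regression coefficients `B = W (P' W)^{-1} Q'` so that
#' predictions are `(X - x_center) B + y_center` (`Y = X B + E`). One
#' response column gives classical PLS1; several give PLS2 with the full
#' inner NIPALS iteration (convergence when the weight vector changes by
#' less than `1e-10`, capped at 500 iterations).
#'
#' @param X samples x channels numeric matrix (typically pre-treated
#'   spectra).
#' @param Y numeric response vector or samples x analytes matrix,
#'   mg g\eqn{^{-1}}.
#' @param A number of latent components, `1 <= A <= min(n - 1, p)`.
#' @return An object of class `pls_fit` with scores `T`, `U`, loadings `P`,
#'   `Q`, weights `W`, coefficients `B`, residual matrices `Fx`, `Fy`
#'   (centered-space, satisfying the bilinear identities exactly) and `E`
#'   (original-space training residuals), plus centering vectors
#'   `x_center`, `y_center`.
#' @export
fit_pls <- function(X, Y, A) {
  assert_matrix_like(X, "X")
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1, dimnames = list(NULL, "Y"))
  assert_matrix_like(Y, "Y")
  n <- nrow(X)
  p <- ncol(X)
  if (nrow(Y) != n) stop_nutrispec("X and Y disagree on sample count")
  if (A < 1 || A > min(n - 1, p)) {
    stop_nutrispec(sprintf("A must lie in [1, min(n - 1, p)] = [1, %d]",
                           min(n - 1, p)))
  }
  y_var <- apply(Y, 2, stats::var)
  if (any(y_var < .Machine$double.eps)) {
    stop_nutrispec("zero-variance response column(s): ",
                   paste(colnames(Y)[y_var < .Machine$double.eps],
                         collapse = ", "))
  }
  x_center <- colMeans(X)
  y_center <- colMeans(Y)
  Xc <- sweep(X, 2, x_center, "-")
  Yc <- sweep(Y, 2, y_center, "-")

  core <- nipals_core(Xc, Yc, A)
  B <- core$W %*% solve(crossprod(core$P, core$W), t(core$Q))
  dimnames(B) <- list(colnames(X), colnames(Y))
  fitted <- sweep(Xc %*% B, 2, y_center, "+")
  structure(
    list(n_components = A,
         T = core$T, U = core$U, P = core$P, Q = core$Q, W = core$W, B = B,
         Fx = core$Fx,
         Fy = Yc - core$U %*% t(core$Q),
         E = Y - fitted,
         x_center = x_center, y_center = y_center,
         analytes = colnames(Y)),
    class = "pls_fit"
  )
}

#' Predict concentrations from a fitted PLS model
#'
#' Applies `Y' = (X_new - x_center) B + y_center`. Rows are independent:
#' identical spectra yield identical predictions.
#'
#' @param object a [fit_pls()] result.
#' @param newdata samples x channels matrix on the same (pre-treated) scale
#'   as the training spectra.
#' @param ... unused.
#' @return Samples x analytes matrix of predicted concentrations.
#' @export
predict.pls_fit <- function(object, newdata, ...) {
  assert_matrix_like(newdata, "newdata")
  if (ncol(newdata) != length(object$x_center)) {
    stop_nutrispec(sprintf("channel count %d does not match fit (%d)",
                           ncol(newdata), length(object$x_center)))
  }
  out <- sweep(sweep(newdata, 2, object$x_center, "-") %*% object$B,
               2, object$y_center, "+")
  rownames(out) <- rownames(newdata)
  out
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("<pls_fit> %d components, %d channels, response(s): %s\n",
              x$n_components, length(x$x_center),
              paste(x$analytes, collapse = ", ")))
  invisible(x)
}
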