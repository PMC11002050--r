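#' Multiplicative scatter correction against a fixed reference
#'
#' Fits each spectrum `s` to the scatter model `s ~ a + b * r` by ordinary
#' least squares over all channels and returns `(s - a) / b`. A spectrum
#' constructed as `b * r + a` with `b != 0` is therefore mapped back to `r`
#' exactly, and the correction is idempotent (a corrected spectrum refits
#' with `a = 0`, `b = 1`).
#'
#' @param spectra samples x channels numeric matrix.
#' @param reference numeric reference spectrum (one value per channel).
#' @param b_floor spectra whose fitted gain has `|b|` below this floor are
#'   rejected as flat/degenerate (default `1e-8`).
#' @return Corrected matrix of the same shape, with attributes `"msc_a"` and
#'   `"msc_b"` holding the fitted per-spectrum coefficients.
#' @export
msc_correct <- function(spectra, reference, b_floor = 1e-8) {
  assert_matrix_like(spectra, "spectra")
  p <- ncol(spectra)
  if (length(reference) != p) {
    stop_nutrispec("reference length must equal the channel count")
  }
  r_mean <- mean(reference)
  r_c <- reference - r_mean
  ss_r <- sum(r_c^2)
  if (ss_r < .Machine$double.eps) {
    stop_nutrispec("MSC reference has no variance across channels")
  }
  s_mean <- rowMeans(spectra)
  b <- as.vector((spectra %*% r_c)) / ss_r
  a <- s_mean - b * r_mean
  bad <- which(abs(b) < b_floor)
  if (length(bad) > 0) {
    stop_nutrispec("degenerate (flat) spectra in MSC, |b| < floor at rows: ",
                   paste(bad, collapse = ", "))
  }
  out <- (spectra - a) / b
  dimnames(out) <- dimnames(spectra)
  attr(out, "msc_a") <- a
  attr(out, "msc_b") <- b
  out
}

#' Fit the spectral pre-treatment on training spectra
#'
#' Derives, from training data only, the state needed to pre-treat any
#' spectrum: the MSC reference (the mean training spectrum) and the
#' per-channel means of the MSC-corrected training spectra used for the
#' subsequent mean-centering. The two classical operations -- multiplicative
#' scatter correction and mean-centering -- are applied in that order;
#' centering column-means first would leave a zero MSC reference and an
#' ill-posed gain fit, so the scatter correction is done on the raw scale.
#'
#' @param train_spectra samples x channels matrix with at least 2 rows.
#' @param b_floor MSC gain floor passed to [msc_correct()].
#' @return An object of class `preprocess_state` with elements
#'   `msc_reference`, `column_means`, `n_channels` and `b_floor`.
#' @export
fit_preprocess <- function(train_spectra, b_floor = 1e-8) {
  assert_matrix_like(train_spectra, "train_spectra")
  if (nrow(train_spectra) < 2) {
    stop_nutrispec("need at least 2 training spectra to fit preprocessing")
  }
  reference <- colMeans(train_spectra)
  corrected <- msc_correct(train_spectra, reference, b_floor = b_floor)
  structure(
    list(msc_reference = reference,
         column_means = colMeans(corrected),
         n_channels = ncol(train_spectra),
         b_floor = b_floor),
    class = "preprocess_state"
  )
}

#' Apply a fitted pre-treatment to spectra
#'
#' MSC-corrects each spectrum against the training-derived reference, then
#' subtracts the training-derived column means. The state is never updated:
#' test spectra cannot leak into it.
#'
#' @param spectra samples x channels matrix.
#' @param state a `preprocess_state` from [fit_preprocess()].
#' @return Pre-treated matrix of the same shape.
#' @export
apply_preprocess <- function(spectra, state) {
  stopifnot(inherits(state, "preprocess_state"))
  assert_matrix_like(spectra, "spectra")
  if (ncol(spectra) != state$n_channels) {
    stop_nutrispec(sprintf("channel count %d does not match fitted state (%d)",
                           ncol(spectra), state$n_channels))
  }
  corrected <- msc_correct(spectra, state$msc_reference,
                           b_floor = state$b_floor)
  out <- sweep(corrected, 2, state$column_means, "-")
  attributes(out)[c("msc_a", "msc_b")] <- NULL
  dimnames(out) <- dimnames(spectra)
  out
}

#' @export
print.preprocess_state <- function(x, ...) {
  cat(sprintf("<preprocess_state> MSC + centering over %d channels\n",
              x$n_channels))
  invisible(x)
}

#' Base-2 logarithm of a positive concentration vector
#'
#' Used by the Z-score assessment to symmetrise skewed concentration
#' distributions. Nonpositive values are rejected outright with their
#' indices: panels whose ranges reach zero need an explicit caller-chosen
#' offset before transformation, never a silent one.
#'
#' @param values numeric vector, all `> 0`.
#' @return `log2(values)`.
#' @export
log2_transform <- function(values) {
  stopifnot(is.numeric(values))
  bad <- which(!(values > 0))
  if (length(bad) > 0) {
    stop_nutrispec("log2_transform requires strictly positive values; ",
                   "offending indices: ", paste(bad, collapse = ", "))
  }
  log2(values)
}
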