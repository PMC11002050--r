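#' Configuration of the synthetic FTIR-PAS generator
#'
#' Holds the sampling-panel composition and the spectral nuisance levels used
#' by [synthesize_spectra()] and [make_default_dataset()]. Defaults emulate a
#' 122-sample biowaste panel measured between 4000 and 400 cm\eqn{^{-1}} at
#' 4 cm\eqn{^{-1}} resolution (901 channels): 57 cow manures, 28 digestates,
#' 16 chicken manures and 21 pig manures.
#'
#' @param counts named integer vector of per-source sample counts.
#' @param seed integer seed governing every random draw of the generator.
#' @param noise_sd additive per-channel Gaussian noise SD, absorbance units.
#' @param a_sd SD of the per-spectrum additive scatter offset.
#' @param b_sd SD of the per-spectrum multiplicative scatter gain (gain is
#'   centred on 1).
#' @param baseline_amp amplitude of the per-spectrum quadratic baseline
#'   drift, absorbance units.
#' @param matrix_amp scale of the constant organic-matrix background
#'   spectrum shared by all samples (1 = default magnitude, absorbance
#'   units; 0 disables it). Dried biowaste spectra are dominated by this
#'   common matrix absorption, which is also what makes a multiplicative
#'   scatter model well-posed.
#' @param grid numeric `c(from, to, by)` wavenumber grid specification in
#'   cm\eqn{^{-1}}; channels run from `from` down to `to` in steps of `by`.
#' @param source_shift named numeric vector of per-source concentration mean
#'   offsets, in margin-SD units; internally recentred against the requested
#'   counts so the panel-wide mean of every analyte matches its spec.
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(counts = c(cow_manure = 57L, digestate = 28L,
                                        chicken_manure = 16L, pig_manure = 21L),
                             seed = 1L,
                             noise_sd = 0.035,
                             a_sd = 0.08,
                             b_sd = 0.08,
                             baseline_amp = 0.04,
                             matrix_amp = 1,
                             grid = c(4000, 400, 4),
                             source_shift = c(cow_manure = 0.4,
                                              digestate = -0.35,
                                              chicken_manure = 0.7,
                                              pig_manure = -0.45)) {
  stopifnot(!is.null(names(counts)), all(counts >= 0),
            length(grid) == 3, grid[1] > grid[2], grid[3] > 0)
  if (noise_sd < 0 || a_sd < 0 || b_sd < 0 || baseline_amp < 0 ||
      matrix_amp < 0) {
    stop_nutrispec("noise/scatter/baseline/matrix amplitudes must be >= 0")
  }
  structure(
    list(counts = counts, seed = as.integer(seed), noise_sd = noise_sd,
         a_sd = a_sd, b_sd = b_sd, baseline_amp = baseline_amp,
         matrix_amp = matrix_amp, grid = as.numeric(grid),
         source_shift = source_shift),
    class = "generator_config"
  )
}

#' Wavenumber axis of a generator configuration
#'
#' @param cfg a [generator_config()].
#' @return Numeric vector of wavenumbers in cm\eqn{^{-1}}, descending
#'   (4000 to 400 in steps of 4 gives 901 channels).
#' @export
wavenumber_grid <- function(cfg = generator_config()) {
  seq(cfg$grid[1], cfg$grid[2], by = -cfg$grid[3])
}

# Latent-correlation pre-compensation (NORTA): mapping latent normals
# through nonlinear truncated-normal quantile functions attenuates Pearson
# correlation, so for each pair we solve for the latent rho whose induced
# output correlation equals the target, by Gauss-Hermite quadrature and
# root finding. `margins` is a list of c(mu, sd, lo, hi) per analyte.
norta_latent_corr <- function(target, margins, n_nodes = 24L) {
  gh <- gauss_hermite_normal(n_nodes)
  z <- gh$nodes
  w <- gh$weights
  k <- length(margins)
  # per-analyte margin values at the quadrature nodes, plus mean/sd
  gvals <- lapply(margins, function(m) {
    truncnorm_quantile(stats::pnorm(z), m[1], m[2], m[3], m[4])
  })
  mom <- lapply(gvals, function(g) {
    mu <- sum(w * g)
    c(mu = mu, sd = sqrt(sum(w * (g - mu)^2)))
  })
  induced <- function(rho, i, j) {
    # E[g_i(Z1) g_j(rho Z1 + sqrt(1-rho^2) Z2)] on the tensor GH grid
    gi <- gvals[[i]]
    acc <- 0
    for (a in seq_along(z)) {
      zj <- rho * z[a] + sqrt(1 - rho^2) * z
      gj <- truncnorm_quantile(stats::pnorm(zj), margins[[j]][1],
                               margins[[j]][2], margins[[j]][3],
                               margins[[j]][4])
      acc <- acc + w[a] * gi[a] * sum(w * gj)
    }
    (acc - mom[[i]]["mu"] * mom[[j]]["mu"]) /
      (mom[[i]]["sd"] * mom[[j]]["sd"])
  }
  L <- diag(k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r_t <- target[i, j]
      if (abs(r_t) < 1e-12) next
      f <- function(rho) induced(rho, i, j) - r_t
      lohi <- sort(c(sign(r_t) * 0.999, r_t * 0.5))
      rho <- if (f(lohi[1]) * f(lohi[2]) < 0) {
        stats::uniroot(f, lower = lohi[1], upper = lohi[2], tol = 1e-6)$root
      } else if (abs(f(sign(r_t) * 0.999)) < abs(f(r_t))) {
        sign(r_t) * 0.999   # target beyond what the margins can induce
      } else {
        r_t
      }
      L[i, j] <- L[j, i] <- rho
    }
  }
  L
}

#' Draw correlated analyte concentrations via a Gaussian copula
#'
#' Samples one concentration table with the requested correlation structure
#' and truncated-normal margins. Each margin is the quantile map of a normal
#' truncated to `[range_lo, range_hi]`, whose location parameter is
#' calibrated (per analyte and source) so the expected value equals the
#' analyte's target mean; the quantile mapping keeps every draw strictly
#' inside its range without clipping, so no probability mass accumulates at
#' the bounds. Because a nonlinear margin attenuates Pearson correlation,
#' the latent Gaussian correlation is pre-compensated pairwise (Gauss-
#' Hermite quadrature + root finding, the NORTA construction) so the
#' emitted table's correlations match the targets, not an attenuated copy
#' of them.
#'
#' Per-source mean shifts (in margin-SD units, recentred against the
#' requested counts) make the sources distinguishable while preserving the
#' panel-wide analyte means.
#'
#' @param specs list of [analyte_spec()] objects.
#' @param corr a [correlation_model()] covering every analyte in `specs`.
#' @param counts named per-source sample counts.
#' @param seed integer seed.
#' @param source_shift per-source mean offsets in margin-SD units; defaults
#'   to no shift for sources not named.
#' @return A list with `concentrations` (samples x analytes matrix,
#'   mg g\eqn{^{-1}}, rownames = sample IDs), `sources` (factor) and
#'   `sample_ids`.
#' @export
sample_concentrations <- function(specs, corr, counts, seed,
                                  source_shift = NULL) {
  analytes <- vapply(specs, `[[`, character(1), "name")
  names(specs) <- analytes
  missing <- setdiff(analytes, corr$analytes)
  if (length(missing) > 0) {
    stop_nutrispec("analytes missing from correlation model: ",
                   paste(missing, collapse = ", "))
  }
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n == 0) stop_nutrispec("no samples requested")
  k <- length(analytes)

  R <- corr$target[analytes, analytes, drop = FALSE]
  margins <- lapply(specs, function(sp) {
    sd_j <- (sp$range_hi - sp$range_lo) / 5
    c(truncnorm_calibrate(sp$mean, sd_j, sp$range_lo, sp$range_hi),
      sd_j, sp$range_lo, sp$range_hi)
  })
  latent <- norta_latent_corr(R, margins)
  ev <- eigen(latent, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    latent <- as.matrix(Matrix::nearPD(latent, corr = TRUE)$mat)
  }
  L <- chol(latent)

  # Recentre the per-source shifts so the count-weighted mean shift is zero.
  shift <- rep(0, length(counts))
  names(shift) <- names(counts)
  if (!is.null(source_shift)) {
    hit <- intersect(names(source_shift), names(counts))
    shift[hit] <- source_shift[hit]
  }
  shift <- shift - sum(shift * counts) / n

  sources <- factor(rep(names(counts), counts), levels = names(counts))
  ids <- sprintf("S%03d", seq_len(n))

  Z <- with_seed(seed, matrix(stats::rnorm(n * k), n, k)) %*% L
  U <- stats::pnorm(Z)

  X <- matrix(NA_real_, n, k, dimnames = list(ids, analytes))
  for (j in seq_len(k)) {
    sp <- specs[[j]]
    sd_j <- (sp$range_hi - sp$range_lo) / 5
    span <- sp$range_hi - sp$range_lo
    for (s in names(counts)) {
      idx <- which(sources == s)
      target <- sp$mean + shift[s] * sd_j
      # keep the shifted target strictly inside the admissible range
      target <- min(max(target, sp$range_lo + 0.02 * span),
                    sp$range_hi - 0.02 * span)
      mu <- truncnorm_calibrate(target, sd_j, sp$range_lo, sp$range_hi)
      X[idx, j] <- truncnorm_quantile(U[idx, j], mu, sd_j,
                                      sp$range_lo, sp$range_hi)
    }
  }
  list(concentrations = X, sources = sources, sample_ids = ids)
}

# Constant organic-matter matrix absorption shared by all samples: broad
# O-H/N-H stretching near 3400, aliphatic C-H near 2920, carbonyl/amide
# near 1650 and carbohydrate C-O near 1030 cm^-1, over a flat offset.
matrix_spectrum <- function(wn) {
  1.2 * exp(-0.5 * ((wn - 3400) / 250)^2) +
    0.8 * exp(-0.5 * ((wn - 2920) / 120)^2) +
    1.0 * exp(-0.5 * ((wn - 1650) / 120)^2) +
    1.1 * exp(-0.5 * ((wn - 1030) / 150)^2) +
    0.3
}

# Analyte-by-channel matrix of unit-concentration band profiles.
band_basis <- function(specs, wn) {
  k <- length(specs)
  G <- matrix(0, k, length(wn))
  rownames(G) <- vapply(specs, `[[`, character(1), "name")
  for (j in seq_len(k)) {
    b <- specs[[j]]$bands
    if (nrow(b) == 0) next
    for (i in seq_len(nrow(b))) {
      G[j, ] <- G[j, ] +
        b$strength[i] * exp(-0.5 * ((wn - b$center[i]) / b$width[i])^2)
    }
  }
  G
}

#' Synthesize FTIR-PAS-like spectra from a concentration table
#'
#' Each clean spectrum is the constant organic-matrix background
#' (`matrix_amp` times a fixed broad-band matrix spectrum) plus a
#' concentration-weighted sum of Gaussian absorption bands (peak absorbance
#' = `strength` per mg g\eqn{^{-1}} at the band center). The emitted
#' spectrum is `b * clean + a + baseline + noise` with a
#' per-spectrum multiplicative gain `b ~ N(1, b_sd)`, additive offset
#' `a ~ N(0, a_sd)`, a random quadratic baseline drift of amplitude
#' `baseline_amp`, and per-channel additive Gaussian noise of SD `noise_sd`.
#' All draws are standard normals scaled by the configured amplitudes, so two
#' configurations sharing a seed share the same underlying draws and differ
#' only by scale. Deterministic given `cfg$seed`.
#'
#' @param concentrations samples x analytes numeric matrix (mg g\eqn{^{-1}}).
#' @param specs list of [analyte_spec()] covering every analyte column.
#' @param cfg a [generator_config()].
#' @return Samples x channels absorbance matrix, columns named with the
#'   wavenumber in cm\eqn{^{-1}}, descending.
#' @export
synthesize_spectra <- function(concentrations, specs, cfg = generator_config()) {
  assert_matrix_like(concentrations, "concentrations")
  analytes <- colnames(concentrations)
  spec_names <- vapply(specs, `[[`, character(1), "name")
  if (!all(analytes %in% spec_names)) {
    stop_nutrispec("no analyte_spec for: ",
                   paste(setdiff(analytes, spec_names), collapse = ", "))
  }
  specs <- specs[match(analytes, spec_names)]
  wn <- wavenumber_grid(cfg)
  p <- length(wn)
  n <- nrow(concentrations)

  clean <- concentrations %*% band_basis(specs, wn)
  clean <- sweep(clean, 2, cfg$matrix_amp * matrix_spectrum(wn), "+")

  draws <- with_seed(derive_seed(cfg$seed, 7919L), {
    list(a = stats::rnorm(n), b = stats::rnorm(n),
         bl = matrix(stats::rnorm(3 * n), n, 3),
         noise = matrix(stats::rnorm(n * p), n, p))
  })
  a <- cfg$a_sd * draws$a
  b <- 1 + cfg$b_sd * draws$b
  # quadratic drift over a [-1, 1]-normalised wavenumber axis
  x <- 2 * (wn - min(wn)) / (max(wn) - min(wn)) - 1
  baseline <- cfg$baseline_amp *
    (draws$bl %*% rbind(rep(1, p), x, x^2))
  out <- clean * b + a + baseline + cfg$noise_sd * draws$noise
  dimnames(out) <- list(rownames(concentrations), format(wn, trim = TRUE))
  out
}

#' Bundle spectra, concentrations and source labels into a dataset
#'
#' @param spectra samples x channels absorbance matrix.
#' @param concentrations samples x analytes concentration matrix.
#' @param sources per-sample source labels (factor or character).
#' @param provenance optional [generator_config()] echo or file origin.
#' @return An object of class `nutri_dataset`.
#' @export
nutri_dataset <- function(spectra, concentrations, sources, provenance = NULL) {
  assert_matrix_like(spectra, "spectra")
  assert_matrix_like(concentrations, "concentrations")
  if (nrow(spectra) != nrow(concentrations)) {
    stop_nutrispec("spectra and concentrations disagree on sample count")
  }
  if (!identical(rownames(spectra), rownames(concentrations))) {
    stop_nutrispec("spectra and concentrations disagree on sample ordering")
  }
  if (length(sources) != nrow(spectra)) {
    stop_nutrispec("sources length must equal the sample count")
  }
  structure(
    list(spectra = spectra, concentrations = concentrations,
         sources = factor(sources), provenance = provenance),
    class = "nutri_dataset"
  )
}

#' @export
print.nutri_dataset <- function(x, ...) {
  cat(sprintf("<nutri_dataset> %d samples x %d channels, %d analytes\n",
              nrow(x$spectra), ncol(x$spectra), ncol(x$concentrations)))
  cat("sources:", paste(sprintf("%s=%d", levels(x$sources),
                                tabulate(x$sources)), collapse = ", "), "\n")
  invisible(x)
}

#' Generate the default 122-sample synthetic panel
#'
#' Runs [sample_concentrations()] with the default analyte panel and
#' correlation model, then [synthesize_spectra()], under the default
#' [generator_config()] (57 cow manure / 28 digestate / 16 chicken manure /
#' 21 pig manure; 901 channels from 4000 to 400 cm\eqn{^{-1}}).
#'
#' @param seed integer seed; overrides `cfg$seed`.
#' @param cfg a [generator_config()].
#' @param specs analyte panel, defaulting to [default_analyte_panel()].
#' @param corr correlation model, defaulting to [default_correlation_model()].
#' @return A [nutri_dataset()].
#' @export
make_default_dataset <- function(seed = 1L, cfg = generator_config(),
                                 specs = default_analyte_panel(),
                                 corr = default_correlation_model(vapply(specs, `[[`, character(1), "name"))) {
  cfg$seed <- as.integer(seed)
  conc <- sample_concentrations(specs, corr, cfg$counts, seed = cfg$seed,
                                source_shift = cfg$source_shift)
  spectra <- synthesize_spectra(conc$concentrations, specs, cfg)
  nutri_dataset(spectra, conc$concentrations, conc$sources, provenance = cfg)
}
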