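#' Describe one analyte for the synthetic generator
#'
#' An analyte specification couples the concentration margin used by the
#' Gaussian-copula sampler (range and target mean, in mg g\eqn{^{-1}},
#' numerically identical to g kg\eqn{^{-1}}) with the mid-infrared absorption
#' bands through which the analyte appears in a synthetic FTIR-PAS spectrum.
#'
#' Spectrally inactive analytes (e.g. potassium, whose photoacoustic
#' absorption is weak, or nitrate at negligible concentration) carry no bands;
#' any predictability they show downstream arises purely from their
#' correlation with spectrally active constituents.
#'
#' @param name analyte identifier, e.g. `"TN"` or `"NH4-N"`.
#' @param range_lo,range_hi concentration bounds, mg g\eqn{^{-1}}
#'   (`range_lo >= 0`).
#' @param mean target mean concentration, must lie in `[range_lo, range_hi]`.
#' @param bands a data frame with columns `center` (cm\eqn{^{-1}}, within
#'   400--4000), `width` (Gaussian SD in cm\eqn{^{-1}}, > 0) and `strength`
#'   (peak absorbance contributed per mg g\eqn{^{-1}}, >= 0). May have zero
#'   rows.
#' @param spectrally_active logical; if `FALSE`, `bands` must be empty.
#'
#' @return An object of class `analyte_spec`.
#' @seealso [default_analyte_panel()]
#' @export
analyte_spec <- function(name, range_lo, range_hi, mean, bands = NULL,
                         spectrally_active = TRUE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (range_lo < 0) stop_nutrispec("range_lo must be >= 0")
  if (!(range_lo <= mean && mean <= range_hi)) {
    stop_nutrispec(sprintf("mean of '%s' must lie in [range_lo, range_hi]", name))
  }
  if (is.null(bands)) {
    bands <- data.frame(center = numeric(0), width = numeric(0),
                        strength = numeric(0))
  }
  stopifnot(is.data.frame(bands),
            all(c("center", "width", "strength") %in% names(bands)))
  if (nrow(bands) > 0) {
    if (any(bands$center < 400 | bands$center > 4000)) {
      stop_nutrispec(sprintf("band centers of '%s' must lie in [400, 4000] cm^-1", name))
    }
    if (any(bands$width <= 0)) stop_nutrispec("band widths must be > 0")
    if (any(bands$strength < 0)) stop_nutrispec("band strengths must be >= 0")
  }
  if (!spectrally_active && nrow(bands) > 0) {
    stop_nutrispec(sprintf("'%s' is spectrally inactive but has bands", name))
  }
  structure(
    list(name = name, range_lo = range_lo, range_hi = range_hi, mean = mean,
         bands = bands, spectrally_active = spectrally_active),
    class = "analyte_spec"
  )
}

band_table <- function(center, width, strength) {
  data.frame(center = center, width = width, strength = strength)
}

#' Default 12-analyte manure/digestate panel
#'
#' Concentration ranges and means follow the wet-chemistry summary of a
#' 122-sample panel of cow, pig and chicken manures plus digestates: total
#' nitrogen 13.2--44.12 (mean 25.16), ammonium-N 0--18.63 (2.57), total
#' phosphorus 0--30 (10.67), bicarbonate-extractable P 1.09--15.62 (4.8),
#' K 0--60 (18), Ca 4.4--90 (19.4), Mg 2.3--28 (7.7), Na 0.1--21 (4.14),
#' S 1.4--15 (5.38), Zn 0--0.67 (0.18) and Fe 0.3--13.1 (2.47), all in
#' mg g\eqn{^{-1}}. Nitrate-N is present at negligible concentration in such
#' dried panels; its margin (0.01--0.9, mean 0.15) is an invented
#' placeholder.
#'
#' Band positions sit in the regions where dried biowaste absorbs in the
#' mid-IR: O--H/N--H stretching near 3400 cm\eqn{^{-1}}, aliphatic C--H near
#' 2850--2926 cm\eqn{^{-1}}, carbonate features at 3100--2900 and 2600--2300
#' cm\eqn{^{-1}}, amide bands near 1365/1090/1050 cm\eqn{^{-1}}, and the
#' phosphate/inorganic-anion region below 1300 cm\eqn{^{-1}}. Exact centers,
#' widths and strengths are calibrated defaults of this generator, not
#' measured constants. K and NO3-N are spectrally inactive.
#'
#' @return A named list of [analyte_spec()] objects.
#' @export
default_analyte_panel <- function() {
  specs <- list(
    analyte_spec("TN", 13.2, 44.12, 25.16,
                 band_table(c(3400, 1365, 1090, 1050),
                            c(120, 40, 35, 35),
                            c(0.008, 0.012, 0.006, 0.005))),
    analyte_spec("NH4-N", 0, 18.63, 2.57,
                 band_table(c(3150, 1440), c(90, 45), c(0.05, 0.08))),
    analyte_spec("NO3-N", 0.01, 0.9, 0.15, spectrally_active = FALSE),
    analyte_spec("TP", 0, 30, 10.67,
                 band_table(c(1080, 950, 590), c(50, 40, 35),
                            c(0.025, 0.02, 0.012))),
    analyte_spec("bicarb-P", 1.09, 15.62, 4.8,
                 band_table(c(1270, 840), c(45, 35), c(0.04, 0.03))),
    analyte_spec("K", 0, 60, 18, spectrally_active = FALSE),
    analyte_spec("Ca", 4.4, 90, 19.4,
                 band_table(c(2980, 2520, 1430, 870), c(70, 60, 55, 30),
                            c(0.01, 0.008, 0.015, 0.012))),
    analyte_spec("Mg", 2.3, 28, 7.7,
                 band_table(c(1610, 1020), c(50, 40), c(0.03, 0.022))),
    analyte_spec("Na", 0.1, 21, 4.14,
                 band_table(c(1140, 710), c(45, 35), c(0.05, 0.04))),
    analyte_spec("S", 1.4, 15, 5.38,
                 band_table(c(1125, 620), c(40, 30), c(0.045, 0.035))),
    analyte_spec("Zn", 0, 0.67, 0.18,
                 band_table(c(1505, 985), c(35, 30), c(1.2, 0.9))),
    analyte_spec("Fe", 0.3, 13.1, 2.47,
                 band_table(c(1680, 565), c(40, 30), c(0.09, 0.07)))
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Pairwise correlation targets for the concentration sampler
#'
#' Wraps a symmetric target correlation matrix, repairing it to the nearest
#' positive semi-definite correlation matrix (eigenvalue clipping via
#' [Matrix::nearPD()]) so it can drive a Gaussian copula.
#'
#' @param analytes character vector of analyte names (matrix order).
#' @param target symmetric numeric matrix of pairwise correlation targets in
#'   `[-1, 1]` with unit diagonal.
#' @return An object of class `correlation_model` with elements `analytes`
#'   and `target` (the PSD-repaired matrix, Cholesky-factorisable).
#' @export
correlation_model <- function(analytes, target) {
  stopifnot(is.character(analytes), is.matrix(target),
            nrow(target) == length(analytes),
            ncol(target) == length(analytes))
  if (max(abs(target - t(target))) > 1e-12) {
    stop_nutrispec("target correlation matrix must be symmetric")
  }
  if (any(abs(diag(target) - 1) > 1e-12)) {
    stop_nutrispec("target correlation matrix must have unit diagonal")
  }
  if (any(target < -1 - 1e-12) || any(target > 1 + 1e-12)) {
    stop_nutrispec("correlation targets must lie in [-1, 1]")
  }
  ev <- eigen(target, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    target <- as.matrix(Matrix::nearPD(target, corr = TRUE)$mat)
    ev <- eigen(target, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop_nutrispec("correlation matrix is not positive semi-definite after repair")
    }
  }
  dimnames(target) <- list(analytes, analytes)
  structure(list(analytes = analytes, target = target),
            class = "correlation_model")
}

#' Default correlation structure of the manure/digestate panel
#'
#' Encodes the qualitative correlation pattern seen in wet-chemistry panels
#' of manures and digestates: ammonium-N tracks total N closely (target
#' 0.90), total P tracks bicarbonate-extractable P closely (0.90) and is
#' strongly tied to Mg and Ca (0.75), the S/Ca/Na/Fe/Zn group is mutually
#' correlated (0.75), nitrate-N is essentially uncorrelated with everything
#' (0.10, its concentration being negligible), and the remaining pairs share
#' a mild common-source correlation (0.30). The numeric values are
#' calibrations of those qualitative statements, not measured correlations.
#'
#' @param analytes analyte name order; defaults to the default panel order.
#' @return A [correlation_model()].
#' @export
default_correlation_model <- function(analytes = names(default_analyte_panel())) {
  k <- length(analytes)
  R <- matrix(0.30, k, k, dimnames = list(analytes, analytes))
  set_r <- function(a, b, r) {
    if (a %in% analytes && b %in% analytes) {
      R[a, b] <<- r
      R[b, a] <<- r
    }
  }
  if ("NO3-N" %in% analytes) {
    R["NO3-N", ] <- 0.10
    R[, "NO3-N"] <- 0.10
  }
  block <- intersect(c("S", "Ca", "Na", "Fe", "Zn"), analytes)
  R[block, block] <- 0.75
  set_r("TN", "NH4-N", 0.90)
  set_r("TP", "bicarb-P", 0.90)
  set_r("TP", "Mg", 0.75)
  set_r("TP", "Ca", 0.75)
  diag(R) <- 1
  correlation_model(analytes, R)
}
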