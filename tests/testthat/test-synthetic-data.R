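# Synthetic concentration sampler and spectra generator.

test_that("analyte_spec validates its invariants", {
  expect_error(analyte_spec("X", -1, 5, 2), "range_lo")
  expect_error(analyte_spec("X", 0, 5, 7), "range_lo, range_hi")
  expect_error(analyte_spec("X", 0, 5, 2,
                            data.frame(center = 5000, width = 10,
                                       strength = 1)), "400, 4000")
  expect_error(analyte_spec("X", 0, 5, 2,
                            data.frame(center = 1000, width = -1,
                                       strength = 1)), "width")
  expect_error(analyte_spec("X", 0, 5, 2,
                            data.frame(center = 1000, width = 10,
                                       strength = 1),
                            spectrally_active = FALSE), "inactive")
})

test_that("correlation_model rejects malformed targets and repairs PSD", {
  expect_error(correlation_model(c("a", "b"),
                                 matrix(c(1, 0.2, 0.5, 1), 2, 2)),
               "symmetric")
  expect_error(correlation_model(c("a", "b"),
                                 matrix(c(2, 0.2, 0.2, 1), 2, 2)),
               "diagonal")
  # a non-PSD 3x3 target gets repaired to a factorisable matrix
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  cm <- correlation_model(c("a", "b", "c"), R)
  expect_silent(chol(cm$target + 1e-12 * diag(3)))
})

test_that("independent margins give near-zero empirical correlation", {
  specs <- tiny_panel()
  cm <- correlation_model(c("TN", "TP"), diag(2))
  sc <- sample_concentrations(specs, cm, c(cow_manure = 1000L), seed = 5)
  expect_lt(abs(cor(sc$concentrations)[1, 2]), 0.15)
})

test_that("a 0.9 target correlation is realised in the emitted table", {
  specs <- default_analyte_panel()[c("TN", "NH4-N")]
  cm <- correlation_model(c("TN", "NH4-N"),
                          matrix(c(1, 0.9, 0.9, 1), 2, 2))
  sc <- sample_concentrations(specs, cm, c(cow_manure = 1000L), seed = 11)
  X <- sc$concentrations
  # oracle: direct correlation of the emitted table, both Pearson and rank
  expect_lt(abs(cor(X[, 1], X[, 2]) - 0.9), 0.05)
  expect_lt(abs(cor(X[, 1], X[, 2], method = "spearman") - 0.9), 0.05)
})

test_that("TN margin honours its range and mean", {
  specs <- default_analyte_panel()["TN"]
  cm <- correlation_model("TN", matrix(1, 1, 1))
  sc <- sample_concentrations(specs, cm, c(cow_manure = 2000L), seed = 3)
  tn <- sc$concentrations[, "TN"]
  expect_gte(min(tn), 13.2)
  expect_lte(max(tn), 44.12)
  expect_lt(abs(mean(tn) - 25.16), 1.0)
})

test_that("margin fidelity holds across the default panel", {
  specs <- default_analyte_panel()
  corr <- default_correlation_model()
  sc <- sample_concentrations(specs, corr, c(cow_manure = 1200L), seed = 42)
  X <- sc$concentrations
  for (sp in specs) {
    x <- X[, sp$name]
    expect_gte(min(x), sp$range_lo)
    expect_lte(max(x), sp$range_hi)
    expect_lt(abs(mean(x) - sp$mean) / sp$mean, 0.05)
  }
  expect_true(all(X >= 0))
})

test_that("pairwise correlations track their targets across the panel", {
  specs <- default_analyte_panel()
  corr <- default_correlation_model()
  sc <- sample_concentrations(specs, corr, c(cow_manure = 2000L), seed = 42)
  dev <- abs(cor(sc$concentrations) - corr$target)
  expect_lt(max(dev[upper.tri(dev)]), 0.07)
})

test_that("per-source shifts separate sources but preserve panel means", {
  specs <- tiny_panel()
  counts <- c(cow_manure = 400L, digestate = 400L)
  sc <- sample_concentrations(specs, tiny_corr(), counts, seed = 9,
                              source_shift = c(cow_manure = 0.5,
                                               digestate = -0.5))
  tn <- sc$concentrations[, "TN"]
  m_cow <- mean(tn[sc$sources == "cow_manure"])
  m_dig <- mean(tn[sc$sources == "digestate"])
  expect_gt(m_cow, m_dig)
  expect_lt(abs(mean(tn) - 25.16) / 25.16, 0.05)
})

test_that("sampler rejects analytes missing from the correlation model", {
  specs <- tiny_panel()
  cm <- correlation_model("TN", matrix(1, 1, 1))
  expect_error(sample_concentrations(specs, cm, c(cow_manure = 5L), seed = 1),
               "missing from correlation model: TP")
})

test_that("zero concentrations and zero nuisance give zero spectra", {
  specs <- tiny_panel()
  conc <- matrix(0, 4, 2, dimnames = list(sprintf("S%03d", 1:4),
                                          c("TN", "TP")))
  cfg <- generator_config(noise_sd = 0, a_sd = 0, b_sd = 0,
                          baseline_amp = 0, matrix_amp = 0)
  sp <- synthesize_spectra(conc, specs, cfg)
  expect_equal(dim(sp), c(4, 901))
  expect_true(all(sp == 0))
})

test_that("a single band reproduces its closed-form Gaussian profile", {
  spec <- list(analyte_spec("A", 0, 10, 5,
                            data.frame(center = 1500, width = 50,
                                       strength = 0.7)))
  conc <- matrix(3.2, 1, 1, dimnames = list("S001", "A"))
  cfg <- generator_config(noise_sd = 0, a_sd = 0, b_sd = 0,
                          baseline_amp = 0, matrix_amp = 0)
  sp <- synthesize_spectra(conc, spec, cfg)
  wn <- wavenumber_grid(cfg)
  oracle <- 3.2 * 0.7 * exp(-0.5 * ((wn - 1500) / 50)^2)
  expect_equal(unname(sp[1, ]), oracle, tolerance = 1e-12)
  expect_equal(unname(sp[1, wn == 1500]), 3.2 * 0.7)
})

test_that("doubling one concentration exactly doubles its contribution", {
  specs <- tiny_panel()
  cfg <- generator_config(noise_sd = 0, a_sd = 0, b_sd = 0,
                          baseline_amp = 0, matrix_amp = 0)
  conc1 <- matrix(c(20, 5), 1, 2, dimnames = list("S001", c("TN", "TP")))
  conc0 <- conc1; conc0[1, "TN"] <- 0
  conc2 <- conc1; conc2[1, "TN"] <- 40
  s0 <- synthesize_spectra(conc0, specs, cfg)
  s1 <- synthesize_spectra(conc1, specs, cfg)
  s2 <- synthesize_spectra(conc2, specs, cfg)
  expect_equal(s2 - s0, 2 * (s1 - s0), tolerance = 1e-12)
})

test_that("the generator is deterministic given its seed", {
  specs <- tiny_panel()
  conc <- matrix(c(20, 30, 5, 8), 2, 2,
                 dimnames = list(c("S001", "S002"), c("TN", "TP")))
  cfg <- generator_config(seed = 77L)
  expect_identical(synthesize_spectra(conc, specs, cfg),
                   synthesize_spectra(conc, specs, cfg))
  d1 <- make_default_dataset(31, cfg = tiny_config(), specs = tiny_panel(),
                             corr = tiny_corr())
  d2 <- make_default_dataset(31, cfg = tiny_config(), specs = tiny_panel(),
                             corr = tiny_corr())
  expect_identical(serialize(d1, NULL), serialize(d2, NULL))
})

test_that("the default dataset reproduces the panel composition", {
  d <- make_default_dataset(1)
  expect_equal(nrow(d$spectra), 122)
  expect_equal(ncol(d$spectra), 901)
  expect_equal(unname(tabulate(d$sources)), c(57, 28, 16, 21))
  expect_identical(rownames(d$spectra), rownames(d$concentrations))
  wn <- as.numeric(colnames(d$spectra))
  expect_equal(wn[1], 4000)
  expect_equal(wn[length(wn)], 400)
  expect_true(all(diff(wn) == -4))
})
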