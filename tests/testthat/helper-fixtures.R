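# Shared fixtures, all built in code at test time.

# A small two-analyte panel with well-separated bands, for fast end-to-end
# tests that do not need the full 12-analyte default.
tiny_panel <- function() {
  list(
    analyte_spec("TN", 13.2, 44.12, 25.16,
                 data.frame(center = c(3400, 1365), width = c(120, 40),
                            strength = c(0.008, 0.012))),
    analyte_spec("TP", 0, 30, 10.67,
                 data.frame(center = c(1080, 590), width = c(50, 35),
                            strength = c(0.025, 0.012)))
  )
}

tiny_corr <- function() {
  correlation_model(c("TN", "TP"), matrix(c(1, 0.3, 0.3, 1), 2, 2))
}

# Small 4-source panel configuration for fast pipeline runs.
tiny_config <- function(...) {
  generator_config(counts = c(cow_manure = 12L, digestate = 8L,
                              chicken_manure = 6L, pig_manure = 8L), ...)
}

tiny_dataset <- function(seed = 1, ...) {
  make_default_dataset(seed, cfg = tiny_config(...), specs = tiny_panel(),
                       corr = tiny_corr())
}

# Random spectra matrix with sample IDs and descending wavenumber names.
random_spectra <- function(n, p, seed = 1) {
  wn <- seq(4000, by = -4, length.out = p)
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("S%03d", seq_len(n)),
                                format(wn, trim = TRUE)))
    m
  })
}

# Seeded random prediction set around a reference vector.
random_prediction_set <- function(n, seed, spread = 2) {
  withr::with_seed(seed, {
    y <- runif(n, 0.5, 40)
    prediction_set(y, y + rnorm(n, sd = spread), analyte = "N")
  })
}
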