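# End-to-end orchestration: generate/load -> split -> preprocess ->
# LOOCV component selection -> fit -> predict -> assess.

#' Configuration of a full pipeline run
#'
#' A run is fully determined by its configuration: every random draw flows
#' from `seed` (fanned out to the generator and the splitter through fixed
#' offsets, so stages can be re-run in isolation).
#'
#' @param seed global integer seed.
#' @param dataset optional pre-built [nutri_dataset()]; when `NULL` the
#'   synthetic generator is run with `gen_config`.
#' @param gen_config a [generator_config()] used when `dataset` is `NULL`.
#' @param analytes analyte names to model; `NULL` means every analyte in
#'   the concentration table.
#' @param train_fraction training proportion for [stratified_split()].
#' @param preprocess `"msc"` (multiplicative scatter correction followed by
#'   mean-centering, the default) or `"none"` (spectra used as-is; PLS still
#'   centers internally).
#' @param pls_mode `"pls1"` (one model and one LOOCV-selected component
#'   count per analyte, the default) or `"pls2"` (all analytes modelled
#'   jointly with a single component count).
#' @param a_max largest candidate component count for [loocv_select()].
#' @param tolerance_map named list mapping analyte names to
#'   [tolerance_spec()] objects; defaults to nitrogen limits on `TN` and
#'   phosphorus-pentoxide limits on `TP` (with the explicit elemental-P to
#'   P2O5 conversion declared by the spec).
#' @param zscore_mode `"linear"` or `"log2"` for [compute_zscores()].
#' @param outdir optional output directory; when given, the dataset,
#'   predictions, report JSON and charts are written there.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       dataset = NULL,
                       gen_config = generator_config(),
                       analytes = NULL,
                       train_fraction = 0.7,
                       preprocess = c("msc", "none"),
                       pls_mode = c("pls1", "pls2"),
                       a_max = 20L,
                       tolerance_map = NULL,
                       zscore_mode = c("linear", "log2"),
                       outdir = NULL) {
  preprocess <- match.arg(preprocess)
  pls_mode <- match.arg(pls_mode)
  zscore_mode <- match.arg(zscore_mode)
  if (is.null(tolerance_map)) {
    specs <- default_tolerance_specs()
    tolerance_map <- list(TN = specs$N, TP = specs$P2O5)
  }
  structure(
    list(seed = as.integer(seed), dataset = dataset, gen_config = gen_config,
         analytes = analytes, train_fraction = train_fraction,
         preprocess = preprocess, pls_mode = pls_mode,
         a_max = as.integer(a_max), tolerance_map = tolerance_map,
         zscore_mode = zscore_mode, outdir = outdir),
    class = "run_config"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_nutrispec(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)))
  })
}

config_hash <- function(config) {
  slim <- config
  slim$dataset <- if (is.null(config$dataset)) NULL else "external-dataset"
  slim$outdir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(slim, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Execute the full analysis pipeline
#'
#' Runs generate (or load) -> stratified split -> spectral pre-treatment ->
#' LOOCV component selection on the training set -> final PLS fit ->
#' prediction on the held-out test set -> assessment (conventional metrics
#' for every analyte; Z-score and tolerance-interval classification for the
#' analytes that carry a tolerance specification). Pre-treatment and
#' centering are derived from training data only; test concentrations are
#' touched solely at the assessment stage.
#'
#' @param config a [run_config()].
#' @return An object of class `run_report`: software version, config hash,
#'   seed, split summary, a per-analyte table (selected components, RMSE,
#'   R2, RPD) and Z-score / tolerance summaries. Full fit, prediction and
#'   assessment objects are attached as the `"details"` attribute (not
#'   serialized).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))

  dataset <- run_stage("dataset", {
    if (is.null(config$dataset)) {
      make_default_dataset(seed = derive_seed(config$seed, 0L),
                           cfg = config$gen_config)
    } else {
      config$dataset
    }
  })

  analytes <- config$analytes %||% colnames(dataset$concentrations)
  missing <- setdiff(analytes, colnames(dataset$concentrations))
  if (length(missing) > 0) {
    stop_nutrispec("analyte(s) absent from the dataset: ",
                   paste(missing, collapse = ", "))
  }

  split <- run_stage("split", {
    stratified_split(dataset, train_fraction = config$train_fraction,
                     seed = derive_seed(config$seed, 101L))
  })
  X_train_raw <- dataset$spectra[split$train_ids, , drop = FALSE]
  X_test_raw <- dataset$spectra[split$test_ids, , drop = FALSE]
  Y_train <- dataset$concentrations[split$train_ids, analytes, drop = FALSE]
  Y_test <- dataset$concentrations[split$test_ids, analytes, drop = FALSE]

  use_msc <- config$preprocess == "msc"
  state <- NULL
  if (use_msc) {
    state <- run_stage("preprocess", fit_preprocess(X_train_raw))
    X_train <- apply_preprocess(X_train_raw, state)
    X_test <- apply_preprocess(X_test_raw, state)
  } else {
    X_train <- X_train_raw
    X_test <- X_test_raw
  }

  fits <- list()
  cv <- list()
  predictions <- matrix(NA_real_, nrow(X_test), length(analytes),
                        dimnames = list(split$test_ids, analytes))
  run_stage("model", {
    if (config$pls_mode == "pls1") {
      for (an in analytes) {
        cv[[an]] <- loocv_select(X_train_raw, Y_train[, an],
                                  A_max = config$a_max,
                                  preprocess = use_msc)
        fit <- fit_pls(X_train, Y_train[, an, drop = FALSE], cv[[an]]$A_star)
        fits[[an]] <- fit
        predictions[, an] <- predict(fit, X_test)
      }
    } else {
      cv[["joint"]] <- loocv_select(X_train_raw, Y_train,
                                     A_max = config$a_max,
                                     preprocess = use_msc)
      fit <- fit_pls(X_train, Y_train, cv[["joint"]]$A_star)
      fits[["joint"]] <- fit
      predictions[, ] <- predict(fit, X_test)
    }
  })

  metrics <- list()
  zreports <- list()
  treports <- list()
  run_stage("assess", {
    for (an in analytes) {
      preds <- prediction_set(Y_test[, an], predictions[, an], analyte = an)
      metrics[[an]] <- compute_metrics(preds)
      tspec <- config$tolerance_map[[an]]
      if (!is.null(tspec)) {
        # assess on the basis the spec declares; conversion is explicit
        conv <- tspec$conversion
        basis_preds <- prediction_set(conv * Y_test[, an],
                                      conv * predictions[, an],
                                      analyte = tspec$basis)
        zreports[[an]] <- compute_zscores(basis_preds, tspec,
                                           mode = config$zscore_mode)
        treports[[an]] <- tolerance_bands(basis_preds, tspec)
      }
    }
  })

  a_sel <- vapply(analytes, function(an) {
    if (config$pls_mode == "pls1") cv[[an]]$A_star else cv[["joint"]]$A_star
  }, integer(1))
  analyte_table <- data.frame(
    analyte = analytes,
    components = a_sel,
    rmse = vapply(metrics, `[[`, numeric(1), "rmse"),
    r2 = vapply(metrics, `[[`, numeric(1), "r2"),
    rpd = vapply(metrics, `[[`, numeric(1), "rpd"),
    row.names = NULL
  )
  zsum <- lapply(zreports, function(z) {
    list(basis = z$analyte, mode = z$mode,
         fraction_inside = z$fraction_inside, limit_95 = z$limit_95)
  })
  tsum <- lapply(treports, function(t) {
    list(basis = t$analyte, n_inside = t$n_inside, n = t$n,
         percent_inside = t$percent_inside)
  })
  report <- structure(
    list(package_version = as.character(utils::packageVersion("nutrispec")),
         config_hash = config_hash(config),
         seed = config$seed,
         split = list(train_n = length(split$train_ids),
                      test_n = length(split$test_ids),
                      achieved = split$achieved),
         analytes = analyte_table,
         zscore = zsum,
         tolerance = tsum),
    class = "run_report"
  )
  attr(report, "details") <- list(dataset = dataset, split = split,
                                  state = state, cv = cv, fits = fits,
                                  predictions = predictions,
                                  metrics = metrics, zscore = zreports,
                                  tolerance = treports)

  if (!is.null(config$outdir)) {
    run_stage("write", {
      dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
      write_dataset(dataset,
                    file.path(config$outdir, "spectra.csv"),
                    file.path(config$outdir, "concentrations.csv"))
      utils::write.csv(
        data.frame(sample_id = rownames(predictions), predictions,
                   check.names = FALSE),
        file.path(config$outdir, "predictions.csv"), row.names = FALSE)
      write_report(report, file.path(config$outdir, "report.json"))
      if (length(zreports) + length(treports) > 0) {
        render_charts(c(zreports, treports),
                      file.path(config$outdir, "charts"))
      }
    })
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> nutrispec %s, seed %d, split %d/%d\n",
              x$package_version, x$seed, x$split$train_n, x$split$test_n))
  tab <- x$analytes
  tab$rmse <- signif(tab$rmse, 4)
  tab$r2 <- signif(tab$r2, 4)
  tab$rpd <- signif(tab$rpd, 4)
  print(tab, row.names = FALSE)
  for (an in names(x$tolerance)) {
    t <- x$tolerance[[an]]
    cat(sprintf("tolerance [%s as %s]: %d of %d inside (%.1f%%)\n",
                an, t$basis, t$n_inside, t$n, t$percent_inside))
  }
  invisible(x)
}
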