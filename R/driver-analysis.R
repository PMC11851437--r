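#' Covariates consumed by the driver analysis
#'
#' @return Character vector of the 11 covariate names: human pressure (GDP,
#'   LUR, CTP) and environmental filtering (WA, VR, TEM, PRE, NRAD, HT, DWN,
#'   ALT).
#' @export
driver_covariates <- function() {
  c("WA", "VR", "TEM", "PRE", "NRAD", "LUR", "HT", "GDP", "DWN", "CTP", "ALT")
}

#' Prepare the covariate model matrix
#'
#' Continuous covariates are `log10(x + 1)` transformed; ordinal covariates
#' (habitat type HT and the connectivity class CTP by default) pass through
#' untransformed. Negative continuous values are an error (the transform is
#' undefined there).
#'
#' @param metadata Site metadata tibble with a `site` column and the
#'   covariates of [driver_covariates()].
#' @param covariates Covariate columns to keep.
#' @param ordinal Covariates passed through untransformed.
#' @return Tibble `site` + transformed covariates, with attribute
#'   `transformed` naming the log-transformed columns.
#' @export
prepare_covariates <- function(metadata, covariates = driver_covariates(),
                               ordinal = c("HT", "CTP")) {
  metadata <- tibble::as_tibble(metadata)
  missing_c <- setdiff(covariates, names(metadata))
  if (length(missing_c)) abort(paste0("missing covariate(s): ",
                                      paste(missing_c, collapse = ", ")))
  out <- metadata[c("site", covariates)]
  logged <- character()
  for (cv in setdiff(covariates, ordinal)) {
    x <- as.numeric(out[[cv]])
    if (any(x < 0, na.rm = TRUE)) {
      abort(sprintf("covariate %s has negative values; log10(x + 1) undefined", cv))
    }
    out[[cv]] <- log10(x + 1)
    logged <- c(logged, cv)
  }
  for (cv in intersect(ordinal, covariates)) out[[cv]] <- as.numeric(out[[cv]])
  attr(out, "transformed") <- logged
  out
}

#' Random-forest driver model with leave-one-out validation
#'
#' Fits a seeded regression forest of the response on the covariates and
#' reports both permutation importance (%IncMSE) and node-purity importance
#' (IncNodePurity), the out-of-bag explained variance
#' \eqn{100 (1 - MSE_{oob} / \widehat{Var}(y))}, and (optionally)
#' leave-one-out predictions from refitting the forest with each site held
#' out, summarised as a LOO \eqn{R^2}.
#'
#' @param data Tibble: `site` column (optional), the response column, and
#'   covariate columns (e.g. a join of scorecard totals with
#'   [prepare_covariates()] output).
#' @param response Name of the response column.
#' @param covariates Covariate columns; default: all numeric columns except
#'   the response and `site`.
#' @param seed Integer seed (mandatory: forests are stochastic).
#' @param n_trees Number of trees.
#' @param mtry Features tried per split; default one third of the
#'   covariates (regression-forest convention).
#' @param loo Compute leave-one-out predictions (one refit per site)?
#' @return Object of class `fibir_driver`: list with `response`,
#'   `importance` (tibble: covariate, inc_mse_pct, inc_node_purity),
#'   `pct_var_oob`, `loo` (tibble: site, observed, predicted, residual),
#'   `loo_r2`, `n_trees`, `mtry`, `seed` and the fitted `forest`.
#' @export
fit_driver_model <- function(data, response, covariates = NULL, seed,
                             n_trees = 1000, mtry = NULL, loo = TRUE) {
  data <- tibble::as_tibble(data)
  if (!response %in% names(data)) abort(sprintf("response '%s' not found", response))
  covariates <- covariates %||%
    setdiff(names(data)[vapply(data, is.numeric, logical(1))], c(response, "site"))
  if (nrow(data) < 8) abort("need at least 8 sites to fit a driver model")
  y <- data[[response]]
  if (sd(y) == 0) abort(sprintf("response '%s' is constant across sites", response))
  x <- as.data.frame(data[covariates])
  mtry <- mtry %||% max(1L, floor(length(covariates) / 3))
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees, mtry = mtry,
                                   importance = TRUE)
  imp <- randomForest::importance(rf)
  importance <- tibble::tibble(
    covariate = rownames(imp),
    inc_mse_pct = unname(imp[, "%IncMSE"]),
    inc_node_purity = unname(imp[, "IncNodePurity"])
  )
  pct_var_oob <- 100 * (1 - rf$mse[n_trees] / ((length(y) - 1) / length(y) * var(y)))
  loo_tab <- NULL; loo_r2 <- NA_real_
  if (loo) {
    pred <- vapply(seq_along(y), function(i) {
      set.seed(seed + i)
      fit <- randomForest::randomForest(x = x[-i, , drop = FALSE], y = y[-i],
                                        ntree = n_trees, mtry = mtry)
      unname(predict(fit, x[i, , drop = FALSE]))
    }, numeric(1))
    loo_tab <- tibble::tibble(
      site = if ("site" %in% names(data)) data$site else as.character(seq_along(y)),
      observed = y, predicted = pred, residual = y - pred)
    loo_r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  }
  structure(list(response = response, importance = importance,
                 pct_var_oob = pct_var_oob, loo = loo_tab, loo_r2 = loo_r2,
                 n_trees = n_trees, mtry = mtry, seed = seed, forest = rf),
            class = "fibir_driver")
}

#' @export
print.fibir_driver <- function(x, ...) {
  cat(sprintf("<fibir_driver> response '%s': %.1f%% variance explained (OOB)",
              x$response, x$pct_var_oob))
  if (!is.null(x$loo)) cat(sprintf(", LOO R2 = %.2f", x$loo_r2))
  cat("\n")
  top <- top_drivers(x)
  cat("top drivers:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Top drivers by agreement of both importance measures
#'
#' Covariates ranking in the top `n` on *both* %IncMSE and IncNodePurity;
#' remaining slots (when the two rankings disagree) are filled by
#' permutation-importance rank.
#'
#' @param model A [fit_driver_model()] result.
#' @param n Number of drivers to report.
#' @return Character vector of covariate names, length `n`.
#' @export
top_drivers <- function(model, n = 4) {
  imp <- model$importance
  by_mse <- imp$covariate[order(-imp$inc_mse_pct)]
  by_purity <- imp$covariate[order(-imp$inc_node_purity)]
  both <- intersect(by_mse[seq_len(n)], by_purity[seq_len(n)])
  both <- both[order(match(both, by_mse))]
  c(both, setdiff(by_mse, both))[seq_len(min(n, nrow(imp)))]
}

#' Response-curve fits for the top drivers
#'
#' For each covariate, fits nested polynomial least-squares models of the
#' response (degrees 1 to `max_degree`) and reports the lowest degree whose
#' incremental term is no longer needed: the selected fit is the highest
#' degree whose added term is significant at `alpha` by the nested-model
#' F-test, starting from the linear fit.
#'
#' @param data Tibble holding the response and covariates.
#' @param response Response column name.
#' @param covariates Covariates to fit (e.g. [top_drivers()] output).
#' @param max_degree Highest polynomial degree considered.
#' @param alpha Significance level of the incremental F-test.
#' @return Tibble: `covariate`, `degree`, `r_squared`, `slope_p` (linear
#'   term p-value), `significant` (is the selected fit's highest-order term,
#'   or the slope for linear fits, significant?), and a `model` list-column
#'   of `lm` objects.
#' @export
fit_response_curves <- function(data, response, covariates, max_degree = 3,
                                alpha = 0.05) {
  data <- tibble::as_tibble(data)
  y <- data[[response]]
  purrr::map_dfr(covariates, function(cv) {
    x <- data[[cv]]
    if (length(y) <= max_degree + 1) abort("fewer points than parameters")
    d <- data.frame(y = y, x = x)
    fits <- lapply(seq_len(max_degree), function(deg) {
      lm(y ~ poly(x, degree = deg, raw = TRUE), data = d)
    })
    tss <- sum((y - mean(y))^2)
    deg <- 1L
    while (deg < max_degree) {
      # an (effectively) exact fit cannot be improved; stop before the
      # nested F-test divides by a zero residual
      if (sum(stats::residuals(fits[[deg]])^2) <= 1e-10 * tss) break
      a <- suppressWarnings(anova(fits[[deg]], fits[[deg + 1]]))
      pval <- a[["Pr(>F)"]][2]
      if (is.na(pval) || pval >= alpha) break
      deg <- deg + 1L
    }
    fit <- fits[[deg]]
    sm <- suppressWarnings(summary(fit))
    coefs <- sm$coefficients
    slope_p <- if (nrow(coefs) >= 2) coefs[2, 4] else NA_real_
    top_p <- coefs[nrow(coefs), 4]
    tibble::tibble(covariate = cv, degree = deg,
                   r_squared = sm$r.squared,
                   slope_p = slope_p,
                   significant = isTRUE(top_p < alpha) ||
                     (deg == 1 && isTRUE(sm$r.squared > 1 - 1e-10)),
                   model = list(fit))
  })
}

#' One driver model per sensitive metric
#'
#' Fits [fit_driver_model()] to each sensitive metric's score column of a
#' scorecard. A metric whose scores are constant across sites cannot be
#' modelled; its entry records the error and the remaining metrics are
#' unaffected.
#'
#' @param scorecard A [score_sites()] result.
#' @param covariate_data [prepare_covariates()] output.
#' @param seed Integer seed; each metric m uses `seed + m`.
#' @param ... Passed to [fit_driver_model()].
#' @return Named list (one element per metric) of `fibir_driver` objects or
#'   `condition` objects where fitting failed.
#' @export
per_metric_models <- function(scorecard, covariate_data, seed, ...) {
  stopifnot(inherits(scorecard, "fibir_scorecard"))
  wide <- scorecard$scores |>
    dplyr::select("site", "metric", "score") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "score")
  dat <- dplyr::inner_join(wide, tibble::as_tibble(covariate_data), by = "site")
  mets <- setdiff(names(wide), "site")
  out <- lapply(seq_along(mets), function(i) {
    tryCatch(
      fit_driver_model(dat[c("site", mets[i], setdiff(names(covariate_data), "site"))],
                       response = mets[i], seed = seed + i, ...),
      error = function(e) e
    )
  })
  names(out) <- mets
  out
}
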