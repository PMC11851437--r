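#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a scorecard into the long per-metric score table
#'
#' @param x A [score_sites()] result.
#' @param ... Unused.
#' @return Long tibble: site, group, metric, current, reference, max,
#'   direction, score.
#' @method tidy fibir_scorecard
#' @export
tidy.fibir_scorecard <- function(x, ...) x$scores

#' One-row summary of a scorecard
#'
#' @param x A [score_sites()] result.
#' @param ... Unused.
#' @return Tibble: n_sites, n_metrics, expected_total, mean/min/max total,
#'   and grade counts.
#' @method glance fibir_scorecard
#' @export
glance.fibir_scorecard <- function(x, ...) {
  tb <- table(x$totals$grade)
  tibble::tibble(
    n_sites = nrow(x$totals),
    n_metrics = x$expected_total,
    expected_total = x$expected_total,
    mean_total = mean(x$totals$total),
    min_total = min(x$totals$total),
    max_total = max(x$totals$total),
    n_excellent = unname(tb[["Excellent"]]),
    n_good = unname(tb[["Good"]]),
    n_fair = unname(tb[["Fair"]]),
    n_poor = unname(tb[["Poor"]]),
    n_very_poor = unname(tb[["Very Poor"]])
  )
}

#' Tidy a driver model into its importance table
#'
#' @param x A [fit_driver_model()] result.
#' @param ... Unused.
#' @return Tibble: covariate, inc_mse_pct, inc_node_purity, rank_mse,
#'   rank_purity.
#' @method tidy fibir_driver
#' @export
tidy.fibir_driver <- function(x, ...) {
  dplyr::mutate(x$importance,
                rank_mse = rank(-.data$inc_mse_pct, ties.method = "min"),
                rank_purity = rank(-.data$inc_node_purity, ties.method = "min"))
}

#' One-row summary of a driver model
#'
#' @param x A [fit_driver_model()] result.
#' @param ... Unused.
#' @return Tibble: response, pct_var_oob, loo_r2, n_trees, mtry.
#' @method glance fibir_driver
#' @export
glance.fibir_driver <- function(x, ...) {
  tibble::tibble(response = x$response, pct_var_oob = x$pct_var_oob,
                 loo_r2 = x$loo_r2, n_trees = x$n_trees, mtry = x$mtry)
}

#' Tidy a cluster solution into its assignment table
#'
#' @param x A [cluster_sites()] result.
#' @param ... Unused.
#' @method tidy fibir_clusters
#' @export
tidy.fibir_clusters <- function(x, ...) x$assignment

#' Tidy a gap-statistic result into its per-k table
#'
#' @param x An [optimal_k()] result.
#' @param ... Unused.
#' @method tidy fibir_gap
#' @export
tidy.fibir_gap <- function(x, ...) x$table

#' Tidy a TRCI result into the per-segment table with CTP ranks
#'
#' @param x A [trci()] result.
#' @param ... Unused.
#' @method tidy fibir_trci
#' @export
tidy.fibir_trci <- function(x, ...) ctp_ordinal(x)

#' Tidy a Hopkins result
#'
#' @param x A [hopkins_statistic()] result.
#' @param ... Unused.
#' @return One-row tibble: H, n, sum_r, sum_r_prime.
#' @method tidy fibir_hopkins
#' @export
tidy.fibir_hopkins <- function(x, ...) {
  tibble::tibble(H = x$H, n = x$n, sum_r = sum(x$r), sum_r_prime = sum(x$r_prime))
}
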