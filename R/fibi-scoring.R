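#' Ratio score of one metric against its reference
#'
#' For metrics that *decrease* under disturbance the score is
#' \eqn{SE_1 = C / R_{group}}; for metrics that *increase* it is
#' \eqn{SE_2 = (Max - C) / (Max - R_{group})}. Scores are clipped to
#' \[0, 1\] so that site totals are bounded by the expected total (one point
#' per sensitive metric). All arguments are vectorised and recycled.
#'
#' @param C Current metric value (%).
#' @param Rgroup Reference value of the site's cluster group (%); must be
#'   positive for decreasing metrics.
#' @param Max Scaling maximum (%) for increasing metrics; must exceed
#'   `Rgroup` where used.
#' @param direction `"decrease"` or `"increase"`.
#' @return Numeric score(s) in \[0, 1\].
#' @export
#' @examples
#' score_metric(11.5, 23, direction = "decrease")       # 0.5
#' score_metric(50, 40, 60, direction = "increase")     # 0.5
score_metric <- function(C, Rgroup, Max = NA_real_, direction) {
  n <- max(length(C), length(Rgroup), length(Max), length(direction))
  C <- rep_len(C, n); Rgroup <- rep_len(Rgroup, n)
  Max <- rep_len(Max, n); direction <- rep_len(direction, n)
  if (!all(direction %in% c("decrease", "increase"))) {
    abort("direction must be 'decrease' or 'increase'")
  }
  dec <- direction == "decrease"
  if (any(dec & Rgroup <= 0)) abort("Rgroup must be > 0 for decreasing metrics")
  if (any(!dec & (is.na(Max) | Max <= Rgroup))) {
    abort("Max must exceed Rgroup for increasing metrics")
  }
  score <- ifelse(dec, C / Rgroup, (Max - C) / (Max - Rgroup))
  pmin(pmax(score, 0), 1)
}

#' Five-band grade of a site total
#'
#' The grading scale is anchored at the 95th percentile of the expected
#' total score, \eqn{P_{95} = 0.95 \times} `expected_total`. Totals above
#' \eqn{P_{95}} grade `Excellent`; the interval \eqn{[0, P_{95}]} is split
#' into four equal lower-inclusive bands graded, from the bottom,
#' `Very Poor`, `Poor`, `Fair`, `Good`.
#'
#' @param total Site total score(s), non-negative.
#' @param expected_total Number of sensitive metrics (each contributing a
#'   maximum of 1); must be positive.
#' @return Ordered factor with levels `Very Poor < Poor < Fair < Good <
#'   Excellent`.
#' @export
#' @examples
#' fibi_grade(c(0, 4.5, 7.8), expected_total = 8)
fibi_grade <- function(total, expected_total) {
  if (expected_total <= 0) abort("expected_total must be positive")
  if (any(total < 0)) abort("total scores cannot be negative")
  p95 <- 0.95 * expected_total
  width <- p95 / 4
  levels <- c("Very Poor", "Poor", "Fair", "Good", "Excellent")
  idx <- ifelse(total > p95, 5L, pmin(floor(total / width), 3) + 1L)
  factor(levels[idx], levels = levels, ordered = TRUE)
}

#' Score sites against their cluster-group references
#'
#' Builds the full scorecard: each retained sensitive metric is scored by
#' [score_metric()] against the reference value of the site's cluster group,
#' per-site totals are the metric-score sums, the expected total is the
#' number of sensitive metrics, and grades follow [fibi_grade()].
#'
#' The scaling maximum of an increasing metric defaults to the largest value
#' the metric attains across all current sites and all group references
#' (`max_rule = "data"`, which guarantees scores in \[0, 1\] on the data at
#' hand); alternatives are the theoretical 100% or the reference-only
#' maximum. In the degenerate case where no current value exceeds the
#' reference maximum, all sites sit at or better than reference and the
#' metric scores 1 everywhere (with a warning).
#'
#' @param metric_curr Current per-site metric table ([metric_values()]).
#' @param refset A [pool_references()] result (carries the site-to-group
#'   assignment and the reference values).
#' @param screening A [run_screening()] report, or any tibble with `metric`
#'   and `direction` columns for the metrics to score.
#' @param max_rule How to set `Max` for increasing metrics.
#' @return Object of class `fibir_scorecard`: list with `scores` (long
#'   tibble: site, group, metric, current, reference, max, direction,
#'   score), `totals` (tibble: site, group, total, expected_total, grade)
#'   and `expected_total`.
#' @export
score_sites <- function(metric_curr, refset, screening,
                        max_rule = c("data", "theoretical", "reference")) {
  max_rule <- match.arg(max_rule)
  stopifnot(inherits(refset, "fibir_reference_set"))
  metric_curr <- tibble::as_tibble(metric_curr)
  sel <- if (inherits(screening, "fibir_screening")) retained_metrics(screening)
         else tibble::as_tibble(screening)[, c("metric", "direction")]
  if (!nrow(sel)) abort("no sensitive metrics to score")
  missing_m <- setdiff(sel$metric, names(metric_curr))
  if (length(missing_m)) abort(paste0("metrics absent from current table: ",
                                      paste(missing_m, collapse = ", ")))
  assignment <- refset$assignment
  unassigned <- setdiff(metric_curr$site, assignment$site)
  if (length(unassigned)) abort(paste0("site(s) without cluster group: ",
                                       paste(unassigned, collapse = ", ")))
  grp <- assignment$group[match(metric_curr$site, assignment$site)]
  scores <- purrr::map_dfr(seq_len(nrow(sel)), function(i) {
    m <- sel$metric[i]; dir <- sel$direction[i]
    refv <- refset$values[[m]][match(grp, refset$values$group)]
    curv <- metric_curr[[m]]
    mx <- switch(max_rule,
                 data = max(c(curv, refset$values[[m]])),
                 theoretical = 100,
                 reference = max(refset$values[[m]]))
    if (dir == "increase" && mx <= max(refv)) {
      warn(sprintf(
        "metric %s: scaling maximum does not exceed the reference; scoring 1 at or below reference", m))
      sc <- as.numeric(curv <= refv)
    } else {
      sc <- score_metric(curv, refv, mx, dir)
    }
    tibble::tibble(site = metric_curr$site, group = grp, metric = m,
                   current = curv, reference = refv,
                   max = if (dir == "increase") mx else NA_real_,
                   direction = dir, score = sc)
  })
  expected <- nrow(sel)
  totals <- scores |>
    dplyr::group_by(.data$site, .data$group) |>
    dplyr::summarise(total = sum(.data$score), .groups = "drop") |>
    dplyr::mutate(expected_total = expected,
                  grade = fibi_grade(.data$total, expected))
  totals <- totals[match(metric_curr$site, totals$site), ]
  structure(list(scores = scores, totals = totals, expected_total = expected),
            class = "fibir_scorecard")
}

#' @export
print.fibir_scorecard <- function(x, ...) {
  cat(sprintf("<fibir_scorecard> %d sites, %d sensitive metrics (expected total %d)\n",
              nrow(x$totals), x$expected_total, x$expected_total))
  print(x$totals)
  invisible(x)
}

#' Compare F-IBI scores between habitat types
#'
#' For the per-site totals and each sensitive metric's current values,
#' tests the difference between the two habitat classes (natural
#' free-flowing reaches, NRAD, vs reservoir transition zones, TR):
#' a Kolmogorov-Smirnov normality check per group (against a normal with
#' the sample moments), a variance-ratio check, and a two-sample t-test
#' (equal-variance by default, Welch when the variance check fails at
#' `var_alpha`).
#'
#' @param scorecard A [score_sites()] result.
#' @param metadata Site metadata with `site` and `habitat_type` columns.
#' @param var_alpha Significance level of the variance-ratio pre-test.
#' @return Tibble: one row per response (`total` plus each metric) with
#'   group means, KS normality p-values, the variance-check p, `t`, `df`
#'   and two-sided `p`.
#' @export
compare_habitats <- function(scorecard, metadata, var_alpha = 0.05) {
  stopifnot(inherits(scorecard, "fibir_scorecard"))
  metadata <- tibble::as_tibble(metadata)
  ht <- metadata$habitat_type[match(scorecard$totals$site, metadata$site)]
  if (anyNA(ht)) abort("every scored site needs a habitat_type in metadata")
  ht <- factor(ht, levels = c("NRAD", "TR"))
  groups_n <- table(ht)
  if (any(groups_n < 2)) abort("each habitat group needs at least 2 sites")

  responses <- c(list(total = scorecard$totals$total),
                 split_metric_columns(scorecard))
  purrr::imap_dfr(responses, function(x, nm) {
    a <- x[ht == "NRAD"]; b <- x[ht == "TR"]
    ks <- function(v) {
      if (sd(v) == 0) return(NA_real_)
      suppressWarnings(ks.test(v, "pnorm", mean(v), sd(v))$p.value)
    }
    vp <- if (sd(a) == 0 && sd(b) == 0) 1
          else suppressWarnings(var.test(a, b)$p.value)
    equal_var <- is.na(vp) || vp >= var_alpha
    tt <- tryCatch(t.test(a, b, var.equal = equal_var),
                   error = function(e) NULL)
    tibble::tibble(
      response = nm,
      mean_NRAD = mean(a), mean_TR = mean(b),
      ks_p_NRAD = ks(a), ks_p_TR = ks(b),
      var_p = vp, equal_var = equal_var,
      t = if (is.null(tt)) { if (mean(a) == mean(b)) 0 else NA_real_ }
          else unname(tt$statistic),
      df = if (is.null(tt)) length(c(a, b)) - 2 else unname(tt$parameter),
      p = if (is.null(tt)) { if (mean(a) == mean(b)) 1 else NA_real_ }
          else tt$p.value
    )
  })
}

# named list of per-site current values, one element per scored metric
split_metric_columns <- function(scorecard) {
  wide <- scorecard$scores |>
    dplyr::select("site", "metric", "current") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "current")
  wide <- wide[match(scorecard$totals$site, wide$site), ]
  as.list(wide[setdiff(names(wide), "site")])
}
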