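#' Redundancy screen on species-level trait vectors
#'
#' Spearman correlations are computed between the binary trait columns of
#' the species pool. For every pair with \eqn{|r| \ge} `threshold`, the
#' member with the *larger* absolute correlation to the anchor trait
#' (endemic species by default) is removed; the anchor itself is never
#' removed. When both members tie on anchor correlation, the first member
#' found in `priority` is dropped.
#'
#' @param traits Trait tibble (see [validate_traits()]).
#' @param anchor Anchor trait retained unconditionally; tie-breaks favour
#'   the metric less correlated with it.
#' @param threshold Absolute Spearman correlation defining collinearity,
#'   in (0, 1).
#' @param priority Character vector: metrics to drop first on exact ties.
#' @param candidates Traits to screen (default: all traits present).
#' @return List with `retained` (character vector) and `report`, a tibble
#'   with one row per candidate: `metric`, `removed` (logical), `partner`,
#'   `r_partner`, `r_anchor`.
#' @export
redundancy_screen <- function(traits, anchor = "EF", threshold = 0.60,
                              priority = c("CF", "STF"), candidates = NULL) {
  traits <- validate_traits(traits)
  candidates <- candidates %||% setdiff(names(traits), "species")
  if (!anchor %in% names(traits)) abort(sprintf("anchor trait '%s' missing", anchor))
  if (threshold <= 0 || threshold >= 1) abort("threshold must lie in (0, 1)")
  cols <- union(anchor, candidates)
  m <- as.matrix(traits[cols])
  suppressWarnings(rho <- cor(m, method = "spearman"))
  rho[is.na(rho)] <- 0
  r_anchor <- abs(rho[, anchor])
  retained <- candidates
  report <- tibble::tibble(metric = candidates, removed = FALSE,
                           partner = NA_character_, r_partner = NA_real_,
                           r_anchor = unname(r_anchor[candidates]))
  pairs <- which(abs(rho) >= threshold & upper.tri(rho), arr.ind = TRUE)
  if (nrow(pairs)) {
    ord <- order(-abs(rho[pairs]))
    for (p in ord) {
      a <- rownames(rho)[pairs[p, 1]]; b <- colnames(rho)[pairs[p, 2]]
      if (!(a %in% retained) || !(b %in% retained)) next
      if (!(a %in% candidates) || !(b %in% candidates)) next
      drop <- if (a == anchor) b else if (b == anchor) a
      else if (r_anchor[a] > r_anchor[b]) a
      else if (r_anchor[b] > r_anchor[a]) b
      else {
        hit <- intersect(priority, c(a, b))
        if (length(hit)) hit[1] else b
      }
      keep <- setdiff(c(a, b), drop)
      retained <- setdiff(retained, drop)
      i <- match(drop, report$metric)
      report$removed[i] <- TRUE
      report$partner[i] <- keep
      report$r_partner[i] <- rho[a, b]
    }
  }
  list(retained = retained, report = report)
}

#' Box-plot discrimination power (IQ score)
#'
#' Scores how well a metric separates reference from impaired samples by
#' interquartile-range overlap (quartiles by linear interpolation, type 7):
#' * **3** - the two IQRs are disjoint (very strong discrimination);
#' * **2** - IQRs overlap but neither median lies inside the other IQR;
#' * **1** - exactly one median lies inside the other IQR;
#' * **0** - each median lies inside the other IQR.
#'
#' The score is symmetric in its arguments for values 0 and 3.
#'
#' @param reference,impaired Numeric vectors of metric values (>= 3 each).
#' @return Integer in `0:3`.
#' @export
#' @examples
#' discrimination_power(c(30, 32, 34, 36, 38), c(10, 12, 14, 16, 18))  # 3
#' discrimination_power(1:5, 1:5)                                      # 0
discrimination_power <- function(reference, impaired) {
  if (length(reference) < 3 || length(impaired) < 3) {
    abort("each sample needs at least 3 values")
  }
  qr <- quantile(reference, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  qi <- quantile(impaired, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  if (qr[3] < qi[1] || qi[3] < qr[1]) return(3L)
  ref_med_in <- qr[2] >= qi[1] && qr[2] <= qi[3]
  imp_med_in <- qi[2] >= qr[1] && qi[2] <= qr[3]
  if (!ref_med_in && !imp_med_in) 2L else if (ref_med_in && imp_med_in) 0L else 1L
}

#' Trend-sensitivity screen
#'
#' A metric is sensitive to environmental stress only if its current value
#' departs from the reference value *in the same strict direction at every
#' site*: all positive deltas retain the metric with direction `increase`,
#' all negative with `decrease`; any mixed signs or exact zeros mark it
#' insensitive (removed).
#'
#' @param reference,current Tibbles (or data frames) of per-site metric
#'   values with matching `site` columns and metric columns.
#' @return Tibble: `metric`, `n_increase`, `n_decrease`, `n_zero`,
#'   `sensitive` (logical), `direction` (`"increase"`, `"decrease"` or NA),
#'   `trend` (per-site sign string, sites in input order).
#' @export
sensitivity_screen <- function(reference, current) {
  reference <- tibble::as_tibble(reference)
  current <- tibble::as_tibble(current)
  if (!"site" %in% names(reference) || !"site" %in% names(current)) {
    abort("both tables need a 'site' column")
  }
  if (!setequal(reference$site, current$site)) {
    abort(paste0("unpaired sites: ",
                 paste(c(setdiff(reference$site, current$site),
                         setdiff(current$site, reference$site)), collapse = ", ")))
  }
  current <- current[match(reference$site, current$site), ]
  mets <- intersect(setdiff(names(reference), "site"), setdiff(names(current), "site"))
  if (!length(mets)) abort("no shared metric columns")
  purrr::map_dfr(mets, function(m) {
    delta <- current[[m]] - reference[[m]]
    npos <- sum(delta > 0); nneg <- sum(delta < 0); nzero <- sum(delta == 0)
    sens <- (npos == length(delta)) || (nneg == length(delta))
    tibble::tibble(
      metric = m, n_increase = npos, n_decrease = nneg, n_zero = nzero,
      sensitive = sens,
      direction = if (npos == length(delta)) "increase"
                  else if (nneg == length(delta)) "decrease" else NA_character_,
      trend = paste(ifelse(delta > 0, "+", ifelse(delta < 0, "-", "0")),
                    collapse = "")
    )
  })
}

#' Full three-stage metric screening
#'
#' Applies, in order: (1) the redundancy screen on species-level trait
#' vectors; (2) the discrimination-power screen, retaining metrics whose IQ
#' score (historical site values vs current site values) reaches `iq_min`;
#' (3) the trend-sensitivity screen on paired per-site values. Every
#' candidate metric appears exactly once in the report with a definite fate.
#'
#' @param metric_hist,metric_curr Per-site metric tables (tibbles with
#'   `site` plus metric columns), e.g. from [metric_values()] on the
#'   historical and current occurrence matrices.
#' @param traits Trait tibble for the redundancy stage.
#' @param candidates Metrics to screen; default: all metric columns shared
#'   by both tables.
#' @param iq_min Minimum IQ score retained at the discrimination stage.
#' @inheritParams redundancy_screen
#' @return Object of class `fibir_screening`: a tibble with one row per
#'   candidate (`metric`, `fate`, `partner`, `r_partner`, `r_anchor`, `iq`,
#'   `direction`, `trend`), where `fate` is one of `removed_redundancy`,
#'   `removed_discrimination`, `removed_sensitivity`, `retained`.
#' @export
run_screening <- function(metric_hist, metric_curr, traits,
                          anchor = "EF", threshold = 0.60,
                          priority = c("CF", "STF"),
                          candidates = NULL, iq_min = 3) {
  metric_hist <- tibble::as_tibble(metric_hist)
  metric_curr <- tibble::as_tibble(metric_curr)
  candidates <- candidates %||%
    intersect(setdiff(names(metric_hist), "site"), setdiff(names(metric_curr), "site"))
  if (!length(candidates)) {
    warn("no candidate metrics supplied; returning empty report")
    return(structure(tibble::tibble(
      metric = character(), fate = character(), partner = character(),
      r_partner = double(), r_anchor = double(), iq = integer(),
      direction = character(), trend = character()
    ), class = c("fibir_screening", "tbl_df", "tbl", "data.frame")))
  }
  red <- redundancy_screen(traits, anchor = anchor, threshold = threshold,
                           priority = priority, candidates = candidates)
  report <- red$report
  report$fate <- ifelse(report$removed, "removed_redundancy", NA_character_)
  report$iq <- NA_integer_
  report$direction <- NA_character_
  report$trend <- NA_character_

  for (m in red$retained) {
    i <- match(m, report$metric)
    report$iq[i] <- discrimination_power(metric_hist[[m]], metric_curr[[m]])
    if (report$iq[i] < iq_min) report$fate[i] <- "removed_discrimination"
  }
  survivors <- report$metric[is.na(report$fate)]
  if (length(survivors)) {
    sens <- sensitivity_screen(metric_hist[c("site", survivors)],
                               metric_curr[c("site", survivors)])
    for (m in survivors) {
      i <- match(m, report$metric)
      j <- match(m, sens$metric)
      report$trend[i] <- sens$trend[j]
      if (sens$sensitive[j]) {
        report$fate[i] <- "retained"
        report$direction[i] <- sens$direction[j]
      } else {
        report$fate[i] <- "removed_sensitivity"
      }
    }
  }
  out <- report[c("metric", "fate", "partner", "r_partner", "r_anchor",
                  "iq", "direction", "trend")]
  class(out) <- c("fibir_screening", class(out))
  out
}

#' Retained sensitive metrics of a screening report
#'
#' @param report A [run_screening()] result.
#' @return Tibble with `metric` and `direction` for retained metrics.
#' @export
retained_metrics <- function(report) {
  report <- tibble::as_tibble(report)
  report[report$fate == "retained", c("metric", "direction")]
}
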