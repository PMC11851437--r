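test_that("ratio scores reproduce the defining equations", {
  expect_equal(score_metric(23, 23, direction = "decrease"), 1)
  expect_equal(score_metric(11.5, 23, direction = "decrease"), 0.5)
  expect_equal(score_metric(40, 40, 60, direction = "increase"), 1)
  expect_equal(score_metric(50, 40, 60, direction = "increase"), 0.5)
  expect_equal(score_metric(60, 40, 60, direction = "increase"), 0)
  # clipping to [0, 1]
  expect_equal(score_metric(50, 23, direction = "decrease"), 1)
  expect_equal(score_metric(10, 40, 60, direction = "increase"), 1)
  expect_error(score_metric(5, 0, direction = "decrease"), "Rgroup")
  expect_error(score_metric(5, 40, 40, direction = "increase"), "Max")
  expect_error(score_metric(5, 4, 6, direction = "sideways"), "direction")
})

test_that("scores are monotone in the current value", {
  cs <- seq(0, 23, length.out = 30)
  s_dec <- score_metric(cs, 23, direction = "decrease")
  expect_true(all(diff(s_dec) >= 0))
  cs2 <- seq(40, 60, length.out = 30)
  s_inc <- score_metric(cs2, 40, 60, direction = "increase")
  expect_true(all(diff(s_inc) <= 0))
  expect_true(all(s_dec >= 0 & s_dec <= 1 & s_inc >= 0 & s_inc <= 1))
})

test_that("grades follow the 95th-percentile band arithmetic", {
  # expected total 8: P95 = 7.6, band width 1.9
  expect_equal(as.character(fibi_grade(7.8, 8)), "Excellent")
  expect_equal(as.character(fibi_grade(7.61, 8)), "Excellent")
  expect_equal(as.character(fibi_grade(7.6, 8)), "Good")
  expect_equal(as.character(fibi_grade(5.7, 8)), "Good")
  expect_equal(as.character(fibi_grade(4.5, 8)), "Fair")
  expect_equal(as.character(fibi_grade(3.8, 8)), "Fair")
  expect_equal(as.character(fibi_grade(1.9, 8)), "Poor")
  expect_equal(as.character(fibi_grade(0, 8)), "Very Poor")
  expect_error(fibi_grade(-1, 8), "negative")
  expect_error(fibi_grade(1, 0), "positive")
})

test_that("grade bands are exhaustive and non-overlapping", {
  totals <- seq(0, 12, by = 0.01)
  g <- fibi_grade(totals, 8)
  expect_false(anyNA(g))
  # grade is non-decreasing in the total
  expect_true(all(diff(as.integer(g)) >= 0))
  # each band spans width 1.9 below P95
  expect_equal(range(totals[g == "Fair"]), c(3.8, 5.69))
})

test_that("a site matching its pooled reference earns the expected total", {
  sp <- sprintf("s%02d", 1:20)
  occ <- occ_from_sets(list(only = sp), era = "historical")
  tr <- traits_from_cols(sp,
                         CUF = rep(c(1, 0), 10),
                         NFM = rep(c(1, 1, 0, 0), 5))
  refs <- pool_references(occ, tibble::tibble(site = "only", group = 1), tr)
  cur <- metric_values(occ, tr)  # current equals the pooled reference
  sel <- tibble::tibble(metric = c("CUF", "NFM"),
                        direction = c("decrease", "increase"))
  sc <- score_sites(cur, refs, sel, max_rule = "theoretical")
  expect_equal(sc$totals$total, 2)
  expect_equal(sc$expected_total, 2)
  expect_true(all(sc$scores$score == 1))
})

test_that("scorecards stay within bounds and demand complete assignments", {
  scn <- simulate_scenario(scenario_config(seed = 13))
  mh <- metric_values(scn$historical, scn$traits)
  mc <- metric_values(scn$current, scn$traits)
  refs <- pool_references(scn$historical, scn$groups, scn$traits)
  rep <- run_screening(mh, mc, scn$traits, candidates = screening_candidates)
  sc <- score_sites(mc, refs, rep)
  expect_true(all(sc$scores$score >= 0 & sc$scores$score <= 1))
  expect_true(all(sc$totals$total >= 0 & sc$totals$total <= sc$expected_total))
  expect_false(anyNA(sc$totals$grade))

  bad <- mc; bad$site[1] <- "unknown_site"
  expect_error(score_sites(bad, refs, rep), "without cluster group")
})

test_that("habitat comparison matches the closed-form equal-variance t", {
  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  # closed form: pooled sd and df = n1 + n2 - 2
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))

  sp <- sprintf("s%02d", 1:20)
  occ <- occ_from_sets(setNames(replicate(8, sample(sp, 15), simplify = FALSE),
                                paste0("site", 1:8)), era = "historical")
  tr <- traits_from_cols(sp, CUF = rep(c(1, 0), 10))
  refs <- pool_references(occ, tibble::tibble(site = occ$site, group = 1), tr)
  sel <- tibble::tibble(metric = "CUF", direction = "decrease")
  cur <- metric_values(occ, tr)
  sc <- score_sites(cur, refs, sel)
  sc$totals$total <- c(a, b)  # inject the worked example totals
  meta <- tibble::tibble(site = occ$site,
                         habitat_type = rep(c("NRAD", "TR"), each = 4))
  cmp <- compare_habitats(sc, meta)
  row <- cmp[cmp$response == "total", ]
  expect_true(row$equal_var)
  expect_equal(row$t, t_hand, tolerance = 1e-10)
  expect_equal(row$df, 6)
  expect_equal(row$p, 2 * pt(t_hand, df = 6), tolerance = 1e-10)

  # identical groups: t = 0, p = 1
  sc$totals$total <- rep(c(1, 2, 3, 4), 2)
  cmp2 <- compare_habitats(sc, meta)
  expect_equal(cmp2$t[cmp2$response == "total"], 0)
  expect_equal(cmp2$p[cmp2$response == "total"], 1)

  meta3 <- meta; meta3$habitat_type <- c("NRAD", rep("TR", 7))
  expect_error(compare_habitats(sc, meta3), "at least 2 sites")
})

test_that("scorecard tidiers expose scores and summaries", {
  scn <- simulate_scenario(scenario_config(seed = 17))
  mc <- metric_values(scn$current, scn$traits)
  refs <- pool_references(scn$historical, scn$groups, scn$traits)
  sc <- score_sites(mc, refs, planted_directions)
  td <- tidy(sc)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 12 * nrow(planted_directions))
  gl <- glance(sc)
  expect_equal(gl$n_sites, 12)
  expect_equal(gl$n_excellent + gl$n_good + gl$n_fair + gl$n_poor + gl$n_very_poor, 12)
  expect_s3_class(autoplot(sc), "ggplot")
})
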