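test_that("discrimination power follows the box-plot overlap rule", {
  # hand quartiles (type 7): disjoint IQRs
  expect_identical(discrimination_power(c(30, 32, 34, 36, 38),
                                        c(10, 12, 14, 16, 18)), 3L)
  # IQRs overlap, both medians outside the other IQR
  expect_identical(discrimination_power(c(10, 20, 30, 40, 50),
                                        c(25, 35, 45, 55, 65)), 2L)
  # identical samples: both medians inside
  expect_identical(discrimination_power(1:5, 1:5), 0L)
  # exactly one median inside the other IQR
  expect_identical(discrimination_power(c(10, 20, 30, 40, 50),
                                        c(32, 36, 40, 70, 90)), 1L)
  expect_error(discrimination_power(1:2, 1:5), "at least 3")
})

test_that("discrimination power is symmetric at its extremes", {
  set.seed(1)
  for (i in 1:20) {
    a <- runif(7, 0, 30); b <- runif(7, 0, 30) + sample(c(0, 40), 1)
    iq_ab <- discrimination_power(a, b)
    iq_ba <- discrimination_power(b, a)
    if (iq_ab %in% c(0L, 3L)) expect_identical(iq_ab, iq_ba)
  }
})

test_that("redundancy screen drops the collinear member closer to the anchor", {
  # A and B strongly correlated; B is more correlated with the anchor EF
  sp <- sprintf("s%02d", 1:12)
  ef <- c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  a  <- c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0)   # near zero r with EF
  b  <- c(1, 0, 1, 0, 1, 1, 1, 0, 1, 0, 0, 0)   # |r(A,B)| high, r(EF,B) > r(EF,A)
  tr <- traits_from_cols(sp, EF = ef, SF = a, MF = b)
  r_ab <- abs(cor(a, b, method = "spearman"))
  expect_gte(r_ab, 0.6)  # construction check
  expect_gt(abs(cor(ef, b)), abs(cor(ef, a)))
  res <- redundancy_screen(tr, anchor = "EF", threshold = 0.6)
  expect_true("SF" %in% res$retained)
  expect_false("MF" %in% res$retained)
  expect_equal(res$report$partner[res$report$metric == "MF"], "SF")
})

test_that("redundancy screen retains everything below threshold and the anchor always", {
  set.seed(2)
  sp <- sprintf("s%02d", 1:40)
  tr <- traits_from_cols(sp, EF = rbinom(40, 1, .5), SF = rbinom(40, 1, .5),
                         HYF = rbinom(40, 1, .5))
  res <- redundancy_screen(tr, anchor = "EF", threshold = 0.99)
  expect_setequal(res$retained, c("EF", "SF", "HYF"))

  # anchor vs strongly correlated partner: partner goes, anchor stays
  tr2 <- traits_from_cols(sp, EF = tr$EF, SF = as.integer(!tr$EF))
  res2 <- redundancy_screen(tr2, anchor = "EF", threshold = 0.6)
  expect_true("EF" %in% res2$retained)
  expect_false("SF" %in% res2$retained)
  expect_error(redundancy_screen(tr, anchor = "ZZ"), "unknown trait|anchor")
})

test_that("exact anchor-correlation ties defer to the priority list", {
  sp <- sprintf("s%02d", 1:8)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  tr <- traits_from_cols(sp, EF = c(1, 0, 1, 0, 1, 0, 1, 0),
                         CF = x, OF = as.integer(!x))  # both r(EF, .) == 0
  res <- redundancy_screen(tr, anchor = "EF", threshold = 0.6,
                           priority = c("CF", "STF"))
  expect_false("CF" %in% res$retained)
  expect_true("OF" %in% res$retained)
})

test_that("sensitivity screen demands a strict uniform trend", {
  ref <- tibble::tibble(site = paste0("s", 1:4), m1 = c(10, 20, 30, 40),
                        m2 = c(10, 20, 30, 40), m3 = c(10, 20, 30, 40))
  cur <- tibble::tibble(site = paste0("s", 1:4), m1 = c(12, 25, 31, 44),
                        m2 = c(8, 15, 29, 39), m3 = c(12, 18, 31, 44))
  out <- sensitivity_screen(ref, cur)
  expect_equal(out$direction, c("increase", "decrease", NA))
  expect_equal(out$sensitive, c(TRUE, TRUE, FALSE))
  expect_equal(out$trend[3], "+-++")

  # a single zero delta breaks the trend
  cur0 <- cur; cur0$m1[2] <- 20
  expect_false(sensitivity_screen(ref, cur0)$sensitive[1])
  expect_error(sensitivity_screen(ref, cur[-1, ]), "unpaired")
})

test_that("full screening assigns every candidate exactly one fate", {
  scn <- simulate_scenario(scenario_config(seed = 21))
  mh <- metric_values(scn$historical, scn$traits)
  mc <- metric_values(scn$current, scn$traits)
  rep <- run_screening(mh, mc, scn$traits, candidates = screening_candidates)
  expect_setequal(rep$metric, screening_candidates)
  expect_true(all(rep$fate %in% c("removed_redundancy", "removed_discrimination",
                                  "removed_sensitivity", "retained")))
  ret <- retained_metrics(rep)
  expect_true(all(!is.na(ret$direction)))
  # screening fate does not depend on candidate order
  rep2 <- run_screening(mh, mc, scn$traits, candidates = rev(screening_candidates))
  expect_equal(dplyr::arrange(tibble::as_tibble(rep), metric)$fate,
               dplyr::arrange(tibble::as_tibble(rep2), metric)$fate)
})

test_that("screening recovers the planted sensitive set", {
  ok <- vapply(1:10, function(s) {
    cfg <- scenario_config(seed = s,
                           disturbance = { set.seed(s + 500); runif(12, 0.7, 1) })
    tr <- simulate_pool(cfg)
    occ <- simulate_occurrence(cfg, tr)
    rep <- run_screening(metric_values(occ$historical, tr),
                         metric_values(occ$current, tr),
                         tr, candidates = screening_candidates)
    setequal(retained_metrics(rep)$metric, planted_metrics)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("empty candidate sets yield an empty report with a warning", {
  scn <- simulate_scenario(scenario_config(seed = 1))
  mh <- metric_values(scn$historical, scn$traits)
  expect_warning(
    rep <- run_screening(mh[, "site"], mh[, "site"], scn$traits),
    "no candidate"
  )
  expect_equal(nrow(rep), 0)
})
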