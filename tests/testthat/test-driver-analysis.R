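test_that("covariate preparation applies log10(x + 1) to continuous variables only", {
  meta <- tibble::tibble(site = paste0("s", 1:3),
                         GDP = c(0, 9, 99), LUR = c(0, 0.5, 1),
                         WA = 1:3, VR = 1:3, TEM = 15:17, PRE = c(1000, 1100, 1200),
                         NRAD = c(10, 20, 30), HT = c(1, 2, 1), DWN = c(.2, .3, .4),
                         CTP = c(1, 2, 3), ALT = c(100, 50, 10))
  out <- prepare_covariates(meta)
  expect_equal(out$GDP, c(0, 1, 2))          # log10(1), log10(10), log10(100)
  expect_equal(out$HT, c(1, 2, 1))           # ordinal passthrough
  expect_equal(out$CTP, c(1, 2, 3))
  expect_setequal(attr(out, "transformed"), setdiff(driver_covariates(), c("HT", "CTP")))

  meta$ALT[1] <- -5
  expect_error(prepare_covariates(meta), "negative")
  expect_error(prepare_covariates(meta[, 1:5]), "missing covariate")
})

test_that("driver models are reproducible and validate their inputs", {
  set.seed(1)
  dat <- tibble::tibble(site = as.character(1:12))
  for (j in 1:5) dat[[paste0("x", j)]] <- rnorm(12)
  dat$y <- dat$x1 + rnorm(12, 0, 0.1)
  m1 <- fit_driver_model(dat, "y", seed = 42, n_trees = 300)
  m2 <- fit_driver_model(dat, "y", seed = 42, n_trees = 300)
  expect_identical(m1$importance, m2$importance)
  expect_identical(m1$loo$predicted, m2$loo$predicted)

  expect_equal(nrow(m1$loo), 12)  # one held-out prediction per site
  expect_false(anyNA(m1$loo$residual))
  expect_error(fit_driver_model(dat[1:5, ], "y", seed = 1), "at least 8")
  dat$y <- 1
  expect_error(fit_driver_model(dat, "y", seed = 1), "constant")
})

test_that("a planted monotone driver earns the top permutation importance", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    dat <- tibble::tibble(site = as.character(1:12))
    for (j in 1:10) dat[[paste0("decoy", j)]] <- rnorm(12)
    dat$driver <- sort(runif(12))
    dat$y <- 2 * dat$driver + rnorm(12, 0, 0.2)
    m <- fit_driver_model(dat, "y", seed = s, loo = FALSE)
    m$importance$covariate[which.max(m$importance$inc_mse_pct)] == "driver"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("a response independent of all covariates explains nothing", {
  nulls <- vapply(1:10, function(s) {
    set.seed(s + 300)
    dat <- tibble::tibble(site = as.character(1:12))
    for (j in 1:8) dat[[paste0("x", j)]] <- rnorm(12)
    dat$y <- rnorm(12)
    fit_driver_model(dat, "y", seed = s, loo = FALSE)$pct_var_oob
  }, numeric(1))
  expect_gte(mean(nulls <= 0), 0.9)
})

test_that("permutation importance of an independent covariate centres on zero", {
  imps <- vapply(1:20, function(s) {
    set.seed(s + 600)
    dat <- tibble::tibble(driver = sort(runif(12)), noisecov = rnorm(12))
    dat$y <- dat$driver + rnorm(12, 0, 0.3)
    m <- fit_driver_model(dat, "y", seed = s, loo = FALSE, n_trees = 500)
    m$importance$inc_mse_pct[m$importance$covariate == "noisecov"]
  }, numeric(1))
  expect_lt(abs(mean(imps)), 2 * sd(imps) / sqrt(length(imps)) + 2)
})

test_that("top-driver selection requires agreement of both rankings", {
  fake <- structure(list(importance = tibble::tibble(
    covariate = c("a", "b", "c", "d", "e"),
    inc_mse_pct = c(5, 4, 3, 2, 1),
    inc_node_purity = c(5, 1, 3, 2, 4)
  )), class = "fibir_driver")
  # top-4 by mse: a b c d; by purity: a e c d -> agreement {a, c, d},
  # fallback by permutation rank adds b
  expect_equal(top_drivers(fake, n = 4), c("a", "c", "d", "b"))
})

test_that("response curves pick the lowest adequate polynomial degree", {
  x <- seq(-2, 3, length.out = 12)
  dat <- tibble::tibble(x = x,
                        line = 2 * x + 1,
                        parab = x^2 - x + 0.5,
                        noise = { set.seed(5); rnorm(12) })
  r1 <- fit_response_curves(dat, "line", "x")
  expect_equal(r1$degree, 1L)
  expect_equal(r1$r_squared, 1)
  expect_true(r1$significant)

  r2 <- fit_response_curves(dat, "parab", "x")
  expect_equal(r2$degree, 2L)
  expect_gt(r2$r_squared, 0.99)

  r3 <- fit_response_curves(dat, "noise", "x")
  expect_equal(r3$degree, 1L)
  expect_false(r3$significant)
  expect_gte(r3$slope_p, 0.05)

  expect_error(fit_response_curves(dat[1:3, ], "line", "x"), "fewer points")
})

test_that("per-metric models isolate failures to the constant metric", {
  scn <- simulate_scenario(scenario_config(seed = 23))
  mc <- metric_values(scn$current, scn$traits)
  refs <- pool_references(scn$historical, scn$groups, scn$traits)
  sc <- score_sites(mc, refs, planted_directions)
  # force one metric's scores constant
  sc$scores$score[sc$scores$metric == "SPF"] <- 1
  cov <- prepare_covariates(scn$metadata)
  mods <- per_metric_models(sc, cov, seed = 1, n_trees = 200, loo = FALSE)
  expect_s3_class(mods$SPF, "condition")
  others <- setdiff(planted_metrics, "SPF")
  expect_true(all(vapply(mods[others], inherits, logical(1), "fibir_driver")))
  gl <- glance(mods$CUF)
  expect_equal(gl$response, "CUF")
  td <- tidy(mods$CUF)
  expect_setequal(td$covariate, driver_covariates())
})
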