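test_that("network construction validates its inputs", {
  segs <- tibble::tibble(id = c("A", "B"), length_km = c(10, 10), rank = 1)
  expect_error(river_network(dplyr::mutate(segs, length_km = c(0, 10))), "positive")
  expect_error(river_network(segs, tibble::tibble(from = "A", to = "Z",
                                                  passability = 0, year = 2000)),
               "unknown segment")
  expect_error(river_network(segs, tibble::tibble(from = "A", to = "B",
                                                  passability = 1.5, year = 2000)),
               "passability")
  edges <- tibble::tibble(from = character(), to = character())
  expect_error(river_network(segs, edges = edges), "disconnected")
})

test_that("passability is the product of active barriers on the path", {
  net <- two_segment_network(passability = 0, year = 2000)
  expect_equal(passability(net, "A", "A"), 1)  # empty product
  expect_equal(passability(net, "A", "B"), 0)  # complete barrier annihilates
  expect_equal(passability(net, "A", "B", year = 1999), 1)  # not yet built

  segs <- tibble::tibble(id = c("A", "B", "C"), length_km = 10, rank = 1)
  barr <- tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                         passability = 0.25, year = 2000)
  net3 <- river_network(segs, barr)
  expect_equal(passability(net3, "A", "C"), 0.0625)  # 0.25 * 0.25
  expect_equal(passability(net3, "A", "B"), 0.25)
})

test_that("static RCI reproduces the closed-form cases", {
  single <- river_network(tibble::tibble(id = "only", length_km = 42, rank = 1))
  expect_equal(rci_static(single)$rci, 100)

  expect_equal(two_segment_network(0) |> rci_static() |> (\(x) x$rci)(),
               c(25, 25))
  expect_equal(two_segment_network(0.25) |> rci_static() |> (\(x) x$rci)(),
               c(31.25, 31.25))
})

test_that("RCI weights sum to one and free-network segment indices sum to 100", {
  for (s in 1:5) {
    net <- random_chain_network(n = sample(3:10, 1), seed = s)
    r <- rci_static(net)
    expect_equal(sum(r$weight), 1)
    expect_lte(sum(r$weight * r$rci), 100 + 1e-9)
    # all barriers fully passable: RCI_i = 100 w_i, so the segment indices
    # sum to 100 regardless of segmentation
    free <- river_network(net$segments,
                          dplyr::mutate(net$barriers, passability = 1))
    rf <- rci_static(free)
    expect_equal(rf$rci, 100 * rf$weight)
    expect_equal(sum(rf$rci), 100)
  }
})

test_that("TRCI time-averages the static index over the commissioning history", {
  # constant configuration: time average equals the static index
  net <- two_segment_network(0.25, year = 1990)
  res <- trci(net, years = 1995:2000)
  expect_equal(res$trci$trci, rci_static(net)$rci)

  # two equal segments, t = 4, complete barrier commissioned in year 3
  net2 <- two_segment_network(0, year = 3)
  res2 <- trci(net2, years = 1:4)
  expect_equal(res2$trci$trci, c(37.5, 37.5))  # (50 + 50 + 25 + 25) / 4
  expect_equal(res2$by_year$rci[res2$by_year$year == 1], c(50, 50))
  expect_error(trci(net2, years = numeric()), "no evaluation years")
})

test_that("raising any passability never lowers TRCI", {
  for (s in 1:8) {
    net <- random_chain_network(n = 6, seed = s + 100)
    years <- 1975:2015
    base <- trci(net, years)$trci$trci
    raised <- net$barriers
    i <- sample(nrow(raised), 1)
    raised$passability[i] <- min(1, raised$passability[i] + runif(1, 0.05, 0.5))
    up <- trci(river_network(net$segments, raised), years)$trci$trci
    expect_true(all(up >= base - 1e-12))
  }
})

test_that("TRCI lies between the first-year and final-year static indices", {
  for (s in 1:5) {
    net <- random_chain_network(n = 6, seed = s + 200)
    years <- 1960:2020  # spans all commissioning years; barriers only accumulate
    res <- trci(net, years)$trci$trci
    first <- rci_static(net, year = min(years))$rci
    last <- rci_static(net, year = max(years))$rci
    expect_true(all(res <= first + 1e-12 & res >= last - 1e-12))
  }
})

test_that("CTP is the dense rank of TRCI", {
  segs <- tibble::tibble(id = c("A", "B", "C"), length_km = c(5, 10, 40), rank = 1)
  barr <- tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                         passability = c(0, 0.25), year = 2000)
  res <- trci(river_network(segs, barr), years = 2001)
  ct <- ctp_ordinal(res)
  expect_equal(ct$ctp[order(ct$trci)], sort(ct$ctp))
  expect_setequal(ct$ctp, seq_along(unique(ct$trci)))

  # all-equal TRCI (equal free segments): every segment shares rank 1
  free <- river_network(tibble::tibble(id = c("A", "B", "C"),
                                       length_km = 10, rank = 1))
  ct2 <- ctp_ordinal(trci(free, years = 2001))
  expect_equal(ct2$ctp, rep(1L, 3))

  # dense rank is invariant under strictly monotone transforms
  res_t <- res; res_t$trci$trci <- exp(res$trci$trci / 10)
  expect_equal(ctp_ordinal(res_t)$ctp, ct$ctp)
})
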