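test_that("a single-point sweep matches find_steady_state", {
  sw <- basal_prx3_sweep(grid = 62)
  ss <- basal_ss(62)
  expect_identical(nrow(sw), 1L)
  expect_equal(sw$h2o2_nM, ss$state[["H2O2"]] * 1e3, tolerance = 1e-10)
  expect_equal(sw$prx3_dimer_fraction,
               fractions(ss$state)$prx3_dimer_fraction, tolerance = 1e-10)
  expect_error(basal_prx3_sweep(grid = c(62, 48)), "increasing")
})

test_that("basal oxidation fractions are ordered and decreasing in Prx3", {
  sw <- basal_prx3_sweep(grid = c(48, 79, 110))
  # ordering at baseline: Prx3 dimer >> Gpx1 >> Prx5 dimer >> Gpx4
  for (i in seq_len(nrow(sw))) {
    expect_gt(sw$prx3_dimer_fraction[i], 10 * sw$gpx1_oxidized_fraction[i])
    expect_gt(sw$gpx1_oxidized_fraction[i], 10 * sw$prx5_dimer_fraction[i])
    expect_gt(sw$prx5_dimer_fraction[i], 10 * sw$gpx4_oxidized_fraction[i])
  }
  expect_true(all(diff(sw$h2o2_nM) < 0))
  expect_true(all(diff(sw$prx3_dimer_fraction) < 0))
  expect_true(all(diff(sw$gpx1_oxidized_fraction) < 0))
})

test_that("Monte Carlo draws are reproducible and extendable", {
  m5 <- monte_carlo_basal(n = 5, seed = 42)
  m5b <- monte_carlo_basal(n = 5, seed = 42)
  expect_identical(m5$samples, m5b$samples)
  # growing n keeps earlier draws (per-sample substreams)
  m10 <- monte_carlo_basal(n = 10, seed = 42)
  expect_identical(m10$samples$prx3_total_uM[1:5], m5$samples$prx3_total_uM)
  # a different seed gives different draws
  expect_false(identical(monte_carlo_basal(n = 5, seed = 43)$samples,
                         m5$samples))
})

test_that("Monte Carlo sampling is uniform over the configured range", {
  m <- monte_carlo_basal(n = 200, seed = 7)
  x <- m$samples$prx3_total_uM
  expect_true(all(x >= 48 & x <= 110))
  expect_equal(mean(x), 79, tolerance = 0.05)  # uniform mean of [48, 110]
  ks <- suppressWarnings(stats::ks.test((x - 48) / 62, "punif"))
  expect_gt(ks$p.value, 0.001)
  # zero-width range collapses to the single-point value
  m0 <- monte_carlo_basal(n = 4, range = c(62, 62), seed = 1)
  expect_equal(diff(range(m0$samples$h2o2_nM)), 0, tolerance = 1e-12)
})

test_that("the unperturbed sweep row matches the basal state", {
  tab <- table5_sweep()
  row0 <- tab[tab$kdaao_uM_s == 0, ]
  fb <- fractions(basal_ss(62)$state)
  expect_equal(row0$prx3_dimer_fraction, fb$prx3_dimer_fraction,
               tolerance = 1e-3)
  expect_equal(row0$h2o2_nM, basal_ss(62)$state[["H2O2"]] * 1e3,
               tolerance = 1e-3)
})

test_that("the 1-h dimer fraction rises with kDAAO then crashes", {
  tab <- table5_sweep()
  pre <- tab[tab$kdaao_uM_s <= 47, "prx3_dimer_fraction"]
  expect_true(all(diff(pre) > 0))
  post <- tab[tab$kdaao_uM_s >= 54, "prx3_dimer_fraction"]
  expect_true(all(post < 0.01))
  expect_true(all(tab[tab$kdaao_uM_s >= 54,
                      "prx3_hyperoxidized_fraction"] > 0.99))
})

test_that("collapse threshold bisection brackets and responds to OxPhos", {
  expect_error(collapse_threshold(lo = 0, hi = 10), "not bracketed")
  th <- collapse_threshold(iterations = 8L)
  expect_gt(th$kdaao_star, th$bracket[1] - 1e-9)
  expect_lt(th$kdaao_star, th$bracket[2] + 1e-9)
  # a higher OxPhos generation rate lowers the collapse threshold
  th_hi <- collapse_threshold(params = default_parameters(k1 = 11),
                              iterations = 8L)
  expect_lt(th_hi$kdaao_star, th$kdaao_star)
})

test_that("normalized sensitivities match the dominant-balance closed form", {
  sa <- sensitivity_analysis(outputs = c("H2O2", "Prx3_SS"))
  h <- sa[sa$output == "H2O2", ]
  # steady state H2O2 ~ k1 / (k6 [Prx3-SH]) so normalized sensitivities of
  # k1 and k6 are +1 and -1
  expect_identical(h$parameter[1], "k1")
  expect_identical(h$parameter[2], "k6")
  expect_equal(h$sensitivity_normalized[1], 1, tolerance = 0.1)
  expect_equal(h$sensitivity_normalized[2], -1, tolerance = 0.1)
  ss <- sa[sa$output == "Prx3_SS", ]
  expect_identical(ss$parameter[1], "k1")
  expect_true("k10" %in% ss$parameter[1:3])
  # tornado truncation
  expect_true(all(abs(sa$sensitivity_normalized) >= 1e-5))
  expect_error(sensitivity_analysis(outputs = "NotASpecies"), "unknown")
})

test_that("forward differences converge toward the central estimate", {
  central <- sensitivity_analysis(outputs = "H2O2", direction = "central")
  f10 <- sensitivity_analysis(outputs = "H2O2", delta = 0.10)
  f05 <- sensitivity_analysis(outputs = "H2O2", delta = 0.05)
  pick <- function(df, p) df$sensitivity_normalized[df$parameter == p]
  for (p in c("k1", "k6")) {
    err10 <- abs(pick(f10, p) - pick(central, p))
    err05 <- abs(pick(f05, p) - pick(central, p))
    expect_lt(err05, err10)
  }
})

test_that("efflux Monte Carlo percentile bands are coherent and in range", {
  mc <- efflux_monte_carlo(n = 30, seed = 5, times = seq(0, 3600, by = 900))
  expect_true(all(mc$samples$kdaao_uM_s >= 50 & mc$samples$kdaao_uM_s <= 100))
  expect_true(all(mc$samples$kefflux >= 0 & mc$samples$kefflux <= 50))
  b <- mc$bands
  for (q in unique(b$quantity)) {
    for (tt in unique(b$time_s)) {
      v <- b$value[b$quantity == q & b$time_s == tt]
      expect_false(is.unsorted(v))
    }
  }
})

test_that("matched zeroth-order efflux cancels the perturbation source", {
  basal <- basal_ss(62)
  p <- default_parameters(kdaao = 70, kefflux = 70,
                          efflux_mode = "zeroth_order")
  tr <- integrate_network(basal$state, p, t_end = 3600)
  expect_equal(state_at(tr, 3600)[["H2O2"]], basal$state[["H2O2"]],
               tolerance = 1e-3)
  expect_equal(fractions(state_at(tr, 3600))$prx3_dimer_fraction,
               fractions(basal$state)$prx3_dimer_fraction, tolerance = 0.01)
})
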