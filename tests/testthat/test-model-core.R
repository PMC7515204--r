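test_that("default parameters carry the literature rate constants", {
  p <- default_parameters()
  expect_s3_class(p, "redox_params")
  expect_length(p$k, 30L)
  expect_identical(p$k[["k1"]], 4)
  expect_identical(p$k[["k5"]], 57)     # Michaelis constant, uM
  expect_identical(p$k[["k6"]], 20)
  expect_identical(p$k[["k9"]], 20)
  expect_identical(p$k[["k20"]], 375)
  expect_identical(p$k[["k22"]], 9.6e-5)
  expect_identical(p$k[["k29"]], 1.23e-5)
  # baseline has neither perturbation nor efflux
  expect_identical(p$k[["k28"]], 0)
  expect_identical(p$k[["k30"]], 0)
})

test_that("parameter overrides are validated", {
  p <- default_parameters(k1 = 11)
  expect_identical(p$k[["k1"]], 11)
  expect_error(default_parameters(k99 = 1), "k99")
  expect_error(default_parameters(k1 = -1), "non-negative")
  expect_identical(default_parameters(kdaao = 47)$k[["k28"]], 47)
})

test_that("initial state reproduces the measured abundances", {
  y <- default_initial_state(62)
  expect_length(y, 28L)
  expect_identical(names(y), species_names())
  expect_identical(y[["GSH"]], 5000)
  expect_identical(y[["NADPH"]], 30)
  expect_identical(y[["Trx2_SH"]], 7.7)
  expect_identical(y[["Srx"]], 8.8e-3)
  expect_identical(y[["Prx3_SH"]], 62)
  expect_identical(y[["Gpx4_ox"]], 0)
  expect_identical(y[["Gpx4_SSG"]], 0)
})

test_that("Prx3 pool feasibility is enforced but overridable", {
  expect_error(default_initial_state(47.9), "\\[48, 110\\]")
  expect_error(default_initial_state(110.1), "feasible")
  expect_silent(default_initial_state(47.9, allow_out_of_range = TRUE))
})

test_that("both initialization policies carry identical pool totals", {
  a <- default_initial_state(62)
  b <- default_initial_state(62, policy = "table3")
  for (pool in conserved_pools()) {
    expect_equal(sum(a[pool]), sum(b[pool]), tolerance = 1e-12)
  }
})

test_that("the network has exactly 30 reactions over 28 species", {
  rset <- reaction_set()
  expect_length(rset, 30L)
  S <- stoichiometry_matrix()
  expect_identical(dim(S), c(28L, 30L))
  expect_length(species_names(), 28L)
})

test_that("every reaction conserves the protein pools it touches", {
  S <- stoichiometry_matrix()
  for (pool in conserved_pools()) {
    expect_equal(unname(colSums(S[pool, , drop = FALSE])),
                 rep(0, ncol(S)))
  }
  # glutathione atoms: conserved by every reaction except import/efflux
  glut <- c(GSH = 1, GSSG = 2, Gpx1_SSG = 1, Gpx4_SSG = 1, Grx2_SSG = 1,
            Pr_SSG = 1)
  net <- colSums(S[names(glut), ] * glut)
  open <- net != 0
  expect_identical(names(net)[open], c("R20", "R21"))
})

test_that("rate laws evaluate as specified", {
  p <- default_parameters()
  y <- default_initial_state(62)

  # Michaelis-Menten half saturation: NADP+ = Km gives Vmax/2
  y_half <- y
  y_half["NADPp"] <- 57
  v <- reaction_rates(y_half, p)
  expect_equal(unname(v[["R05"]]), 375 / 2)

  # all-zero state: only the zeroth-order sources fire
  v0 <- reaction_rates(stats::setNames(numeric(28), species_names()), p)
  expect_identical(names(v0)[v0 > 0], c("R01", "R20", "R29"))
  expect_equal(unname(v0[["R01"]]), 4)

  pk <- default_parameters(kdaao = 47)
  v0k <- reaction_rates(stats::setNames(numeric(28), species_names()), pk)
  expect_identical(names(v0k)[v0k > 0], c("R01", "R20", "R28", "R29"))

  # Srx-mediated repair flux at the basal sulfinic-acid level balances the
  # Srx import rate (hand evaluation: 3e-3 * 0.466 * 8.8e-3)
  y_srx <- y
  y_srx["Prx3_SOOH"] <- 0.466
  vs <- reaction_rates(y_srx, p)
  expect_equal(unname(vs[["R08"]]), 3e-3 * 0.466 * 8.8e-3)
  expect_equal(unname(vs[["R08"]]), p$k[["k29"]], tolerance = 0.01)
})

test_that("negative concentrations are rejected", {
  y <- default_initial_state(62)
  y["GSH"] <- -1
  expect_error(reaction_rates(y), "negative")
  expect_error(network_rhs(y), "negative")
})

test_that("rhs conserves protein pools and the NADP couple exactly", {
  y <- default_initial_state(62, policy = "table3")
  d <- network_rhs(y)
  for (pool in conserved_pools()) {
    expect_equal(sum(d[pool]), 0, tolerance = 1e-10)
  }
})

test_that("basal H2O2 obeys the algebraic clearance balance", {
  # independent oracle: at steady state the OxPhos source is balanced by
  # the sum of second-order clearance terms, dominated by Prx3
  ss <- basal_ss(62)
  st <- ss$state
  k <- default_parameters()$k
  clearance <- k[["k6"]] * st[["Prx3_SH"]] + k[["k23"]] * st[["Prx5_SH"]] +
    k[["k2"]] * st[["Gpx1_red"]] + k[["k26"]] * st[["Gpx4_red"]] +
    k[["k12"]] * st[["Pr_SH"]] + k[["k16"]] * st[["Pr_SH2"]]
  h2o2_pred <- k[["k1"]] / clearance
  expect_equal(st[["H2O2"]], h2o2_pred, tolerance = 0.02)
  # Prx3 dominates clearance
  expect_equal(k[["k6"]] * st[["Prx3_SH"]] * st[["H2O2"]], k[["k1"]],
               tolerance = 0.2)
  expect_lt(abs(network_rhs(st)[["H2O2"]]), 1e-3)
})

test_that("compiled and R integration engines agree", {
  y <- default_initial_state(62)
  p <- default_parameters(kdaao = 8)
  a <- state_at(integrate_network(y, p, t_end = 2))
  b <- state_at(integrate_network(y, p, t_end = 2, engine = "R"))
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("the model definition exports as a readable text document", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_definition(default_parameters(), path)
  doc <- yaml::read_yaml(path)
  expect_length(doc$species, 28L)
  expect_length(doc$reactions, 30L)
  expect_equal(doc$parameters$k6, 20)
})
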