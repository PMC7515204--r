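test_that("integration contracts are enforced", {
  y <- default_initial_state(62)
  expect_error(integrate_network(y, t_end = -1), "positive")
  expect_error(integrate_network(y, t_end = 5, output_times = c(0, 3, 2)),
               "increasing")
  expect_error(integrate_network(y, t_end = 5, output_times = c(1, 2)),
               "start at 0")
})

test_that("conserved pools drift below 1e-6 relative over an hour", {
  tr <- integrate_network(default_initial_state(62), default_parameters(),
                          t_end = 3600)
  s0 <- state_at(tr, 0)
  s1 <- state_at(tr, 3600)
  for (pool in conserved_pools()) {
    expect_lt(abs(sum(s1[pool]) / sum(s0[pool]) - 1), 1e-6)
  }
  expect_true(all(s1 > -1e-12))
})

test_that("the baseline reaches steady state in under a second", {
  traj <- integrate_network(default_initial_state(62), default_parameters(),
                            t_end = 5,
                            output_times = seq(0, 5, by = 0.001))
  # H2O2 at 5 s within 1% of its value at 1 s
  h1 <- traj$states[traj$times == 1, "H2O2"]
  h5 <- traj$states[traj$times == 5, "H2O2"]
  expect_equal(unname(h5 / h1), 1, tolerance = 0.01)
  expect_lt(time_to_steady(traj, "H2O2", band = 0.01), 1)
})

test_that("without any H2O2 source the peroxide level is zero", {
  p <- default_parameters(k1 = 0)
  tr <- integrate_network(default_initial_state(62), p, t_end = 5)
  expect_lt(state_at(tr, 5)[["H2O2"]], 1e-10)
  # table3 policy starts at 3 nM and must decay away
  tr3 <- integrate_network(default_initial_state(62, policy = "table3"), p,
                           t_end = 5)
  expect_lt(state_at(tr3, 5)[["H2O2"]], 1e-8)
})

test_that("time_to_steady handles constant and still-moving traces", {
  p <- default_parameters()
  traj <- integrate_network(default_initial_state(62), p, t_end = 5,
                            output_times = seq(0, 5, by = 0.01))
  const <- traj
  const$states[, "GSH"] <- 5000
  expect_identical(time_to_steady(const, "GSH"), 0)
  rising <- traj
  rising$states[, "GSH"] <- seq(0, 100, length.out = length(traj$times))
  expect_true(is.na(time_to_steady(rising, "GSH")))
})

test_that("a collapse-regime perturbation settles late in the hour", {
  # regression fixture: with kDAAO = 70 uM/s the H2O2 trace is a slow
  # sigmoid that only becomes stationary (1% band) deep into the hour
  basal <- basal_ss(62)
  p <- default_parameters(kdaao = 70)
  traj <- integrate_network(basal$state, p, t_end = 3600,
                            output_times = seq(0, 3600, by = 10))
  tss <- time_to_steady(traj, "H2O2", band = 0.01)
  expect_gt(tss, 1000)
  expect_equal(tss, 1410, tolerance = 0.05)
  # sigmoid asymptote in the tens of uM
  expect_gt(state_at(traj, 3600)[["H2O2"]], 10)
  expect_lt(state_at(traj, 3600)[["H2O2"]], 100)
})

test_that("fractions follow the monomer-equivalent conventions", {
  y <- default_initial_state(62)  # fully reduced
  fr <- fractions(y)
  expect_identical(unname(unlist(fr)), rep(0, 5))

  st <- basal_ss(62)$state
  fb <- fractions(st)
  expect_equal(fb$prx3_dimer_fraction,
               st[["Prx3_SS"]] / sum(st[conserved_pools()$Prx3]))
  expect_true(all(unlist(fb) >= 0 & unlist(fb) <= 1))
  expect_lte(fb$prx3_dimer_fraction + fb$prx3_hyperoxidized_fraction, 1)

  bad <- y
  bad[conserved_pools()$Gpx1] <- 0
  expect_error(fractions(bad), "Gpx1")
})

test_that("steady-state H2O2 decreases in the Prx3 pool and halves on doubling", {
  h <- vapply(c(48, 62, 96, 110), function(p3) {
    basal_ss(p3)$state[["H2O2"]]
  }, numeric(1))
  expect_true(all(diff(h) < 0))
  # two-fold law: doubling 48 -> 96 halves basal H2O2 within 10%
  expect_equal(h[1] / h[3], 2, tolerance = 0.1)
})

test_that("integrated steady state agrees with the refined fixed point", {
  ss <- basal_ss(62)
  expect_true(ss$converged)
  expect_lt(ss$residual, 1e-9)
  # the fixed point confirms the integrated fast-species values (the
  # sulfinic acid form approaches its repair balance only over hours, so it
  # is exempt from this comparison)
  fs <- setdiff(fast_species(), "Prx3_SOOH")
  big <- fs[ss$state[fs] > 1e-6]
  expect_equal(ss$refined_state[big], ss$state[big], tolerance = 0.01)
  expect_equal(ss$refined_state[["H2O2"]], ss$state[["H2O2"]],
               tolerance = 0.01)
})

test_that("both initialization policies reach the same fixed point", {
  a <- basal_ss(62)
  b <- find_steady_state(default_initial_state(62, policy = "table3"))
  fs <- setdiff(fast_species(), "Prx3_SOOH")
  big <- fs[a$refined_state[fs] > 1e-6]
  expect_equal(b$refined_state[big] / a$refined_state[big],
               stats::setNames(rep(1, length(big)), big), tolerance = 1e-3)
  # the sulfinic acid inherits the (slow, frozen) Srx difference; still <1%
  expect_equal(b$refined_state[["Prx3_SOOH"]],
               a$refined_state[["Prx3_SOOH"]], tolerance = 0.01)
})

test_that("trajectories serialize to tidy and wide CSV", {
  traj <- integrate_network(default_initial_state(62), t_end = 1,
                            output_times = c(0, 0.5, 1))
  tidy <- withr::local_tempfile(fileext = ".csv")
  wide <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, tidy, "tidy")
  write_trajectory_csv(traj, wide, "wide")
  td <- utils::read.csv(tidy)
  expect_identical(names(td), c("time_s", "species", "concentration_uM"))
  expect_identical(nrow(td), 3L * 28L)
  wd <- utils::read.csv(wide, check.names = FALSE)
  expect_identical(dim(wd), c(3L, 29L))
})

test_that("glutathione budget holds over a baseline hour", {
  tr <- integrate_network(default_initial_state(62), default_parameters(),
                          t_end = 3600)
  g0 <- total_glutathione(state_at(tr, 0))
  g1 <- total_glutathione(state_at(tr, 3600))
  expect_lt(abs(g1 / g0 - 1), 0.05)
})
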