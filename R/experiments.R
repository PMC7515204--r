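#' Basal steady-state sweep over the feasible Prx3 pool
#'
#' Computes the basal (OxPhos-only, kDAAO = 0) steady state at each Prx3
#' total in `grid` and summarizes H2O2 and the fractional oxidation of the
#' four major antioxidants.  The default grid is ten evenly spaced points
#' over the feasible range 48--110 uM.
#'
#' @param grid Increasing vector of Prx3 totals (uM) within \[48, 110\].
#' @param params A `redox_params` object (kDAAO is expected to be 0).
#' @param t_quasi Basal reporting time (s).
#' @return `data.frame` with one row per grid point: `prx3_total_uM`,
#'   `h2o2_nM`, the four oxidized fractions, the hyperoxidized fraction and
#'   the fast-subsystem residual.
#' @export
basal_prx3_sweep <- function(grid = seq(48, 110, length.out = 10),
                             params = default_parameters(), t_quasi = 5) {
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  rows <- lapply(grid, function(p3) {
    ss <- find_steady_state(default_initial_state(p3), params,
                            t_quasi = t_quasi)
    fr <- fractions(ss$state)
    data.frame(
      prx3_total_uM = p3,
      h2o2_nM = ss$state[["H2O2"]] * 1e3,
      prx3_dimer_fraction = fr$prx3_dimer_fraction,
      prx5_dimer_fraction = fr$prx5_dimer_fraction,
      gpx1_oxidized_fraction = fr$gpx1_oxidized_fraction,
      gpx4_oxidized_fraction = fr$gpx4_oxidized_fraction,
      prx3_hyperoxidized_fraction = fr$prx3_hyperoxidized_fraction,
      residual_uM_s = ss$residual
    )
  })
  do.call(rbind, rows)
}

# deterministic per-sample substream: draw i depends only on (seed, i), so
# growing n extends the sample set without reshuffling earlier draws
substream_uniform <- function(seed, i) {
  s <- (as.numeric(seed) * 1000003 + i * 7919) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(s))
  stats::runif(1)
}

#' Monte Carlo distribution of basal H2O2 over the Prx3 pool
#'
#' Draws `n` Prx3 totals uniformly from `range` (each draw `u * (max - min)
#' + min` with `u ~ U(0, 1)` from a deterministic per-sample substream of the
#' root seed), computes the basal steady state for each and returns the
#' distribution of H2O2.
#'
#' @param n Number of samples.
#' @param range Length-2 feasible range of the Prx3 pool (uM).
#' @param seed Root seed (integer); identical seeds give bit-identical
#'   sample sets.
#' @param params A `redox_params` object.
#' @param t_quasi Basal reporting time (s).
#' @param probs Percentiles for the summary.
#' @return List with `samples` (`data.frame`: `sample`, `prx3_total_uM`,
#'   `h2o2_nM`) and `summary` (named percentiles of basal H2O2 in nM).
#' @export
monte_carlo_basal <- function(n = 10000, range = c(48, 110), seed = 1,
                              params = default_parameters(), t_quasi = 5,
                              probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  stopifnot(n >= 1, length(range) == 2, range[1] <= range[2])
  u <- vapply(seq_len(n), function(i) substream_uniform(seed, i), numeric(1))
  prx3 <- u * (range[2] - range[1]) + range[1]
  h2o2 <- vapply(prx3, function(p3) {
    traj <- integrate_network(
      default_initial_state(p3, allow_out_of_range = TRUE), params,
      t_end = t_quasi)
    state_at(traj)[["H2O2"]] * 1e3
  }, numeric(1))
  list(
    samples = data.frame(sample = seq_len(n), prx3_total_uM = prx3,
                         h2o2_nM = h2o2),
    summary = c(n = n, mean_nM = mean(h2o2), min_nM = min(h2o2),
                max_nM = max(h2o2),
                stats::quantile(h2o2, probs = probs))
  )
}

#' Perturbation sweep over the DAAO generation rate
#'
#' Starting from the relaxed basal steady state at `prx3_total`, switches on
#' a constant additional H2O2 source kDAAO at t = 0 and integrates for
#' `t_end` seconds, for each rate in `kdaao_grid`.  Summarizes the
#' end-of-run H2O2 and fractional oxidation; optionally retains the full
#' trajectories of H2O2 and the four Prx3 forms.
#'
#' @param kdaao_grid Vector of kDAAO values (uM/s).  The default is the
#'   rounded grid used for the 1-h oxidation summary.
#' @param prx3_total Total Prx3 pool (uM).
#' @param t_end Horizon (s).
#' @param params Baseline parameters (kDAAO is overridden per grid point).
#' @param keep_trajectories If `TRUE`, attach per-rate trajectories sampled
#'   at `trace_times`.
#' @param trace_times Report times for retained trajectories (s).
#' @return List with `summary` (`data.frame`, one row per kDAAO) and, when
#'   requested, `trajectories` (named list of `redox_trajectory`).
#' @export
perturbation_sweep <- function(kdaao_grid = c(0, 8, 16, 23, 31, 39, 47, 54,
                                              62, 70),
                               prx3_total = 62, t_end = 3600,
                               params = default_parameters(),
                               keep_trajectories = FALSE,
                               trace_times = seq(0, t_end, length.out = 241)) {
  basal <- find_steady_state(default_initial_state(prx3_total), params)
  trajectories <- list()
  rows <- lapply(kdaao_grid, function(kd) {
    p <- params
    p$k[["k28"]] <- kd
    times <- if (keep_trajectories) trace_times else c(0, t_end)
    traj <- integrate_network(basal$state, p, t_end = t_end,
                              output_times = times)
    if (keep_trajectories) {
      trajectories[[as.character(kd)]] <<- traj
    }
    st <- state_at(traj, t_end)
    fr <- fractions(st)
    data.frame(
      kdaao_uM_s = kd,
      h2o2_nM = st[["H2O2"]] * 1e3,
      prx3_dimer_fraction = fr$prx3_dimer_fraction,
      gpx1_oxidized_fraction = fr$gpx1_oxidized_fraction,
      prx5_dimer_fraction = fr$prx5_dimer_fraction,
      gpx4_oxidized_fraction = fr$gpx4_oxidized_fraction,
      prx3_hyperoxidized_fraction = fr$prx3_hyperoxidized_fraction
    )
  })
  out <- list(summary = do.call(rbind, rows))
  if (keep_trajectories) out$trajectories <- trajectories
  out
}

#' Collapse threshold of the Prx3 system by bisection
#'
#' Finds the DAAO generation rate at which the network transitions to
#' collapse, defined by default as the 1-hour Prx3 hyperoxidized fraction
#' exceeding 0.5.  Bisection assumes the indicator is monotone in kDAAO over
#' the bracket.
#'
#' @param lo,hi Bracket (uM/s); the criterion must be FALSE at `lo` and TRUE
#'   at `hi`.
#' @param prx3_total Total Prx3 pool (uM).
#' @param params Baseline parameters.
#' @param t_end Horizon (s).
#' @param criterion Function of the end-of-run state returning TRUE in the
#'   collapsed regime.
#' @param iterations Number of bisection steps (12 gives a width of
#'   (hi - lo) / 4096).
#' @return List with `kdaao_star` (midpoint of the final bracket, uM/s),
#'   `bracket` and `iterations`.
#' @export
collapse_threshold <- function(lo = 0, hi = 100, prx3_total = 62,
                               params = default_parameters(), t_end = 3600,
                               criterion = function(state)
                                 fractions(state)$prx3_hyperoxidized_fraction > 0.5,
                               iterations = 12L) {
  basal <- find_steady_state(default_initial_state(prx3_total), params)
  indicator <- function(kd) {
    p <- params
    p$k[["k28"]] <- kd
    traj <- integrate_network(basal$state, p, t_end = t_end)
    isTRUE(criterion(state_at(traj, t_end)))
  }
  if (indicator(lo)) {
    stop("criterion already met at lo; threshold not bracketed", call. = FALSE)
  }
  if (!indicator(hi)) {
    stop("criterion not met at hi; threshold not bracketed", call. = FALSE)
  }
  for (i in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    if (indicator(mid)) hi <- mid else lo <- mid
  }
  list(kdaao_star = (lo + hi) / 2, bracket = c(lo, hi),
       iterations = iterations)
}

#' Local finite-difference sensitivity analysis
#'
#' Perturbs each positive rate parameter by `delta` (forward difference by
#' default, central behind a flag), recomputes the basal prediction at
#' `t_eval`, and reports raw sensitivities s = dC/dk together with the
#' dimensionless normalized form s_norm = (dC/C)/(dk/k).  Records are sorted
#' by |s_norm| (descending, ties broken by parameter index) and truncated
#' below `truncate`, giving the tornado ordering.
#'
#' @param outputs Species whose basal predictions are analyzed.
#' @param delta Relative perturbation (default 0.10).
#' @param t_eval Evaluation time (s).
#' @param prx3_total Total Prx3 pool (uM).
#' @param params Baseline parameters.
#' @param direction `"forward"` or `"central"`.
#' @param truncate Drop records with |normalized sensitivity| below this.
#' @return `data.frame` with columns `output`, `parameter`, `param_index`,
#'   `sensitivity_raw`, `sensitivity_normalized`, `t_eval_s`, ordered per
#'   output by decreasing |normalized| value.
#' @export
sensitivity_analysis <- function(outputs = c("H2O2", "Prx3_SH", "Prx3_SS",
                                             "Prx3_SOOH"),
                                 delta = 0.10, t_eval = 5, prx3_total = 62,
                                 params = default_parameters(),
                                 direction = c("forward", "central"),
                                 truncate = 1e-5) {
  direction <- match.arg(direction)
  bad <- setdiff(outputs, species_names())
  if (length(bad)) {
    stop("unknown output species: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  y0 <- default_initial_state(prx3_total)
  run <- function(p) {
    state_at(integrate_network(y0, p, t_end = t_eval))[outputs]
  }
  base <- run(params)
  knames <- names(params$k)
  active <- knames[params$k > 0]

  recs <- lapply(active, function(kn) {
    ki <- params$k[[kn]]
    dk <- delta * ki
    pp <- params
    pp$k[[kn]] <- ki + dk
    up <- run(pp)
    if (direction == "central") {
      pm <- params
      pm$k[[kn]] <- ki - dk
      dn <- run(pm)
      s <- (up - dn) / (2 * dk)
    } else {
      s <- (up - base) / dk
    }
    data.frame(
      output = outputs,
      parameter = kn,
      param_index = match(kn, knames),
      sensitivity_raw = unname(s),
      sensitivity_normalized = unname(s) * ki / unname(base),
      t_eval_s = t_eval
    )
  })
  df <- do.call(rbind, recs)
  df <- df[abs(df$sensitivity_normalized) >= truncate, ]
  ord <- order(match(df$output, outputs),
               -abs(df$sensitivity_normalized),
               df$param_index)
  df <- df[ord, ]
  rownames(df) <- NULL
  df
}

#' Efflux-refined Monte Carlo over (kDAAO, kefflux)
#'
#' Samples `n` independent (kDAAO, kefflux) pairs uniformly from their
#' ranges, integrates each from the relaxed basal steady state for one hour,
#' and summarizes H2O2, the Prx3 forms and the dimer fraction as percentile
#' bands over time.  The efflux reaction defaults to the H2O2-dependent
#' (first-order) form, which reproduces the described low/high-efflux
#' phenotypes; the throttled zeroth-order form is available via
#' `efflux_mode`.
#'
#' @param kdaao_range,kefflux_range Length-2 sampling ranges.
#' @param n Number of sampled pairs.
#' @param seed Root seed; per-sample substreams are deterministic in
#'   (seed, sample index).
#' @param percentiles Reported percentile levels (in percent).
#' @param times Report times (s), 0 to 3600 by default.
#' @param prx3_total Total Prx3 pool (uM).
#' @param efflux_mode `"first_order"` (default) or `"zeroth_order"`.
#' @param params Baseline parameters.
#' @return List with `bands` (`data.frame`: `quantity`, `time_s`,
#'   `percentile`, `value`) and `samples` (`data.frame` of the sampled
#'   pairs).
#' @export
efflux_monte_carlo <- function(kdaao_range = c(50, 100),
                               kefflux_range = c(0, 50),
                               n = 10000, seed = 1,
                               percentiles = c(2.5, 25, 50, 75, 97.5),
                               times = seq(0, 3600, by = 300),
                               prx3_total = 62,
                               efflux_mode = c("first_order", "zeroth_order"),
                               params = default_parameters()) {
  efflux_mode <- match.arg(efflux_mode)
  stopifnot(n >= 1, diff(kdaao_range) >= 0, diff(kefflux_range) >= 0)
  params$efflux_mode <- efflux_mode
  basal <- find_steady_state(default_initial_state(prx3_total), params)

  u1 <- vapply(seq_len(n), function(i) substream_uniform(seed, 2L * i - 1L),
               numeric(1))
  u2 <- vapply(seq_len(n), function(i) substream_uniform(seed, 2L * i),
               numeric(1))
  kdaao <- u1 * diff(kdaao_range) + kdaao_range[1]
  kefflux <- u2 * diff(kefflux_range) + kefflux_range[1]

  quantities <- c("H2O2", "Prx3_SH", "Prx3_SS", "Prx3_SOOH", "dimer_fraction")
  acc <- array(NA_real_, dim = c(n, length(times), length(quantities)),
               dimnames = list(NULL, NULL, quantities))
  prx3_pool <- sum(basal$state[conserved_pools()$Prx3])
  for (i in seq_len(n)) {
    p <- params
    p$k[["k28"]] <- kdaao[i]
    p$k[["k30"]] <- kefflux[i]
    traj <- integrate_network(basal$state, p, t_end = max(times),
                              output_times = times)
    acc[i, , "H2O2"] <- traj$states[, "H2O2"]
    acc[i, , "Prx3_SH"] <- traj$states[, "Prx3_SH"]
    acc[i, , "Prx3_SS"] <- traj$states[, "Prx3_SS"]
    acc[i, , "Prx3_SOOH"] <- traj$states[, "Prx3_SOOH"]
    acc[i, , "dimer_fraction"] <- traj$states[, "Prx3_SS"] / prx3_pool
  }

  bands <- do.call(rbind, lapply(quantities, function(q) {
    do.call(rbind, lapply(seq_along(times), function(j) {
      qs <- stats::quantile(acc[, j, q], probs = percentiles / 100,
                            names = FALSE)
      data.frame(quantity = q, time_s = times[j], percentile = percentiles,
                 value = qs)
    }))
  }))
  rownames(bands) <- NULL
  list(bands = bands,
       samples = data.frame(sample = seq_len(n), kdaao_uM_s = kdaao,
                            kefflux = kefflux),
       efflux_mode = efflux_mode)
}
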