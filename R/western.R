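#' Dose-to-rate map for the synthetic redox-Western stage
#'
#' Maps D-alanine doses (mM) to intramitochondrial H2O2 generation rates
#' kDAAO (uM/s).  The quantitative calibration of this map is not
#' experimentally established, so the default is an explicitly synthetic
#' Michaelis-like curve, `kdaao = kmax * dose / (half_dose + dose)`, chosen
#' so the top dose of the 0--25 mM experimental design lands near but below
#' the collapse threshold (25 mM maps to ~42 uM/s with the defaults).
#'
#' @param doses D-alanine doses (mM), unique and non-negative; must include
#'   the 0 mM control.
#' @param kmax Saturating kDAAO (uM/s).
#' @param half_dose Dose at half-saturation (mM).
#' @return `data.frame` with columns `dose_mM` and `kdaao_uM_s`; dose 0 maps
#'   to rate 0 and the map is non-decreasing in dose.
#' @export
dose_map <- function(doses = c(0, 2, 5, 10, 25), kmax = 55, half_dose = 7.5) {
  if (anyDuplicated(doses) || any(doses < 0)) {
    stop("doses must be unique and non-negative", call. = FALSE)
  }
  doses <- sort(doses)
  data.frame(dose_mM = doses,
             kdaao_uM_s = kmax * doses / (half_dose + doses))
}

#' Noise model for synthetic densitometry
#'
#' Band intensities receive independent multiplicative log-normal noise;
#' both bands of a lane share a log-normal loading factor that the loading-
#' control band also carries (emulating lane-to-lane loading differences
#' corrected by an endogenous control).
#'
#' @param band_sdlog Log-scale SD of per-band noise (0 = noiseless).
#' @param loading_sdlog Log-scale SD of the per-lane loading factor.
#' @return A `western_noise` list.
#' @export
noise_model <- function(band_sdlog = 0.1, loading_sdlog = 0.15) {
  if (band_sdlog < 0 || loading_sdlog < 0) {
    stop("noise scales must be non-negative", call. = FALSE)
  }
  structure(list(band_sdlog = band_sdlog, loading_sdlog = loading_sdlog),
            class = "western_noise")
}

#' Model-predicted dimer fractions for a dose/time design
#'
#' Runs the perturbation model once per dose (from the relaxed basal steady
#' state, constant kDAAO from the dose map) and reads the Prx3 dimer
#' fraction at each requested time.
#'
#' @param dmap A [dose_map()] `data.frame`.
#' @param times_min Observation times (minutes).
#' @param prx3_total Total Prx3 pool (uM).
#' @param params Baseline parameters.
#' @return `data.frame` with `dose_mM`, `time_min`, `kdaao_uM_s`,
#'   `dimer_fraction`, `hyperoxidized_fraction`.
#' @export
western_model_fractions <- function(dmap = dose_map(),
                                    times_min = c(15, 30, 60),
                                    prx3_total = 62,
                                    params = default_parameters()) {
  basal <- find_steady_state(default_initial_state(prx3_total), params)
  times_s <- sort(unique(times_min)) * 60
  rows <- lapply(seq_len(nrow(dmap)), function(i) {
    p <- params
    p$k[["k28"]] <- dmap$kdaao_uM_s[i]
    traj <- integrate_network(basal$state, p, t_end = max(times_s),
                              output_times = c(0, times_s))
    do.call(rbind, lapply(times_s, function(ts) {
      fr <- fractions(state_at(traj, ts))
      data.frame(dose_mM = dmap$dose_mM[i], time_min = ts / 60,
                 kdaao_uM_s = dmap$kdaao_uM_s[i],
                 dimer_fraction = fr$prx3_dimer_fraction,
                 hyperoxidized_fraction = fr$prx3_hyperoxidized_fraction)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Draw synthetic band intensities from model fractions
#'
#' Produces one lane per (dose, time, replicate).  The dimer band carries
#' the expected share `f` (the model dimer fraction) of the lane's Prx3
#' signal and the monomer band the share `1 - f`: hyperoxidized Prx3 runs as
#' monomer under non-reducing SDS-PAGE, so collapse shows up as a *loss* of
#' dimer signal, not extra dimer.
#'
#' @param fractions_table Output of [western_model_fractions()].
#' @param n_reps Replicates per condition (>= 1).
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param mean_intensity Expected total Prx3 band intensity per lane (a.u.).
#' @return `data.frame` of `WesternObservation` records: `dose_mM`,
#'   `time_min`, `replicate`, `monomer`, `dimer`, `loading`.
#' @export
sample_western_intensities <- function(fractions_table, n_reps = 3,
                                       noise = noise_model(), seed = 1,
                                       mean_intensity = 100) {
  stopifnot(n_reps >= 1)
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(nrow(fractions_table)), function(i) {
    f <- fractions_table$dimer_fraction[i]
    lane <- function(rep) {
      loading <- exp(stats::rnorm(1, 0, noise$loading_sdlog))
      eps <- exp(stats::rnorm(3, 0, noise$band_sdlog))
      data.frame(
        dose_mM = fractions_table$dose_mM[i],
        time_min = fractions_table$time_min[i],
        replicate = rep,
        monomer = mean_intensity * (1 - f) * loading * eps[1],
        dimer = mean_intensity * f * loading * eps[2],
        loading = mean_intensity * loading * eps[3]
      )
    }
    do.call(rbind, lapply(seq_len(n_reps), lane))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a full synthetic redox-Western experiment
#'
#' Convenience wrapper: model fractions via [western_model_fractions()],
#' then replicate band intensities via [sample_western_intensities()].
#'
#' @inheritParams western_model_fractions
#' @inheritParams sample_western_intensities
#' @param dmap A [dose_map()] `data.frame`.
#' @return `data.frame` of synthetic Western observations.
#' @export
simulate_westerns <- function(dmap = dose_map(), times_min = c(15, 30, 60),
                              n_reps = 3, noise = noise_model(), seed = 1,
                              prx3_total = 62,
                              params = default_parameters(),
                              mean_intensity = 100) {
  ft <- western_model_fractions(dmap, times_min, prx3_total, params)
  sample_western_intensities(ft, n_reps = n_reps, noise = noise, seed = seed,
                             mean_intensity = mean_intensity)
}

#' Densitometry: per-replicate fraction oxidized
#'
#' The fraction oxidized of each lane is `dimer / (monomer + dimer)`; the
#' loading-normalized total Prx3 signal `(monomer + dimer) / loading` is
#' reported alongside for total-abundance checks.
#'
#' @param obs `data.frame` of Western observations (columns `dose_mM`,
#'   `time_min`, `replicate`, `monomer`, `dimer`, `loading`).
#' @return Input with added columns `fraction_oxidized` and
#'   `total_loadnorm`.
#' @export
densitometry_fractions <- function(obs) {
  need <- c("dose_mM", "time_min", "replicate", "monomer", "dimer", "loading")
  if (!all(need %in% names(obs))) {
    stop("observations must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  total <- obs$monomer + obs$dimer
  if (any(total <= 0)) {
    stop("fraction undefined: monomer + dimer is zero for some lane",
         call. = FALSE)
  }
  if (any(obs$loading <= 0)) {
    stop("loading-control intensity must be positive", call. = FALSE)
  }
  obs$fraction_oxidized <- obs$dimer / total
  obs$total_loadnorm <- total / obs$loading
  obs
}

#' One-way ANOVA with Tukey HSD against the 0 mM control
#'
#' Tests, within one observation time, whether mean fraction oxidized
#' differs across doses (one-factor ANOVA), with post-hoc Tukey honest
#' significant difference comparisons of each dose against the 0 mM control.
#'
#' @param fractions_df `data.frame` with columns `dose_mM` and
#'   `fraction_oxidized` (one observation time).
#' @param alpha Significance level for flagging pairs.
#' @return List with `p_omnibus`, and `vs_control` (`data.frame`: `dose_mM`,
#'   `diff`, `p_adj`, `significant`).
#' @export
anova_tukey <- function(fractions_df, alpha = 0.05) {
  if (!all(c("dose_mM", "fraction_oxidized") %in% names(fractions_df))) {
    stop("need columns dose_mM and fraction_oxidized", call. = FALSE)
  }
  fractions_df$dose <- factor(fractions_df$dose_mM)
  counts <- table(fractions_df$dose)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("need >= 2 dose groups with >= 2 replicates each", call. = FALSE)
  }
  if (!"0" %in% levels(fractions_df$dose)) {
    stop("the 0 mM control group is required", call. = FALSE)
  }
  fit <- stats::aov(fraction_oxidized ~ dose, data = fractions_df)
  p_omnibus <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$dose
  cmp <- rownames(tk)
  vs0 <- grepl("(^0-)|(-0$)", cmp)
  tab <- tk[vs0, , drop = FALSE]
  other <- sub("-0$", "", sub("^0-", "", rownames(tab)))
  sign_flip <- ifelse(grepl("^0-", rownames(tab)), -1, 1)
  vs_control <- data.frame(
    dose_mM = as.numeric(other),
    diff = unname(tab[, "diff"] * sign_flip),
    p_adj = unname(tab[, "p adj"]),
    significant = unname(tab[, "p adj"] < alpha)
  )
  vs_control <- vs_control[order(vs_control$dose_mM), ]
  rownames(vs_control) <- NULL
  list(p_omnibus = p_omnibus, vs_control = vs_control)
}
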