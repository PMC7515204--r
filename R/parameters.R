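#' Default kinetic parameters of the mitochondrial H2O2 network
#'
#' Returns the literature-derived rate parameters of the 30-reaction network.
#' Units: zeroth-order source terms in uM/s (k1 OxPhos generation, k21 GSH
#' import, k29 Srx import, k28 = kDAAO); first-order rate constants in 1/s
#' (k9, k11, k22, k24); second-order rate constants in 1/(uM s); k5 is the
#' Michaelis constant (uM) and k20 the maximal rate (uM/s) of the
#' NADPH-regeneration step.  k28 (the DAAO perturbation source) and k30 (the
#' H2O2 efflux rate) default to 0: the baseline model has neither.
#'
#' @param kdaao H2O2 generation rate of the DAAO perturbation (uM/s); stored
#'   as k28.
#' @param kefflux H2O2 efflux rate parameter, stored as k30.  Units depend on
#'   `efflux_mode`: uM/s for `"zeroth_order"`, 1/s for `"first_order"`.
#' @param efflux_mode Form of the efflux rate law.  `"zeroth_order"`: flux =
#'   k30 * min(1, \[H2O2\]/eps), a constant-rate efflux smoothly throttled
#'   below `eps` so concentrations cannot be driven negative.
#'   `"first_order"`: flux = k30 * \[H2O2\].
#' @param eps Throttle scale of the zeroth-order efflux (uM).
#' @param ... Named overrides `k1` ... `k30` (e.g. `k1 = 11` for the higher
#'   OxPhos generation rate).
#'
#' @return An object of class `redox_params`: a list with elements `k`
#'   (named numeric, `k1` ... `k30`), `efflux_mode` and `eps`.
#' @export
default_parameters <- function(kdaao = 0, kefflux = 0,
                               efflux_mode = c("zeroth_order", "first_order"),
                               eps = 1e-3, ...) {
  efflux_mode <- match.arg(efflux_mode)
  k <- c(
    k1  = 4,       # H2O2 generation by OxPhos, uM/s
    k2  = 60,      # Gpx1red + H2O2
    k3  = 0.04,    # Gpx1ox + GSH
    k4  = 10,      # Gpx-SSG + GSH (shared by Gpx1 and Gpx4 recycling)
    k5  = 57,      # Michaelis constant of NADPH regeneration, uM
    k6  = 20,      # Prx3-SH + H2O2
    k7  = 0.014,   # Prx3-SOH + H2O2 (hyperoxidation)
    k8  = 3e-3,    # Prx3-SOOH + Srx (repair)
    k9  = 20,      # Prx3-SOH resolution, 1/s
    k10 = 0.22,    # Prx3-SS + Trx2-SH
    k11 = 7.4e-5,  # GSH autoxidation, 1/s
    k12 = 1e-4,    # Pr-SH + H2O2
    k13 = 0.12,    # Pr-SOH + GSH
    k14 = 0.01,    # Grx2-SH + Pr-SSG
    k15 = 0.04,    # Grx2-SSG + GSH
    k16 = 1e-4,    # Pr-(SH)2 + H2O2
    k17 = 1e-4,    # Pr-SS + Trx2-SH
    k18 = 3.2,     # GSSG + NADPH
    k19 = 20,      # Trx2-SS + NADPH
    k20 = 375,     # maximal NADPH regeneration rate, uM/s
    k21 = 0.48,    # GSH import, uM/s
    k22 = 9.6e-5,  # GSH efflux, 1/s
    k23 = 0.3,     # Prx5-SH + H2O2
    k24 = 14.7,    # Prx5-SOH resolution, 1/s
    k25 = 2,       # Prx5-SS + Trx2-SH
    k26 = 0.05,    # Gpx4red + H2O2
    k27 = 0.02,    # Gpx4ox + GSH
    k28 = 0,       # kDAAO, uM/s
    k29 = 1.23e-5, # Srx import, uM/s
    k30 = 0        # kefflux
  )
  k[["k28"]] <- kdaao
  k[["k30"]] <- kefflux
  overrides <- list(...)
  if (length(overrides)) {
    nm <- names(overrides)
    bad <- setdiff(nm, names(k))
    if (length(bad)) {
      stop("unknown rate parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    k[nm] <- unlist(overrides)
  }
  if (any(k < 0)) {
    stop("rate parameters must be non-negative", call. = FALSE)
  }
  structure(list(k = k, efflux_mode = efflux_mode, eps = eps),
            class = "redox_params")
}

#' @export
print.redox_params <- function(x, ...) {
  cat("Mitochondrial H2O2 network parameters (30 rate parameters)\n")
  cat(sprintf("  OxPhos source k1 = %g uM/s; kDAAO (k28) = %g uM/s; ",
              x$k[["k1"]], x$k[["k28"]]))
  cat(sprintf("kefflux (k30) = %g [%s]\n", x$k[["k30"]], x$efflux_mode))
  print(x$k, ...)
  invisible(x)
}

as_parms_vector <- function(params) {
  stopifnot(inherits(params, "redox_params"))
  c(unname(params$k),
    if (identical(params$efflux_mode, "first_order")) 1 else 0,
    params$eps)
}

#' Initial species abundances
#'
#' Builds the 28-species initial state.  The measured abundances (Prx5-SH 14,
#' Gpx1 1.5e-2, Gpx4 0.23, Grx2 1, Trx2-SH 7.7, Trx2-SS 0.075, GSH 5000,
#' GSSG 1.78, NADPH 30, NADP+ 0.03, Pr-SH 1e-3, Pr-(SH)2 1090, Srx 8.8e-3,
#' all uM) are fixed; the Prx3 pool is supplied by the caller because the
#' proteomics-derived per-mitochondrion concentration is only known as the
#' range 48--110 uM.
#'
#' Two initialization policies are available.  `"reduced"` (default) starts
#' all derivative/oxidized species at zero; the fast subsystem relaxes to the
#' basal steady state in well under a second, so basal quantities are read
#' from the relaxed state.  `"table3"` seeds the oxidized forms at the
#' midpoints of their derived basal ranges (subtracting them from the reduced
#' forms so every pool total is identical to the `"reduced"` policy); both
#' policies relax to the same fast-subsystem steady state.
#'
#' @param prx3_total Total Prx3 pool (uM, monomer-equivalents), feasible range
#'   48--110.
#' @param policy Initialization policy, `"reduced"` or `"table3"`.
#' @param allow_out_of_range Set `TRUE` to bypass the feasibility check on
#'   `prx3_total`.
#'
#' @return Named numeric state vector (uM) in `species_names()` order.
#' @export
default_initial_state <- function(prx3_total,
                                  policy = c("reduced", "table3"),
                                  allow_out_of_range = FALSE) {
  policy <- match.arg(policy)
  if (!is.numeric(prx3_total) || length(prx3_total) != 1L || is.na(prx3_total)) {
    stop("prx3_total must be a single number (uM)", call. = FALSE)
  }
  if (!allow_out_of_range && (prx3_total < 48 || prx3_total > 110)) {
    stop(sprintf(
      "prx3_total = %g uM is outside the feasible range [48, 110] uM; ",
      prx3_total),
      "use allow_out_of_range = TRUE to override", call. = FALSE)
  }
  y <- stats::setNames(numeric(28L), species_names())
  y["Prx3_SH"] <- prx3_total
  y["Prx5_SH"] <- 14
  y["Gpx1_red"] <- 1.5e-2
  y["Gpx4_red"] <- 0.23
  y["Grx2_SH"] <- 1
  y["Trx2_SH"] <- 7.7
  y["Trx2_SS"] <- 0.075
  y["GSH"] <- 5e3
  y["GSSG"] <- 1.78
  y["NADPH"] <- 30
  y["NADPp"] <- 0.03
  y["Pr_SH"] <- 1e-3
  y["Pr_SH2"] <- 1.09e3
  y["Srx"] <- 8.8e-3

  if (policy == "table3") {
    # midpoints of the derived basal ranges, removed from the reduced forms
    # so pool totals match the "reduced" policy exactly
    y["H2O2"] <- 3e-3
    y["Prx3_SOH"] <- 0.19
    y["Prx3_SS"] <- 2.25
    y["Prx3_SOOH"] <- 0.305
    y["Prx3_SH"] <- prx3_total - y["Prx3_SOH"] - y["Prx3_SS"] - y["Prx3_SOOH"]
    y["Prx5_SOH"] <- 7.5e-4
    y["Prx5_SS"] <- 7.5e-4
    y["Prx5_SH"] <- 14 - y["Prx5_SOH"] - y["Prx5_SS"]
    y["Gpx1_ox"] <- 1.4e-5
    y["Gpx1_SSG"] <- 5e-8
    y["Gpx1_red"] <- 1.5e-2 - y["Gpx1_ox"] - y["Gpx1_SSG"]
    y["Grx2_SSG"] <- 1e-16
    y["Grx2_SH"] <- 1 - y["Grx2_SSG"]
    y["Pr_SOH"] <- 4.5e-13
    y["Pr_SSG"] <- 2e-8
    y["Pr_SS"] <- 0.425
    y["Pr_SH2"] <- 1.09e3 - y["Pr_SS"]
  }
  y
}
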