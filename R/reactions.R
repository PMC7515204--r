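#' The 30-reaction set of the mitochondrial H2O2 network
#'
#' Each reaction carries an identifier, a human-readable description, a
#' rate-law evaluator (a function of the state vector and the `k` parameter
#' vector returning a flux in uM/s) and a signed stoichiometry map over the
#' species it touches.  Protein pools are conserved reaction-by-reaction;
#' the open species are H2O2 (sources k1/k28, efflux k30), glutathione
#' (import k21, efflux k22, with the one-electron autoxidation step consuming
#' one GSH and producing half a GSSG so glutathione atoms are conserved) and
#' Srx (import k29, stoichiometric consumption in the repair step).
#'
#' @param params A `redox_params` object; only the efflux mode and throttle
#'   scale affect the reaction definitions.
#' @return List of 30 reactions, each a list with elements `id`, `description`,
#'   `rate` and `stoich`.
#' @export
reaction_set <- function(params = default_parameters()) {
  stopifnot(inherits(params, "redox_params"))
  first_order_efflux <- identical(params$efflux_mode, "first_order")
  eps <- params$eps

  rx <- function(id, description, rate, stoich) {
    list(id = id, description = description, rate = rate, stoich = stoich)
  }

  list(
    rx("R01", "H2O2 generation by OxPhos",
       function(y, k) k[["k1"]],
       c(H2O2 = 1)),
    rx("R02", "Gpx1 oxidation by H2O2",
       function(y, k) k[["k2"]] * y[["Gpx1_red"]] * y[["H2O2"]],
       c(Gpx1_red = -1, H2O2 = -1, Gpx1_ox = 1)),
    rx("R03", "Gpx1ox glutathionylation",
       function(y, k) k[["k3"]] * y[["Gpx1_ox"]] * y[["GSH"]],
       c(Gpx1_ox = -1, GSH = -1, Gpx1_SSG = 1)),
    rx("R04", "Gpx1-SSG reduction by GSH",
       function(y, k) k[["k4"]] * y[["Gpx1_SSG"]] * y[["GSH"]],
       c(Gpx1_SSG = -1, GSH = -1, Gpx1_red = 1, GSSG = 1)),
    rx("R05", "NADPH regeneration (Michaelis-Menten, Vmax k20, Km k5)",
       function(y, k) k[["k20"]] * y[["NADPp"]] / (k[["k5"]] + y[["NADPp"]]),
       c(NADPp = -1, NADPH = 1)),
    rx("R06", "Prx3 peroxidatic oxidation",
       function(y, k) k[["k6"]] * y[["Prx3_SH"]] * y[["H2O2"]],
       c(Prx3_SH = -1, H2O2 = -1, Prx3_SOH = 1)),
    rx("R07", "Prx3 hyperoxidation to sulfinic acid",
       function(y, k) k[["k7"]] * y[["Prx3_SOH"]] * y[["H2O2"]],
       c(Prx3_SOH = -1, H2O2 = -1, Prx3_SOOH = 1)),
    rx("R08", "Srx-mediated Prx3-SOOH repair (Srx consumed)",
       function(y, k) k[["k8"]] * y[["Prx3_SOOH"]] * y[["Srx"]],
       c(Prx3_SOOH = -1, Srx = -1, Prx3_SOH = 1)),
    rx("R09", "Prx3 resolution (disulfide formation)",
       function(y, k) k[["k9"]] * y[["Prx3_SOH"]],
       c(Prx3_SOH = -1, Prx3_SS = 1)),
    rx("R10", "Prx3-SS recycling by Trx2",
       function(y, k) k[["k10"]] * y[["Prx3_SS"]] * y[["Trx2_SH"]],
       c(Prx3_SS = -1, Trx2_SH = -1, Prx3_SH = 1, Trx2_SS = 1)),
    rx("R11", "GSH autoxidation",
       function(y, k) k[["k11"]] * y[["GSH"]],
       c(GSH = -1, GSSG = 0.5)),
    rx("R12", "Protein monothiol oxidation by H2O2",
       function(y, k) k[["k12"]] * y[["Pr_SH"]] * y[["H2O2"]],
       c(Pr_SH = -1, H2O2 = -1, Pr_SOH = 1)),
    rx("R13", "Protein sulfenic acid glutathionylation",
       function(y, k) k[["k13"]] * y[["Pr_SOH"]] * y[["GSH"]],
       c(Pr_SOH = -1, GSH = -1, Pr_SSG = 1)),
    rx("R14", "Grx2 deglutathionylation of Pr-SSG",
       function(y, k) k[["k14"]] * y[["Grx2_SH"]] * y[["Pr_SSG"]],
       c(Grx2_SH = -1, Pr_SSG = -1, Pr_SH = 1, Grx2_SSG = 1)),
    rx("R15", "Grx2-SSG reduction by GSH",
       function(y, k) k[["k15"]] * y[["Grx2_SSG"]] * y[["GSH"]],
       c(Grx2_SSG = -1, GSH = -1, Grx2_SH = 1, GSSG = 1)),
    rx("R16", "Protein dithiol oxidation by H2O2",
       function(y, k) k[["k16"]] * y[["Pr_SH2"]] * y[["H2O2"]],
       c(Pr_SH2 = -1, H2O2 = -1, Pr_SS = 1)),
    rx("R17", "Protein disulfide recycling by Trx2",
       function(y, k) k[["k17"]] * y[["Pr_SS"]] * y[["Trx2_SH"]],
       c(Pr_SS = -1, Trx2_SH = -1, Pr_SH2 = 1, Trx2_SS = 1)),
    rx("R18", "GSSG reduction by NADPH (glutathione reductase)",
       function(y, k) k[["k18"]] * y[["GSSG"]] * y[["NADPH"]],
       c(GSSG = -1, NADPH = -1, GSH = 2, NADPp = 1)),
    rx("R19", "Trx2-SS reduction by NADPH (thioredoxin reductase)",
       function(y, k) k[["k19"]] * y[["Trx2_SS"]] * y[["NADPH"]],
       c(Trx2_SS = -1, NADPH = -1, Trx2_SH = 1, NADPp = 1)),
    rx("R20", "GSH import",
       function(y, k) k[["k21"]],
       c(GSH = 1)),
    rx("R21", "GSH efflux",
       function(y, k) k[["k22"]] * y[["GSH"]],
       c(GSH = -1)),
    rx("R22", "Prx5 peroxidatic oxidation",
       function(y, k) k[["k23"]] * y[["Prx5_SH"]] * y[["H2O2"]],
       c(Prx5_SH = -1, H2O2 = -1, Prx5_SOH = 1)),
    rx("R23", "Prx5 resolution",
       function(y, k) k[["k24"]] * y[["Prx5_SOH"]],
       c(Prx5_SOH = -1, Prx5_SS = 1)),
    rx("R24", "Prx5-SS recycling by Trx2",
       function(y, k) k[["k25"]] * y[["Prx5_SS"]] * y[["Trx2_SH"]],
       c(Prx5_SS = -1, Trx2_SH = -1, Prx5_SH = 1, Trx2_SS = 1)),
    rx("R25", "Gpx4 oxidation by H2O2",
       function(y, k) k[["k26"]] * y[["Gpx4_red"]] * y[["H2O2"]],
       c(Gpx4_red = -1, H2O2 = -1, Gpx4_ox = 1)),
    rx("R26", "Gpx4ox glutathionylation",
       function(y, k) k[["k27"]] * y[["Gpx4_ox"]] * y[["GSH"]],
       c(Gpx4_ox = -1, GSH = -1, Gpx4_SSG = 1)),
    rx("R27", "Gpx4-SSG reduction by GSH (rate constant k4)",
       function(y, k) k[["k4"]] * y[["Gpx4_SSG"]] * y[["GSH"]],
       c(Gpx4_SSG = -1, GSH = -1, Gpx4_red = 1, GSSG = 1)),
    rx("R28", "H2O2 generation by DAAO (kDAAO)",
       function(y, k) k[["k28"]],
       c(H2O2 = 1)),
    rx("R29", "Srx import",
       function(y, k) k[["k29"]],
       c(Srx = 1)),
    rx("R30",
       if (first_order_efflux) "H2O2 efflux (first order)" else
         "H2O2 efflux (zeroth order, throttled below eps)",
       if (first_order_efflux) {
         function(y, k) k[["k30"]] * y[["H2O2"]]
       } else {
         function(y, k) k[["k30"]] * min(1, y[["H2O2"]] / eps)
       },
       c(H2O2 = -1))
  )
}

#' Stoichiometry matrix of the network
#'
#' @param params A `redox_params` object.
#' @return A 28 x 30 numeric matrix; rows are species, columns reactions.
#'   Entry (i, j) is the signed coefficient of species i in reaction j.
#' @export
stoichiometry_matrix <- function(params = default_parameters()) {
  rset <- reaction_set(params)
  S <- matrix(0, nrow = 28L, ncol = length(rset),
              dimnames = list(species_names(),
                              vapply(rset, `[[`, "", "id")))
  for (j in seq_along(rset)) {
    st <- rset[[j]]$stoich
    S[names(st), j] <- st
  }
  S
}

#' Evaluate the 30 reaction fluxes at a state
#'
#' @param state Named numeric state vector (uM); must be non-negative.
#' @param params A `redox_params` object.
#' @return Named numeric vector of 30 fluxes (uM/s), all non-negative.
#' @export
reaction_rates <- function(state, params = default_parameters()) {
  state <- assert_state(state)
  rset <- reaction_set(params)
  v <- vapply(rset, function(r) r$rate(state, params$k), numeric(1))
  names(v) <- vapply(rset, `[[`, "", "id")
  v
}

#' Right-hand side of the ODE system
#'
#' The time derivative of every species is the stoichiometry-weighted sum of
#' the 30 reaction fluxes.  This is the reference (pure R) implementation; the
#' integrator uses a compiled translation that the test suite verifies against
#' this one.
#'
#' @inheritParams reaction_rates
#' @return Named numeric vector of d(state)/dt (uM/s).
#' @export
network_rhs <- function(state, params = default_parameters()) {
  v <- reaction_rates(state, params)
  S <- stoichiometry_matrix(params)
  stats::setNames(as.vector(S %*% v), rownames(S))
}

# rhs in the signature deSolve expects, for the "R" integration engine
rhs_desolve_r <- function(t, y, parms) {
  params <- parms$params
  S <- parms$S
  rset <- parms$rset
  k <- params$k
  v <- vapply(rset, function(r) r$rate(y, k), numeric(1))
  list(as.vector(S %*% v))
}

#' Export the model definition as a structured text document
#'
#' Writes species, parameters (with the efflux mode) and the reaction list
#' (rate constants and signed stoichiometry) as YAML, a plain-text schema that
#' can be re-read with [yaml::read_yaml()] or translated to other exchange
#' formats.
#'
#' @param params A `redox_params` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_model_definition <- function(params = default_parameters(), path) {
  rset <- reaction_set(params)
  doc <- list(
    model = "mitochondrial H2O2 reaction network",
    units = list(concentration = "uM", time = "s"),
    species = as.list(species_names()),
    parameters = c(as.list(params$k),
                   list(efflux_mode = params$efflux_mode, eps = params$eps)),
    reactions = lapply(rset, function(r) {
      list(id = r$id, description = r$description,
           stoichiometry = as.list(r$stoich))
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}
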