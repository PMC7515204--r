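#' Mitochondrial geometry for unit conversions
#'
#' @param volume_um3 Volume of a single mitochondrion (cubic micrometers).
#' @param mito_per_cell Length-2 ordered range of the number of mitochondria
#'   per cell.
#' @param protein_density_mg_l Total cellular protein density (mg/L), assumed
#'   organelle-invariant.
#' @return A `mito_geometry` list.
#' @export
mito_geometry <- function(volume_um3 = 0.29,
                          mito_per_cell = c(383, 882),
                          protein_density_mg_l = 2e5) {
  if (volume_um3 <= 0 || any(mito_per_cell <= 0) ||
      protein_density_mg_l <= 0) {
    stop("geometry values must be strictly positive", call. = FALSE)
  }
  if (length(mito_per_cell) != 2L || mito_per_cell[1] > mito_per_cell[2]) {
    stop("mito_per_cell must be an ordered range c(min, max)", call. = FALSE)
  }
  structure(list(volume_um3 = volume_um3, mito_per_cell = mito_per_cell,
                 protein_density_mg_l = protein_density_mg_l),
            class = "mito_geometry")
}

AVOGADRO <- 6.02214076e23

#' Convert per-cell protein copy numbers to per-mitochondrion concentration
#'
#' Assumes the copies are partitioned equally across the cell's mitochondria;
#' the per-mitochondrion concentration is then
#' `copies / (N_A * V_mito * n_mito)`.  Because the mitochondrial count is
#' only known as a range, a concentration range is returned: the lower bound
#' uses the maximum count, the upper bound the minimum count (their ratio is
#' fixed at `max / min` of the count range).
#'
#' @param copies_per_cell Protein copies per cell (>= 0).
#' @param geometry A [mito_geometry()] object.
#' @return Named numeric vector `c(min_uM, max_uM)`.
#' @export
copies_to_concentration <- function(copies_per_cell,
                                    geometry = mito_geometry()) {
  stopifnot(inherits(geometry, "mito_geometry"))
  if (copies_per_cell < 0) {
    stop("copies_per_cell must be non-negative", call. = FALSE)
  }
  v_l <- geometry$volume_um3 * 1e-15           # um^3 -> L
  conc <- function(n_mito) {
    copies_per_cell / (AVOGADRO * v_l * n_mito) * 1e6  # mol/L -> uM
  }
  c(min_uM = conc(geometry$mito_per_cell[2]),
    max_uM = conc(geometry$mito_per_cell[1]))
}

#' Invert [copies_to_concentration()] for a single mitochondrial count
#'
#' @param concentration_uM Per-mitochondrion concentration (uM).
#' @param n_mito Mitochondria per cell used for the inversion.
#' @param geometry A [mito_geometry()] object.
#' @return Protein copies per cell.
#' @export
concentration_to_copies <- function(concentration_uM, n_mito = 1,
                                    geometry = mito_geometry()) {
  stopifnot(inherits(geometry, "mito_geometry"))
  if (concentration_uM < 0) {
    stop("concentration must be non-negative", call. = FALSE)
  }
  v_l <- geometry$volume_um3 * 1e-15
  concentration_uM * 1e-6 * AVOGADRO * v_l * n_mito
}

#' Convert a volumetric rate to a protein-specific rate
#'
#' Expresses a volumetric H2O2 generation rate (uM/s) per milligram of
#' protein, using the cellular protein density: `rate / density` in
#' nmol/mg-protein/s.  At the default density of 2e5 mg/L, 50 uM/s
#' corresponds to 0.25 nmol/mg-protein/s.
#'
#' @param rate_uM_s Volumetric rate (uM/s).
#' @param protein_density_mg_l Protein density (mg/L), > 0.
#' @return Rate in nmol per mg protein per second.
#' @export
volumetric_to_specific_rate <- function(rate_uM_s,
                                        protein_density_mg_l = 2e5) {
  if (protein_density_mg_l <= 0) {
    stop("protein density must be positive", call. = FALSE)
  }
  # uM/s = 1e-6 mol/L/s = 1e3 nmol/L/s; divide by mg/L to get nmol/mg/s
  rate_uM_s * 1e3 / protein_density_mg_l
}
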