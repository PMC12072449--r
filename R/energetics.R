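# Center-of-mass collision energy with degrees-of-freedom correction.
#
# In-source CID on a single quadrupole: the cone voltage (V) is taken
# numerically as the laboratory collision energy E_lab (eV) for a singly
# charged ion. The maximum energy transferable to internal modes is
#   E_com_delta = delta * E_lab * m_g / (m_p + m_g)
# with m_g the collision-gas mass (N2, 28 amu), m_p the adduct ion mass, and
# delta = DOF_ref / DOF_adduct the correction that makes adducts of different
# sizes comparable (delta = 1 for the reference, conventionally the smallest
# adduct analyzed).

#' Collision settings for an in-source CID experiment
#'
#' @param cone_voltages Ordered cone voltages in V (numerically the laboratory
#'   collision energies in eV for singly charged ions). Default is the
#'   low-voltage ramp 10, 15, 20, 25, 30 V used to avoid glycosidic cleavage.
#' @param gas_mass Collision-gas mass in amu; default 28 (N2).
#' @param reference_dof DOF of the reference adduct (the one with delta = 1).
#'   May be `NULL` at construction and filled later by
#'   [select_reference_dof()].
#' @return A `collision_settings` list.
#' @export
collision_settings <- function(cone_voltages = c(10, 15, 20, 25, 30),
                               gas_mass = 28, reference_dof = NULL) {
  if (!is.numeric(gas_mass) || gas_mass <= 0) stop("gas_mass must be > 0")
  if (length(cone_voltages) < 1L || any(cone_voltages <= 0)) {
    stop("cone_voltages must all be > 0")
  }
  if (is.unsorted(cone_voltages, strictly = TRUE)) {
    stop("cone_voltages must be strictly increasing")
  }
  if (!is.null(reference_dof)) {
    if (reference_dof < 3) stop("reference_dof must be >= 3")
    reference_dof <- as.integer(reference_dof)
  }
  structure(list(gas_mass = gas_mass,
                 cone_voltages = as.numeric(cone_voltages),
                 reference_dof = reference_dof),
            class = "collision_settings")
}

#' DOF correction factor delta = DOF_ref / DOF_adduct
#'
#' Equals 1 when the adduct is the reference; lies in (0, 1] for every adduct
#' when the reference is the minimum-DOF adduct of the analyzed set. A value
#' above 1 (non-minimal reference supplied by the caller) is computed but
#' flagged with a warning.
#'
#' @param adduct_dof,reference_dof Integer vibrational DOF (>= 3).
#' @return Dimensionless correction factor.
#' @examples
#' delta_factor(246, 246)  # reference adduct: 1
#' @export
delta_factor <- function(adduct_dof, reference_dof) {
  if (any(adduct_dof < 3) || any(reference_dof < 3)) {
    stop("DOF values must be >= 3")
  }
  d <- reference_dof / adduct_dof
  if (any(d > 1)) {
    warning("delta > 1: reference adduct is not the smallest in the set")
  }
  d
}

#' Center-of-mass collision energy
#'
#' `E_com_delta = delta * e_lab * m_g / (m_p + m_g)`. Linear in `e_lab`,
#' strictly decreasing in the adduct mass.
#'
#' @param e_lab Laboratory collision energy in eV (cone voltage in V for a
#'   singly charged ion).
#' @param adduct_mass Adduct ion mass m_p in Da (treated as amu).
#' @param gas_mass Collision-gas mass m_g in amu, or a [collision_settings]
#'   object whose `gas_mass` is used.
#' @param delta DOF correction factor (default 1, the reference adduct).
#' @return Center-of-mass energy in eV.
#' @examples
#' ecom(30, 784, 28)  # ~1.034 eV
#' @export
ecom <- function(e_lab, adduct_mass, gas_mass = 28, delta = 1) {
  if (inherits(gas_mass, "collision_settings")) gas_mass <- gas_mass$gas_mass
  if (any(e_lab <= 0)) stop("e_lab must be > 0")
  if (any(adduct_mass <= 0)) stop("adduct_mass must be > 0")
  if (any(gas_mass <= 0)) stop("gas_mass must be > 0")
  if (any(delta <= 0)) stop("delta must be > 0")
  delta * e_lab * gas_mass / (adduct_mass + gas_mass)
}

#' Select the reference DOF from a set of adducts
#'
#' The reference is the minimum-DOF adduct among those analyzed, so every
#' delta lies in (0, 1].
#'
#' @param adducts List of `adduct_ion` objects (or integer DOF values).
#' @return Integer reference DOF.
#' @export
select_reference_dof <- function(adducts) {
  dofs <- vapply(adducts, function(a) {
    if (inherits(a, "adduct_ion")) a$dof else as.integer(a)
  }, integer(1))
  if (length(dofs) == 0L) stop("no adducts supplied")
  min(dofs)
}

#' Energy axis for one adduct across the cone-voltage ramp
#'
#' One row per cone voltage with the DOF correction and center-of-mass energy
#' for the given adduct. The `ratio` column is `NA` until filled by the
#' stability stage.
#'
#' @param adduct An `adduct_ion` (from [make_adduct()]).
#' @param settings A [collision_settings] with `reference_dof` set.
#' @return Tibble with columns `e_lab_V`, `delta`, `e_com_eV`, `ratio`.
#' @export
energy_axis <- function(adduct, settings) {
  stopifnot(inherits(adduct, "adduct_ion"),
            inherits(settings, "collision_settings"))
  if (is.null(settings$reference_dof)) {
    stop("settings$reference_dof is not set; see select_reference_dof()")
  }
  d <- delta_factor(adduct$dof, settings$reference_dof)
  tibble::tibble(
    e_lab_V = settings$cone_voltages,
    delta = d,
    e_com_eV = ecom(settings$cone_voltages, adduct$mz_mono,
                    settings$gas_mass, d),
    ratio = NA_real_
  )
}
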