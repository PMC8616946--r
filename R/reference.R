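# Worked-example records: literature-reported descriptor values for
# materials whose superoxide-scavenging behaviour is experimentally
# established. These anchor the tests and the documentation examples.

#' Reference worked-example materials
#'
#' A named list of frozen literature descriptor values, each entry
#' carrying a short `note` naming the quantity in plain words:
#' \describe{
#'   \item{graphene}{metal; measured Fermi level -0.19 V vs HE pH 7,
#'     just below the window edge (an example of a near-miss that a small
#'     classification tolerance admits).}
#'   \item{V2C}{MXene metal; measured reduction potential -0.11 V,
#'     inside the window.}
#'   \item{nanographene}{measured reduction potential 0.40 V, inside the
#'     window and near its midpoint; ingested as a lone unoccupied
#'     frontier level (see [reduction_potential_summary()]).}
#'   \item{MIL53_NH2 / MIL53_NO2}{the two metal-organic-framework series
#'     endpoints with individually reported reduction potentials, 0.28 V
#'     and 0.31 V.}
#'   \item{CeO2_111_pristine}{defect-free ceria (111): computed
#'     `E_ads,H = -3.68` eV, violating the H-adsorption criterion (oxygen
#'     vacancies in practical nanoceria weaken the binding).}
#'   \item{MIL47_V}{vanadium MOF: computed adsorption energies about
#'     -0.76 eV (HO) and -4.25 eV (H); the H criterion fails, matching
#'     its negligible measured activity.}
#' }
#'
#' @return a named list; entries carry numeric fields plus a `note`.
#' @seealso [mil53_series()] for the full substituent series.
#' @export
reference_materials <- function() {
  list(
    graphene = list(
      is_metal = TRUE, fermi_potential = -0.19,
      band = band_summary("graphene", is_metal = TRUE,
                          fermi_potential = -0.19),
      note = "measured Fermi level of graphene, V vs HE at pH 7"),
    V2C = list(
      is_metal = TRUE, fermi_potential = -0.11,
      band = band_summary("V2C", is_metal = TRUE, fermi_potential = -0.11),
      note = "measured reduction potential of the V2C MXene"),
    nanographene = list(
      reduction_potential = 0.40,
      band = reduction_potential_summary("nanographene", 0.40),
      note = "measured reduction potential of nanographene"),
    MIL53_NH2 = list(
      reduction_potential = 0.28,
      band = reduction_potential_summary("MIL53_NH2", 0.28),
      note = "reduction potential of the NH2-substituted iron MOF"),
    MIL53_NO2 = list(
      reduction_potential = 0.31,
      band = reduction_potential_summary("MIL53_NO2", 0.31),
      note = "reduction potential of the NO2-substituted iron MOF"),
    CeO2_111_pristine = list(
      ads = list(e_ads_h = -3.68),
      note = "computed H adsorption energy on defect-free ceria (111), eV"),
    MIL47_V = list(
      ads = list(e_ads_ho = -0.76, e_ads_h = -4.25),
      note = "computed HO and H adsorption energies of the vanadium MOF, eV")
  )
}

#' Iron-MOF substituent series
#'
#' The MIL-53(Fe)-X substituent series ordered by increasing Hammett
#' sigma-meta constant (increasing electron-withdrawing strength). Only
#' the series endpoints carry individually reported reduction potentials
#' (0.28 V for NH2, 0.31 V for NO2); the `reduction_potential_interp_V`
#' column linearly interpolates between them in sigma and is marked
#' synthetic -- use it for illustration only. `activity_rank` orders the
#' measured activities (1 = best), which track proximity of the reduction
#' potential to the window midpoint.
#'
#' @return a data frame with columns `substituent`, `hammett_sigma_m`,
#'   `reduction_potential_V` (NA except the endpoints),
#'   `reduction_potential_interp_V` (synthetic interpolation) and
#'   `activity_rank`.
#' @export
mil53_series <- function() {
  # Hammett sigma-meta constants from the standard substituent tables.
  sigma <- c(NH2 = -0.16, CH3 = -0.07, H = 0.00, HO = 0.12,
             F = 0.34, Cl = 0.37, Br = 0.39, NO2 = 0.71)
  measured <- c(NH2 = 0.28, NO2 = 0.31)
  pot <- rep(NA_real_, length(sigma))
  names(pot) <- names(sigma)
  pot[names(measured)] <- measured
  interp <- measured[["NH2"]] +
    (sigma - sigma[["NH2"]]) / (sigma[["NO2"]] - sigma[["NH2"]]) *
    (measured[["NO2"]] - measured[["NH2"]])
  # measured activity improves with sigma (NO2 best, NH2 worst)
  rank <- rev(seq_along(sigma))
  data.frame(substituent = names(sigma),
             hammett_sigma_m = unname(sigma),
             reduction_potential_V = unname(pot),
             reduction_potential_interp_V = unname(interp),
             activity_rank = rank,
             stringsAsFactors = FALSE)
}
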