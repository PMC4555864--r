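#' Reference calibration table: 14 extant quadrupedal mammal skeletons
#'
#' Published museum reference sample used to calibrate the predictive
#' equations: species, assigned body mass (kg), unsegmented convex-hull
#' volume `c_vol_m3`, summed segmented convex-hull volume
#' `c_vol_sub_m3`, and alpha-shape volume `alpha_vol_m3` at the optimal
#' refinement coefficient, all computed from skeletons downsampled to
#' 500 000 points.
#'
#' @return data.frame with columns `species`, `mass_kg`, `c_vol_m3`,
#'   `c_vol_sub_m3`, `alpha_vol_m3`.
#' @export
#' @examples
#' ref <- reference_skeletons()
#' fit_loglog_ols(ref$alpha_vol_m3, ref$mass_kg)
reference_skeletons <- function() {
  read.csv(system.file("extdata", "reference_skeletons.csv",
                       package = "alphamass"))
}

#' Published fossil alpha-shape volumes
#'
#' Reconstructed alpha-shape volumes (m^3) of the woolly mammoth and the
#' giant ground sloth composite skeletons at 500 000 points, the inputs
#' to the published mass predictions.
#'
#' @return data.frame with columns `specimen_id`, `alpha_vol_m3`,
#'   `n_points`.
#' @export
fossil_volumes <- function() {
  read.csv(system.file("extdata", "fossil_volumes.csv",
                       package = "alphamass"))
}

#' Published 500k-point predictive model
#'
#' The published predictive equation `ln(mass) = a + b ln(alpha_vol)`
#' calibrated on [reference_skeletons()] at 500 000 points per skeleton
#' (a = 6.922, b = 0.988, k = 0.427), as a ready-to-use `mass_model` for
#' [predict_mass()].
#'
#' @return a `mass_model`.
#' @export
#' @examples
#' predict_mass(published_model(), fossil_volumes()$alpha_vol_m3)
published_model <- function() {
  read_model(system.file("extdata", "published_model_500k.json",
                         package = "alphamass"))
}
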