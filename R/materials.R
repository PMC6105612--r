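# Packaged reference tables.

#' Fabricated dye-in-polymer standard materials
#'
#' Thickness (inches) and europium pigment concentration
#' (parts-per-thousand by weight) of the nine fabricated standard sheets.
#'
#' @return Data.frame `standard, thickness_in, concentration_ppt`.
#' @export
standard_materials <- function() {
  path <- system.file("extdata", "standards_materials.csv",
                      package = "ppixquant", mustWork = TRUE)
  utils::read.csv(path)
}

#' Packaged power-meter anchor readings
#'
#' The peak incident blue-light power densities measured at 100% light
#' setting: 25.2 mW/cm^2 at 20 cm and 4.7 mW/cm^2 at 35 cm working
#' distance, used to calibrate the distance exponent.
#'
#' @return Data.frame `distance_cm, setting_pct, power_mw_cm2`.
#' @export
power_anchors <- function() {
  read_power_meter(system.file("extdata", "power_anchors.csv",
                               package = "ppixquant", mustWork = TRUE))
}
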