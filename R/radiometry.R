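#' Radiant emission via the Stefan-Boltzmann law
#'
#' Total radiation emitted by a grey body, `E = emissivity * sigma * T^4`
#' (W m^-2). This is the radiometric relationship a thermal camera inverts
#' to report per-pixel temperature: emissivity is static for most materials,
#' so changes in observed radiation are attributed to temperature changes.
#'
#' @param temperature_k Absolute temperature in kelvin (> 0). Vectorized.
#' @param emissivity Dimensionless emissivity in (0, 1]; 1 is a black body.
#' @param sigma Stefan-Boltzmann constant, W m^-2 K^-4.
#' @return Emitted flux in W m^-2, same length as `temperature_k`.
#' @examples
#' radiant_emission(300)                 # black body at room temperature
#' radiant_emission(300, emissivity = 0.95)
#' @export
radiant_emission <- function(temperature_k, emissivity = 1,
                             sigma = 5.670374419e-8) {
  stopifnot(is.numeric(temperature_k), is.numeric(emissivity))
  if (any(temperature_k <= 0)) {
    stop("absolute temperature must be strictly positive", call. = FALSE)
  }
  if (any(emissivity < 0 | emissivity > 1)) {
    stop("emissivity must lie in [0, 1]", call. = FALSE)
  }
  emissivity * sigma * temperature_k^4
}
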