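## Compartment label codes shared by the simulator ground truth and the
## pixel classifier.  Kept as plain integers so label maps serialize to TIFF.
LABELS <- c(background = 0L, cytosol = 1L, matrix = 2L, ibm = 3L,
            crista = 4L, vesicle = 5L)

#' Compartment label palette
#'
#' Integer codes used in compartment label maps: background = 0, cytosol = 1,
#' matrix = 2, ibm = 3, crista = 4, vesicle = 5.
#'
#' @return Named integer vector of label codes.
#' @export
compartment_labels <- function() LABELS

## CODATA physical constants.
.R_GAS <- 8.314462618   # J mol^-1 K^-1
.FARADAY <- 96485.33212 # C mol^-1

#' Nernstian slope RT/F in millivolt
#'
#' The factor converting a log concentration ratio of a monovalent cation
#' into a potential difference: kappa = 1000 * R * T / (z * F) mV with
#' z = +1 for TMRE/TMRM/Rho123.
#'
#' @param temperature_K Absolute temperature in kelvin (default 310.15 K,
#'   i.e. 37 C live-cell imaging).
#' @return kappa in mV (about 26.73 mV at 310.15 K).
#' @examples
#' nernst_kappa()          # 26.73
#' nernst_kappa(298.15)    # room temperature
#' @export
nernst_kappa <- function(temperature_K = 310.15) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  1000 * .R_GAS * temperature_K / .FARADAY
}
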