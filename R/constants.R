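#' Physical constants and unit conversions
#'
#' Internal unit system: Angstrom (length), femtosecond (time),
#' electronvolt (energy), unified atomic mass unit (mass).  In these units
#' kinetic energy is `0.5 * m * v^2 * EV_PER_AMU_A2_FS2`.
#'
#' @format Named list with elements:
#' \describe{
#'   \item{EV_PER_AMU_A2_FS2}{1 amu (Angstrom/fs)^2 expressed in eV
#'     (103.642697...), from 1 amu = 1.66053906660e-27 kg and
#'     1 eV = 1.602176634e-19 J.}
#'   \item{KB_EV}{Boltzmann constant, eV/K (8.617333262e-5, CODATA 2018).}
#' }
#' @export
eims_constants <- list(
  EV_PER_AMU_A2_FS2 = 1.66053906660e-27 * 1e10 / 1.602176634e-19,
  KB_EV = 8.617333262e-5
)

# shorthand used throughout the package internals
.EV_KIN <- eims_constants$EV_PER_AMU_A2_FS2
.KB <- eims_constants$KB_EV
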