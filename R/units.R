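# Unit conventions used throughout: pressure in mmHg on the circuit side and
# kPa on the tissue side, length in cm, time in s, flow in mL/s,
# resistance in mmHg s/mL, compliance in mL/mmHg.

#' Unit conversion constants
#'
#' `DYN_PER_MMHG` converts mmHg to dyn/cm^2 (CGS pressure); `KPA_PER_MMHG`
#' converts mmHg to kPa. Exposed because the Bernoulli orifice law mixes CGS
#' fluid quantities with mmHg circuit pressures.
#'
#' @format Numeric scalars.
#' @name units
NULL

#' @rdname units
#' @export
DYN_PER_MMHG <- 1333.22

#' @rdname units
#' @export
KPA_PER_MMHG <- 1333.22 / 1e4

# cP -> poise (g/(cm s))
POISE_PER_CP <- 0.01
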