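#' Pressure unit conversion
#'
#' Convert between millimetres of mercury and pascals. All internal
#' computation in the package is in SI units (Pa, m, m^3/s); mmHg appears
#' only at input/output boundaries such as cohort tables and configs.
#'
#' The conversion factor is 133.322 Pa per mmHg, applied exactly in both
#' directions.
#'
#' @param x numeric vector of pressures.
#' @return numeric vector of converted pressures.
#' @examples
#' mmHg_to_Pa(90)       # 11999 Pa, a typical mean aortic pressure
#' Pa_to_mmHg(mmHg_to_Pa(72.5))
#' @export
mmHg_to_Pa <- function(x) x * 133.322

#' @rdname mmHg_to_Pa
#' @export
Pa_to_mmHg <- function(x) x / 133.322
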