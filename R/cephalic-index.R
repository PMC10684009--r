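#' Cephalic index
#'
#' The cephalic index is the ratio of maximum skull width (mediolateral) to
#' maximum skull length (anteroposterior). It is the standard aesthetic
#' outcome measure in sagittal craniosynostosis, where the skull is long and
#' narrow (scaphocephaly, CI around 0.70 or below in affected infants).
#'
#' The index is returned as a dimensionless ratio (e.g. 116/165 = 0.703);
#' multiply by 100 for the percent convention used when comparing surrogate
#' error magnitudes.
#'
#' @param width Skull width(s), mm (or any consistent unit).
#' @param length Skull length(s), mm. Must be strictly positive.
#' @return Numeric vector `width / length`.
#' @examples
#' compute_cephalic_index(116, 165) # 0.703, reported as 0.70
#' compute_cephalic_index(114, 160) # 0.7125, reported as 0.71
#' @export
compute_cephalic_index <- function(width, length) {
  if (!is.numeric(width) || !is.numeric(length)) {
    abort("`width` and `length` must be numeric.")
  }
  if (any(!is.finite(length)) || any(length <= 0)) {
    abort("`length` must be finite and strictly positive.")
  }
  if (any(!is.finite(width)) || any(width < 0)) {
    abort("`width` must be finite and non-negative.")
  }
  width / length
}
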