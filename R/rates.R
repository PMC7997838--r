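#' Specific reaction rate laws
#'
#' The two rate laws used throughout the package, both returning a specific
#' rate in umol per mg biomass per h (the network ODE multiplies by biomass
#' to obtain umol l^-1 h^-1).
#'
#' `rate_first_order()` is the plain first-order law r = kS.
#'
#' `rate_inhibited()` multiplies the first-order rate by the inhibition
#' factor `k_i / (k_i + S_i)`, giving r = k (k_i / (k_i + S_i)) S. With `S_i`
#' the concentration of a different compound this expresses competitive
#' inhibition by a secondary substrate; with `S_i` the substrate's own
#' concentration it expresses substrate self-inhibition. At `S_i = 0` it
#' reduces exactly to the first-order law; at `S_i = k_i` the rate is
#' exactly half the uninhibited rate; as `S_i` grows the rate decreases
#' monotonically toward zero.
#'
#' @param k first-order rate constant, l mg^-1 h^-1, `>= 0`.
#' @param S substrate concentration, umol/l, `>= 0`.
#' @param k_i inhibition factor, umol/l, `> 0`.
#' @param S_i inhibitory substrate concentration, umol/l, `>= 0`.
#' @return Specific rate(s), umol mg^-1 h^-1. All arguments are vectorized
#'   under the usual recycling rules.
#' @export
rate_first_order <- function(k, S) {
  if (any(k < 0, na.rm = TRUE)) abort("`k` must be >= 0")
  if (any(S < 0, na.rm = TRUE)) abort("`S` must be >= 0")
  k * S
}

#' @rdname rate_first_order
#' @export
rate_inhibited <- function(k, k_i, S, S_i) {
  if (any(k < 0, na.rm = TRUE)) abort("`k` must be >= 0")
  if (any(S < 0, na.rm = TRUE)) abort("`S` must be >= 0")
  if (any(S_i < 0, na.rm = TRUE)) abort("`S_i` must be >= 0")
  if (any(k_i <= 0, na.rm = TRUE)) abort("`k_i` must be > 0")
  k * (k_i / (k_i + S_i)) * S
}
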