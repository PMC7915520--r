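#' Map-function and RIL recombination utilities
#'
#' Conversions between genetic distance (cM), meiotic recombination
#' fraction r, and the recombination fraction R observed between fully
#' inbred (selfed) recombinant inbred lines.  The Kosambi map function is
#' used throughout; for selfed RILs the observed two-point recombination
#' fraction is inflated relative to a single meiosis, R = 2r / (1 + 2r)
#' (Haldane & Waddington), with inverse r = R / (2 - 2R).
#'
#' @param d_cM genetic distance in centimorgans (vectorized)
#' @param r meiotic recombination fraction in [0, 0.5)
#' @param R observed RIL recombination fraction in [0, 0.5)
#' @return the converted quantity, same length as the input
#' @name map_functions
NULL

#' @rdname map_functions
#' @export
kosambi_cM_to_r <- function(d_cM) {
  stopifnot(all(d_cM >= 0))
  0.5 * tanh(2 * d_cM / 100)
}

#' @rdname map_functions
#' @export
kosambi_r_to_cM <- function(r) {
  stopifnot(all(r >= 0), all(r < 0.5))
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname map_functions
#' @export
ril_r_to_R <- function(r) {
  stopifnot(all(r >= 0), all(r <= 0.5))
  2 * r / (1 + 2 * r)
}

#' @rdname map_functions
#' @export
ril_R_to_r <- function(R) {
  stopifnot(all(R >= 0), all(R < 0.5))
  R / (2 - 2 * R)
}

#' Expected RIL recombination fraction between map positions
#'
#' Composes the Kosambi map function with the selfed-RIL correction:
#' cM -> meiotic r -> observed R.
#'
#' @param d_cM inter-marker distance in cM
#' @return observed RIL recombination fraction
#' @export
ril_cM_to_R <- function(d_cM) {
  ril_r_to_R(kosambi_cM_to_r(d_cM))
}

#' Observed RIL recombination fraction back to map distance
#'
#' Inverse of [ril_cM_to_R()].  R is clamped just below 0.5 so that a
#' truncated estimate maps to a finite distance.
#'
#' @param R observed RIL recombination fraction
#' @param max_R clamp applied before back-transformation (default 0.49)
#' @return distance in cM
#' @export
ril_R_to_cM <- function(R, max_R = 0.49) {
  kosambi_r_to_cM(ril_R_to_r(pmin(R, max_R)))
}
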