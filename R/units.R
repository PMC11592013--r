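#' Unit conversions for the mm-N-s-tonne system
#'
#' The solver works internally in a consistent mm-N-s-tonne system: stress in
#' MPa (N/mm^2), density in tonne/mm^3, energy in mJ (N mm). Interfaces accept
#' the units the bone literature prints: Young's modulus in GPa, density in
#' g/cm^3, impactor mass in kg and speed in km/h.
#'
#' @param x numeric value(s) to convert.
#' @return converted numeric value(s).
#' @name units
NULL

#' @rdname units
#' @export
gpa_to_mpa <- function(x) x * 1000

#' @rdname units
#' @export
mpa_to_gpa <- function(x) x / 1000

#' @rdname units
#' @export
gcm3_to_tmm3 <- function(x) x * 1e-9

#' @rdname units
#' @export
tmm3_to_gcm3 <- function(x) x * 1e9

#' @rdname units
#' @export
kmh_to_mms <- function(x) x * 1e6 / 3600

#' @rdname units
#' @export
kg_to_tonne <- function(x) x * 1e-3

#' Newtons to kilogram-force
#'
#' Impact forces in the craniofacial literature are often quoted in kgf;
#' 1 kgf = 9.80665 N.
#' @param x force in N.
#' @export
n_to_kgf <- function(x) x / 9.80665
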