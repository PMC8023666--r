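#' Physical constants used throughout the package
#'
#' Internal energies are in eV, coordinates in Angstrom, masses in amu,
#' angles in degrees.
#'
#' @format A named list:
#' \describe{
#'   \item{kB}{Boltzmann constant, eV/K.}
#'   \item{hbar_omega_factor}{Multiply by sqrt(lambda) with lambda an
#'     eigenvalue of the mass-weighted Hessian in eV/(Angstrom^2 amu) to
#'     obtain the mode quantum \eqn{\hbar\omega} in eV.}
#'   \item{cm1_to_eV}{One wavenumber (cm^-1) expressed in eV.}
#' }
#' @export
tbo_constants <- local({
  e_C <- 1.602176634e-19       # J per eV
  amu_kg <- 1.66053906660e-27
  hbar_Js <- 1.054571817e-34
  list(
    kB = 8.617333e-5,
    hbar_omega_factor = hbar_Js / e_C * sqrt(e_C / (amu_kg * 1e-20)),
    cm1_to_eV = 1.986445857e-23 / e_C
  )
})

#' Wrap an angle into the canonical interval [-180, 180)
#'
#' Dihedral angles live on a circle; all package functions canonicalize to
#' the half-open interval \eqn{[-180, 180)} degrees. Wrapping is idempotent
#' and preserves the angle modulo 360.
#'
#' @param angle Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, each value in [-180, 180).
#' @examples
#' wrap_angle(c(190, -180, 360))  # -170 -180 0
#' @export
wrap_angle <- function(angle) {
  if (!is.numeric(angle) || any(!is.finite(angle)))
    stop("wrap_angle: angles must be finite numeric values", call. = FALSE)
  ((angle + 180) %% 360) - 180
}

#' Periodic distance between two angles
#'
#' Shortest arc distance on the circle, \eqn{\min_k |a - b + 360k|},
#' in degrees. Symmetric, bounded by 180, and invariant under adding
#' full turns to either argument.
#'
#' @param a,b Numeric vectors of angles in degrees (recycled).
#' @return Numeric vector of distances in [0, 180].
#' @examples
#' periodic_distance(-179, 179)  # 2
#' @export
periodic_distance <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("periodic_distance: angles must be finite", call. = FALSE)
  d <- abs(wrap_angle(a - b))
  # wrap_angle maps 180 to -180; the distance metric needs |.| <= 180
  pmin(d, 360 - d)
}

#' Maximum per-component periodic distance between two torsion vectors
#' @param x,y Numeric vectors of equal length (degrees).
#' @return Scalar, degrees.
#' @keywords internal
max_periodic_distance <- function(x, y) {
  max(periodic_distance(x, y))
}
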