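## Elasticity-based contractile stress/force estimate for a spherical
## organoid.
##
## The organoid is treated as an incompressible, purely elastic sphere
## whose contraction is driven by an internal contractile stress acting
## like an external compressive pressure. The model relates that stress
## to the bulk response through K ~ 3E and represents the volume change
## by (4*pi/3) * deltaR^3, giving
##
##     sigma = 3 * E * (deltaR / r0)^3,      F = sigma * 4 * pi * r0^2,
##
## with deltaR taken from the PIV contraction deformation distance. Note
## the physics caveat: small-strain elasticity would give
## deltaV ~ 4*pi*r0^2*deltaR and K = E/(3(1-2nu)); the relations above
## are the model's own convention and are implemented verbatim, so the
## estimate should be read as a relative index of contractile force
## rather than an absolute wall stress.

#' Contractile stress from radial deformation
#'
#' `sigma = 3 * E * (deltaR / r0)^3` (Pa).
#'
#' @param geom an [OrganoidGeometry-class].
#' @param deltaR radial deformation in metres, `0 <= deltaR <= r0`;
#'   conventionally the per-beat contraction deformation distance.
#' @return Contractile stress in Pa.
#' @examples
#' g <- organoidGeometry(E = 1000, r0 = 100e-6)
#' contractileStress(g, 10e-6)  # 3 Pa
#' @export
contractileStress <- function(geom, deltaR) {
  stopifnot(is(geom, "OrganoidGeometry"))
  if (any(deltaR < 0)) stop("deltaR must be >= 0")
  if (any(deltaR > geom@r0))
    stop("deltaR exceeds the organoid radius; deformation beyond r0 ",
         "is unphysical")
  3 * geom@E * (deltaR / geom@r0)^3
}

#' Contractile force estimate
#'
#' `F = sigma * A` with the surface area `A = 4 * pi * r0^2`.
#'
#' @inheritParams contractileStress
#' @return A [ForceEstimate-class] carrying sigma (Pa), force (N), the
#'   deformation used (m) and the surface area (m^2).
#' @export
contractileForce <- function(geom, deltaR) {
  sigma <- contractileStress(geom, deltaR)
  area <- 4 * pi * geom@r0^2
  new("ForceEstimate", sigma = sigma, force = sigma * area,
      deltaR = deltaR, area = area)
}
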