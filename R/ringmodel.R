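#' Sphere diameter of a globular protein from its mass
#'
#' Treats the protein as a sphere of volume \eqn{M \bar v}, the standard
#' globular approximation with partial specific volume \eqn{\bar v} (default
#' 0.73 cm^3/g). In these units 1 Da at \eqn{\bar v = 0.73} cm^3/g occupies
#' \eqn{1.212 \times 10^{-3}} nm^3.
#'
#' @param mass_kda Molecular mass, kDa.
#' @param partial_specific_volume \eqn{\bar v}, cm^3/g.
#' @return Sphere diameter, nm.
#' @export
sphere_diameter_from_mass <- function(mass_kda,
                                      partial_specific_volume = 0.73) {
  if (!is.numeric(mass_kda) || any(mass_kda <= 0))
    stop("mass must be positive")
  stopifnot(partial_specific_volume > 0)
  # 1 Da * 1 cm^3/g = 1.66054e-3 nm^3
  volume_nm3 <- mass_kda * 1000 * partial_specific_volume * 1.66054e-3
  2 * (3 * volume_nm3 / (4 * pi))^(1 / 3)
}

#' Center-circle diameter of a ring of touching spheres
#'
#' For \code{n} identical touching spheres of diameter \code{d} arranged in a
#' closed circle, the circle through the sphere centres has circumference
#' approximately \code{n * d}, giving diameter \code{n * d / pi}.
#'
#' @param n_subunits Number of subunits (at least 3 to close a ring).
#' @param subunit_diameter Sphere diameter, nm.
#' @return Ring (centre-circle) diameter, nm.
#' @export
ring_diameter <- function(n_subunits, subunit_diameter) {
  if (any(n_subunits < 3)) stop("a closed ring needs at least 3 subunits")
  stopifnot(all(subunit_diameter >= 0))
  n_subunits * subunit_diameter / pi
}

#' Subunit count from ring and subunit diameters
#'
#' Exact inverse of \code{\link{ring_diameter}}: \code{pi * ring_diameter /
#' subunit_diameter}. Returned as a real number; non-integer values indicate
#' geometric inconsistency between the measured ring and the assumed subunit
#' size.
#'
#' @param ring_diameter Centre-circle diameter, nm.
#' @param subunit_diameter Sphere diameter, nm.
#' @return Real-valued subunit count.
#' @export
subunits_from_diameter <- function(ring_diameter, subunit_diameter) {
  stopifnot(all(ring_diameter > 0), all(subunit_diameter > 0))
  pi * ring_diameter / subunit_diameter
}

#' Geometric model of a circular protein oligomer
#'
#' Combines the mass-to-diameter and ring-packing relations into one model of
#' a ring of \code{n_subunits} globular proteins: subunit diameter from mass,
#' centre-circle diameter \code{n d / pi}, and outer envelope diameter
#' (centre circle plus one subunit diameter).
#'
#' @param n_subunits Number of subunits.
#' @param mass_kda Monomer mass, kDa.
#' @param partial_specific_volume \eqn{\bar v}, cm^3/g.
#' @return Object of class \code{ring_model} with \code{n_subunits},
#'   \code{subunit_diameter}, \code{ring_diameter}, \code{outer_diameter}
#'   (all nm).
#' @export
ring_model <- function(n_subunits, mass_kda, partial_specific_volume = 0.73) {
  d <- sphere_diameter_from_mass(mass_kda, partial_specific_volume)
  rd <- ring_diameter(n_subunits, d)
  structure(
    list(n_subunits = n_subunits, mass_kda = mass_kda,
         partial_specific_volume = partial_specific_volume,
         subunit_diameter = d, ring_diameter = rd,
         outer_diameter = rd + d),
    class = "ring_model"
  )
}

#' @export
print.ring_model <- function(x, ...) {
  cat(sprintf("Ring of %d globular subunits (%.1f kDa each):\n",
              x$n_subunits, x$mass_kda))
  cat(sprintf("  subunit diameter %.2f nm, centre-circle diameter %.1f nm, outer diameter %.1f nm\n",
              x$subunit_diameter, x$ring_diameter, x$outer_diameter))
  invisible(x)
}
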