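#' The Ramachandran number
#'
#' Collapses a backbone dihedral pair (phi, psi) onto a single unitless value
#' in \[0, 1\],
#' \deqn{R(\phi, \psi) = \frac{\phi + \psi - (\phi_{min} + \psi_{min})}
#'                            {(\phi_{max} + \psi_{max}) - (\phi_{min} + \psi_{min})},}
#' which with the default bounds reduces to \eqn{(\phi + \psi + 360)/720} in
#' degrees.  R is constant along the negative-sloping diagonals of the
#' Ramachandran plot and increases in sweeps from the bottom-left to the
#' top-right corner, so conformations with similar R have similar backbone
#' geometry: right-handed alpha-helices sit near R = 0.34, beta-sheets near
#' R = 0.52, polyproline-II near 0.6, and fully extended states near 0, 0.5
#' and 1.
#'
#' Inputs outside the bounds are first wrapped into them by adding or
#' subtracting multiples of 360; an input of exactly `phi_max` (or `psi_max`)
#' is kept, so that R(180, 180) = 1 rather than 0 (the two are equivalent in
#' meaning).  `NA` dihedrals (e.g. at chain termini) give `NA`.
#'
#' @param phi,psi Backbone dihedral angles in degrees (vectorized, recycled
#'   to a common length).
#' @param bounds An [angle_bounds()] object; defaults to
#'   \[-180, 180) x \[-180, 180).
#'
#' @return A numeric vector of Ramachandran numbers in \[0, 1\]
#'   (`ramachandran_number`) or signed values in \[-1, 1\]
#'   (`signed_ramachandran_number`).
#'
#' @examples
#' ramachandran_number(0, 0)        # 0.5
#' ramachandran_number(-180, -180)  # 0
#' ramachandran_number(180, 180)    # 1
#' ramachandran_number(-57, -47)    # alpha-helix, ~0.356
#'
#' # the signed variant distinguishes mirror-image conformations that share
#' # the same diagonal sweep (e.g. ppII vs the D-helix):
#' signed_ramachandran_number(-75, 145)  #  ~0.597
#' signed_ramachandran_number(145, -75)  # ~-0.597
#'
#' @seealso [signed_ramachandran_number()], [discretized_ramachandran_number()]
#' @export
ramachandran_number <- function(phi, psi, bounds = angle_bounds()) {
  b <- as_angle_bounds(bounds)
  n <- max(length(phi), length(psi))
  phi <- rep_len(as.numeric(phi), n)
  psi <- rep_len(as.numeric(psi), n)
  if (any(is.nan(phi) | is.nan(psi) | is.infinite(phi) | is.infinite(psi)))
    stop("phi and psi must be finite angles or NA (missing dihedral)")
  phi <- wrap_angle(phi, b$phi_min)
  psi <- wrap_angle(psi, b$psi_min)
  (phi + psi - (b$phi_min + b$psi_min)) /
    ((b$phi_max + b$psi_max) - (b$phi_min + b$psi_min))
}

#' @rdname ramachandran_number
#'
#' @details
#' `signed_ramachandran_number()` keeps the magnitude of R but flips its sign
#' for conformations below the positively-sloped diagonal of the plot:
#' \deqn{R_S = R \ \mathrm{if}\ \psi \ge \phi; \quad -R \ \mathrm{if}\ \psi < \phi,}
#' with the comparison made on the wrapped angles and the boundary
#' \eqn{\psi = \phi} assigned to the positive branch.  Most chiral protein
#' backbones lie in the upper-left half-plane (psi >= phi) and never need the
#' sign, but achiral backbones (glycine-rich peptides, peptoids) populate
#' both halves, where unsigned R conflates mirror-image states.
#'
#' @export
signed_ramachandran_number <- function(phi, psi, bounds = angle_bounds()) {
  b <- as_angle_bounds(bounds)
  n <- max(length(phi), length(psi))
  phi <- rep_len(as.numeric(phi), n)
  psi <- rep_len(as.numeric(psi), n)
  r <- ramachandran_number(phi, psi, b)
  phi_w <- wrap_angle(phi, b$phi_min)
  psi_w <- wrap_angle(psi, b$psi_min)
  ifelse(psi_w >= phi_w, r, -r)
}

# Nearest-integer rounding, half away from zero.  base::round() rounds
# half-to-even, which would break ties differently on either side of zero.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' The sigma-discretized Ramachandran number
#'
#' The original formulation of the Ramachandran number tiles the
#' Ramachandran plot into small squares of side `1/sigma` degrees, assigns
#' each square an increasing integer while slicing along the
#' negative-sloping diagonals, and normalizes the integer of the square
#' containing (phi, psi) by the corner squares:
#' \deqn{R_Z(\phi, \psi) = [(\phi - \psi + \lambda)\sigma/\sqrt{2}] +
#'       [\sqrt{2}\lambda\sigma]\,[(\phi + \psi + \lambda)\sigma/\sqrt{2}],}
#' where \eqn{[x]} rounds to the nearest integer and \eqn{\lambda} is the
#' 360-degree range width, followed by
#' \deqn{R = \frac{R_Z(\phi,\psi) - R_Z(\phi_{min},\psi_{min})}
#'                {R_Z(\phi_{max},\psi_{max}) - R_Z(\phi_{min},\psi_{min})}.}
#'
#' As `sigma` grows the tiling refines and this value converges to the
#' closed form computed by [ramachandran_number()]; the discretized form is
#' retained here as an independent reference for that limit.  Half-integer
#' rounding ties are broken away from zero.
#'
#' @inheritParams ramachandran_number
#' @param sigma Scaling factor in reciprocal degrees; must be positive.
#'   Larger values give a finer tiling and a more accurate value.
#'
#' @return A numeric vector in \[0, 1\].
#'
#' @examples
#' discretized_ramachandran_number(0, 0, sigma = 100)   # ~0.5
#' discretized_ramachandran_number(-180, -180, sigma = 3)  # exactly 0
#'
#' @export
discretized_ramachandran_number <- function(phi, psi, sigma,
                                            bounds = angle_bounds()) {
  b <- as_angle_bounds(bounds)
  stopifnot(is.numeric(sigma), length(sigma) == 1L)
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  n <- max(length(phi), length(psi))
  phi <- wrap_angle(rep_len(as.numeric(phi), n), b$phi_min)
  psi <- wrap_angle(rep_len(as.numeric(psi), n), b$psi_min)
  lam <- b$lambda
  rz <- function(p, s) {
    round_half_away((p - s + lam) * sigma / sqrt(2)) +
      round_half_away(sqrt(2) * lam * sigma) *
        round_half_away((p + s + lam) * sigma / sqrt(2))
  }
  lo <- rz(b$phi_min, b$psi_min)
  hi <- rz(b$phi_max, b$psi_max)
  (rz(phi, psi) - lo) / (hi - lo)
}
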