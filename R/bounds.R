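#' Angle bounds for the Ramachandran number
#'
#' The Ramachandran number is defined relative to a convention for the
#' backbone dihedral ranges, `phi in [phi_min, phi_max)` and
#' `psi in [psi_min, psi_max)`, where each maximum exceeds its minimum by
#' exactly one full turn (360 degrees).  The default convention used
#' throughout the package places both minima at -180 degrees, so that
#' `R = (phi + psi + 360) / 720`.
#'
#' Angles are stored in degrees internally; radian minima are accepted via
#' `units = "radians"` and converted on construction.
#'
#' @param phi_min Lower bound of the phi range (default -180 degrees).
#' @param psi_min Lower bound of the psi range (default -180 degrees).
#' @param units Either `"degrees"` (default) or `"radians"` for the values
#'   supplied in `phi_min` and `psi_min`.
#'
#' @return An object of class `"angle_bounds"`: a list with elements
#'   `phi_min`, `phi_max`, `psi_min`, `psi_max` and `lambda` (the common
#'   range width, always 360), all in degrees.
#'
#' @examples
#' angle_bounds()                    # the default [-180, 180) x [-180, 180)
#' angle_bounds(0, 0)                # the alternate [0, 360) x [0, 360)
#' angle_bounds(-pi, -pi, "radians") # same as the default
#'
#' @export
angle_bounds <- function(phi_min = -180, psi_min = -180,
                         units = c("degrees", "radians")) {
  units <- match.arg(units)
  stopifnot(is.numeric(phi_min), length(phi_min) == 1L, is.finite(phi_min),
            is.numeric(psi_min), length(psi_min) == 1L, is.finite(psi_min))
  if (units == "radians") {
    phi_min <- phi_min * 180 / pi
    psi_min <- psi_min * 180 / pi
  }
  structure(list(phi_min = phi_min, phi_max = phi_min + 360,
                 psi_min = psi_min, psi_max = psi_min + 360,
                 lambda = 360),
            class = "angle_bounds")
}

#' @export
print.angle_bounds <- function(x, ...) {
  cat(sprintf("angle bounds: phi in [%g, %g), psi in [%g, %g) degrees\n",
              x$phi_min, x$phi_max, x$psi_min, x$psi_max))
  invisible(x)
}

# Wrap angles into [lo, lo + 360], keeping the upper boundary itself:
# a dihedral reported as exactly lo + 360 is retained (R may then reach 1,
# which is equivalent in meaning to 0 but kept distinct in value).
wrap_angle <- function(x, lo) {
  inside <- !is.na(x) & x >= lo & x <= lo + 360
  out <- x
  out[!inside] <- lo + (x[!inside] - lo) %% 360
  out
}

as_angle_bounds <- function(bounds) {
  if (inherits(bounds, "angle_bounds")) return(bounds)
  stop("`bounds` must be created with angle_bounds()")
}
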