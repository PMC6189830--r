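#' Droplet geometry and merge-dilution accounting
#'
#' Droplets produced in flow-focusing devices are, to a good approximation,
#' spheres once off-chip, so the nominal droplet volume follows directly from
#' the generated diameter. The screening workflow merges a small bacterial
#' droplet (grown in LB medium) with a larger mammalian-cell droplet, which
#' dilutes the LB carried over; `dilution_factor()` quantifies that fold
#' dilution.
#'
#' @name geometry
NULL

#' Volume of a spherical droplet
#'
#' Converts a droplet diameter in micrometres to its volume in picolitres
#' using the sphere formula \eqn{V = \pi d^3 / 6} (1 pL = 1000 \eqn{\mu m^3}).
#'
#' @param diameter_um Droplet diameter in micrometres. Vectorised;
#'   must be non-negative.
#' @return Volume(s) in picolitres.
#' @examples
#' sphere_volume(75)   # ~220 pL bacterial droplet
#' sphere_volume(110)  # ~700 pL mammalian-cell droplet
#' @export
sphere_volume <- function(diameter_um) {
  stopifnot(is.numeric(diameter_um))
  if (any(!is.finite(diameter_um)) || any(diameter_um < 0)) {
    stop("`diameter_um` must be finite and non-negative", call. = FALSE)
  }
  pi * diameter_um^3 / 6 / 1e3
}

#' Fold dilution of a droplet component after merging
#'
#' When a droplet of volume `component_volume_pl` is merged with
#' `added_volume_pl` of other fluid, everything dissolved in the component
#' droplet is diluted by `(component + added) / component` fold. Used to
#' account for the dilution of bacterial growth medium when monoclonal
#' droplets are fused with mammalian-cell droplets.
#'
#' @param component_volume_pl Volume (pL) of the droplet carrying the
#'   component of interest; must be positive.
#' @param added_volume_pl Volume (pL) merged in; must be non-negative.
#' @return Dimensionless fold dilution, always >= 1.
#' @examples
#' dilution_factor(220, 700)  # LB dilution on merging 75 um into 110 um drops
#' @export
dilution_factor <- function(component_volume_pl, added_volume_pl) {
  stopifnot(is.numeric(component_volume_pl), is.numeric(added_volume_pl))
  if (any(!is.finite(component_volume_pl)) || any(component_volume_pl <= 0)) {
    stop("`component_volume_pl` must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(added_volume_pl)) || any(added_volume_pl < 0)) {
    stop("`added_volume_pl` must be finite and >= 0", call. = FALSE)
  }
  (component_volume_pl + added_volume_pl) / component_volume_pl
}

#' Construct a droplet specification
#'
#' Bundles a droplet diameter, its spherical volume and its role in the
#' workflow. If `volume_pl` is supplied it must agree with the sphere
#' formula within 0.5\% (rounding nominal volumes to the nearest 10 or
#' 100 pL stays well inside this).
#'
#' @param diameter_um Diameter in micrometres (> 0).
#' @param role One of `"bacterial"`, `"mammalian"`, `"merged"`.
#' @param volume_pl Optional volume in pL; defaults to `sphere_volume(diameter_um)`.
#' @return An object of class `droplet_spec` with fields `diameter_um`,
#'   `volume_pl`, `role`.
#' @examples
#' droplet_spec(75, "bacterial")
#' @export
droplet_spec <- function(diameter_um, role = c("bacterial", "mammalian", "merged"),
                         volume_pl = NULL) {
  role <- match.arg(role)
  stopifnot(length(diameter_um) == 1L, is.numeric(diameter_um))
  if (!is.finite(diameter_um) || diameter_um <= 0) {
    stop("`diameter_um` must be a positive finite number", call. = FALSE)
  }
  v <- sphere_volume(diameter_um)
  if (!is.null(volume_pl)) {
    if (abs(volume_pl - v) / v > 0.005) {
      stop(sprintf("volume %.4g pL inconsistent with diameter %g um (sphere gives %.4g pL)",
                   volume_pl, diameter_um, v), call. = FALSE)
    }
    v <- volume_pl
  }
  structure(list(diameter_um = diameter_um, volume_pl = v, role = role),
            class = "droplet_spec")
}

#' @export
print.droplet_spec <- function(x, ...) {
  cat(sprintf("<droplet_spec> %s droplet: d = %g um, V = %s pL\n",
              x$role, x$diameter_um, signif(x$volume_pl, 3)))
  invisible(x)
}
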