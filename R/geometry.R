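#' Transwell insert geometry
#'
#' Describes a single permeable-support (transwell) insert: the membrane the
#' cell monolayer grows on and the two medium compartments it separates.
#' Defaults are the 24-well format used for the mammary epithelial barrier
#' model: 0.3 cm² PET membrane with 0.4 µm pores, and transport-phase volumes
#' of 0.5 mL apical / 1.2 mL basolateral. Smaller pre-experiment maintenance
#' volumes can be recorded as metadata; all kinetic calculations use the
#' transport-phase volumes.
#'
#' @param membrane_area membrane surface area in cm².
#' @param pore_size membrane pore size in µm.
#' @param apical_volume apical (upper) compartment volume during the transport
#'   experiment, in mL.
#' @param basolateral_volume basolateral (lower) compartment volume during the
#'   transport experiment, in mL.
#' @param material membrane material tag, e.g. `"PET"` or `"PC"`.
#' @param maintenance_apical,maintenance_basolateral optional pre-experiment
#'   maintenance volumes in mL (metadata only).
#' @return An object of class `"transwell_geometry"`.
#' @examples
#' geom <- transwell_geometry()
#' geom$membrane_area
#' @export
transwell_geometry <- function(membrane_area = 0.3, pore_size = 0.4,
                               apical_volume = 0.5, basolateral_volume = 1.2,
                               material = "PET",
                               maintenance_apical = 0.3,
                               maintenance_basolateral = 0.72) {
  stopifnot(is.numeric(membrane_area), length(membrane_area) == 1L,
            is.numeric(pore_size), length(pore_size) == 1L,
            is.numeric(apical_volume), length(apical_volume) == 1L,
            is.numeric(basolateral_volume), length(basolateral_volume) == 1L)
  if (!(membrane_area > 0)) stop("membrane_area must be > 0")
  if (!(pore_size > 0)) stop("pore_size must be > 0")
  if (!(apical_volume > 0 && basolateral_volume > 0))
    stop("compartment volumes must be > 0")
  structure(list(membrane_area = membrane_area,
                 pore_size = pore_size,
                 apical_volume = apical_volume,
                 basolateral_volume = basolateral_volume,
                 material = as.character(material),
                 maintenance_apical = maintenance_apical,
                 maintenance_basolateral = maintenance_basolateral),
            class = "transwell_geometry")
}

#' @export
print.transwell_geometry <- function(x, ...) {
  cat(sprintf("Transwell insert: %.3g cm^2 %s membrane, %.2g um pores\n",
              x$membrane_area, x$material, x$pore_size))
  cat(sprintf("  volumes (transport phase): apical %.3g mL, basolateral %.3g mL\n",
              x$apical_volume, x$basolateral_volume))
  invisible(x)
}

# receiver/donor compartment volume for a transport direction
receiver_volume <- function(geometry, direction = c("A2B", "B2A")) {
  direction <- match.arg(direction)
  if (direction == "A2B") geometry$basolateral_volume else geometry$apical_volume
}

donor_volume <- function(geometry, direction = c("A2B", "B2A")) {
  direction <- match.arg(direction)
  if (direction == "A2B") geometry$apical_volume else geometry$basolateral_volume
}
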