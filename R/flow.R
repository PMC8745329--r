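#' Parallel-plate flow chamber geometry
#'
#' Describes the rectangular cross-section of a parallel-plate flow chamber
#' together with the volumetric flow rate driven through it. Defaults match
#' a standard microfluidic thrombus-formation chamber (50 um height, 3.0 mm
#' width, 30 mm length).
#'
#' @param height_um Chamber height in micrometres (default 50).
#' @param width_mm Chamber width in millimetres (default 3.0).
#' @param length_mm Chamber length in millimetres (default 30).
#' @param flow_ul_min Volumetric flow rate in microlitres per minute.
#'
#' @return An object of class `flow_geometry`.
#' @seealso [wall_shear_rate()]
#' @export
#' @examples
#' geom <- flow_geometry(flow_ul_min = 75)
#' wall_shear_rate(geom)
flow_geometry <- function(height_um = 50, width_mm = 3.0, length_mm = 30,
                          flow_ul_min) {
  stopifnot(is.numeric(height_um), is.numeric(width_mm), is.numeric(length_mm),
            is.numeric(flow_ul_min), length(flow_ul_min) == 1L)
  if (height_um <= 0 || width_mm <= 0 || length_mm <= 0)
    stop("invalid flow geometry: all chamber dimensions must be strictly positive")
  if (flow_ul_min < 0)
    stop("invalid flow geometry: volumetric flow must be non-negative")
  if (height_um * 1e-3 >= width_mm)
    stop("invalid flow geometry: height must be smaller than width (parallel-plate assumption)")
  structure(
    list(height_um = height_um, width_mm = width_mm, length_mm = length_mm,
         flow_ul_min = flow_ul_min),
    class = "flow_geometry"
  )
}

#' Wall-shear rate of a parallel-plate chamber
#'
#' Computes the wall-shear rate \eqn{\gamma_w = 6 Q / (w h^2)} of laminar
#' Poiseuille flow between parallel plates, the standard relation used to set
#' arterial shear conditions in microfluidic thrombus-formation assays.
#' At the default chamber geometry (50 um x 3.0 mm) a flow of 75 uL/min
#' gives the usual arterial operating point of 1000 s^-1.
#'
#' @param geometry A [flow_geometry()] object.
#'
#' @return Wall-shear rate in s^-1 (a single number).
#' @export
#' @examples
#' wall_shear_rate(flow_geometry(flow_ul_min = 75))  # 1000 s^-1
wall_shear_rate <- function(geometry) {
  stopifnot(inherits(geometry, "flow_geometry"))
  q_m3_s <- geometry$flow_ul_min * 1e-9 / 60     # uL/min -> m^3/s
  w_m <- geometry$width_mm * 1e-3
  h_m <- geometry$height_um * 1e-6
  6 * q_m3_s / (w_m * h_m^2)
}

#' Blood / recalcification-medium mixing specification
#'
#' Describes the in-line mixing of citrated whole blood with recalcification
#' medium at the chamber inlet. Defaults correspond to a 10:1 blood:medium
#' volume ratio and a medium containing 63 mM CaCl2 and 32 mM MgCl2.
#'
#' @param blood_parts,medium_parts Positive integer volume parts
#'   (default 10 and 1).
#' @param medium_solutes Named numeric vector of stock concentrations in the
#'   medium, in mM.
#'
#' @return An object of class `mixing_spec`.
#' @export
#' @examples
#' mix <- mixing_spec()
#' final_concentration(mix, "CaCl2")  # 63/11 mM
mixing_spec <- function(blood_parts = 10, medium_parts = 1,
                        medium_solutes = c(CaCl2 = 63, MgCl2 = 32)) {
  if (blood_parts < 0 || medium_parts <= 0 ||
      blood_parts != round(blood_parts) || medium_parts != round(medium_parts))
    stop("mixing parts must be non-negative integers with medium_parts >= 1")
  if (is.null(names(medium_solutes)) || any(!nzchar(names(medium_solutes))))
    stop("medium_solutes must be a named vector")
  if (any(medium_solutes < 0)) stop("solute concentrations must be non-negative")
  structure(
    list(blood_parts = blood_parts, medium_parts = medium_parts,
         medium_solutes = medium_solutes),
    class = "mixing_spec"
  )
}

#' Final solute concentration after inlet mixing
#'
#' Dilution arithmetic for the three-way inlet: a medium solute at stock
#' concentration `c` ends up at `c * medium_parts / (blood_parts + medium_parts)`
#' in the perfused blood.
#'
#' @param mix A [mixing_spec()] object.
#' @param species Name of a solute present in `mix$medium_solutes`.
#'
#' @return Final concentration in mM.
#' @export
final_concentration <- function(mix, species) {
  stopifnot(inherits(mix, "mixing_spec"), is.character(species),
            length(species) == 1L)
  if (!species %in% names(mix$medium_solutes))
    stop(sprintf("unknown species '%s'; medium contains: %s", species,
                 paste(names(mix$medium_solutes), collapse = ", ")))
  stock <- mix$medium_solutes[[species]]
  stock * mix$medium_parts / (mix$blood_parts + mix$medium_parts)
}
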