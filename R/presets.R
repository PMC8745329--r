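#' Pharmacological intervention presets
#'
#' Each preset describes how an inhibitor rescales the kinetic processes of
#' thrombus formation from the moment inhibited blood enters the chamber.
#' Factors are multiplicative rate factors in \[0, 1\] on the five modelled
#' processes (platelet adhesion, aggregation, phosphatidylserine exposure,
#' thrombin/fibrin generation, thrombus stabilisation); `detach_per_min` is an
#' additional first-order detachment rate on established thrombi (integrin
#' alphaIIbbeta3 blockade makes aggregation reversible).
#'
#' The available presets are:
#' \describe{
#'   \item{vehicle}{solvent control; all factors 1, no detachment.}
#'   \item{iFVIIa}{active-site inhibited factor VIIa; blocks extrinsic
#'     (TF/FVIIa) initiation of coagulation. Marked `initiation_only`:
#'     extrinsic initiation is complete within the first two minutes of flow,
#'     so the inhibitor only acts when present from the start.}
#'   \item{PAR1_4}{combined PAR1 + PAR4 thrombin-receptor antagonism
#'     (atopaxar + BMS-986120); dampens adhesion, aggregation, stabilisation
#'     and thrombin-dependent fibrin formation at early and late stages.}
#'   \item{GPVI_Fab}{anti-GPVI Fab fragment; strongly reduces aggregation and
#'     nearly abolishes collagen-induced phosphatidylserine exposure.}
#'   \item{Syk_IN}{Syk tyrosine-kinase inhibitor (PRT-060318), acting
#'     directly downstream of GPVI; effect profile close to GPVI blockade.}
#'   \item{tirofiban}{integrin alphaIIbbeta3 antagonist; abolishes new
#'     aggregation and stabilisation and detaches existing multilayered
#'     thrombi (0.3/min) unless thrombin-driven fibrin has consolidated them.}
#' }
#'
#' Factor values are model configuration chosen to reproduce the directional
#' early/late inhibition effects observed experimentally; they are tunable
#' settings, not measured constants.
#'
#' @param name Preset name, one of
#'   `c("vehicle", "iFVIIa", "PAR1_4", "GPVI_Fab", "Syk_IN", "tirofiban")`.
#'
#' @return For `intervention_preset()`, a list of class `intervention_preset`
#'   with elements `name`, `factors` (named numeric vector over the five
#'   processes), `detach_per_min` and `initiation_only`. For
#'   `intervention_presets()`, a data.frame with one row per preset.
#' @export
#' @examples
#' intervention_preset("tirofiban")$detach_per_min
#' intervention_presets()
intervention_preset <- function(name = c("vehicle", "iFVIIa", "PAR1_4",
                                         "GPVI_Fab", "Syk_IN", "tirofiban")) {
  name <- match.arg(name)
  tab <- .preset_table()
  row <- tab[tab$name == name, ]
  structure(
    list(
      name = name,
      factors = c(adhesion = row$adhesion, aggregation = row$aggregation,
                  ps_exposure = row$ps_exposure,
                  thrombin_fibrin = row$thrombin_fibrin,
                  stability = row$stability),
      detach_per_min = row$detach_per_min,
      initiation_only = row$initiation_only
    ),
    class = "intervention_preset"
  )
}

#' @rdname intervention_preset
#' @export
intervention_presets <- function() .preset_table()

.preset_table <- function() {
  data.frame(
    name = c("vehicle", "iFVIIa", "PAR1_4", "GPVI_Fab", "Syk_IN", "tirofiban"),
    adhesion        = c(1, 1, 0.50, 0.70, 0.80, 1),
    aggregation     = c(1, 1, 0.35, 0.30, 0.25, 0),
    ps_exposure     = c(1, 1, 1.00, 0.005, 0.005, 1),
    thrombin_fibrin = c(1, 0, 0.50, 0.30, 0.30, 0.70),
    stability       = c(1, 1, 0.50, 0.60, 0.50, 0),
    detach_per_min  = c(0, 0, 0, 0, 0, 0.30),
    initiation_only = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}
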