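# Conversion of per-channel masks and brightfield features into the seven
# thrombus parameters. P1, P2, P6, P7 are surface-area coverages; P3-P5 are
# automated proxies for what are visual ordinal scores at the microscope:
# explicit, documented rules on connected components, not replications of
# human judgment.

# Area cut points (px^2) of the morphology classes at full resolution
# (0.108 um/px); rescaled by pixel_scale^2 for down-sampled rasters.
.AREA_SINGLE <- 200
.AREA_MEDIUM <- 2000
.AREA_BIG <- 10000

# Component areas (8-connectivity) of a binary mask.
.component_areas <- function(mask) {
  if (!any(mask > 0)) return(numeric(0))
  lab <- EBImage::bwlabel(matrix(as.integer(mask > 0), nrow(mask), ncol(mask)))
  tabulate(lab[lab > 0])
}

#' Thrombus morphology score (0-5)
#'
#' Ordinal morphology of the brightfield thrombus mask:
#' 0 no or little attached platelets; 1 multiple single attached platelets;
#' 2 widespread coverage of single attached platelets; 3 small platelet
#' aggregates; 4 medium-sized aggregates or thrombi; 5 big aggregates or
#' thrombi. Components are classified by area (single < 200 px^2, small
#' aggregate < 2,000 px^2, medium < 10,000 px^2, big >= 10,000 px^2, at full
#' resolution; cut points scale with `pixel_scale^2`); the score is the
#' highest class present, with 0/1/2 decided by component count and total
#' SAC ("widespread" = at least 50 single-size components covering >= 5%).
#'
#' @param mask Binary thrombus mask.
#' @param pixel_scale Linear scale of the raster relative to full resolution
#'   (1 for 1360 x 1024; 0.25 for the quarter-scale default raster).
#'
#' @return Integer score in 0..5.
#' @export
score_morphology <- function(mask, pixel_scale = ncol(mask) / 1360) {
  stopifnot(is.matrix(mask), pixel_scale > 0)
  s2 <- pixel_scale^2
  areas <- .component_areas(mask)
  if (length(areas) == 0) return(0L)
  if (any(areas >= .AREA_BIG * s2)) return(5L)
  if (any(areas >= .AREA_MEDIUM * s2)) return(4L)
  if (any(areas >= .AREA_SINGLE * s2)) return(3L)
  n_single <- length(areas)
  sac <- 100 * sum(areas) / length(mask)
  if (n_single >= 50 && sac >= 5) return(2L)
  if (n_single >= 5) return(1L)
  0L
}

# Convex-hull solidity of one component's pixel set (used for isolated toy
# shapes and cross-checks).
.solidity <- function(rows, cols) {
  n <- length(rows)
  if (n < 3) return(1)
  pts <- unique(cbind(rows, cols))
  if (nrow(pts) < 3) return(1)
  h <- grDevices::chull(pts[, 2], pts[, 1])
  hx <- pts[h, 2]; hy <- pts[h, 1]
  # shoelace area of the hull through pixel centres; half-pixel border term
  # approximates the hull of the pixel squares
  a <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  hull_area <- a + length(h) / 2 + 1
  min(1, n / hull_area)
}

# Fill solidity of a mask: mask area over the area of its closed and
# hole-filled envelope. Ragged, loose aggregates gain a lot of area when
# their concavities are closed; compact contracted ones barely change.
# Unlike convex-hull solidity this remains meaningful when aggregates merge
# into image-spanning components at high coverage.
.fill_solidity <- function(mask, k = 7L) {
  if (!any(mask > 0)) return(NA_real_)
  cl <- .line_filter(.line_filter(mask, k, TRUE, TRUE), k, FALSE, TRUE)
  cl <- .line_filter(.line_filter(cl, k, TRUE, FALSE), k, FALSE, FALSE)
  filled <- EBImage::fillHull(matrix(as.integer(cl > 0), nrow(mask),
                                     ncol(mask)))
  sum(mask > 0) / sum(filled > 0)
}

#' Thrombus contraction score (0-3)
#'
#' Proxy for the visual contraction score: contracted thrombi are compact
#' (high fill solidity, i.e. little area gained by closing and hole-filling
#' the mask) and dense (dark interior in brightfield). The dark-core
#' fraction is the share of mask pixels with brightfield intensity below
#' `dark_intensity`. Bins: solidity >= 0.90 and dark fraction >= 0.5 score
#' 3; >= 0.80 / 0.3 score 2; >= 0.70 / 0.10 score 1; otherwise 1 when
#' thrombi cover >= 5% of the field, else 0.
#'
#' @param bf_image Raw brightfield image (0-255).
#' @param thrombus_mask Binary thrombus mask.
#' @param dark_intensity Intensity below which a thrombus pixel counts as
#'   dark core (default 70; background renders ~200, thrombi ~80).
#'
#' @return Integer score in 0..3.
#' @export
score_contraction <- function(bf_image, thrombus_mask, dark_intensity = 70) {
  stopifnot(is.matrix(bf_image), is.matrix(thrombus_mask),
            all(dim(bf_image) == dim(thrombus_mask)))
  if (!any(thrombus_mask > 0)) return(0L)
  sol <- .fill_solidity(thrombus_mask)
  dark <- sum(bf_image[thrombus_mask > 0] < dark_intensity) /
    sum(thrombus_mask > 0)
  sac <- compute_sac(thrombus_mask)
  if (is.na(sol)) return(if (sac >= 5) 1L else 0L)
  if (sol >= 0.90 && dark >= 0.5) return(3L)
  if (sol >= 0.80 && dark >= 0.3) return(2L)
  if (sol >= 0.70 && dark >= 0.10) return(1L)
  if (sac >= 5) 1L else 0L
}

#' Thrombus multilayering score (0-3)
#'
#' Proxy for the visual multilayering score: stacked platelets render
#' brighter in the DiOC6 channel, so the score bins the fraction of thrombus
#' pixels whose DiOC6 intensity exceeds `bright_intensity`. Bins: fraction
#' >= 0.5 scores 3, >= 0.25 scores 2, >= 0.08 scores 1, else 0.
#'
#' @param dioc6_image Raw DiOC6 image (0-255).
#' @param thrombus_mask Binary thrombus mask.
#' @param bright_intensity High-intensity cut (default 180; monolayer
#'   platelets render ~140, stacked cores ~215).
#'
#' @return Integer score in 0..3.
#' @export
score_multilayering <- function(dioc6_image, thrombus_mask,
                                bright_intensity = 180) {
  stopifnot(is.matrix(dioc6_image), is.matrix(thrombus_mask),
            all(dim(dioc6_image) == dim(thrombus_mask)))
  if (!any(thrombus_mask > 0)) return(0L)
  frac <- sum(dioc6_image[thrombus_mask > 0] > bright_intensity) /
    sum(thrombus_mask > 0)
  if (frac >= 0.5) return(3L)
  if (frac >= 0.25) return(2L)
  if (frac >= 0.08) return(1L)
  0L
}

#' Extract the seven thrombus parameters from one image set
#'
#' Combines the four channel masks and the raw brightfield / DiOC6 images of
#' one microspot and time point into a parameter record:
#' P1 platelet adhesion (% SAC of the DiOC6 mask), P2 thrombus coverage
#' (% SAC of the brightfield thrombus mask), P3 thrombus morphology (0-5),
#' P4 thrombus contraction (0-3), P5 thrombus multilayering (0-3), P6
#' phosphatidylserine exposure (% SAC of the AF568 mask) and P7 fibrin
#' deposition (% SAC of the fibrin mask).
#'
#' @param masks Named list of binary masks (`bf`, `dioc6`, `af568`, `af647`).
#' @param images Named list with at least the raw `bf` and `dioc6` images
#'   (used by the ordinal scores).
#' @param keys Optional named list/vector of identifying columns (donor,
#'   replicate, surface, preset, switch_time, timepoint) carried through.
#' @param pixel_scale Linear raster scale relative to full resolution.
#'
#' @return One-row data.frame with columns P1..P7 plus any keys.
#' @export
extract_parameters <- function(masks, images, keys = NULL,
                               pixel_scale = ncol(masks$bf) / 1360) {
  need <- c("bf", "dioc6", "af568", "af647")
  miss <- setdiff(need, names(masks))
  if (length(miss))
    stop("incomplete mask set: missing channel(s) ", paste(miss, collapse = ", "))
  if (!all(c("bf", "dioc6") %in% names(images)))
    stop("incomplete image set: raw 'bf' and 'dioc6' images required for scoring")
  rec <- data.frame(
    P1 = compute_sac(masks$dioc6),
    P2 = compute_sac(masks$bf),
    P3 = score_morphology(masks$bf, pixel_scale = pixel_scale),
    P4 = score_contraction(images$bf, masks$bf),
    P5 = score_multilayering(images$dioc6, masks$bf),
    P6 = compute_sac(masks$af568),
    P7 = compute_sac(masks$af647)
  )
  if (!is.null(keys)) rec <- cbind(as.data.frame(as.list(keys)), rec)
  rec
}
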