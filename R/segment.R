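# Segmentation chain: FFT background suppression, directional morphological
# cleanup, thresholding to binary masks, and fibrin/fibrinogen intensity
# discrimination. Images are numeric matrices on the 8-bit 0-255 intensity
# scale, indexed [row, column] with origin at the top-left.

#' Segmentation configuration
#'
#' Tunable settings of the per-channel segmentation chain. The FFT high-pass
#' cutoffs are in cycles per image; structuring-element lengths are in pixels.
#' Defaults were tuned on the package's synthetic renderer (brightfield needs
#' a stronger cutoff because thrombi are large dark objects on a bright,
#' unevenly illuminated background).
#'
#' @param fft_highpass_cutoff Named numeric vector of high-pass cutoffs per
#'   channel (`bf`, `dioc6`, `af568`, `af647`), cycles/image. The default
#'   1.5 cycles/image sits between the illumination field (at most ~1 cycle)
#'   and the smallest aggregates worth keeping (>= 3 cycles), and the mask
#'   edge is steep enough to separate the two.
#' @param erode_dilate_h,erode_dilate_v Horizontal and vertical line
#'   structuring-element lengths in pixels (>= 1).
#' @param threshold_method `"fixed"` (default) or `"otsu"`. The high-pass
#'   filter clips the background at zero, so a fixed threshold just above
#'   the residual noise floor binarizes robustly at any coverage; this
#'   mirrors the per-channel threshold-resetting workflow of semi-automated
#'   analysis scripts. Otsu's method is available for bimodal images but
#'   misplaces the threshold when foreground spans most of the field.
#' @param fixed_threshold Intensity threshold 0-255 used when
#'   `threshold_method = "fixed"` (default 8, on the filtered scale).
#' @param fibrin_high_threshold Intensity above which AF647 signal is counted
#'   as fibrin rather than soluble-fibrinogen background (default 120).
#' @param min_object_area Minimum connected-component area kept, in px^2
#'   (default 4; sub-platelet specks are noise at 0.108 um/px).
#' @param morphology_on Whether the directional opening runs on the
#'   `"grayscale"` filtered image before thresholding (default) or on the
#'   `"binary"` mask after it.
#'
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(fft_highpass_cutoff = c(bf = 1.5, dioc6 = 1.5,
                                                        af568 = 1.5,
                                                        af647 = 1.5),
                                erode_dilate_h = 3, erode_dilate_v = 3,
                                threshold_method = c("fixed", "otsu"),
                                fixed_threshold = 8,
                                fibrin_high_threshold = 120,
                                min_object_area = 4,
                                morphology_on = c("grayscale", "binary")) {
  threshold_method <- match.arg(threshold_method)
  morphology_on <- match.arg(morphology_on)
  stopifnot(all(fft_highpass_cutoff >= 0), erode_dilate_h >= 1,
            erode_dilate_v >= 1, min_object_area >= 0,
            fibrin_high_threshold >= 0, fibrin_high_threshold <= 255)
  if (threshold_method == "fixed") {
    if (is.null(fixed_threshold))
      stop("fixed_threshold required when threshold_method = 'fixed'")
    stopifnot(fixed_threshold >= 0, fixed_threshold <= 255)
  }
  structure(
    list(fft_highpass_cutoff = fft_highpass_cutoff,
         erode_dilate_h = as.integer(erode_dilate_h),
         erode_dilate_v = as.integer(erode_dilate_v),
         threshold_method = threshold_method,
         fixed_threshold = fixed_threshold,
         fibrin_high_threshold = fibrin_high_threshold,
         min_object_area = min_object_area,
         morphology_on = morphology_on),
    class = "segmentation_config"
  )
}

#' FFT high-pass background filter
#'
#' Suppresses image-wide structures (uneven illumination, DC offset, slow
#' background drifts) by attenuating low spatial frequencies in the Fourier
#' domain with a smooth, soft-edged high-pass mask
#' \eqn{H(f) = 1 - \exp(-(f/c)^4)}, where `f` is the radial frequency in
#' cycles per image and `c` the cutoff. Frequencies well below the cutoff are
#' removed (including DC), frequencies at twice the cutoff pass essentially
#' unattenuated. The image is mirror-padded to twice its size before the
#' transform, so the filter sees a continuous periodic extension and leaves
#' no wrap-around ringing at the borders. The output stays on the 0-255
#' intensity scale; negative lobes are clipped at zero (which keeps the
#' background exactly at zero after the low frequencies are gone), so the
#' filter is positively homogeneous (`filter(a*img) = a*filter(img)` for
#' `a > 0`).
#'
#' @param image 2-D numeric matrix, intensities 0-255.
#' @param cutoff High-pass cutoff in cycles/image; 0 disables filtering.
#'
#' @return Filtered numeric matrix (same shape), values >= 0.
#' @export
fft_background_filter <- function(image, cutoff) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a 2-D numeric matrix")
  stopifnot(length(cutoff) == 1L, cutoff >= 0)
  if (cutoff == 0) return(image)
  nr <- nrow(image); nc <- ncol(image)
  # mirror-pad to 2x size: continuous periodic extension, no wrap ringing
  padded <- rbind(cbind(image, image[, nc:1]),
                  cbind(image[nr:1, ], image[nr:1, nc:1]))
  pr <- 2L * nr; pc <- 2L * nc
  # unshifted frequency coordinates, in cycles per *original* image
  fr <- pmin(0:(pr - 1), pr - (0:(pr - 1))) / 2
  fc <- pmin(0:(pc - 1), pc - (0:(pc - 1))) / 2
  f <- sqrt(outer(fr^2, fc^2, `+`))
  H <- 1 - exp(-(f / cutoff)^4)
  filtered <- Re(stats::fft(stats::fft(padded) * H, inverse = TRUE)) /
    (pr * pc)
  pmax(filtered[seq_len(nr), seq_len(nc)], 0)
}

# Running min/max over a centered 1-D line window, outside pixels ignored.
# EBImage's erode/dilate binarize their input, so grayscale line morphology
# is done here directly.
.line_filter <- function(m, len, horizontal, maximum) {
  if (len == 1L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if ((horizontal && len > nc) || (!horizontal && len > nr))
    stop("structuring element larger than image")
  pad <- if (maximum) -Inf else Inf
  offs <- seq.int(-((len - 1L) %/% 2L), len %/% 2L)
  acc <- NULL
  for (o in offs) {
    shifted <- matrix(pad, nr, nc)
    if (horizontal) {
      src <- seq_len(nc) + o
      keep <- src >= 1L & src <= nc
      shifted[, keep] <- m[, src[keep]]
    } else {
      src <- seq_len(nr) + o
      keep <- src >= 1L & src <= nr
      shifted[keep, ] <- m[src[keep], ]
    }
    acc <- if (is.null(acc)) shifted
           else if (maximum) pmax(acc, shifted) else pmin(acc, shifted)
  }
  acc
}

#' Directional morphological opening
#'
#' Applies an opening (erosion then dilation) with a horizontal line element
#' of length `h_len`, followed by an opening with a vertical line element of
#' length `v_len`. Works on binary masks and on grayscale images alike
#' (running minimum / maximum). Objects shorter than the element in both
#' directions are removed; larger objects are preserved. Pixels outside the
#' image are ignored, so structures touching the border survive.
#'
#' @param x Numeric matrix: a \{0,1\} mask or a grayscale image.
#' @param h_len,v_len Structuring-element lengths in pixels (>= 1).
#'
#' @return Cleaned matrix of the same type and shape.
#' @export
morphological_clean <- function(x, h_len = 3, v_len = 3) {
  if (!is.matrix(x)) stop("x must be a matrix")
  stopifnot(h_len >= 1, v_len >= 1)
  h_len <- as.integer(h_len); v_len <- as.integer(v_len)
  x <- .line_filter(.line_filter(x, h_len, TRUE, FALSE), h_len, TRUE, TRUE)
  .line_filter(.line_filter(x, v_len, FALSE, FALSE), v_len, FALSE, TRUE)
}

# Otsu threshold on the 0-255 scale: maximizes between-class variance over
# the 256-bin histogram; returns t such that foreground is intensity > t.
.otsu_threshold <- function(image) {
  v <- pmin(pmax(floor(image), 0), 255)
  h <- tabulate(as.integer(v) + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b[1:255]) - 1L
}

# Drop connected components (8-connectivity) below min_area pixels.
.filter_small_objects <- function(mask, min_area) {
  if (min_area <= 1 || !any(mask > 0)) return(mask)
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[lab %in% keep] <- 1L
  out
}

#' Threshold a filtered channel image to a binary mask
#'
#' Binarizes a (filtered) grayscale image. In `"otsu"` mode the threshold
#' maximizes the between-class variance of the 256-bin intensity histogram;
#' in `"fixed"` mode `cfg$fixed_threshold` is used. Pixels strictly above the
#' threshold are foreground. Connected components smaller than
#' `cfg$min_object_area` are removed. A constant image has no foreground /
#' background structure; in otsu mode it yields an empty mask with a warning.
#'
#' @param image Numeric matrix, intensities 0-255.
#' @param cfg A [segmentation_config()].
#'
#' @return Integer \{0,1\} matrix of class `binary_mask` with attributes
#'   `threshold` and `channel`.
#' @export
threshold_channel <- function(image, cfg = segmentation_config()) {
  stopifnot(is.matrix(image), inherits(cfg, "segmentation_config"))
  if (cfg$threshold_method == "fixed") {
    thr <- cfg$fixed_threshold
  } else {
    if (diff(range(image)) < 1e-9) {
      warning("constant image: no bimodality, returning empty mask")
      out <- matrix(0L, nrow(image), ncol(image))
      attr(out, "threshold") <- NA_real_
      class(out) <- c("binary_mask", class(out))
      return(out)
    }
    thr <- .otsu_threshold(image)
  }
  mask <- matrix(as.integer(image > thr), nrow(image), ncol(image))
  mask <- .filter_small_objects(mask, cfg$min_object_area)
  attr(mask, "threshold") <- thr
  class(mask) <- c("binary_mask", class(mask))
  mask
}

#' Discriminate fibrin fibers from fibrinogen background
#'
#' Fibrin fibers incorporate far more labelled fibrinogen than the soluble /
#' adsorbed pool, so they render at high intensity in the AF647 channel while
#' unconverted fibrinogen forms a dim haze. The discrimination is a fixed
#' high-intensity threshold (`cfg$fibrin_high_threshold`) followed by the
#' directional morphological cleanup and the small-object filter.
#'
#' @param image AF647 channel image, numeric matrix 0-255.
#' @param cfg A [segmentation_config()].
#'
#' @return Integer \{0,1\} `binary_mask` of fibrin-positive pixels.
#' @export
fibrin_discriminate <- function(image, cfg = segmentation_config()) {
  stopifnot(is.matrix(image), inherits(cfg, "segmentation_config"))
  mask <- matrix(as.integer(image > cfg$fibrin_high_threshold),
                 nrow(image), ncol(image))
  mask <- morphological_clean(mask, cfg$erode_dilate_h, cfg$erode_dilate_v)
  mask <- .filter_small_objects(mask, cfg$min_object_area)
  attr(mask, "threshold") <- cfg$fibrin_high_threshold
  class(mask) <- c("binary_mask", class(mask))
  mask
}

#' Surface area coverage of a binary mask
#'
#' SAC is the percentage of pixels of the region of interest covered by the
#' mask, the unit of the coverage parameters P1, P2, P6 and P7.
#'
#' @param mask \{0,1\} matrix.
#' @param roi Optional rectangular region `c(row1, row2, col1, col2)`
#'   (1-based, inclusive); default is the whole image.
#'
#' @return Coverage in percent (0-100).
#' @export
#' @examples
#' compute_sac(matrix(c(1, 0, 0, 0), 2, 2))  # 25
compute_sac <- function(mask, roi = NULL) {
  stopifnot(is.matrix(mask))
  if (!is.null(roi)) {
    stopifnot(length(roi) == 4)
    if (roi[1] > roi[2] || roi[3] > roi[4] ||
        roi[1] < 1 || roi[3] < 1 || roi[2] > nrow(mask) || roi[4] > ncol(mask))
      stop("invalid roi: empty or out of bounds")
    mask <- mask[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  }
  if (length(mask) == 0) stop("invalid roi: no pixels")
  100 * sum(mask > 0) / length(mask)
}

# Boundary of a binary mask: mask pixels with at least one 4-neighbour
# outside the mask, the image border counting as outside.
.mask_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(0L, nr + 2L, nc + 2L)
  m[2:(nr + 1L), 2:(nc + 1L)] <- as.integer(mask > 0)
  interior <- .line_filter(.line_filter(m, 3L, TRUE, FALSE), 3L, FALSE, FALSE)
  (m & !interior)[2:(nr + 1L), 2:(nc + 1L)]
}

#' Write a QC overlay of a mask over its source image
#'
#' Draws the mask contour in saturated red over the grayscale image and
#' writes the result as an RGB PNG, for visual verification of threshold
#' settings (with looped re-segmentation under adjusted thresholds replacing
#' an interactive reset).
#'
#' @param image Grayscale matrix 0-255.
#' @param mask \{0,1\} matrix, same shape.
#' @param path Output PNG path.
#'
#' @return Invisibly, the RGB array written (rows x cols x 3, 0-1 range).
#' @export
overlay_qc <- function(image, mask, path) {
  stopifnot(is.matrix(image), is.matrix(mask), all(dim(image) == dim(mask)))
  g <- pmin(pmax(image / 255, 0), 1)
  rgb <- array(g, dim = c(dim(image), 3))
  b <- .mask_boundary(mask)
  rgb[, , 1][b] <- 1
  rgb[, , 2][b] <- 0
  rgb[, , 3][b] <- 0
  ok <- try(png::writePNG(rgb, target = path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write overlay to '", path, "'")
  invisible(rgb)
}

#' Segment a four-channel image set
#'
#' Runs the full per-channel chain on one microspot / time point image set:
#' brightfield is inverted (thrombi are dark on a bright background), each
#' channel is FFT background-filtered at its cutoff, the directional opening
#' is applied (on grayscale by default), the image is thresholded, and the
#' AF647 channel additionally passes the fibrin/fibrinogen discrimination.
#'
#' @param images Named list of numeric matrices with elements `bf`, `dioc6`,
#'   `af568`, `af647` (0-255).
#' @param cfg A [segmentation_config()].
#'
#' @return Named list of `binary_mask` matrices: `bf` (thrombus), `dioc6`
#'   (platelet), `af568` (PS-positive), `af647` (fibrin).
#' @export
segment_image_set <- function(images, cfg = segmentation_config()) {
  need <- c("bf", "dioc6", "af568", "af647")
  miss <- setdiff(need, names(images))
  if (length(miss))
    stop("incomplete image set: missing channel(s) ", paste(miss, collapse = ", "))
  seg_one <- function(img, channel) {
    if (channel == "bf") img <- 255 - img
    filt <- fft_background_filter(img, cfg$fft_highpass_cutoff[[channel]])
    if (cfg$morphology_on == "grayscale") {
      filt <- morphological_clean(filt, cfg$erode_dilate_h, cfg$erode_dilate_v)
      mask <- threshold_channel(filt, cfg)
    } else {
      mask <- threshold_channel(filt, cfg)
      mask2 <- morphological_clean(unclass(mask), cfg$erode_dilate_h,
                                   cfg$erode_dilate_v)
      mask2 <- .filter_small_objects(mask2, cfg$min_object_area)
      attr(mask2, "threshold") <- attr(mask, "threshold")
      class(mask2) <- c("binary_mask", class(mask2))
      mask <- mask2
    }
    attr(mask, "channel") <- channel
    mask
  }
  list(bf = seg_one(images$bf, "bf"),
       dioc6 = seg_one(images$dioc6, "dioc6"),
       af568 = seg_one(images$af568, "af568"),
       af647 = fibrin_discriminate(images$af647, cfg))
}
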