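# Cohort generation and quantification: writes rendered image stacks and
# ground truth to disk as single-channel 8-bit grayscale TIFFs plus a
# manifest CSV, and runs the segmentation + parameter extraction over a
# manifest.

.CHANNELS <- c("bf", "dioc6", "af568", "af647")

#' Read / write single-channel 8-bit grayscale TIFF images
#'
#' Thin wrappers around the tiff package keeping images as numeric matrices
#' on the 0-255 scale.
#'
#' @param image Numeric matrix 0-255.
#' @param path File path (`.tif`).
#' @return `write_channel_tiff()` returns the path invisibly;
#'   `read_channel_tiff()` returns the image matrix.
#' @export
write_channel_tiff <- function(image, path) {
  stopifnot(is.matrix(image))
  tiff::writeTIFF(pmin(pmax(image, 0), 255) / 255, path,
                  bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' @rdname write_channel_tiff
#' @export
read_channel_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  round(img * 255)
}

# File name for one channel image of one run/time point.
.image_filename <- function(donor, replicate, surface, preset, switch_time,
                            timepoint, channel, mask = FALSE) {
  sw <- if (is.na(switch_time)) "never" else switch_time
  paste0(donor, "_", replicate, "_", surface, "_", preset, "_", sw,
         "_t", timepoint, "_", channel, if (mask) "_mask", ".tif")
}

#' Generate a synthetic cohort on disk
#'
#' Simulates and renders a full cohort: for every donor, condition template
#' and replicate, one flow run per surface with image sets at each time
#' point. Donor kinetic factors are shared across all of a donor's runs
#' (paired design). Writes per-channel images and ground-truth masks as
#' 8-bit TIFFs, a `manifest.csv` (one row per image set, with all run keys
#' and file paths) and a `truth.csv` with the true parameter values.
#'
#' @param out_dir Output directory; must be empty or absent unless
#'   `overwrite = TRUE`.
#' @param n_donors Number of donors (>= 2).
#' @param conditions data.frame with columns `surface`, `preset`,
#'   `switch_time` (one row per condition template). Default: vehicle on
#'   both surfaces.
#' @param replicates Flow runs per donor and condition (2 or 3).
#' @param seed Integer master seed.
#' @param timepoints Measurement times in minutes.
#' @param render_cfg A [render_config()]; its seed is derived from `seed`.
#' @param write_masks Also write ground-truth masks (default TRUE).
#' @param overwrite Allow writing into a non-empty directory.
#'
#' @return Invisibly, the manifest data.frame.
#' @export
generate_cohort <- function(out_dir, n_donors = 3,
                            conditions = data.frame(
                              surface = c("collagen", "collagen_TF"),
                              preset = "vehicle", switch_time = NA),
                            replicates = 2, seed = 1L,
                            timepoints = c(2, 4, 6, 8, 10),
                            render_cfg = render_config(),
                            write_masks = TRUE, overwrite = FALSE) {
  stopifnot(n_donors >= 2, replicates %in% 2:3)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("output directory '", out_dir, "' is not empty; use overwrite = TRUE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(); truth <- list(); n <- 0L
  for (d in seq_len(n_donors)) {
    donor <- sprintf("d%02d", d)
    for (k in seq_len(nrow(conditions))) {
      for (r in seq_len(replicates)) {
        repl <- sprintf("r%d", r)
        cfg <- flow_run_config(
          surface = conditions$surface[k], preset = conditions$preset[k],
          switch_time = conditions$switch_time[k], donor_id = donor,
          replicate_id = repl, seed = seed, timepoints = timepoints)
        states <- simulate_kinetics(cfg)
        rcfg <- render_cfg
        rcfg$seed <- (as.numeric(seed) * 7 + d * 101 + k * 17 + r * 3) %%
          2147483629
        run <- render_images(states, cfg, rcfg)
        for (i in seq_along(timepoints)) {
          files <- setNames(vapply(.CHANNELS, function(ch) {
            fn <- .image_filename(donor, repl, cfg$surface, cfg$preset$name,
                                  cfg$switch_time, timepoints[i], ch)
            write_channel_tiff(run$sets[[i]]$images[[ch]],
                               file.path(out_dir, fn))
            fn
          }, character(1)), .CHANNELS)
          if (write_masks)
            for (ch in .CHANNELS) {
              fn <- .image_filename(donor, repl, cfg$surface, cfg$preset$name,
                                    cfg$switch_time, timepoints[i], ch,
                                    mask = TRUE)
              write_channel_tiff(255 * run$sets[[i]]$masks[[ch]],
                                 file.path(out_dir, fn))
            }
          n <- n + 1L
          manifest[[n]] <- data.frame(
            donor = donor, replicate = repl, surface = cfg$surface,
            preset = cfg$preset$name, switch_time = cfg$switch_time,
            timepoint = timepoints[i], seed = seed,
            file_bf = files[["bf"]], file_dioc6 = files[["dioc6"]],
            file_af568 = files[["af568"]], file_af647 = files[["af647"]])
          truth[[n]] <- cbind(
            data.frame(donor = donor, replicate = repl, surface = cfg$surface,
                       preset = cfg$preset$name,
                       switch_time = cfg$switch_time),
            run$truth[i, , drop = FALSE])
        }
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  truth <- do.call(rbind, truth)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Quantify a cohort of image sets
#'
#' Runs the segmentation chain and parameter extraction over every image set
#' listed in a cohort manifest, yielding a tidy parameter table (one row per
#' run and time point, columns P1..P7 plus keys). Optionally writes binary
#' masks (`_mask.tif` suffix is reserved for ground truth; estimated masks
#' get `_seg.tif`) and QC overlay PNGs.
#'
#' @param dir Cohort directory containing `manifest.csv` and the images.
#' @param seg_cfg A [segmentation_config()].
#' @param write_masks Write estimated masks next to the images.
#' @param qc Write QC contour overlays (PNG) per channel.
#' @param out_csv If non-NULL, write the parameter table to this path.
#'
#' @return data.frame of parameter records.
#' @export
quantify_cohort <- function(dir, seg_cfg = segmentation_config(),
                            write_masks = FALSE, qc = FALSE, out_csv = NULL) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path))
    stop("no manifest.csv in '", dir, "'")
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  out <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    files <- c(bf = row$file_bf, dioc6 = row$file_dioc6,
               af568 = row$file_af568, af647 = row$file_af647)
    missing <- !file.exists(file.path(dir, files))
    if (any(missing))
      stop("incomplete image set for ", row$donor, "/", row$replicate, " t",
           row$timepoint, ": missing ", paste(files[missing], collapse = ", "))
    images <- lapply(files, function(f) read_channel_tiff(file.path(dir, f)))
    masks <- segment_image_set(images, seg_cfg)
    if (write_masks || qc)
      for (ch in .CHANNELS) {
        stem <- sub("\\.tif$", "", files[[ch]])
        if (write_masks)
          write_channel_tiff(255 * unclass(masks[[ch]]),
                             file.path(dir, paste0(stem, "_seg.tif")))
        if (qc)
          overlay_qc(images[[ch]], masks[[ch]],
                     file.path(dir, paste0(stem, "_qc.png")))
      }
    out[[i]] <- extract_parameters(
      masks, images,
      keys = list(donor = row$donor, replicate = row$replicate,
                  surface = row$surface, preset = row$preset,
                  switch_time = row$switch_time, timepoint = row$timepoint))
  }
  res <- do.call(rbind, out)
  if (!is.null(out_csv)) write.csv(res, out_csv, row.names = FALSE)
  res
}
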