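test_that("FFT filter removes DC: constant image maps to near zero", {
  img <- matrix(137, 64, 96)
  out <- fft_background_filter(img, cutoff = 4)
  expect_lt(max(abs(out)), 2)
  expect_error(fft_background_filter(array(0, c(4, 4, 2)), 4), "2-D")
})

test_that("FFT filter suppresses a gradient but keeps a small bright spot", {
  nr <- 128; nc <- 128
  base <- 60
  grad <- matrix(seq(0, 40, length.out = nr), nr, nc)  # 40-unit ramp
  img <- base + grad
  img[62:66, 62:66] <- img[62:66, 62:66] + 120       # 5-px bright spot
  out <- fft_background_filter(img, cutoff = 4)
  # oracle: spatial-domain subtraction of a heavily smoothed copy
  k <- round(nr / 4)
  sm <- img
  for (pass in 1:3) {  # separable box blur approximating a wide Gaussian
    sm <- t(apply(sm, 1, function(r) stats::filter(r, rep(1 / k, k),
                                                   circular = TRUE)))
    sm <- apply(sm, 2, function(cl) stats::filter(cl, rep(1 / k, k),
                                                  circular = TRUE))
  }
  oracle <- pmax(img - sm, 0)
  # spot contrast: peak over its local background, at least 70% retained
  spot_out <- max(out[62:66, 62:66]) - stats::median(out[40:50, 40:50])
  spot_oracle <- max(oracle[62:66, 62:66]) -
    stats::median(oracle[40:50, 40:50])
  expect_gte(spot_out, 0.7 * 120)
  expect_gte(spot_oracle, 0.7 * 120)   # the oracle agrees the spot survives
  # gradient: residual large-scale variation of the background reduced >= 90%
  bg_ramp <- function(m) abs(mean(m[118:126, 10:120]) - mean(m[2:10, 10:120]))
  expect_lt(bg_ramp(out), 0.1 * bg_ramp(img))
})

test_that("FFT filter passes a sinusoid at twice the cutoff nearly unchanged", {
  nr <- 128; nc <- 128
  cutoff <- 4
  f <- 2 * cutoff  # cycles per image along rows
  s <- 100 + 40 * sin(2 * pi * f * (0:(nr - 1)) / nr)
  img <- matrix(s, nr, nc)
  out <- fft_background_filter(img, cutoff)
  # after DC removal the crests carry the wave's amplitude: >= 90% retained
  expect_gte(max(out), 0.9 * 40)
  # the output follows the (zero-clipped) input wave away from the borders
  expect_gte(cor(out[20:108, 1], pmax(img[20:108, 1] - 100, 0)), 0.9)
  # a sinusoid well below the cutoff is almost fully suppressed away from
  # the image borders (the mirror reflection kinks there)
  slow <- matrix(100 + 40 * sin(2 * pi * 1 * (0:(nr - 1)) / nr), nr, nc)
  expect_lt(max(fft_background_filter(slow, cutoff)[20:108, ]), 0.15 * 40)
})

test_that("FFT filter is positively homogeneous", {
  set.seed(21)
  img <- matrix(runif(64 * 64, 0, 120), 64, 64)
  out1 <- fft_background_filter(img, 3)
  out2 <- fft_background_filter(2.5 * img, 3)
  expect_equal(out2, 2.5 * out1, tolerance = 1e-9)
})

test_that("directional opening matches brute-force set morphology", {
  set.seed(31)
  mask <- matrix(as.integer(runif(40 * 40) < 0.25), 40, 40)
  mask[15:30, 8:20] <- 1L   # one solid block that must survive
  got <- morphological_clean(mask, h_len = 3, v_len = 3)
  oracle <- opening_bruteforce(opening_bruteforce(mask, 3, TRUE), 3, FALSE)
  expect_identical(matrix(as.integer(got > 0), 40, 40), oracle)
})

test_that("opening removes specks, keeps solid objects, is anti-extensive", {
  # single isolated pixel vanishes
  speck <- matrix(0L, 20, 20); speck[10, 10] <- 1L
  expect_equal(sum(morphological_clean(speck, 3, 3)), 0)
  # a 50x50 solid square keeps its area (within 5%)
  sq <- matrix(0L, 80, 80); sq[16:65, 16:65] <- 1L
  opened <- morphological_clean(sq, 3, 3)
  expect_lt(abs(sum(opened) - 2500) / 2500, 0.05)
  # empty stays empty
  expect_equal(sum(morphological_clean(matrix(0L, 10, 10), 3, 3)), 0)
  # anti-extensivity on random masks: opening never adds pixels
  set.seed(8)
  for (i in 1:5) {
    m <- matrix(as.integer(runif(30 * 30) < 0.4), 30, 30)
    o <- morphological_clean(m, 3, 5)
    expect_true(all(o <= m))
  }
  expect_error(morphological_clean(matrix(0L, 5, 5), h_len = 9), "larger")
})

test_that("horizontal-vertical order barely changes the opened area", {
  run <- demo_run()$run
  mask <- run$sets[[3]]$masks$bf
  hv <- morphological_clean(mask, 3, 5)
  # manual vertical-then-horizontal pass
  vh <- thrombusflow:::.line_filter(
    thrombusflow:::.line_filter(mask, 5L, FALSE, FALSE), 5L, FALSE, TRUE)
  vh <- thrombusflow:::.line_filter(
    thrombusflow:::.line_filter(vh, 3L, TRUE, FALSE), 3L, TRUE, TRUE)
  expect_lt(abs(compute_sac(hv) - compute_sac(vh)), 2)
})

test_that("Otsu thresholding matches the exhaustive search oracle", {
  set.seed(77)
  for (i in 1:20) {
    img <- make_bimodal_image(64, 64, fg_frac = runif(1, 0.1, 0.5))
    expect_equal(thrombusflow:::.otsu_threshold(img), otsu_exhaustive(img))
  }
  # a clean two-population image recovers its foreground fraction
  # (no object-size filter: the foreground here is scattered single pixels)
  img <- make_bimodal_image(128, 128, fg_frac = 0.3)
  mask <- threshold_channel(img, segmentation_config(threshold_method = "otsu",
                                                     min_object_area = 0))
  expect_gte(compute_sac(mask), 27)
  expect_lte(compute_sac(mask), 33)
})

test_that("degenerate and fixed thresholding behave as documented", {
  flat <- matrix(100, 32, 32)
  expect_warning(m <- threshold_channel(
    flat, segmentation_config(threshold_method = "otsu")), "constant")
  expect_equal(sum(m), 0)
  # fixed mode: strictly-above semantics
  img <- matrix(c(10, 120, 120, 10), 2, 2)
  cfg <- segmentation_config(threshold_method = "fixed", fixed_threshold = 119,
                             min_object_area = 0)
  expect_equal(sum(threshold_channel(img, cfg)), 2)
  cfg$fixed_threshold <- 120
  expect_equal(sum(threshold_channel(img, cfg)), 0)
})

test_that("SAC is non-increasing in the threshold for any image", {
  run <- demo_run()$run
  img <- fft_background_filter(run$sets[[2]]$images$dioc6, 1.5)
  sacs <- vapply(seq(0, 250, by = 10), function(thr) {
    cfg <- segmentation_config(threshold_method = "fixed",
                               fixed_threshold = thr)
    compute_sac(threshold_channel(img, cfg))
  }, numeric(1))
  expect_true(all(diff(sacs) <= 1e-12))
})

test_that("fibrin discrimination keeps fibers and rejects fibrinogen haze", {
  run <- demo_run()$run
  i_late <- which(run$timepoints == 10)
  af647 <- run$sets[[i_late]]$images$af647
  truth <- run$sets[[i_late]]$masks$af647
  mask <- fibrin_discriminate(af647, segmentation_config())
  expect_lt(abs(compute_sac(mask) - compute_sac(truth)), 3)
  # pre-onset timepoint: haze only, nothing detected
  i_early <- which(run$timepoints == 2)
  early <- fibrin_discriminate(run$sets[[i_early]]$images$af647,
                               segmentation_config())
  expect_lt(compute_sac(early), 1)
})

test_that("surface area coverage is an exact pixel ratio", {
  expect_equal(compute_sac(matrix(1L, 10, 10)), 100)
  expect_equal(compute_sac(matrix(0L, 10, 10)), 0)
  # 139,264 pixels on the native raster are exactly 10%
  m <- matrix(0L, 1024, 1360)
  m[seq_len(139264)] <- 1L
  expect_equal(compute_sac(m), 10)
  # roi restriction and validation
  m2 <- matrix(0L, 10, 10); m2[1:5, 1:10] <- 1L
  expect_equal(compute_sac(m2, roi = c(1, 5, 1, 10)), 100)
  expect_error(compute_sac(m2, roi = c(6, 5, 1, 10)), "invalid roi")
  expect_error(compute_sac(m2, roi = c(1, 11, 1, 10)), "invalid roi")
})

test_that("QC overlays draw the mask boundary and only the boundary", {
  img <- matrix(128, 40, 40)
  mask <- matrix(0L, 40, 40); mask[10:20, 15:30] <- 1L
  path <- tempfile(fileext = ".png")
  rgb <- overlay_qc(img, mask, path)
  expect_true(file.exists(path))
  # empty mask: overlay equals the grayscale image in all channels
  rgb0 <- overlay_qc(img, matrix(0L, 40, 40), tempfile(fileext = ".png"))
  expect_equal(rgb0[, , 1], rgb0[, , 2])
  expect_equal(rgb0[, , 1], img / 255)
  # boundary oracle: mask pixels with a 4-neighbour outside the mask
  inside <- mask[2:39, 2:39] > 0 &
    mask[1:38, 2:39] > 0 & mask[3:40, 2:39] > 0 &
    mask[2:39, 1:38] > 0 & mask[2:39, 3:40] > 0
  boundary_oracle <- mask
  boundary_oracle[2:39, 2:39][inside] <- 0L
  marked <- rgb[, , 1] == 1 & rgb[, , 2] == 0
  expect_equal(matrix(as.integer(marked), 40, 40), boundary_oracle)
  # full mask: contour along the image border
  rgb_full <- overlay_qc(img, matrix(1L, 40, 40), tempfile(fileext = ".png"))
  expect_true(all(rgb_full[1, , 1] == 1))
  expect_true(all(rgb_full[, 40, 1] == 1))
  expect_true(rgb_full[20, 20, 1] == 128 / 255)
})

test_that("segmenting an image set requires all four channels", {
  run <- demo_run()$run
  imgs <- run$sets[[2]]$images
  expect_error(segment_image_set(imgs[c("bf", "dioc6", "af568")]),
               "af647")
})
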