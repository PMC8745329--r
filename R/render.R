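# Renders four-channel 8-bit microscopy image stacks from simulated kinetic
# states, with per-channel ground-truth masks. The raster emulates the
# acquisition geometry of the assay (1360 x 1024 px at 0.108 um/px at full
# scale); the default is quarter scale, since surface-area coverage is
# scale-free.

#' Rendering configuration
#'
#' @param width,height Raster size in pixels. Default 340 x 256 (quarter
#'   scale); use `full_size = TRUE` for the native 1360 x 1024.
#' @param full_size If `TRUE`, overrides width/height with 1360 x 1024.
#' @param pixel_um Pixel size in micrometres (0.108 at full scale; scaled
#'   automatically with the raster).
#' @param noise_sd Gaussian read-noise standard deviation (8-bit units).
#' @param gradient_amplitude Peak amplitude of the low-frequency illumination
#'   gradient (8-bit units) that the FFT background filter must remove.
#' @param seed Integer seed for the renderer's RNG.
#'
#' @return An object of class `render_config`.
#' @export
render_config <- function(width = 340, height = 256, full_size = FALSE,
                          pixel_um = 0.108 * 1360 / width,
                          noise_sd = 6, gradient_amplitude = 20, seed = 1L) {
  if (full_size) { width <- 1360; height <- 1024; pixel_um <- 0.108 }
  stopifnot(width >= 32, height >= 32, noise_sd >= 0, gradient_amplitude >= 0)
  structure(
    list(width = as.integer(width), height = as.integer(height),
         pixel_um = pixel_um, noise_sd = noise_sd,
         gradient_amplitude = gradient_amplitude, seed = as.integer(seed)),
    class = "render_config"
  )
}

# Linear scale factor relative to the full-resolution raster.
.pixel_scale <- function(render_cfg) render_cfg$width / 1360

# Row/col offsets of a filled disc of radius r (pixels).
.disc_offsets <- function(r) {
  r <- max(1L, round(r))
  d <- -r:r
  g <- expand.grid(dr = d, dc = d)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

# Stamp a disc into the mask held in environment `e`, clipping at the
# borders and keeping e$count (set pixels) up to date.
.stamp <- function(e, row, col, offs) {
  rr <- row + offs$dr; cc <- col + offs$dc
  ok <- rr >= 1L & rr <= e$nr & cc >= 1L & cc <= e$nc
  cells <- cbind(rr[ok], cc[ok])
  fresh <- e$mask[cells] == 0L
  if (any(fresh)) {
    e$mask[cells[fresh, , drop = FALSE]] <- 1L
    e$count <- e$count + sum(fresh)
  }
  invisible(e)
}

# Add stamped shapes until the mask reaches `target` fractional coverage.
# `stamp_fun(e)` places one shape into the mask environment. Errors out if
# the target is not reached within `max_iter` placements.
.fill_to_coverage <- function(mask, target, stamp_fun, max_iter = 100000L) {
  if (target > 0.97)
    stop("placement failure: target coverage ", target, " unreachable")
  e <- new.env(parent = emptyenv())
  e$mask <- mask; e$count <- sum(mask != 0)
  e$nr <- nrow(mask); e$nc <- ncol(mask)
  npx <- length(mask)
  it <- 0L
  while (e$count / npx < target) {
    it <- it + 1L
    if (it > max_iter)
      stop("placement failure: coverage ", target, " not reached after ",
           max_iter, " placements")
    stamp_fun(e)
  }
  e$mask
}

# Low-frequency illumination field: tilted plane plus a half-period bulge.
.illumination <- function(nr, nc, amplitude) {
  r <- matrix(seq(0, 1, length.out = nr), nr, nc)
  c_ <- matrix(seq(0, 1, length.out = nc), nr, nc, byrow = TRUE)
  amplitude * (0.4 * r + 0.3 * c_ + 0.3 * sin(pi * r) * sin(pi * c_))
}

.quantize8 <- function(img) {
  matrix(as.numeric(pmin(pmax(round(img), 0), 255)), nrow(img), ncol(img))
}

# One thrombus aggregate: a main disc (radius r_c) with satellite discs.
# Satellites make the aggregate ragged; contracted thrombi (high level) get
# none and stay compact.
.stamp_aggregate <- function(e, r_c, n_sat) {
  row <- sample.int(e$nr, 1L); col <- sample.int(e$nc, 1L)
  .stamp(e, row, col, .disc_offsets(r_c))
  if (n_sat > 0) {
    r_s <- max(1L, round(r_c * 0.4))
    for (i in seq_len(n_sat)) {
      ang <- runif(1, 0, 2 * pi)
      d <- r_c * runif(1, 1.0, 1.5)
      .stamp(e, row + round(d * sin(ang)), col + round(d * cos(ang)),
             .disc_offsets(r_s))
    }
  }
  invisible(e)
}

# Fibrin fiber: a thick line segment of random orientation, anchored near
# thrombi when any exist.
.stamp_fiber <- function(e, anchor_idx, len_range, width_px) {
  if (length(anchor_idx)) {
    i <- anchor_idx[sample.int(length(anchor_idx), 1L)]
    row <- ((i - 1L) %% e$nr) + 1L; col <- ((i - 1L) %/% e$nr) + 1L
  } else {
    row <- sample.int(e$nr, 1L); col <- sample.int(e$nc, 1L)
  }
  ang <- runif(1, 0, pi)
  len <- runif(1, len_range[1], len_range[2])
  ts <- seq(-len / 2, len / 2, by = 0.5)
  half_w <- (width_px - 1) / 2
  ws <- seq(-half_w, half_w, by = 0.5)
  pr <- round(rep(row + ts * sin(ang), each = length(ws)) +
                rep(ws * cos(ang), times = length(ts)))
  pc <- round(rep(col + ts * cos(ang), each = length(ws)) -
                rep(ws * sin(ang), times = length(ts)))
  ok <- pr >= 1L & pr <= e$nr & pc >= 1L & pc <= e$nc
  cells <- unique(cbind(pr[ok], pc[ok]))
  fresh <- e$mask[cells] == 0L
  if (any(fresh)) {
    e$mask[cells[fresh, , drop = FALSE]] <- 1L
    e$count <- e$count + sum(fresh)
  }
  invisible(e)
}

# Render the four channels and masks for a single kinetic state.
.render_state <- function(state, render_cfg) {
  nr <- render_cfg$height; nc <- render_cfg$width
  scale <- .pixel_scale(render_cfg)
  grad <- .illumination(nr, nc, render_cfg$gradient_amplitude)
  noise <- function(sd) matrix(rnorm(nr * nc, 0, sd), nr, nc)
  empty <- matrix(0L, nr, nc)

  lev_mul <- state$multilayer_level
  lev_con <- state$contraction_level

  # --- thrombus mask: clustered aggregates, size grows with multilayering
  r_c <- max(2L, round((4 + 5 * lev_mul) * scale / 0.25))
  n_sat <- round((3 - lev_con) * 2)
  thrombus <- empty
  if (state$thrombus_coverage > 0)
    thrombus <- .fill_to_coverage(
      thrombus, state$thrombus_coverage,
      function(e) .stamp_aggregate(e, r_c, n_sat))

  # --- platelet mask: thrombus footprint plus single adhered platelets
  r_plt <- max(1L, round(3 * scale / 0.25))
  platelet <- thrombus
  if (state$platelet_coverage > sum(platelet) / length(platelet))
    platelet <- .fill_to_coverage(
      platelet, state$platelet_coverage,
      function(e) .stamp(e, sample.int(nr, 1L), sample.int(nc, 1L),
                         .disc_offsets(r_plt)))

  # --- PS-positive platelets: ballooned platelets on the platelet carpet
  ps <- empty
  if (state$ps_coverage > 0) {
    plt_idx <- which(platelet > 0)
    offs_ps <- .disc_offsets(r_plt)
    ps <- .fill_to_coverage(ps, state$ps_coverage, function(e) {
      if (length(plt_idx)) {
        i <- plt_idx[sample.int(length(plt_idx), 1L)]
        row <- ((i - 1L) %% nr) + 1L; col <- ((i - 1L) %/% nr) + 1L
      } else {
        row <- sample.int(nr, 1L); col <- sample.int(nc, 1L)
      }
      .stamp(e, row, col, offs_ps)
    })
  }

  # --- fibrin fibers
  fibrin <- empty
  if (state$fibrin_coverage > 0) {
    anchor <- which(morphological_clean(thrombus, 1, 1) > 0)  # thrombus pixels
    len_range <- c(20, 60) * scale / 0.25
    wpx <- max(2, round(3 * scale / 0.25))
    fibrin <- .fill_to_coverage(
      fibrin, state$fibrin_coverage,
      function(e) .stamp_fiber(e, anchor, len_range, wpx))
  }

  # --- cores: dark (contracted) and bright (multilayered) thrombus interior.
  # Approximated as the deep interior of each aggregate via grayscale-safe
  # erosion of the thrombus mask; the eroded depth grows with the level.
  core_of <- function(level, max_frac) {
    if (!any(thrombus > 0) || level < 0.4) return(empty)
    frac <- min(max_frac, 0.15 + 0.28 * level)
    # erosion depth leaving ~frac of a disc of radius r_c
    depth <- max(1L, round(r_c * (1 - sqrt(frac))))
    k <- 2L * depth + 1L
    if (k >= min(nr, nc)) return(empty)
    .line_filter(.line_filter(thrombus, k, TRUE, FALSE), k, FALSE, FALSE)
  }
  dark_core <- core_of(lev_con, 0.95)
  bright_core <- core_of(lev_mul, 0.90)

  # --- compose channels (8-bit)
  bf <- 200 + grad - 120 * thrombus - 25 * dark_core +
    noise(render_cfg$noise_sd) + 12 * thrombus * noise(1)
  dioc6 <- 18 + grad + noise(render_cfg$noise_sd)
  dioc6[platelet > 0] <- 140 + rnorm(sum(platelet > 0), 0, 8)
  dioc6[bright_core > 0] <- 215 + rnorm(sum(bright_core > 0), 0, 8)
  af568 <- 18 + grad + noise(render_cfg$noise_sd)
  af568[ps > 0] <- 165 + rnorm(sum(ps > 0), 0, 10)
  af647 <- 18 + grad + noise(render_cfg$noise_sd)
  haze <- .line_filter(thrombus, 5L, TRUE, TRUE)  # fibrinogen haze on thrombi
  af647[haze > 0] <- af647[haze > 0] + 45 + rnorm(sum(haze > 0), 0, 6)
  af647[fibrin > 0] <- 205 + rnorm(sum(fibrin > 0), 0, 12)

  list(
    images = list(bf = .quantize8(bf), dioc6 = .quantize8(dioc6),
                  af568 = .quantize8(af568), af647 = .quantize8(af647)),
    masks = list(bf = thrombus, dioc6 = platelet, af568 = ps, af647 = fibrin)
  )
}

#' Render multichannel image stacks from kinetic states
#'
#' Converts the true kinetic trajectory of one flow run into 8-bit grayscale
#' images of the four acquisition channels (brightfield, DiOC6, AF568-annexin
#' A5, AF647-fibrin(ogen)) at each time point, plus the ground-truth binary
#' masks they were drawn from. Platelets are rendered as small discs,
#' thrombi as clustered aggregates whose size grows with multilayering and
#' whose raggedness falls with contraction; contracted aggregates get dark
#' cores in brightfield and multilayered ones bright cores in DiOC6. Fibrin
#' is rendered as high-intensity fiber segments over a dim fibrinogen haze
#' (so threshold discrimination is exercised), and every channel receives
#' Gaussian read noise plus a low-frequency illumination gradient (so the
#' FFT background filter is exercised). Rendering is deterministic given
#' `config$seed` and `render_cfg$seed`.
#'
#' @param states A `kinetic_states` data.frame from [simulate_kinetics()].
#' @param config The run's [flow_run_config()].
#' @param render_cfg A [render_config()].
#'
#' @return A list of class `rendered_run`:
#' \describe{
#'   \item{timepoints}{measurement times (min).}
#'   \item{sets}{per time point, a list with `images` and `masks`, each a
#'     named list over channels `bf`, `dioc6`, `af568`, `af647`.}
#'   \item{truth}{data.frame of true parameter values P1-P7 per time point
#'     (coverages in % SAC; P3 scored on the true thrombus mask; P4, P5 as
#'     rounded contraction / multilayer levels), plus the continuous levels.}
#' }
#' @export
render_images <- function(states, config, render_cfg = render_config()) {
  stopifnot(inherits(states, "data.frame"), inherits(config, "flow_run_config"),
            inherits(render_cfg, "render_config"))
  sets <- vector("list", nrow(states))
  truth <- vector("list", nrow(states))
  for (i in seq_len(nrow(states))) {
    st <- states[i, ]
    seed_i <- (as.numeric(render_cfg$seed) * 2903 +
                 as.numeric(config$seed) * 181 + i * 7) %% 2147483629
    sets[[i]] <- .with_seed(seed_i, .render_state(st, render_cfg))
    sc <- .pixel_scale(render_cfg)
    truth[[i]] <- data.frame(
      time = st$time,
      P1 = 100 * sum(sets[[i]]$masks$dioc6) / length(sets[[i]]$masks$dioc6),
      P2 = 100 * sum(sets[[i]]$masks$bf) / length(sets[[i]]$masks$bf),
      P3 = score_morphology(sets[[i]]$masks$bf, pixel_scale = sc),
      P4 = round(st$contraction_level),
      P5 = round(st$multilayer_level),
      P6 = 100 * sum(sets[[i]]$masks$af568) / length(sets[[i]]$masks$af568),
      P7 = 100 * sum(sets[[i]]$masks$af647) / length(sets[[i]]$masks$af647),
      contraction_level = st$contraction_level,
      multilayer_level = st$multilayer_level,
      target_P1 = 100 * st$platelet_coverage,
      target_P2 = 100 * st$thrombus_coverage,
      target_P6 = 100 * st$ps_coverage,
      target_P7 = 100 * st$fibrin_coverage
    )
  }
  structure(
    list(timepoints = states$time, sets = sets, truth = do.call(rbind, truth)),
    class = "rendered_run"
  )
}

#' Render a single showcase field
#'
#' Deterministic single-time-point renders of archetypal fields, used for
#' calibrating and testing the ordinal scoring proxies: `big_thrombi` (one
#' large contracted, multilayered aggregate class), `monolayer` (spread
#' single platelets, no aggregates), `contracted` (compact dark-cored
#' aggregates) and `loose` (ragged uncontracted aggregates).
#'
#' @param kind Showcase name.
#' @param render_cfg A [render_config()]; its `seed` fixes the field.
#'
#' @return A list with `images` and `masks` as in one element of
#'   [render_images()]'s `sets`, plus the `state` used.
#' @export
render_showcase <- function(kind = c("big_thrombi", "monolayer", "contracted",
                                     "loose"),
                            render_cfg = render_config()) {
  kind <- match.arg(kind)
  state <- switch(kind,
    big_thrombi = data.frame(time = 10, platelet_coverage = 0.45,
                             thrombus_coverage = 0.35, ps_coverage = 0.10,
                             fibrin_coverage = 0.20, contraction_level = 2.2,
                             multilayer_level = 3.0),
    monolayer = data.frame(time = 2, platelet_coverage = 0.12,
                           thrombus_coverage = 0, ps_coverage = 0.01,
                           fibrin_coverage = 0, contraction_level = 0,
                           multilayer_level = 0),
    contracted = data.frame(time = 8, platelet_coverage = 0.30,
                            thrombus_coverage = 0.20, ps_coverage = 0.08,
                            fibrin_coverage = 0, contraction_level = 3.0,
                            multilayer_level = 1.5),
    loose = data.frame(time = 6, platelet_coverage = 0.28, thrombus_coverage = 0.18,
                       ps_coverage = 0.05, fibrin_coverage = 0,
                       contraction_level = 0.2, multilayer_level = 1.0)
  )
  out <- .with_seed((as.numeric(render_cfg$seed) * 911 +
                       .hash_id(kind) %% 10000) %% 2147483629,
                    .render_state(state, render_cfg))
  out$state <- state
  out
}
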