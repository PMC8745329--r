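# Kinetic model of thrombus formation under flow.
#
# Coverages follow seeded logistic growth, dC/dt = f * r * (C + c0) * (1 - C/K),
# with per-process rate r, carrying capacity K, seeding term c0 and the
# preset's multiplicative factor f applied from the intervention switch time
# onward. Fibrin formation starts after a surface-dependent onset delay
# (tissue factor shortens it); thrombin generation on TF surfaces is treated
# as committed within the first two minutes, so extrinsic-pathway inhibition
# arriving later is inert and fibrin protects TF-surface thrombi against
# integrin-blockade detachment.

.KIN_STATE_COLS <- c("time", "platelet_coverage", "thrombus_coverage",
                     "ps_coverage", "fibrin_coverage",
                     "contraction_level", "multilayer_level")

# Surface-specific base rates (per min), capacities and fibrin onset (min).
.surface_rates <- function(surface) {
  switch(surface,
    collagen = list(
      r_adh = 0.80, r_agg = 0.50, r_ps = 0.35, r_fib = 1.2,
      r_con = 0.20, r_mul = 0.30, tau_fibrin = 12
    ),
    collagen_TF = list(
      r_adh = 0.90, r_agg = 0.70, r_ps = 0.35, r_fib = 1.2,
      r_con = 0.35, r_mul = 0.40, tau_fibrin = 4
    ),
    stop("unknown surface: ", surface)
  )
}

.KIN_CAPS <- list(K_P = 0.60, K_T = 0.50, K_S = 0.25, K_F = 0.45)
.KIN_SEEDS <- list(c0_adh = 0.05, c0_agg = 0.08, c0_fib = 0.02)
.THROMBIN_COMMIT_MIN <- 2   # extrinsic initiation window on TF surfaces

#' Configuration of one microfluidic flow run
#'
#' Bundles the experimental identity of a single flow run: microspot surface,
#' intervention preset, the time at which perfusion switches from untreated to
#' inhibitor-treated blood, donor and replicate identifiers, RNG seed and
#' measurement time points.
#'
#' @param surface `"collagen"` or `"collagen_TF"` (collagen co-coated with
#'   tissue factor).
#' @param preset Preset name (see [intervention_preset()]) or an
#'   `intervention_preset` object.
#' @param switch_time Minute at which inhibited blood enters the chamber:
#'   0 (from the start), 2 (after two minutes of untreated flow) or `NA`
#'   (never; forced to `NA` for the vehicle preset).
#' @param donor_id,replicate_id Character identifiers.
#' @param seed Integer seed controlling donor- and run-level variability.
#' @param timepoints Strictly increasing measurement times in minutes
#'   (default `c(2, 4, 6, 8, 10)`).
#'
#' @return An object of class `flow_run_config`.
#' @export
#' @examples
#' cfg <- flow_run_config("collagen_TF", "iFVIIa", switch_time = 0, seed = 1)
#' simulate_kinetics(cfg)
flow_run_config <- function(surface = c("collagen", "collagen_TF"),
                            preset = "vehicle", switch_time = NA,
                            donor_id = "d1", replicate_id = "r1",
                            seed = 1L, timepoints = c(2, 4, 6, 8, 10)) {
  surface <- match.arg(surface)
  if (!inherits(preset, "intervention_preset"))
    preset <- intervention_preset(preset)
  if (preset$name == "vehicle") switch_time <- NA_real_
  if (!is.na(switch_time) && !switch_time %in% c(0, timepoints))
    stop("switch_time must be 0, NA, or one of the measurement timepoints")
  if (length(timepoints) < 1 || is.unsorted(timepoints, strictly = TRUE) ||
      any(timepoints <= 0))
    stop("timepoints must be strictly increasing and positive")
  seed <- as.integer(seed)
  structure(
    list(surface = surface, preset = preset,
         switch_time = as.numeric(switch_time),
         donor_id = as.character(donor_id),
         replicate_id = as.character(replicate_id),
         seed = seed, timepoints = as.numeric(timepoints)),
    class = "flow_run_config"
  )
}

# Deterministic 31-bit hash of a string, for deriving sub-seeds.
.hash_id <- function(...) {
  s <- paste(..., sep = "|")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483629
  as.integer(h)
}

# Evaluate expr under a temporary RNG seed, restoring global RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Donor- and run-level variability factors
#'
#' Draws log-normal multiplicative factors for the five kinetic processes.
#' Donor factors depend only on `(seed, donor_id)`, so all runs of one donor
#' share them (paired design); run factors additionally depend on surface,
#' preset, switch time and replicate.
#'
#' @param config A [flow_run_config()].
#' @param sigma_donor,sigma_run Log-scale standard deviations
#'   (defaults 0.15 and 0.10).
#' @return List with numeric vectors `donor` and `run` (length 5 each, named
#'   by process).
#' @export
kinetic_noise_factors <- function(config, sigma_donor = 0.15, sigma_run = 0.10) {
  procs <- c("adhesion", "aggregation", "ps_exposure", "thrombin_fibrin",
             "stability")
  # seed arithmetic in double precision; 31-bit modulus avoids overflow
  donor_seed <- (as.numeric(config$seed %% 100000L) * 13001 +
                   .hash_id(config$donor_id)) %% 2147483629
  donor <- .with_seed(donor_seed,
                      setNames(rlnorm(5, 0, sigma_donor), procs))
  run_seed <- (as.numeric(config$seed %% 100000L) * 17027 +
                 .hash_id(config$donor_id, config$replicate_id,
                          config$surface, config$preset$name,
                          config$switch_time)) %% 2147483629
  run <- .with_seed(run_seed,
                    setNames(rlnorm(5, 0, sigma_run), procs))
  list(donor = donor, run = run)
}

#' Simulate thrombus-formation kinetics for one flow run
#'
#' Integrates the logistic-with-delay kinetic model (Euler scheme, 0.02 min
#' steps) for one run and reports the true state at each measurement time
#' point: platelet adhesion coverage, thrombus coverage, phosphatidylserine
#' (PS) exposure coverage, fibrin coverage (all fractions of the field of
#' view) and continuous contraction and multilayering levels on a 0-3 scale.
#'
#' Intervention semantics: the preset's rate factors (and detachment, for
#' integrin blockade) act from `switch_time` onward. Two mechanistic rules
#' encode the role of tissue-factor-triggered thrombin: (1) a preset flagged
#' `initiation_only` (extrinsic-pathway inhibition) is inert unless present
#' from the start, because extrinsic initiation completes within the first
#' 2 min; (2) on collagen/TF the detachment term only acts within that same
#' initial window, after which thrombin/fibrin consolidates the thrombi; on
#' collagen alone detachment continues and can dismantle established thrombi.
#'
#' @param config A [flow_run_config()].
#' @param noise `"donor_run"` (default) applies the donor- and run-level
#'   log-normal factors from [kinetic_noise_factors()]; `"none"` disables
#'   biological variability (pure model trajectories).
#' @param dt Euler step in minutes.
#'
#' @return A data.frame of class `kinetic_states` with one row per time point
#'   and columns `time`, `platelet_coverage`, `thrombus_coverage`,
#'   `ps_coverage`, `fibrin_coverage`, `contraction_level`,
#'   `multilayer_level`.
#' @export
#' @examples
#' simulate_kinetics(flow_run_config("collagen_TF", seed = 7), noise = "none")
simulate_kinetics <- function(config, noise = c("donor_run", "none"),
                              dt = 0.02) {
  stopifnot(inherits(config, "flow_run_config"))
  noise <- match.arg(noise)
  sr <- .surface_rates(config$surface)
  caps <- .KIN_CAPS; seeds <- .KIN_SEEDS
  preset <- config$preset
  switch_t <- if (is.na(config$switch_time)) Inf else config$switch_time

  # extrinsic-initiation gate: initiation-only inhibitors act only from t = 0
  inert <- preset$initiation_only && switch_t > 0
  factors <- if (inert) rep(1, 5) else preset$factors
  names(factors) <- names(preset$factors)
  detach <- if (inert) 0 else preset$detach_per_min

  nf <- if (noise == "donor_run") kinetic_noise_factors(config)
        else list(donor = rep(1, 5), run = rep(1, 5))
  biol <- setNames(as.numeric(nf$donor) * as.numeric(nf$run),
                   names(preset$factors))

  t_end <- max(config$timepoints)
  n_steps <- ceiling(t_end / dt)
  out <- matrix(NA_real_, nrow = length(config$timepoints),
                ncol = length(.KIN_STATE_COLS),
                dimnames = list(NULL, .KIN_STATE_COLS))

  P <- 0; Tc <- 0; S <- 0; Fb <- 0; Lcon <- 0; Lmul <- 0
  next_tp <- 1L
  for (i in seq_len(n_steps)) {
    t0 <- (i - 1) * dt
    act <- t0 >= switch_t                      # inhibitor present at this step
    f <- function(p) if (act) factors[[p]] * biol[[p]] else biol[[p]]

    d_eff <- 0
    if (act && detach > 0) {
      if (config$surface == "collagen" || t0 < .THROMBIN_COMMIT_MIN)
        d_eff <- detach
    }

    dP <- f("adhesion") * sr$r_adh * (P + seeds$c0_adh) * (1 - P / caps$K_P)
    gate <- min(1, P / 0.05)                   # thrombi need adhered platelets
    dT <- f("aggregation") * sr$r_agg * (Tc + seeds$c0_agg) *
      (1 - Tc / caps$K_T) * gate - d_eff * Tc
    dS <- f("ps_exposure") * sr$r_ps * P * (1 - S / caps$K_S)
    dF <- if (t0 >= sr$tau_fibrin)
      f("thrombin_fibrin") * sr$r_fib * (Fb + seeds$c0_fib) *
        (1 - Fb / caps$K_F) else 0
    dLc <- f("stability") * sr$r_con * (Tc / caps$K_T) * (3 - Lcon) -
      d_eff * Lcon
    dLm <- f("aggregation") * sr$r_mul * (Tc / caps$K_T) * (3 - Lmul) -
      d_eff * Lmul

    P <- min(max(P + dt * dP, 0), 1)
    Tc <- min(max(Tc + dt * dT, 0), 1, P)      # thrombus within platelet field
    S <- min(max(S + dt * dS, 0), 1)
    Fb <- min(max(Fb + dt * dF, 0), 1)
    Lcon <- min(max(Lcon + dt * dLc, 0), 3)
    Lmul <- min(max(Lmul + dt * dLm, 0), 3)

    t1 <- i * dt
    while (next_tp <= length(config$timepoints) &&
           config$timepoints[next_tp] <= t1 + 1e-9) {
      out[next_tp, ] <- c(config$timepoints[next_tp], P, Tc, S, Fb, Lcon, Lmul)
      next_tp <- next_tp + 1L
    }
  }
  res <- as.data.frame(out)
  class(res) <- c("kinetic_states", "data.frame")
  res
}
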