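final_state <- function(surface, preset, sw = NA, noise = "none", seed = 1) {
  st <- simulate_kinetics(flow_run_config(surface, preset, switch_time = sw,
                                          seed = seed), noise = noise)
  st[nrow(st), ]
}

test_that("coverages stay in [0,1] for every preset, switch and surface", {
  presets <- intervention_presets()$name
  for (surface in c("collagen", "collagen_TF"))
    for (preset in presets)
      for (sw in list(0, 2, NA)) {
        st <- simulate_kinetics(
          flow_run_config(surface, preset, switch_time = sw,
                          donor_id = paste0("d", preset), seed = 11))
        covs <- as.matrix(st[, c("platelet_coverage", "thrombus_coverage",
                                 "ps_coverage", "fibrin_coverage")])
        expect_true(all(covs >= 0 & covs <= 1),
                    info = paste(surface, preset, sw))
        expect_true(all(st$thrombus_coverage <= st$platelet_coverage + 1e-9),
                    info = paste(surface, preset, sw))
        expect_true(all(st$contraction_level >= 0 & st$contraction_level <= 3))
        expect_true(all(st$multilayer_level >= 0 & st$multilayer_level <= 3))
      }
})

test_that("vehicle thrombus and fibrin coverage are non-decreasing in time", {
  for (surface in c("collagen", "collagen_TF")) {
    st <- simulate_kinetics(flow_run_config(surface, "vehicle", seed = 5))
    expect_true(all(diff(st$thrombus_coverage) >= -1e-12), info = surface)
    expect_true(all(diff(st$fibrin_coverage) >= -1e-12), info = surface)
  }
})

test_that("fibrin appears after onset on collagen/TF and not on collagen", {
  st_tf <- simulate_kinetics(flow_run_config("collagen_TF", seed = 2),
                             noise = "none")
  # onset around 4 min: none at 2, present from ~4-6 onward
  expect_equal(st_tf$fibrin_coverage[st_tf$time == 2], 0)
  expect_gt(st_tf$fibrin_coverage[st_tf$time == 6], 0)
  st_c <- simulate_kinetics(flow_run_config("collagen", seed = 2),
                            noise = "none")
  expect_equal(max(st_c$fibrin_coverage), 0)
})

test_that("tissue factor accelerates thrombus and fibrin at every timepoint", {
  tf <- simulate_kinetics(flow_run_config("collagen_TF", seed = 1),
                          noise = "none")
  cn <- simulate_kinetics(flow_run_config("collagen", seed = 1),
                          noise = "none")
  expect_true(all(tf$thrombus_coverage >= cn$thrombus_coverage - 1e-12))
  expect_true(all(tf$fibrin_coverage >= cn$fibrin_coverage - 1e-12))
})

test_that("earlier inhibition gives at most the coverage of later inhibition", {
  for (surface in c("collagen", "collagen_TF"))
    for (preset in c("iFVIIa", "PAR1_4", "GPVI_Fab", "Syk_IN", "tirofiban")) {
      f0 <- final_state(surface, preset, 0)$thrombus_coverage
      f2 <- final_state(surface, preset, 2)$thrombus_coverage
      veh <- final_state(surface, "vehicle")$thrombus_coverage
      expect_lte(f0, f2 + 1e-9, label = paste(surface, preset, "sw0 vs sw2"))
      # detachment can push the late switch below the early monolayer plateau
      if (!(preset == "tirofiban" && surface == "collagen"))
        expect_lte(f2, veh + 1e-9, label = paste(surface, preset, "sw2 vs veh"))
    }
})

test_that("extrinsic-pathway inhibition abolishes fibrin only from the start", {
  i0 <- simulate_kinetics(flow_run_config("collagen_TF", "iFVIIa",
                                          switch_time = 0, seed = 3))
  expect_equal(max(i0$fibrin_coverage), 0)
  # introduced after 2 min: inert, trajectories equal the vehicle run
  veh <- simulate_kinetics(flow_run_config("collagen_TF", "vehicle", seed = 3),
                           noise = "none")
  i2 <- simulate_kinetics(flow_run_config("collagen_TF", "iFVIIa",
                                          switch_time = 2, seed = 3),
                          noise = "none")
  expect_equal(as.matrix(i2), as.matrix(veh), tolerance = 0.01)
})

test_that("GPVI or Syk blockade from start nearly annuls PS exposure", {
  veh <- final_state("collagen_TF", "vehicle")
  for (preset in c("GPVI_Fab", "Syk_IN")) {
    inh <- final_state("collagen_TF", preset, 0)
    expect_lt(inh$ps_coverage, 0.05 * veh$ps_coverage, label = preset)
  }
})

test_that("late integrin blockade dismantles thrombi on collagen but not collagen/TF", {
  tc <- simulate_kinetics(flow_run_config("collagen", "tirofiban",
                                          switch_time = 2, seed = 6),
                          noise = "none")
  expect_lt(tc$thrombus_coverage[tc$time == 10],
            tc$thrombus_coverage[tc$time == 2])
  ttf <- simulate_kinetics(flow_run_config("collagen_TF", "tirofiban",
                                           switch_time = 2, seed = 6),
                           noise = "none")
  expect_gte(ttf$thrombus_coverage[ttf$time == 10],
             ttf$thrombus_coverage[ttf$time == 2] - 1e-9)
})

test_that("simulation is deterministic and donor factors pair across conditions", {
  cfg <- flow_run_config("collagen_TF", "PAR1_4", switch_time = 0, seed = 9)
  expect_identical(simulate_kinetics(cfg), simulate_kinetics(cfg))
  # same donor, different condition: shared donor factors, new run factors
  a <- kinetic_noise_factors(flow_run_config("collagen", "vehicle",
                                             donor_id = "dA", seed = 4))
  b <- kinetic_noise_factors(flow_run_config("collagen_TF", "tirofiban",
                                             switch_time = 2,
                                             donor_id = "dA", seed = 4))
  d <- kinetic_noise_factors(flow_run_config("collagen", "vehicle",
                                             donor_id = "dB", seed = 4))
  expect_identical(a$donor, b$donor)
  expect_false(identical(a$run, b$run))
  expect_false(identical(a$donor, d$donor))
})

test_that("run configurations are validated", {
  expect_error(flow_run_config("collagen", "vehicle", timepoints = c(4, 2)),
               "strictly increasing")
  expect_error(flow_run_config("collagen", "iFVIIa", switch_time = 3),
               "switch_time")
  expect_error(flow_run_config("granite"), "arg")
  # vehicle never switches
  expect_true(is.na(flow_run_config("collagen", "vehicle",
                                    switch_time = 2)$switch_time))
})
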