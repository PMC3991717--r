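test_that("injection rate is the dose-conserving step function", {
  bolus <- injection_protocol(0.025, 73, 7, "bolus")
  expect_equal(injection_rate(3, bolus), 1.825 / 7)
  expect_equal(injection_rate(10, bolus), 0)
  infusion <- injection_protocol(0.2, 83, 600, "infusion")
  expect_equal(injection_rate(300, infusion), 16.6 / 600)
  expect_equal(injection_rate(c(0, 599.99, 600), infusion),
               c(16.6 / 600, 16.6 / 600, 0))
  expect_error(injection_rate(-1, bolus), "time")
})

test_that("flux_amount implements the kinetic laws on the reference volume", {
  phys <- physiology(V_liver = 1.8, hepatocyte_fraction = 0.68)  # V_h = 1.224
  spec <- build_variant("M0")
  par <- ref_par()
  expect_equal(
    flux_amount("hepatocyte_to_bile", list(C_h = 1), par, phys, spec),
    3.852e-4 * 1.224)
  # MM saturation limit approaches v_max * V_ref
  mm_par <- kinetic_parameters(
    k_diff = par$k_diff, k_ph = par$k_ph, k_hp = par$k_hp,
    mm = list(hepatocyte_to_bile = list(v_max = 2e-4, K_m = 0.05)))
  m1 <- build_variant("M1")
  f_inf <- flux_amount("hepatocyte_to_bile", list(C_h = 1e6), mm_par, phys, m1)
  expect_equal(f_inf, 2e-4 * 1.224, tolerance = 1e-4)
  # plasma/EES equilibrium: net diffusion flux vanishes when
  # C_e = (1 - f_alb) * C_p (both directions share the EES reference volume)
  cp <- 0.3
  ce <- (1 - phys$albumin_bound_fraction) * cp
  jpe <- flux_amount("plasma_to_ees", list(C_p = cp), par, phys, spec)
  jep <- flux_amount("ees_to_plasma", list(C_e = ce), par, phys, spec)
  expect_equal(jpe, jep)
  expect_error(
    flux_amount("hepatocyte_to_bile", list(C_h = 1), par, phys,
                build_variant("M6")), "absent")
  expect_error(
    flux_amount("plasma_to_ees", list(C_p = -1), par, phys, spec), ">= 0")
  expect_error(flux_amount("nope", list(), par, phys, spec), "valid edges")
})

test_that("zero dose gives the identically-zero trajectory", {
  prot <- injection_protocol(dose_per_kg = 0)
  traj <- simulate_model(build_variant("M0"), ref_par(), def_phys(), prot,
                         c(0, 100, 1000))
  expect_true(all(as.matrix(traj[, -1]) == 0))
})

test_that("with no EES or hepatocyte exchange the plasma curve is mono-exponential", {
  par <- kinetic_parameters(xi = 1, k_hb = 0, k_diff = 0, k_ph = 0, k_hp = 0)
  phys <- def_phys()
  prot <- clin_prot()
  D <- total_dose(prot)
  times <- c(7, 60, 600, 3600, 10800)
  traj <- simulate_model(build_variant("M0"), par, phys, prot, times)
  c0 <- traj$C_p[1]   # end of the 7 s bolus
  expected <- c0 * exp(-par$k_kid * (times - 7))
  expect_equal(traj$C_p, expected, tolerance = 1e-6)
  expect_equal(traj$A_u, D - expected * phys$V_plasma, tolerance = 1e-6)
})

test_that("RK45 matches the independent matrix-exponential route for linear variants", {
  skip_if_not_installed("Matrix")
  phys <- def_phys(); prot <- clin_prot()
  times <- c(0, 5, 7, 20, 70, 600, 2400, 10800)
  for (v in c("M0", "M2", "M5", "M6")) {   # the all-linear registry members
    spec <- build_variant(v)
    num <- simulate_model(spec, ref_par(), phys, prot, times)
    ora <- linear_oracle_traj(spec, ref_par(), phys, prot, times)
    for (col in c("C_p", "C_e", "C_h", "A_b", "A_u"))
      expect_equal(num[[col]], ora[[col]], tolerance = 1e-6,
                   label = paste(v, col))
  }
})

test_that("mass is conserved and sinks are monotone for random linear models", {
  phys <- def_phys(); prot <- clin_prot()
  D <- total_dose(prot)
  times <- c(0, 3, 7, 50, 600, 2400, 10800)
  set.seed(11)
  for (i in 1:8) {
    par <- random_linear_params()
    traj <- simulate_model(build_variant("M0"), par, phys, prot, times)
    injected <- pmin(D, D * times / 7)
    expect_lt(max(abs(total_mass(traj, phys) - injected)) / D, 1e-6)
    expect_true(all(as.matrix(traj[, -1]) >= 0))
    expect_true(all(diff(traj$A_b) >= 0))
    expect_true(all(diff(traj$A_u) >= 0))
  }
})

test_that("mass is conserved for Michaelis-Menten variants too", {
  phys <- def_phys(); prot <- clin_prot()
  D <- total_dose(prot)
  par <- kinetic_parameters(xi = 1.6, k_diff = 1.7e-3, k_ph = 4.8e-3,
                            k_hp = 2.9e-4,
                            mm = list(hepatocyte_to_bile =
                                        list(v_max = 2e-4, K_m = 0.1)))
  traj <- simulate_model(build_variant("M1"), par, phys, prot,
                         c(0, 7, 600, 2400, 10800))
  injected <- pmin(D, D * traj$time / 7)
  expect_lt(max(abs(total_mass(traj, phys) - injected)) / D, 1e-6)
})

test_that("all-linear trajectories scale proportionally with dose", {
  phys <- def_phys()
  t1 <- simulate_model(build_variant("M0"), ref_par(), phys,
                       injection_protocol(dose_per_kg = 0.025),
                       c(60, 600, 2400))
  t2 <- simulate_model(build_variant("M0"), ref_par(), phys,
                       injection_protocol(dose_per_kg = 0.050),
                       c(60, 600, 2400))
  for (col in c("C_p", "C_e", "C_h", "A_b", "A_u"))
    expect_equal(t2[[col]] / t1[[col]], rep(2, 3), tolerance = 1e-6)
})

test_that("elimination fractions and plasma dose fraction behave at the edges", {
  phys <- def_phys(); prot <- clin_prot()
  spec <- build_variant("M0")
  traj0 <- simulate_model(spec, ref_par(), phys, prot, 0)
  expect_equal(unname(elimination_fractions(traj0)), c(0, 0))
  # no hepatic uptake -> no biliary elimination ever
  par_nouptake <- kinetic_parameters(xi = 1, k_hb = 3.852e-4,
                                     k_diff = 1.731e-3, k_ph = 0, k_hp = 0)
  trj <- simulate_model(spec, par_nouptake, phys, prot, c(0, 600, 10800))
  expect_equal(elimination_fractions(trj)[["bile_pct"]], 0)
  # everything eventually reaches the sinks
  trl <- simulate_model(spec, ref_par(), phys, prot, c(0, 2e6))
  expect_equal(sum(elimination_fractions(trl)), 100, tolerance = 1e-4)
  expect_error(elimination_fractions(trl, dose = 0), "dose")
  # conservation right after an effectively instantaneous bolus
  par_noelim <- kinetic_parameters(xi = 1, k_kid = 0)
  tri <- simulate_model(spec, par_noelim, phys,
                        injection_protocol(duration = 1e-3), c(0.001, 1))
  expect_equal(plasma_dose_fraction(tri, t = 0.001), 100, tolerance = 1e-6)
  expect_error(plasma_dose_fraction(tri, t = 5), "span")
})

test_that("the variant registry matches the published model family", {
  m0 <- build_variant("M0")
  expect_true(all(vapply(m0$flux_config, `[[`, TRUE, "present")))
  expect_true(all(vapply(m0$flux_config, `[[`, "", "law") == "linear"))
  expect_false(build_variant("M7")$flux_config$plasma_to_ees$present)
  expect_false(build_variant("M6")$flux_config$hepatocyte_to_bile$present)
  expect_false(build_variant("M2")$flux_config$hepatocyte_to_plasma$present)
  expect_error(build_variant("M42"), "valid names")
  # fitted-parameter counts per variant (published selection table)
  counts <- vapply(paste0("M", 0:9), function(v)
    length(fitted_parameter_names(build_variant(v))), integer(1))
  expect_equal(unname(counts[c("M0", "M1", "M2", "M4", "M6", "M7", "M8", "M9")]),
               c(5L, 6L, 4L, 5L, 4L, 5L, 8L, 6L))
  # sinks may not use a destination reference volume
  cfg <- m0$flux_config
  cfg$hepatocyte_to_bile$vref <- "destination"
  expect_error(model_spec("bad", cfg), "sink")
})

test_that("type constructors validate their invariants", {
  expect_error(kinetic_parameters(xi = 0), "positive")
  expect_error(kinetic_parameters(k_ph = -1), ">= 0")
  expect_error(kinetic_parameters(mm = list(plasma_to_urine =
                                              list(v_max = 1, K_m = 1))),
               "unknown")
  expect_error(physiology(hematocrit = 1), "hematocrit")
  expect_error(physiology(V_ees = -1), "volume")
  expect_error(physiology(roi_fractions = list(
    liver = c(plasma = 0.12, ees = 0.2, hepatocyte = 0.68),
    spleen = c(plasma = 0.35, ees = 0.2),
    vein = c(plasma = 0.9))), "vein")
  expect_error(injection_protocol(duration = 0), "duration")
  expect_equal(total_dose(injection_protocol(0.025, 73)), 1.825)
})
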