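# a dataset + fit shared by the profile-likelihood tests (noise-free, so the
# optimum is the generating parameter vector and cost is ~0)
pl_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_estimation_like(ref_par(), noisy = FALSE)
      res <- fit_model(build_variant("M0"), ds, restarts = 2,
                       evals_per_restart = 3000, seed = 2)
      cache <<- list(ds = ds, res = res)
    }
    cache
  }
})

test_that("profile likelihood brackets the generating value on noise-free data", {
  fx <- pl_fixture()
  pr <- profile_likelihood(build_variant("M0"), fx$ds, "k_ph", fx$res,
                           protocol = clin_prot(), include_constraint = FALSE)
  expect_true(pr$finite)
  # on noise-free data the acceptable region can be narrower than one
  # multiplicative profile step, so containment may be at the boundary
  expect_lte(pr$lower, 4.776e-3 * (1 + 1e-6))
  expect_gte(pr$upper, 4.776e-3 * (1 - 1e-6))
  expect_lte(pr$optimal_cost, min(pr$costs) + 1e-6)
  expect_error(
    profile_likelihood(build_variant("M0"), fx$ds, "k_nope", fx$res,
                       protocol = clin_prot()), "unknown parameter")
})

test_that("a parameter with no effect on the outputs has an unbounded profile", {
  # remove the uptake edge but keep the bile edge: k_hb never sees any agent
  cfg <- build_variant("M0")$flux_config
  cfg$plasma_to_hepatocyte$present <- FALSE
  cfg$hepatocyte_to_plasma$present <- FALSE
  spec <- model_spec("inert_bile", cfg)
  expect_setequal(fitted_parameter_names(spec), c("xi", "k_diff", "k_hb"))
  par <- kinetic_parameters(xi = 1.604, k_hb = 3.852e-4, k_diff = 1.731e-3)
  ds <- generate_estimation_like(par, spec = spec, noisy = FALSE)
  res <- fit_model(spec, ds, restarts = 2, evals_per_restart = 2000,
                   seed = 6)
  pr <- profile_likelihood(spec, ds, "k_hb", res, protocol = clin_prot(),
                           span = 50, include_constraint = FALSE)
  expect_false(pr$finite)
})

test_that("core prediction bands are envelopes with subset nesting", {
  spec <- build_variant("M0"); phys <- def_phys(); prot <- clin_prot()
  fx <- pl_fixture()
  ens <- fx$res$ensemble
  expect_gt(nrow(ens), 10)
  times <- c(0, 600, 2400)
  one <- core_prediction_band(ens[1, , drop = FALSE], "liver", spec, phys,
                              prot, times)
  expect_equal(one$lower, one$upper)
  sub <- core_prediction_band(ens[1:10, , drop = FALSE], "bile_pct", spec,
                              phys, prot, times)
  full <- core_prediction_band(ens[1:40, , drop = FALSE], "bile_pct", spec,
                               phys, prot, times)
  expect_true(all(sub$lower >= full$lower - 1e-12))
  expect_true(all(sub$upper <= full$upper + 1e-12))
  expect_error(core_prediction_band(ens[0, ], "liver", spec, phys, prot),
               "empty")
  expect_error(core_prediction_band(ens, "nonsense", spec, phys, prot),
               "quantity")
})

test_that("applying the ad hoc constraint never widens a prediction band", {
  spec <- build_variant("M0"); phys <- def_phys(); prot <- clin_prot()
  ds <- generate_estimation_like(ref_par(), noisy = TRUE, seed = 12)
  res <- fit_model(spec, ds, restarts = 2, evals_per_restart = 3000,
                   seed = 12)
  expect_false(res$rejected)
  res$ensemble <- hepatokin:::.thin_ensemble(res$ensemble, 300)
  con <- apply_adhoc_constraint(res, spec, phys, prot)
  expect_gt(nrow(con$ensemble), 0)
  times <- c(600, 2400, 10800)
  for (q in c("bile_pct", "urine_pct", "plasma_fraction")) {
    b_all <- core_prediction_band(res$ensemble, q, spec, phys, prot, times,
                                  cap = 1e9)
    b_con <- core_prediction_band(con$ensemble, q, spec, phys, prot, times,
                                  cap = 1e9)
    expect_true(all(b_con$lower >= b_all$lower - 1e-9), label = q)
    expect_true(all(b_con$upper <= b_all$upper + 1e-9), label = q)
  }
})

test_that("volume sensitivity reduces to nominal at zero change and is EES-led", {
  spec <- build_variant("M0"); phys <- def_phys(); prot <- clin_prot()
  times <- seq(0, 2400, by = 300)
  vs0 <- volume_sensitivity(spec, ref_par(), phys, prot, rel_change = 0,
                            times = times)
  for (nm in names(vs0$curves)) {
    expect_equal(vs0$curves[[nm]]$minus, vs0$curves[[nm]]$nominal)
    expect_equal(vs0$curves[[nm]]$plus, vs0$curves[[nm]]$nominal)
  }
  vs <- volume_sensitivity(spec, ref_par(), phys, prot, times = times)
  expect_equal(vs$ranking$volume[1], "V_ees")
  # envelope entries equal direct re-simulation
  ph2 <- physiology(V_ees = phys$V_ees * 1.2)
  tr2 <- simulate_model(spec, ref_par(), ph2, prot, times)
  direct <- roi_signal(tr2, "liver", signal_design(ph2, ref_par()$xi))
  expect_equal(vs$curves$V_ees$plus, direct, tolerance = 1e-10)
  expect_error(volume_sensitivity(spec, ref_par(), phys, prot,
                                  rel_change = -1), "rel_change")
})

test_that("simulated loss of liver function shifts elimination to urine", {
  spec <- build_variant("M0"); phys <- def_phys(); prot <- clin_prot()
  fl <- simulate_function_loss(spec, ref_par(), phys, prot,
                               uptake_scalings = c(1, 0.5, 0.1, 1e-3),
                               times = seq(0, 2400, by = 300))
  # s = 1 reproduces the nominal simulation
  nominal <- roi_signal(simulate_model(spec, ref_par(), phys, prot,
                                       seq(0, 2400, by = 300)),
                        "liver", signal_design(phys, ref_par()$xi))
  expect_equal(fl$signals$s_1, nominal)
  # liver signal decreases monotonically with decreasing uptake
  post <- fl$signals$time > 0
  expect_true(all(fl$signals$s_1[post] >= fl$signals$s_0.5[post]))
  expect_true(all(fl$signals$s_0.5[post] >= fl$signals$s_0.1[post]))
  expect_true(all(fl$signals$s_0.1[post] >= fl$signals$s_0.001[post]))
  # vanishing uptake sends essentially all elimination through the kidneys
  expect_gt(fl$elimination$urine_share_pct[4], 99)
  expect_error(simulate_function_loss(spec, ref_par(), phys, prot,
                                      uptake_scalings = c(1, 0)), "scalings")
})
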