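make_ds <- function(values, sigma = 1, in_cost = TRUE) {
  structure(data.frame(time = seq_along(values), value = values,
                       sigma = sigma, label = "liver", in_cost = in_cost),
            protocol = clin_prot(),
            class = c("timeseries_dataset", "data.frame"))
}

test_that("chi-square cost is the sigma-normalised sum of squares", {
  ds <- make_ds(c(1, 2, 3))
  expect_equal(chi2_cost(c(1, 2, 3), ds), 0)
  expect_equal(chi2_cost(c(1, 2, 6), ds), 9)        # single 3-sigma residual
  expect_equal(chi2_cost(c(2, 4, 3), ds), 5)        # 1 sigma + 2 sigma
  ds2 <- make_ds(c(1, 2), sigma = 0.5)
  expect_equal(chi2_cost(c(1.5, 2), ds2), 1)
  expect_error(chi2_cost(c(1, 2), ds), "match")
  expect_error(chi2_cost(c(1, 2, 3), make_ds(c(1, 2, 3), sigma = 0)),
               "sigma")
  # baseline records are excluded from the cost
  ds3 <- make_ds(c(5, 1, 2), in_cost = c(FALSE, TRUE, TRUE))
  expect_equal(chi2_cost(c(0, 1, 2), ds3), 0)
})

test_that("chi-square threshold reproduces the published cut-offs", {
  # the printed cut-off 23.684 is the truncated qchisq(0.95, 14) = 23.68479
  expect_lt(abs(chi2_threshold(18, 4, 0.05) - 23.684), 1e-3)
  expect_equal(round(chi2_threshold(2, 1, 0.05), 3), 3.841)
  expect_equal(round(chi2_threshold(9, 0, 0.05), 3), 16.919)
  expect_error(chi2_threshold(4, 4, 0.05), "n_data")
  expect_error(chi2_threshold(18, 4, 1.2), "alpha")
  # monotone in degrees of freedom
  th <- vapply(5:15, function(n) chi2_threshold(n, 4), numeric(1))
  expect_true(all(diff(th) > 0))
})

test_that("infinitely noisy data accept every sampled candidate", {
  ds <- generate_estimation_like(ref_par(), noisy = FALSE)
  ds$sigma <- 1e12
  res <- fit_model(build_variant("M0"), ds, restarts = 1,
                   evals_per_restart = 200, seed = 3)
  expect_false(res$rejected)
  expect_lt(res$optimal_cost, 1e-10)
  expect_equal(nrow(res$ensemble), res$diagnostics$n_eval)
})

test_that("the acceptable ensemble is sound and reproducible", {
  ds <- generate_estimation_like(ref_par(), noisy = TRUE, seed = 5)
  res <- fit_model(build_variant("M0"), ds, restarts = 1,
                   evals_per_restart = 1500, seed = 9)
  expect_true(all(res$ensemble$cost <= res$threshold))
  expect_lte(res$optimal_cost, min(res$ensemble$cost))
  res2 <- fit_model(build_variant("M0"), ds, restarts = 1,
                    evals_per_restart = 1500, seed = 9)
  expect_identical(res$optimal_vector, res2$optimal_vector)
  expect_identical(res$ensemble, res2$ensemble)
})

test_that("a structurally wrong variant is rejected, not an error", {
  ds <- generate_estimation_like(ref_par(), noisy = TRUE, seed = 1)
  res <- fit_model(build_variant("M7"), ds, restarts = 2,
                   evals_per_restart = 2500, seed = 1)
  expect_true(res$rejected)
  expect_gt(res$optimal_cost, res$threshold)
  expect_null(res$optimal_params)
  expect_s3_class(res, "fit_result")
})

test_that("the ad hoc constraint filters plasma-depleting members", {
  spec <- build_variant("M0")
  phys <- def_phys(); prot <- clin_prot()
  # an engineered member that empties plasma by 3 h: huge uptake, no return
  depleting <- c(xi = 1.6, k_diff = 1.731e-3, k_ph = 5e-2, k_hp = 1e-6,
                 k_hb = 3.852e-4)
  keeping <- c(xi = 1.6, k_diff = 1.731e-3, k_ph = 4.776e-3, k_hp = 2.857e-4,
               k_hb = 3.852e-4)
  ens <- rbind(as.data.frame(as.list(depleting)),
               as.data.frame(as.list(keeping)))
  ens$cost <- c(1, 2)
  res <- structure(list(ensemble = ens, optimal_cost = 1, spec = spec,
                        optimal_vector = depleting, threshold = 23.684,
                        rejected = FALSE, seed = 1L,
                        diagnostics = list()), class = "fit_result")
  out <- apply_adhoc_constraint(res, spec, phys, prot)
  expect_equal(nrow(out$ensemble), 1)
  expect_equal(out$optimal_vector[["k_ph"]], 4.776e-3)
  # empty in, empty out, no error
  res$ensemble <- ens[0, ]
  out0 <- apply_adhoc_constraint(res, spec, phys, prot)
  expect_equal(nrow(out0$ensemble), 0)
  expect_true(out0$rejected)
})
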