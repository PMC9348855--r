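test_that("GFP map satisfies the mean-duration identity", {
  g <- gfp_map(11)
  expect_equal(naivedyn:::.p_gfp(0, g), 1)
  a <- seq(0, 600, by = 0.01)
  expect_equal(sum(naivedyn:::.p_gfp(a, g)) * 0.01, 11, tolerance = 1e-2)
  expect_error(gfp_map(0))
})

test_that("co-transfer ratio stays at 1 for age-independent kinetics", {
  p <- kinetic_params("neutral", delta0 = 1 / 30, rho0 = 1 / 500, psi = 0.3)
  ct <- simulate_cotransfer(p, influx_cd4, cotransfer_setup(horizon = 42))
  expect_equal(ct$ratio, rep(1, nrow(ct)), tolerance = 1e-9)
})

test_that("age-dependent loss drives a monotone decline in the RTE:MN ratio", {
  ct <- simulate_cotransfer(params_cd4, influx_cd4,
                            cotransfer_setup(horizon = 84))
  expect_equal(ct$ratio[1], 1)
  expect_true(all(diff(ct$ratio) < 0))
  expect_lt(ct$ratio[ct$t_days == 84], 0.75)
  # fitted age-dependent division kinetics are too weak to separate pools
  pd <- kinetic_params("age_division", delta0 = 1 / 40, rho0 = 1 / 548,
                       r_rho = log(2) / 304.4, psi = 0.3)
  ctd <- simulate_cotransfer(pd, influx_cd8, cotransfer_setup(horizon = 42))
  expect_equal(ctd$ratio[ctd$t_days == 42], 1, tolerance = 0.05)
})

test_that("co-transfer envelope spans the point prediction", {
  draws <- cbind(delta0 = c(1 / 20, 1 / 22, 1 / 25),
                 r_delta = log(2) / c(80, 92, 110))
  ct <- simulate_cotransfer(params_cd4, influx_cd4,
                            cotransfer_setup(horizon = 28), draws = draws)
  expect_true(all(ct$lo <= ct$ratio + 1e-9 & ct$ratio <= ct$hi + 1e-9))
})

test_that("hard age cutoff gives a qualitatively similar decline", {
  ct <- simulate_cotransfer(params_cd4, influx_cd4,
                            cotransfer_setup(horizon = 42),
                            hard_cutoff_age = 21)
  expect_true(all(diff(ct$ratio) < 0))
})

test_that("reporter fractions reduce to totals as GFP persists forever", {
  tr <- solve_age_structured(params_cd4, influx_cd4, c(1, 100),
                             t_out = c(30, 60, 100), a_step = 0.5)
  ob <- observables_from_trajectory(tr)
  pr <- predict_reporter_fractions(tr, gfp_map(1e9))
  expect_equal(pr$gfp_count, ob$total_count, tolerance = 1e-6)
  expect_equal(pr$pct_gfp_ki67pos + pr$pct_gfp_ki67neg, rep(100, 3),
               tolerance = 1e-6)
})

test_that("with Ki67- influx and no division there are no GFP+Ki67+ cells", {
  d <- influx_descriptor(count_params = c(A = 1e4),
                         ki67_params = c(k = 0), psi = 1,
                         count_family = "constant", ki67_family = "constant")
  p <- kinetic_params("neutral", delta0 = 0.03, rho0 = 0, psi = 1)
  tr <- solve_age_structured(p, d, c(1, 60), t_out = c(30, 60), a_step = 0.5)
  pr <- predict_reporter_fractions(tr, gfp_map(10))
  expect_equal(pr$pct_gfp_ki67pos, c(0, 0))
  expect_gt(pr$pct_gfp_ki67neg[1], 0)
})

test_that("compartmental trajectories are rejected for reporter mapping", {
  pn <- kinetic_params("neutral", delta0 = 0.03, psi = 0.3)
  tc <- solve_compartmental(pn, influx_cd4, c(1, 60), t_out = 60)
  expect_error(predict_reporter_fractions(tc, gfp_map(10)), "age-resolved")
})

test_that("GFP duration is recovered from reporter data", {
  rep0 <- generate_reporter_dataset(params_cd4, influx_cd4, gfp_map(11),
                                    noise = noise_spec(0, 0), seed = 1)
  est0 <- estimate_gfp_duration(rep0, params_cd4, influx_cd4)
  expect_equal(est0$median, 11, tolerance = 0.05)
  rep1 <- generate_reporter_dataset(params_cd4, influx_cd4, gfp_map(11),
                                    seed = 2)
  est1 <- estimate_gfp_duration(rep1, params_cd4, influx_cd4)
  expect_gt(est1$q97.5, 11)
  expect_lt(est1$q2.5, 11)
  rep8 <- generate_reporter_dataset(params_cd8, influx_cd8, gfp_map(8),
                                    seed = 3)
  est8 <- estimate_gfp_duration(rep8, params_cd8, influx_cd8)
  expect_equal(est8$median, 8, tolerance = 0.25)
  expect_gt(est8$q97.5, est8$q2.5)
})

test_that("extrapolation to birth reproduces neonatal Ki67 dynamics", {
  tr <- extrapolate_to_birth(params_cd4, influx_cd4, "CD4", t_end = 120,
                             a_step = 0.5)
  ob <- observables_from_trajectory(tr)
  wk1 <- ob$ki67_host[ob$t_days >= 2 & ob$t_days <= 8]
  expect_gt(max(wk1, na.rm = TRUE), 0.6)   # >60% Ki67+ early in life
  k90 <- ob$ki67_host[which.min(abs(ob$t_days - 90))]
  expect_lt(k90, 0.05)              # a few percent by 3 months
  expect_true(all(diff(ob$ki67_host[ob$t_days > 10]) < 0))
})

test_that("zero influx from birth leaves an identically empty pool", {
  p0 <- kinetic_params("neutral", delta0 = 0.03, psi = 0)
  tr <- solve_age_structured(p0, influx_cd4, c(1, 50), t_out = c(25, 50))
  ob <- observables_from_trajectory(tr)
  expect_equal(ob$total_count, c(0, 0))
})

test_that("the CD8 neonatal modifier raises early loss, sparing adults", {
  mod <- default_lambda0_hill()
  # modifier scaling within 2% of 1 for cohorts exported after 100 d
  expect_lt(max(naivedyn:::.modifier_scale(mod, seq(100, 600, by = 1))) - 1,
            0.02)
  p8m <- reference_params("CD8", neonatal_modifier = mod)
  ob_m <- observables_from_trajectory(
    extrapolate_to_birth(p8m, influx_cd8, "CD8", t_end = 60, a_step = 0.5,
                         t_out = c(14, 28, 56)))
  ob_0 <- observables_from_trajectory(
    extrapolate_to_birth(params_cd8, influx_cd8, "CD8", t_end = 60,
                         a_step = 0.5, t_out = c(14, 28, 56)))
  expect_true(all(ob_m$total_count < ob_0$total_count))
  # faster loss of young Ki67+ cohorts raises the Ki67+ fraction... of the
  # smaller pool relative to its Ki67- remainder: fractions shift measurably
  expect_gt(max(abs(ob_m$ki67_host - ob_0$ki67_host)), 0.005)
  expect_error(extrapolate_to_birth(params_cd4, influx_cd4, "CD4",
                                    neonatal_modifier = mod), "CD4")
  tr_forced <- extrapolate_to_birth(params_cd4, influx_cd4, "CD4",
                                    neonatal_modifier = mod, t_end = 30,
                                    force = TRUE)
  expect_s3_class(tr_forced, "population_trajectory")
})

test_that("mean residence time reduces to 1/delta for constant loss", {
  p <- kinetic_params("neutral", delta0 = 0.05, psi = 0.3)
  expect_equal(mean_mn_residence_time(p, influx_cd4, t = 84, a_min = 21),
               20, tolerance = 1e-4)
  expect_equal(mean_mn_residence_time(p, influx_cd4, t = 84, a_min = 21,
                                      definition = "instantaneous"), 20)
  expect_error(mean_mn_residence_time(p, influx_cd4, t = 22, a_min = 21),
               "empty age window")
})

test_that("residence time of mature cells grows with host age under age_loss", {
  r60 <- mean_mn_residence_time(params_cd4, influx_cd4, t = 60, a_min = 21)
  r84 <- mean_mn_residence_time(params_cd4, influx_cd4, t = 84, a_min = 21)
  r200 <- mean_mn_residence_time(params_cd4, influx_cd4, t = 200, a_min = 21)
  expect_true(r60 < r84 && r84 < r200)
})

test_that("thymic grafts scale the pool by the expected factor", {
  p <- kinetic_params("neutral", delta0 = 1 / 20, rho0 = 0, psi = 1)
  gr0 <- simulate_thymus_grafts(p, influx_const(), n_lobes = 0)
  expect_equal(gr0$fold_change, rep(1, nrow(gr0)))
  # constant influx, constant loss: fold change -> 1 + n_lobes/2 as the
  # grafted export dominates the pre-graft pool
  gr <- simulate_thymus_grafts(p, influx_const(), n_lobes = 6,
                               graft_age = 300, horizon = 250)
  expect_equal(tail(gr$fold_change, 1), 4, tolerance = 0.02)
  # excess cells correspond to roughly the preceding ~3 weeks of export
  gr4 <- simulate_thymus_grafts(params_cd4, influx_cd4, n_lobes = 6,
                                graft_age = 56, horizon = 56)
  eq <- tail(gr4$export_equiv_days, 1)
  expect_gt(eq, 14); expect_lt(eq, 35)
})
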