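test_that("closed cohort with constant loss decays exponentially", {
  i0 <- default_influx("CD4", psi = 0)
  p <- kinetic_params("neutral", delta0 = 0.05, rho0 = 0, beta = 0, psi = 0)
  tr <- solve_age_structured(p, i0, c(1, 61), t_out = seq(1, 61, by = 2),
                             a_step = 0.5,
                             init = list(N0 = 1e6, ki67 = 0.3, mean_age = 10))
  ob <- observables_from_trajectory(tr)
  expect_equal(ob$total_count, 1e6 * exp(-0.05 * (ob$t_days - 1)),
               tolerance = 1e-4)
})

test_that("conservation: with no loss or division the pool grows linearly", {
  p0 <- kinetic_params("neutral", delta0 = 0, rho0 = 0, beta = 0.2, psi = 1)
  ob <- observables_from_trajectory(
    solve_age_structured(p0, influx_const(S = 1e4), c(1, 101),
                         t_out = c(21, 51, 101), a_step = 0.25))
  expect_equal(ob$total_count, 1e4 * (ob$t_days - 1), tolerance = 1e-9)
})

test_that("Ki67+ fraction of a closed undividing cohort decays as exp(-beta t)", {
  i0 <- default_influx("CD4", psi = 0)
  p <- kinetic_params("neutral", delta0 = 0.05, rho0 = 0, psi = 0)
  ob <- observables_from_trajectory(
    solve_age_structured(p, i0, c(1, 31), t_out = seq(1, 31, by = 3),
                         a_step = 0.5,
                         init = list(N0 = 1e6, ki67 = 0.5, mean_age = 10)))
  expect_equal(ob$ki67_host, 0.5 * exp(-(1 / 3.5) * (ob$t_days - 1)),
               tolerance = 1e-8)
})

test_that("age-structured solution with constant rates matches the neutral ODE", {
  pn <- kinetic_params("neutral", delta0 = 1 / 30, rho0 = 1 / 400, psi = 0.3)
  tt <- seq(15, 250, by = 5)
  oa <- observables_from_trajectory(
    solve_age_structured(pn, influx_cd4, c(1, 250), t_out = tt, a_step = 0.25))
  oc <- compartmental_observables(
    solve_compartmental(pn, influx_cd4, c(1, 250), t_out = tt, rtol = 1e-10))
  expect_lt(max(abs(oa$total_count / oc$total_count - 1)), 1e-3)
  expect_lt(max(abs(oa$ki67_host - oc$ki67_host)), 1e-3)
})

test_that("density dependence with gamma = 0 reproduces the neutral solution", {
  pn <- kinetic_params("neutral", delta0 = 1 / 30, rho0 = 1 / 400, psi = 0.3)
  pd <- kinetic_params("dd_loss", delta0 = 1 / 30, rho0 = 1 / 400, psi = 0.3,
                       gamma = 0)
  tt <- seq(10, 150, by = 10)
  on <- compartmental_observables(
    solve_compartmental(pn, influx_cd4, c(1, 150), t_out = tt, rtol = 1e-10))
  od <- compartmental_observables(
    solve_compartmental(pd, influx_cd4, c(1, 150), t_out = tt, rtol = 1e-10))
  expect_equal(od$total_count, on$total_count, tolerance = 1e-6)
  expect_equal(od$ki67_host, on$ki67_host, tolerance = 1e-6)
})

test_that("rte_mn with very fast maturation approaches the neutral model", {
  pn <- kinetic_params("neutral", delta0 = 1 / 30, rho0 = 1 / 400, psi = 0.3)
  pr <- kinetic_params("rte_mn", delta0 = 1 / 30, rho0 = 1 / 400, psi = 0.3,
                       mu = 1e3, delta_mn = 1 / 30, rho_mn = 1 / 400)
  tt <- seq(20, 150, by = 10)
  on <- compartmental_observables(
    solve_compartmental(pn, influx_cd4, c(1, 150), t_out = tt))
  or <- compartmental_observables(
    solve_compartmental(pr, influx_cd4, c(1, 150), t_out = tt))
  expect_lt(max(abs(or$total_count / on$total_count - 1)), 1e-3)
})

test_that("density-dependent loss shrinks large pools relative to neutral", {
  pn <- kinetic_params("neutral", delta0 = 1 / 30, rho0 = 0, psi = 0.3)
  pd <- kinetic_params("dd_loss", delta0 = 1 / 30, rho0 = 0, psi = 0.3,
                       gamma = 0.5, n_ref = 1e6)
  tt <- c(60, 120)
  on <- compartmental_observables(
    solve_compartmental(pn, influx_cd4, c(1, 120), t_out = tt))
  od <- compartmental_observables(
    solve_compartmental(pd, influx_cd4, c(1, 120), t_out = tt))
  expect_true(all(od$total_count < on$total_count))
})

test_that("mass balance holds along the compartmental solution", {
  # d(total)/dt = influx + (rho - delta) N for the neutral model
  pn <- kinetic_params("neutral", delta0 = 1 / 30, rho0 = 1 / 400, psi = 0.3)
  tt <- seq(20, 200, by = 1)
  ob <- compartmental_observables(
    solve_compartmental(pn, influx_cd4, c(1, 200), t_out = tt, rtol = 1e-10))
  dN <- diff(ob$total_count)
  mid <- (ob$total_count[-1] + ob$total_count[-length(tt)]) / 2
  tm <- (tt[-1] + tt[-length(tt)]) / 2
  rhs <- pn$psi * sp_count_curve(tm, influx_cd4) +
    (pn$rho0 - pn$delta0) * mid
  # absolute flux error relative to the flux scale (rhs crosses zero at the
  # pool peak, so a pointwise relative criterion is ill-posed there)
  expect_lt(max(abs(dN - rhs)), 1e-3 * max(abs(rhs)))
})

test_that("Ki67 is a shadow of thymic export when division is switched off", {
  # with the Ki67 lifetime of 3.5 d and no peripheral division, Ki67+ cells
  # older than 14 d are a ~1% sliver of the Ki67+ pool: peripheral Ki67 is
  # almost entirely carried by cells exported within the past few days
  p <- kinetic_params("age_loss", delta0 = 1 / 22, r_delta = log(2) / 92,
                      rho0 = 0, psi = 0.3)
  tr <- solve_age_structured(p, influx_cd4, c(1, 120),
                             t_out = 120, a_step = 0.25)
  a <- tr$a
  up <- tr$u_pos[, 1]
  w <- c(0.125, rep(0.25, length(a) - 2), 0.125)
  frac_old <- sum(w * up * (a > 14)) / sum(w * up)
  expect_lt(frac_old, 0.015)
  frac_young <- sum(w * up * (a <= 7)) / sum(w * up)
  expect_gt(frac_young, 0.85)
})

test_that("observables flag empty donor pools and bad chimerism", {
  tr <- solve_age_structured(params_cd4, influx_cd4, c(1, 100),
                             t_out = c(50, 100), t_bmt = 200, a_step = 0.5)
  ob <- observables_from_trajectory(tr, reference_chimerism = 0.85)
  expect_true(all(is.na(ob$ki67_donor)))   # donor pool empty before BMT
  expect_equal(ob$fd, c(0, 0))
  expect_error(observables_from_trajectory(tr, reference_chimerism = 0),
               "chimerism")
  expect_error(observables_from_trajectory(tr, reference_chimerism = 1.2),
               "chimerism")
})

test_that("normalised donor fraction saturates below 1 under age-dependent loss", {
  ob <- chimera_observables(params_cd4, influx_cd4,
                            host_age = c(120, 250, 400, 600), age_bmt = 56,
                            a_step = 0.5)
  expect_true(all(diff(ob$fd[1:3]) > 0))   # rises towards its plateau
  expect_true(all(ob$fd < 0.995))          # never reaches complete turnover
  expect_gt(ob$fd[4], 0.8)
})

test_that("host and donor Ki67 fractions start apart and converge", {
  ages <- c(70, 84, 120, 250, 420)
  ob <- chimera_observables(params_cd4, influx_cd4, host_age = ages,
                            age_bmt = 56, a_step = 0.5)
  gap <- abs(ob$ki67_donor - ob$ki67_host)
  expect_gt(gap[1], 5 * gap[5])   # early gap collapses at late times
  expect_lt(gap[5] / ob$ki67_host[5], 0.2)
})
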