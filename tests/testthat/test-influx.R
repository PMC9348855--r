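test_that("Ki67-split influx conserves total export", {
  d <- default_influx("CD4", psi = 0.01)
  tt <- c(1, 7, 30, 60, 200, 600)
  expect_equal(influx_rate(tt, "pos", d) + influx_rate(tt, "neg", d),
               influx_rate(tt, "total", d), tolerance = 1e-12)
  expect_equal(influx_rate(60, "total", d), 0.01 * sp_count_curve(60, d))
  expect_error(influx_rate(0.5, "total", d), "t >= 1")
})

test_that("influx arithmetic matches hand computation", {
  # psi = 0.01/d, S = 1e6, kappa = 0.3 -> pos 3e3/d, neg 7e3/d
  d <- influx_descriptor(count_params = c(A = 1e6),
                         ki67_params = c(k = 0.3), psi = 0.01,
                         count_family = "constant", ki67_family = "constant")
  expect_equal(influx_rate(60, "pos", d), 3e3)
  expect_equal(influx_rate(60, "neg", d), 7e3)
  d0 <- influx_descriptor(count_params = c(A = 1e6),
                          ki67_params = c(k = 1), psi = 0,
                          count_family = "constant", ki67_family = "constant")
  expect_equal(influx_rate(c(1, 50, 600), "total", d0), c(0, 0, 0))
  d1 <- influx_descriptor(count_params = c(A = 1e6),
                          ki67_params = c(k = 1), psi = 0.02,
                          count_family = "constant", ki67_family = "constant")
  expect_equal(influx_rate(30, "neg", d1), 0)
  expect_equal(influx_rate(30, "pos", d1), influx_rate(30, "total", d1))
})

test_that("descriptor curves respect their invariants on [1, 600]", {
  for (ss in c("CD4", "CD8")) {
    d <- default_influx(ss)
    tt <- seq(1, 600, by = 1)
    expect_true(all(sp_count_curve(tt, d) > 0))
    k <- sp_ki67_curve(tt, d)
    expect_true(all(k >= 0 & k <= 1))
    expect_true(all(diff(k) <= 1e-12))   # monotone non-increasing
  }
  expect_error(influx_descriptor(count_params = c(A = -1, l1 = 0.1, l2 = 0.2),
                                 ki67_params = c(k_min = 0.2, t_half = 30,
                                                 slope = 2), psi = 1),
               "positive")
})

test_that("fitting recovers generating curves from noisy SP data", {
  tru <- default_influx("CD4")
  sp <- generate_sp_timecourse(tru, noise = noise_spec(0.1, 0.2), seed = 7)
  fit <- fit_sp_descriptor(sp, "CD4")
  tt <- seq(5, 300, by = 5)
  expect_lt(max(abs(sp_count_curve(tt, fit) / sp_count_curve(tt, tru) - 1)),
            0.15)
  expect_lt(max(abs(sp_ki67_curve(tt, fit) - sp_ki67_curve(tt, tru))), 0.1)
  # kappa ~ 1 in neonates, ~ 0.2 at 90 d
  expect_gt(sp_ki67_curve(3, fit), 0.9)
  expect_equal(sp_ki67_curve(90, fit), 0.2, tolerance = 0.25)
  # fitted curve monotone non-increasing over [5, 120]
  expect_true(all(diff(sp_ki67_curve(5:120, fit)) <= 1e-12))
})

test_that("noise-free and constant inputs are recovered essentially exactly", {
  tru <- default_influx("CD8")
  sp0 <- generate_sp_timecourse(tru, noise = noise_spec(0, 0), subset = "CD8",
                                seed = 1)
  fit0 <- fit_sp_descriptor(sp0, "CD8")
  tt <- seq(5, 400, by = 5)
  expect_lt(max(abs(sp_count_curve(tt, fit0) / sp_count_curve(tt, tru) - 1)),
            0.01)
  spc <- data.frame(mouse_age_days = c(5, 10, 20, 40, 80, 120, 200, 400),
                    subset = "CD4", sp_count = 1e6, sp_ki67_frac = 0.5)
  fc <- fit_sp_descriptor(spc, "CD4")
  expect_equal(unname(sp_count_curve(tt, fc)), rep(1e6, length(tt)),
               tolerance = 1e-3)
  expect_equal(unname(sp_ki67_curve(tt, fc)), rep(0.5, length(tt)),
               tolerance = 1e-3)
})

test_that("out-of-range ages are rejected with a warning; thin data error", {
  tru <- default_influx("CD4")
  sp <- generate_sp_timecourse(tru, seed = 2)
  sp$mouse_age_days[1] <- 700
  expect_warning(fit_sp_descriptor(sp, "CD4"), "rejected")
  expect_error(fit_sp_descriptor(sp[1:5, ], "CD4"), "at least 8")
  adult_only <- sp[sp$mouse_age_days > 90, ]
  expect_error(fit_sp_descriptor(adult_only, "CD4"), "span")
})

test_that("descriptors survive a JSON round trip", {
  d <- default_influx("CD4", psi = 0.12)
  f <- tempfile(fileext = ".json")
  write_influx_json(d, f)
  d2 <- read_influx_json(f)
  tt <- c(1, 10, 100, 600)
  expect_equal(sp_count_curve(tt, d2), sp_count_curve(tt, d))
  expect_equal(sp_ki67_curve(tt, d2), sp_ki67_curve(tt, d))
  expect_equal(d2$psi, 0.12)
  unlink(f)
})
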