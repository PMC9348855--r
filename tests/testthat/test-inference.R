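test_that("pointwise likelihood at exact data equals the normalising constants", {
  des <- chimera_design(n_mice = 8, seed = 3)
  dat <- generate_chimera_dataset(params_cd4, influx_cd4, des,
                                  noise = noise_spec(0, 0), seed = 1)
  sig <- c(sigma_count = 0.2, sigma_fd = 0.3, sigma_ki67 = 0.25)
  ll <- chimera_log_likelihood(params_cd4, sig, dat, influx_cd4)
  stream <- attr(ll, "stream")
  const <- -log(sig[c(count = "sigma_count", fd = "sigma_fd",
                      ki67_host = "sigma_ki67",
                      ki67_donor = "sigma_ki67")[stream]]) -
    0.5 * log(2 * pi)
  expect_equal(unname(as.numeric(ll)), unname(const), tolerance = 1e-6)
})

test_that("doubling sigma_count lowers the best count contribution by log 2", {
  des <- chimera_design(n_mice = 6, seed = 4)
  dat <- generate_chimera_dataset(params_cd4, influx_cd4, des,
                                  noise = noise_spec(0, 0), seed = 2)
  s1 <- c(sigma_count = 0.2, sigma_fd = 0.3, sigma_ki67 = 0.25)
  s2 <- s1; s2[["sigma_count"]] <- 0.4
  l1 <- chimera_log_likelihood(params_cd4, s1, dat, influx_cd4)
  l2 <- chimera_log_likelihood(params_cd4, s2, dat, influx_cd4)
  cnt <- attr(l1, "stream") == "count"
  expect_equal(as.numeric(l1[cnt] - l2[cnt]), rep(log(2), sum(cnt)),
               tolerance = 1e-9)
  expect_equal(as.numeric(l1[!cnt]), as.numeric(l2[!cnt]), tolerance = 1e-9)
})

test_that("true parameters beat a +50% delta0 perturbation on simulated data", {
  p_bad <- params_cd4; p_bad$delta0 <- 1.5 * p_bad$delta0
  sig <- c(sigma_count = sqrt(log(1 + 0.05^2)), sigma_fd = 0.05,
           sigma_ki67 = 0.05)
  wins <- 0
  n_rep <- 25
  for (r in seq_len(n_rep)) {
    des <- chimera_design(n_mice = 40, seed = 600 + r)
    dat <- generate_chimera_dataset(params_cd4, influx_cd4, des,
                                    noise = noise_spec(0.05, 0.05),
                                    seed = 700 + r)
    ctx <- naivedyn:::.chimera_ctx(dat, influx_cd4)
    if (sum(naivedyn:::.fast_loglik(params_cd4, sig, ctx)) >
        sum(naivedyn:::.fast_loglik(p_bad, sig, ctx))) wins <- wins + 1
  }
  expect_equal(wins, n_rep)
})

test_that("a point-mass prior pins its parameter at the given value", {
  des <- chimera_design(n_mice = 20, seed = 5)
  dat <- generate_chimera_dataset(params_cd4, influx_cd4, des, seed = 6)
  pri <- default_priors("age_loss")
  pri$rho0 <- prior_fixed(1 / 548)
  fit <- fit_model(dat, "age_loss", influx_cd4, priors = pri, chains = 1,
                   iter_warmup = 100, iter_sampling = 100, seed = 2)
  expect_false("rho0" %in% colnames(fit$draws))
  expect_equal(unname(fit$meta$fixed[["rho0"]]), 1 / 548)
})

test_that("seeded fits are exactly reproducible", {
  des <- chimera_design(n_mice = 15, seed = 8)
  dat <- generate_chimera_dataset(params_cd4, influx_cd4, des, seed = 9)
  f1 <- fit_model(dat, "age_loss", influx_cd4, chains = 1,
                  iter_warmup = 80, iter_sampling = 80, seed = 42)
  f2 <- fit_model(dat, "age_loss", influx_cd4, chains = 1,
                  iter_warmup = 80, iter_sampling = 80, seed = 42)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$pointwise, f2$pointwise)
})

test_that("PSIS-LOO matches brute-force leave-one-out on a conjugate model", {
  set.seed(11)
  y <- rnorm(6, 1, 1)
  sd_mu <- 10
  post_prec <- 1 / sd_mu^2 + length(y)
  post_mean <- sum(y) / post_prec
  S <- 8000
  mu_draws <- rnorm(S, post_mean, sqrt(1 / post_prec))
  ll <- sapply(y, function(yi) dnorm(yi, mu_draws, 1, log = TRUE))
  res <- loo_elpd(ll)
  exact <- exact_loo_normal(y, 1, sd_mu)
  expect_lt(abs(res$elpd_loo - sum(exact)), 0.1)
  expect_lt(max(abs(res$pointwise - exact)), 0.1)
})

test_that("identical models have zero elpd difference and equal weights", {
  set.seed(12)
  ll <- matrix(rnorm(2000, -1, 0.3), 100, 20)
  l1 <- loo_elpd(ll); l2 <- loo_elpd(ll)
  expect_equal(l1$elpd_loo - l2$elpd_loo, 0)
  w <- pseudo_bma_weights(list(a = l1, b = l2), method = "plain")
  expect_equal(unname(w), c(0.5, 0.5))
  wp <- pseudo_bma_weights(list(a = l1, b = l2), method = "plus", seed = 1)
  expect_equal(unname(wp), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(sum(wp), 1, tolerance = 1e-9)
})

test_that("a decisively better model takes essentially all the weight", {
  set.seed(13)
  base <- matrix(rnorm(3000, -1, 0.2), 150, 20)
  worse <- base - 1      # elpd lower by 20 with tiny pointwise sd
  w <- pseudo_bma_weights(list(good = loo_elpd(base), bad = loo_elpd(worse)),
                          method = "plain")
  expect_gt(w[["good"]], 0.99)
})

test_that("weights are permutation invariant and need a shared observation set", {
  set.seed(14)
  lls <- lapply(1:3, function(i) loo_elpd(matrix(rnorm(1200, -i / 2, 0.4),
                                                 60, 20)))
  names(lls) <- c("a", "b", "c")
  w1 <- pseudo_bma_weights(lls, seed = 5)
  w2 <- pseudo_bma_weights(rev(lls), seed = 5)
  expect_equal(w1[c("a", "b", "c")], w2[c("a", "b", "c")], tolerance = 0.02)
  bad <- loo_elpd(matrix(rnorm(300, -1, 0.3), 30, 10))
  expect_error(pseudo_bma_weights(list(a = lls$a, b = bad)), "observation set")
  expect_error(pseudo_bma_weights(list(a = lls$a)), "two models")
})

test_that("posterior summaries expose convergence diagnostics", {
  des <- chimera_design(n_mice = 20, seed = 15)
  dat <- generate_chimera_dataset(params_cd4, influx_cd4, des, seed = 16)
  fit <- fit_model(dat, "age_loss", influx_cd4, chains = 2,
                   iter_warmup = 150, iter_sampling = 150, seed = 3)
  s <- summary(fit)
  expect_true(all(c("median", "q2.5", "q97.5", "rhat", "ess") %in% names(s)))
  expect_true(all(is.finite(s$rhat)))
  expect_true(is.logical(fit$unreliable))
})
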