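# Independent oracles for the age-structured solver. Both deliberately avoid
# the characteristics representation used by the package: the first is a
# first-order upwind finite-difference discretisation of the transport PDE,
# the second an individual-based stochastic simulation.

# upwind finite-difference solver on a fixed age grid; returns total counts
# and Ki67+ fractions at the checkpoint times (run from an empty pool at
# t = 1 d)
fd_oracle <- function(p, influx, checkpoints, da = 0.1, cfl = 0.5) {
  dt <- cfl * da
  t_end <- max(checkpoints)
  a <- seq(0, t_end + da, by = da)
  n <- length(a)
  delta <- loss_rate(a, p)
  rho <- division_rate(a, p)
  beta <- p$beta
  up <- numeric(n); un <- numeric(n)
  out <- data.frame(t = checkpoints, total = NA_real_, ki67 = NA_real_)
  t <- 1
  next_cp <- 1
  while (next_cp <= length(checkpoints)) {
    th <- p$psi * sp_count_curve(t, influx)
    kap <- sp_ki67_curve(t, influx)
    # operator splitting: upwind advection in age, then RK2 reaction
    adv_p <- c(th * kap, up[-n])        # inflow boundary at a = 0
    adv_n <- c(th * (1 - kap), un[-n])
    up <- up - dt / da * (up - adv_p)
    un <- un - dt / da * (un - adv_n)
    fp <- function(up, un) 2 * rho * un + rho * up - (beta + delta) * up
    fn <- function(up, un) beta * up - (rho + delta) * un
    mp <- up + dt / 2 * fp(up, un)
    mn <- un + dt / 2 * fn(up, un)
    up <- pmax(up + dt * fp(mp, mn), 0)
    un <- pmax(un + dt * fn(mp, mn), 0)
    t <- t + dt
    if (t >= checkpoints[next_cp] - 1e-9) {
      sup <- which(a <= t - 1)
      w <- rep(da, length(sup)); w[1] <- da / 2; w[length(sup)] <- da / 2
      tot <- sum(w * (up[sup] + un[sup]))
      out$total[next_cp] <- tot
      out$ki67[next_cp] <- sum(w * up[sup]) / tot
      next_cp <- next_cp + 1
    }
  }
  out
}

# individual-based stochastic simulation with independent batches (each
# batch is an iid copy of the system at 1/n_batch influx); returns per-batch
# totals and Ki67+ counts at the checkpoints, from which Monte-Carlo means
# and standard errors of the aggregate are formed
stoch_oracle <- function(p, influx, checkpoints, dt = 0.1, n_batches = 10,
                         seed = 1) {
  set.seed(seed)
  t_end <- max(checkpoints)
  age <- numeric(0); kpos <- logical(0); batch <- integer(0)
  res_tot <- matrix(0, length(checkpoints), n_batches)
  res_kp <- matrix(0, length(checkpoints), n_batches)
  t <- 1
  next_cp <- 1
  beta <- p$beta
  while (t < t_end + 1e-9) {
    th <- p$psi * sp_count_curve(t, influx) * dt
    kap <- sp_ki67_curve(t, influx)
    n_new <- stats::rpois(n_batches, th / n_batches)
    if (sum(n_new) > 0) {
      age <- c(age, rep(0, sum(n_new)))
      kpos <- c(kpos, stats::runif(sum(n_new)) < kap)
      batch <- c(batch, rep(seq_len(n_batches), n_new))
    }
    if (length(age)) {
      u <- stats::runif(length(age))
      die <- u < loss_rate(age, p) * dt
      u2 <- stats::runif(length(age))
      divide <- !die & u2 < division_rate(age, p) * dt
      flip <- !die & !divide & kpos &
        (stats::runif(length(age)) < beta * dt)
      kpos[flip] <- FALSE
      if (any(divide)) {
        kpos[divide] <- TRUE            # mother re-enters as Ki67+ daughter
        age <- c(age[!die], age[divide])
        kpos <- c(kpos[!die], rep(TRUE, sum(divide)))
        batch <- c(batch[!die], batch[divide])
      } else {
        age <- age[!die]; kpos <- kpos[!die]; batch <- batch[!die]
      }
      age <- age + dt
    }
    t <- t + dt
    if (next_cp <= length(checkpoints) && t >= checkpoints[next_cp] - 1e-9) {
      for (b in seq_len(n_batches)) {
        sel <- batch == b
        res_tot[next_cp, b] <- sum(sel)
        res_kp[next_cp, b] <- sum(kpos[sel])
      }
      next_cp <- next_cp + 1
    }
  }
  list(total = res_tot, kpos = res_kp, checkpoints = checkpoints,
       n_batches = n_batches)
}

# exact leave-one-out elpd for the conjugate normal-mean model
# y_i ~ N(mu, sd_y), mu ~ N(0, sd_mu)
exact_loo_normal <- function(y, sd_y = 1, sd_mu = 10) {
  vapply(seq_along(y), function(i) {
    yy <- y[-i]
    post_prec <- 1 / sd_mu^2 + length(yy) / sd_y^2
    post_mean <- sum(yy) / sd_y^2 / post_prec
    stats::dnorm(y[i], post_mean, sqrt(sd_y^2 + 1 / post_prec), log = TRUE)
  }, 0)
}
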