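#' Prior specifications
#'
#' Priors are declared per parameter, on the natural scale, as one of
#' `lognormal(meanlog, sdlog)` (the default for all rates, sampled as a
#' normal on the log scale) or `fixed(value)` (a point mass: the parameter is
#' excluded from sampling). Weakly-informative defaults centre the rates on
#' biologically plausible scales: residence times of order 10-100 days,
#' interdivision times of order 6-36 months, export rate of order 0.1-1 per
#' SP thymocyte per day, and observation scales of order 0.1-0.5.
#'
#' @param variant model variant (see [kinetic_params()]).
#' @return named list of prior declarations, one per sampled parameter
#'   (kinetic parameters of the variant plus the three observation scales).
#' @export
default_priors <- function(variant) {
  ln <- function(m, s) list(dist = "lognormal", meanlog = m, sdlog = s)
  pri <- list(
    delta0 = ln(log(1 / 30), 0.7),
    r_delta = ln(log(0.006), 1),
    rho0 = ln(log(1 / 400), 1),
    r_rho = ln(log(0.003), 1),
    psi = ln(log(0.3), 1),
    gamma = ln(log(0.3), 1),
    mu = ln(log(1 / 30), 1),
    delta_mn = ln(log(1 / 60), 0.7),
    rho_mn = ln(log(1 / 400), 1),
    sigma_count = ln(log(0.25), 0.5),
    sigma_fd = ln(log(0.3), 0.5),
    sigma_ki67 = ln(log(0.3), 0.5))
  pri[c(.variant_parnames(variant), "sigma_count", "sigma_fd", "sigma_ki67")]
}

#' Fixed-value (point mass) prior
#' @param value the fixed value.
#' @export
prior_fixed <- function(value) list(dist = "fixed", value = value)

.prior_logdens <- function(theta_log, prior) {
  stats::dnorm(theta_log, prior$meanlog, prior$sdlog, log = TRUE)
}

## assemble kinetic_params + sigmas from a named natural-scale vector
.build_params <- function(vals, variant, template) {
  p <- template
  for (nm in intersect(names(vals), names(p))) p[[nm]] <- vals[[nm]]
  class(p) <- "kinetic_params"
  sig <- c(sigma_count = vals[["sigma_count"]], sigma_fd = vals[["sigma_fd"]],
           sigma_ki67 = vals[["sigma_ki67"]])
  list(p = p, sigmas = sig)
}

#' Fit a model variant to chimera data by MCMC
#'
#' Posterior sampling uses an adaptive random-walk Metropolis scheme: the
#' posterior mode is located first (Nelder-Mead on the log-parameter scale),
#' the proposal covariance is set from the Laplace approximation at the mode,
#' and a short warmup adapts the global proposal scale towards an acceptance
#' rate of ~0.3. Runs are reproducible given `seed` and the sampler
#' settings. Rates are sampled on the log scale with lognormal priors.
#'
#' @param data chimera observations (`chimera` schema data frame).
#' @param variant model variant (see [kinetic_params()]).
#' @param influx an [influx_descriptor()].
#' @param priors prior list as from [default_priors()]; entries may be
#'   replaced by [prior_fixed()] to pin a parameter.
#' @param chains,iter_warmup,iter_sampling sampler settings (defaults sized
#'   for routine checks; increase for replication runs).
#' @param seed integer seed; every chain derives its stream from it.
#' @param chimerism DP1 donor chimerism assumed in the observation map.
#' @param a_step cell-age quadrature step, days.
#' @param beta Ki67+ -> Ki67- rate, fixed by default at 1/3.5 per day.
#' @param neonatal_modifier optional [lambda0_hill()] carried into the model.
#' @return A `posterior_result`: `draws` (natural scale, with chain index),
#'   `pointwise` log-likelihood matrix (draws x observation streams),
#'   `diagnostics` (split rank-normalised R-hat, effective sample sizes,
#'   acceptance rates, MAP value) and an `unreliable` flag set when any
#'   R-hat exceeds 1.01.
#' @export
fit_model <- function(data, variant, influx, priors = NULL,
                      chains = 2, iter_warmup = 400, iter_sampling = 400,
                      seed = 1, chimerism = 0.85, a_step = 1,
                      beta = 1 / 3.5, neonatal_modifier = NULL) {
  if (is.null(priors)) priors <- default_priors(variant)
  need <- c(.variant_parnames(variant), "sigma_count", "sigma_fd", "sigma_ki67")
  if (!all(need %in% names(priors)))
    stop("priors missing for: ", paste(setdiff(need, names(priors)), collapse = ", "))
  fixed <- vapply(priors[need], function(x) identical(x$dist, "fixed"), TRUE)
  sampled <- need[!fixed]
  fixed_vals <- vapply(priors[need[fixed]], `[[`, 0, "value")

  template <- kinetic_params(
    variant,
    delta0 = 0.03, rho0 = 0.002, beta = beta,
    mu = if (variant == "rte_mn") 0.05 else 0,
    delta_mn = if (variant == "rte_mn") 0.02 else NA,
    rho_mn = if (variant == "rte_mn") 0.002 else NA,
    neonatal_modifier = neonatal_modifier)

  nat_vals <- function(theta_log) {
    v <- c(exp(theta_log), fixed_vals)
    v[need]
  }
  ctx <- if (variant %in% c("neutral", "age_loss", "age_division"))
    .chimera_ctx(data, influx, chimerism, a_step)
  log_post <- function(theta_log) {
    v <- nat_vals(theta_log)
    bp <- .build_params(v, variant, template)
    ll <- tryCatch(
      chimera_log_likelihood(bp$p, bp$sigmas, data, influx,
                             chimerism = chimerism, a_step = a_step,
                             ctx = ctx),
      error = function(e) NULL)
    if (is.null(ll) || any(!is.finite(ll)))
      return(list(lp = -Inf, pointwise = NULL))
    lp <- sum(ll) + sum(vapply(sampled, function(nm)
      .prior_logdens(theta_log[[nm]], priors[[nm]]), 0))
    list(lp = lp, pointwise = as.numeric(ll))
  }

  start <- vapply(priors[sampled], `[[`, 0, "meanlog")
  names(start) <- sampled
  .run_mh(log_post, start, chains = chains, iter_warmup = iter_warmup,
          iter_sampling = iter_sampling, seed = seed,
          meta = list(variant = variant, parnames = sampled,
                      fixed = fixed_vals, data_n = nrow(data),
                      chimerism = chimerism, a_step = a_step,
                      template = template, influx = influx, priors = priors))
}

## Generic adaptive random-walk Metropolis driver. log_post(theta) must
## return list(lp, pointwise). Used by fit_model() and the GFP fit.
.run_mh <- function(log_post, start, chains, iter_warmup, iter_sampling,
                    seed, meta = list()) {
  d <- length(start)
  ## Laplace proposal from a mode search
  obj <- function(th) {
    names(th) <- names(start)
    lp <- log_post(th)$lp
    if (!is.finite(lp)) 1e10 else -lp
  }
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  map <- opt$par
  H <- tryCatch(stats::optimHess(map, obj), error = function(e) NULL)
  cov_prop <- NULL
  if (!is.null(H)) {
    ev <- eigen(H, symmetric = TRUE)
    if (all(ev$values > 0)) cov_prop <- solve(H)
  }
  if (is.null(cov_prop)) cov_prop <- diag(0.05, d)
  L <- t(chol(cov_prop + diag(1e-10, d)))

  n_keep <- iter_sampling
  draws <- vector("list", chains)
  pointwise <- vector("list", chains)
  lps <- vector("list", chains)
  acc_rates <- numeric(chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + 7919L * ch)
    th <- map + as.numeric(L %*% stats::rnorm(d)) * 0.3
    names(th) <- names(start)
    cur <- log_post(th)
    tries <- 0
    while (!is.finite(cur$lp) && tries < 50) {
      th <- map + as.numeric(L %*% stats::rnorm(d)) * 0.1
      names(th) <- names(start)
      cur <- log_post(th); tries <- tries + 1
    }
    if (!is.finite(cur$lp)) stop("could not initialise chain ", ch)
    scale <- 2.38 / sqrt(d)
    n_iter <- iter_warmup + n_keep
    kd <- matrix(NA_real_, n_keep, d)
    kp <- NULL
    klp <- numeric(n_keep)
    acc <- 0; acc_win <- 0
    for (it in seq_len(n_iter)) {
      prop <- th + as.numeric(L %*% stats::rnorm(d)) * scale
      names(prop) <- names(start)
      cand <- log_post(prop)
      if (is.finite(cand$lp) &&
          log(stats::runif(1)) < cand$lp - cur$lp) {
        th <- prop; cur <- cand; acc <- acc + 1; acc_win <- acc_win + 1
      }
      if (it <= iter_warmup && it %% 25 == 0) {
        rate <- acc_win / 25
        scale <- scale * exp(0.8 * (rate - 0.3))
        acc_win <- 0
      }
      if (it > iter_warmup) {
        k <- it - iter_warmup
        kd[k, ] <- th
        klp[k] <- cur$lp
        if (!is.null(cur$pointwise)) {
          if (is.null(kp)) kp <- matrix(NA_real_, n_keep, length(cur$pointwise))
          kp[k, ] <- cur$pointwise
        }
      }
    }
    colnames(kd) <- names(start)
    draws[[ch]] <- kd
    pointwise[[ch]] <- kp
    lps[[ch]] <- klp
    acc_rates[ch] <- acc / n_iter
  }
  all_draws <- exp(do.call(rbind, draws))
  rhat <- vapply(seq_len(d), function(j)
    .split_rhat(sapply(draws, function(m) m[, j])), 0)
  ess <- vapply(seq_len(d), function(j)
    .ess_basic(sapply(draws, function(m) m[, j])), 0)
  names(rhat) <- names(ess) <- names(start)
  structure(list(
    draws = all_draws,
    chain = rep(seq_len(chains), each = n_keep),
    lp = unlist(lps),
    pointwise = if (!is.null(pointwise[[1]])) do.call(rbind, pointwise),
    map = exp(map),
    diagnostics = list(rhat = rhat, ess = ess, accept = acc_rates,
                       map_lp = -opt$value),
    unreliable = any(rhat > 1.01, na.rm = TRUE),
    seed = seed, meta = meta),
    class = "posterior_result")
}

#' @export
print.posterior_result <- function(x, ...) {
  cat("Posterior result (", x$meta$variant %||% "model", "): ",
      nrow(x$draws), " draws, ", max(x$chain), " chains\n", sep = "")
  print(summary(x))
  if (x$unreliable)
    cat("WARNING: convergence flagged (some R-hat > 1.01); treat as unreliable\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Posterior summaries
#' @param object a `posterior_result`.
#' @param ... unused.
#' @return data frame of median and central 95% interval per parameter,
#'   with R-hat and bulk ESS.
#' @export
summary.posterior_result <- function(object, ...) {
  q <- t(apply(object$draws, 2, stats::quantile,
               probs = c(0.5, 0.025, 0.975)))
  data.frame(parameter = colnames(object$draws),
             median = q[, 1], q2.5 = q[, 2], q97.5 = q[, 3],
             rhat = object$diagnostics$rhat,
             ess = object$diagnostics$ess,
             row.names = NULL)
}

## split rank-normalised R-hat (chains as columns)
.split_rhat <- function(m) {
  m <- as.matrix(m)
  n <- floor(nrow(m) / 2)
  halves <- cbind(m[seq_len(n), , drop = FALSE],
                  m[n + seq_len(n), , drop = FALSE])
  z <- matrix(stats::qnorm((rank(halves) - 0.375) / (length(halves) + 0.25)),
              nrow = n)
  mns <- colMeans(z)
  vars <- apply(z, 2, stats::var)
  B <- n * stats::var(mns)
  W <- mean(vars)
  if (W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

## crude bulk ESS: chains pooled after centring, initial positive sequence
.ess_basic <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  x <- sweep(m, 2, colMeans(m))
  rho_sum <- 0
  for (lag in seq_len(min(n - 2, 100))) {
    rho <- mean(vapply(seq_len(k), function(j)
      sum(x[seq_len(n - lag), j] * x[lag + seq_len(n - lag), j]) / n, 0)) /
      mean(apply(m, 2, stats::var))
    if (rho < 0.02) break
    rho_sum <- rho_sum + rho
  }
  n * k / (1 + 2 * rho_sum)
}
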