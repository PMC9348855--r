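#' Cohort survival curve under age-declining net loss
#'
#' A time-stamped cohort of naive cells, labelled at thymic export, decays
#' with a net loss rate (loss minus self-renewal) that declines
#' exponentially with cohort cell age `a`:
#' `lambda(a) = lambda0 * exp(-r_lambda * a)`, giving
#' \deqn{N(a) = N0 exp(-(lambda0/r_lambda)(1 - e^{-r_lambda a}))}
#' with the series-safe limit `N0 exp(-lambda0 a)` as `r_lambda -> 0`.
#'
#' @param a cohort cell age (time since labelling), days.
#' @param n0 cohort size at labelling, cells.
#' @param lambda0 net loss rate at cell age 0, day^-1.
#' @param r_lambda decline rate of the net loss with cell age, day^-1.
#' @return expected labelled cells at each `a`; non-increasing in `a`.
#' @export
cohort_curve <- function(a, n0, lambda0, r_lambda) {
  if (any(a < 0)) stop("cell age a must be non-negative")
  stopifnot(n0 > 0, lambda0 >= 0, r_lambda >= 0)
  x <- r_lambda * a
  ## 2nd-order expansion of (1 - exp(-x))/x for tiny x avoids 0/0
  f <- ifelse(x < 1e-6, a * (1 - x / 2 + x^2 / 6),
              (1 - exp(-x)) / pmax(r_lambda, .Machine$double.xmin))
  n0 * exp(-lambda0 * f)
}

#' Hierarchical fit of time-stamped cohort data
#'
#' Fits the net-loss cohort model to labelled-count timecourses with a
#' two-level hierarchy: `N0` varies by mouse or by group, and `lambda0` by
#' mouse or by group, each as lognormal deviates around a common
#' hyperdistribution (normal hyper-parameters on the log scale); `r_lambda`
#' and the lognormal observation scale are shared. The four hierarchy
#' variants share one interface so [loo_elpd()] and [pseudo_bma_weights()]
#' apply directly.
#'
#' Sampling is Metropolis-within-Gibbs: unit-level `log N0` is conjugate
#' normal given the rest and is Gibbs-updated; `lambda0` effects, hyper
#' scales, `r_lambda` and the observation scale take adaptive scalar
#' random-walk updates.
#'
#' @param data cohort observations (`cohort` schema: `mouse_id`,
#'   `group_age_days`, `time_since_label_days`, `labelled_count`).
#' @param variant hierarchy spec string: one of `"n0:mouse+lambda0:group"`
#'   (default), `"n0:mouse+lambda0:mouse"`, `"n0:group+lambda0:group"`,
#'   `"n0:group+lambda0:mouse"`.
#' @param chains,iter_warmup,iter_sampling sampler settings.
#' @param seed integer seed.
#' @param priors optional list overriding hyperprior settings (see source).
#' @return a `posterior_result`; unit-level parameters are named
#'   `logN0[unit]` / `lambda0[unit]`.
#' @export
fit_cohort_hierarchy <- function(data, variant = "n0:mouse+lambda0:group",
                                 chains = 2, iter_warmup = 800,
                                 iter_sampling = 800, seed = 1,
                                 priors = NULL) {
  spec <- .parse_hierarchy(variant)
  mice <- unique(data$mouse_id)
  groups <- sort(unique(data$group_age_days))
  if (length(groups) < 2 || length(mice) < 4 ||
      min(table(data$mouse_id)) < 3)
    stop("need >= 2 groups, >= 2 mice per group, >= 3 timepoints per mouse")
  mg <- data$group_age_days[match(mice, data$mouse_id)]
  if (spec$lambda0 == "mouse" && any(table(mg) < 2))
    warning("a group has one mouse; mouse-level lambda0 is weakly identified")

  i_mouse <- match(data$mouse_id, mice)
  i_group <- match(data$group_age_days, groups)
  g_of_mouse <- i_group[match(mice, data$mouse_id)]
  y <- log(data$labelled_count)
  a <- data$time_since_label_days
  n_obs <- length(y)

  n0_units <- if (spec$n0 == "mouse") length(mice) else length(groups)
  l_units <- if (spec$lambda0 == "mouse") length(mice) else length(groups)
  i_n0 <- if (spec$n0 == "mouse") i_mouse else i_group
  i_l <- if (spec$lambda0 == "mouse") i_mouse else i_group

  pri <- list(m_n0 = c(12.5, 3), tau_n0 = 1, m_l = c(log(0.04), 1.5),
              tau_l = 0.8, r_lambda = c(log(0.004), 1.5),
              sigma = c(log(0.2), 0.7))
  if (!is.null(priors)) pri[names(priors)] <- priors

  run_chain <- function(ch) {
    set.seed(seed + 7919L * ch)
    ## state
    st <- list(
      logN0 = rep(stats::median(y) + 0.2, n0_units) + stats::rnorm(n0_units, 0, 0.2),
      logl = rep(pri$m_l[1], l_units) + stats::rnorm(l_units, 0, 0.2),
      logr = pri$r_lambda[1] + stats::rnorm(1, 0, 0.2),
      logsig = pri$sigma[1],
      m_n0 = stats::median(y), t_n0 = 0.5,
      m_l = pri$m_l[1], t_l = 0.3)
    curve_log <- function(st) {
      l0 <- exp(st$logl)[i_l]
      r <- exp(st$logr)
      x <- r * a
      f <- ifelse(x < 1e-6, a * (1 - x / 2), (1 - exp(-x)) / r)
      st$logN0[i_n0] - l0 * f
    }
    loglik_vec <- function(st)
      stats::dnorm(y, curve_log(st), exp(st$logsig), log = TRUE)
    logpost_rest <- function(st) {
      sum(loglik_vec(st)) +
        sum(stats::dnorm(st$logl, st$m_l, st$t_l, log = TRUE)) +
        stats::dnorm(st$m_l, pri$m_l[1], pri$m_l[2], log = TRUE) +
        stats::dnorm(log(st$t_l), log(pri$tau_l), 0.7, log = TRUE) +
        stats::dnorm(st$logr, pri$r_lambda[1], pri$r_lambda[2], log = TRUE) +
        stats::dnorm(st$logsig, pri$sigma[1], pri$sigma[2], log = TRUE) +
        stats::dnorm(log(st$t_n0), log(pri$tau_n0), 0.7, log = TRUE)
    }
    scales <- list(logl = rep(0.15, l_units), joint = rep(0.3, l_units),
                   logr = 0.2, logsig = 0.12,
                   t_l = 0.25, t_n0 = 0.25, ridge = 0.4)
    acc <- list(logl = rep(0, l_units), joint = rep(0, l_units),
                logr = 0, logsig = 0, t_l = 0, t_n0 = 0, ridge = 0)
    n_iter <- iter_warmup + iter_sampling
    pn <- c(sprintf("logN0[%s]",
                    if (spec$n0 == "mouse") mice else paste0("g", groups)),
            sprintf("lambda0[%s]",
                    if (spec$lambda0 == "mouse") mice else paste0("g", groups)),
            "r_lambda", "sigma", "mu_N0", "tau_N0", "mu_l0", "tau_l0")
    kd <- matrix(NA_real_, iter_sampling, length(pn),
                 dimnames = list(NULL, pn))
    kp <- matrix(NA_real_, iter_sampling, n_obs)
    klp <- numeric(iter_sampling)

    for (it in seq_len(n_iter)) {
      ## --- Gibbs: unit-level logN0 (conjugate normal) ---
      sig2 <- exp(2 * st$logsig)
      l0 <- exp(st$logl)[i_l]; r <- exp(st$logr)
      x <- r * a
      f <- ifelse(x < 1e-6, a * (1 - x / 2), (1 - exp(-x)) / r)
      resid0 <- y + l0 * f            # y - (curve - logN0 term)
      for (u in seq_len(n0_units)) {
        sel <- i_n0 == u
        nu <- sum(sel)
        prec <- nu / sig2 + 1 / st$t_n0^2
        mean_u <- (sum(resid0[sel]) / sig2 + st$m_n0 / st$t_n0^2) / prec
        st$logN0[u] <- stats::rnorm(1, mean_u, sqrt(1 / prec))
      }
      ## Gibbs: hypermean of logN0 (flat-ish prior N(m0, 3))
      prec_m <- n0_units / st$t_n0^2 + 1 / pri$m_n0[2]^2
      mean_m <- (sum(st$logN0) / st$t_n0^2 + pri$m_n0[1] / pri$m_n0[2]^2) / prec_m
      st$m_n0 <- stats::rnorm(1, mean_m, sqrt(1 / prec_m))
      ## MH: hyper-sd of logN0
      prop <- st; prop$t_n0 <- st$t_n0 * exp(stats::rnorm(1, 0, scales$t_n0))
      lr <- sum(stats::dnorm(prop$logN0, prop$m_n0, prop$t_n0, log = TRUE)) -
        sum(stats::dnorm(st$logN0, st$m_n0, st$t_n0, log = TRUE)) +
        stats::dnorm(log(prop$t_n0), log(pri$tau_n0), 0.7, log = TRUE) -
        stats::dnorm(log(st$t_n0), log(pri$tau_n0), 0.7, log = TRUE) +
        log(prop$t_n0) - log(st$t_n0)   # jacobian of log-scale walk
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        st$t_n0 <- prop$t_n0; acc$t_n0 <- acc$t_n0 + 1
      }
      ## --- MH: lambda0 units (likelihood factorises over units) ---
      for (u in seq_len(l_units)) {
        sel <- i_l == u
        cur_ll <- sum(stats::dnorm(y[sel],
                                   st$logN0[i_n0[sel]] - exp(st$logl[u]) * f[sel],
                                   exp(st$logsig), log = TRUE)) +
          stats::dnorm(st$logl[u], st$m_l, st$t_l, log = TRUE)
        cand <- st$logl[u] + stats::rnorm(1, 0, scales$logl[u])
        cand_ll <- sum(stats::dnorm(y[sel],
                                    st$logN0[i_n0[sel]] - exp(cand) * f[sel],
                                    exp(st$logsig), log = TRUE)) +
          stats::dnorm(cand, st$m_l, st$t_l, log = TRUE)
        if (is.finite(cand_ll) && log(stats::runif(1)) < cand_ll - cur_ll) {
          st$logl[u] <- cand; acc$logl[u] <- acc$logl[u] + 1
        }
        ## joint slope-intercept move: shift lambda0[u] and compensate the
        ## intercepts of the affected N0 units so each curve is pinned at
        ## the median sampling age (lambda0 and N0 are strongly negatively
        ## correlated along that direction)
        A_ref <- stats::median(a[sel])
        fr <- (1 - exp(-exp(st$logr) * A_ref)) / exp(st$logr)
        cand <- st$logl[u] + stats::rnorm(1, 0, scales$joint[u])
        dshift <- (exp(cand) - exp(st$logl[u])) * fr
        units_n0 <- unique(i_n0[sel])
        prop_N0 <- st$logN0
        prop_N0[units_n0] <- prop_N0[units_n0] + dshift
        cur_j <- sum(stats::dnorm(y[sel],
                                  st$logN0[i_n0[sel]] - exp(st$logl[u]) * f[sel],
                                  exp(st$logsig), log = TRUE)) +
          stats::dnorm(st$logl[u], st$m_l, st$t_l, log = TRUE) +
          sum(stats::dnorm(st$logN0[units_n0], st$m_n0, st$t_n0, log = TRUE))
        cand_j <- sum(stats::dnorm(y[sel],
                                   prop_N0[i_n0[sel]] - exp(cand) * f[sel],
                                   exp(st$logsig), log = TRUE)) +
          stats::dnorm(cand, st$m_l, st$t_l, log = TRUE) +
          sum(stats::dnorm(prop_N0[units_n0], st$m_n0, st$t_n0, log = TRUE))
        if (is.finite(cand_j) && log(stats::runif(1)) < cand_j - cur_j) {
          st$logl[u] <- cand
          st$logN0 <- prop_N0
          acc$joint[u] <- acc$joint[u] + 1
        }
      }
      ## Gibbs: hypermean of log lambda0
      prec_l <- l_units / st$t_l^2 + 1 / pri$m_l[2]^2
      mean_l <- (sum(st$logl) / st$t_l^2 + pri$m_l[1] / pri$m_l[2]^2) / prec_l
      st$m_l <- stats::rnorm(1, mean_l, sqrt(1 / prec_l))
      ## MH: hyper-sd of log lambda0
      prop_t <- st$t_l * exp(stats::rnorm(1, 0, scales$t_l))
      lr <- sum(stats::dnorm(st$logl, st$m_l, prop_t, log = TRUE)) -
        sum(stats::dnorm(st$logl, st$m_l, st$t_l, log = TRUE)) +
        stats::dnorm(log(prop_t), log(pri$tau_l), 0.7, log = TRUE) -
        stats::dnorm(log(st$t_l), log(pri$tau_l), 0.7, log = TRUE) +
        log(prop_t) - log(st$t_l)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        st$t_l <- prop_t; acc$t_l <- acc$t_l + 1
      }
      ## --- joint ridge move: r_lambda with compensating lambda0 shift ---
      ## lambda0 and r_lambda trade off along curves of equal cumulative
      ## loss; proposing them together (keeping the integrated loss at a
      ## reference cohort age fixed) decorrelates the walk.
      {
        A_ref <- stats::median(a)
        fint <- function(lr) { r <- exp(lr); (1 - exp(-r * A_ref)) / r }
        cand_r <- st$logr + stats::rnorm(1, 0, scales$ridge)
        prop <- st
        prop$logr <- cand_r
        prop$logl <- st$logl + log(fint(st$logr) / fint(cand_r))
        ## shift hypermean along with the block so the hyperprior tracks
        prop$m_l <- st$m_l + log(fint(st$logr) / fint(cand_r))
        lr <- logpost_rest(prop) - logpost_rest(st)
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          st <- prop; acc$ridge <- acc$ridge + 1
        }
      }
      ## --- MH: r_lambda and sigma (global) ---
      for (nm in c("logr", "logsig")) {
        prop <- st
        prop[[nm]] <- st[[nm]] + stats::rnorm(1, 0, scales[[if (nm == "logr") "logr" else "logsig"]])
        lr <- logpost_rest(prop) - logpost_rest(st)
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          st <- prop
          if (nm == "logr") acc$logr <- acc$logr + 1 else acc$logsig <- acc$logsig + 1
        }
      }
      ## adapt scalar scales during warmup
      if (it <= iter_warmup && it %% 50 == 0) {
        tune <- function(s, a) s * exp(0.8 * (a / 50 - 0.35))
        scales$logl <- mapply(tune, scales$logl, acc$logl)
        scales$joint <- mapply(tune, scales$joint, acc$joint)
        scales$logr <- tune(scales$logr, acc$logr)
        scales$logsig <- tune(scales$logsig, acc$logsig)
        scales$t_l <- tune(scales$t_l, acc$t_l)
        scales$t_n0 <- tune(scales$t_n0, acc$t_n0)
        scales$ridge <- tune(scales$ridge, acc$ridge)
        acc <- list(logl = rep(0, l_units), joint = rep(0, l_units),
                    logr = 0, logsig = 0, t_l = 0, t_n0 = 0, ridge = 0)
      }
      if (it > iter_warmup) {
        k <- it - iter_warmup
        kd[k, ] <- c(st$logN0, exp(st$logl), exp(st$logr), exp(st$logsig),
                     st$m_n0, st$t_n0, st$m_l, st$t_l)
        pw <- loglik_vec(st)
        kp[k, ] <- pw
        klp[k] <- sum(pw)
      }
    }
    list(draws = kd, pointwise = kp, lp = klp)
  }

  res <- lapply(seq_len(chains), run_chain)
  all_draws <- do.call(rbind, lapply(res, `[[`, "draws"))
  dlog <- all_draws
  dlog[, grep("^lambda0|^r_lambda|^sigma|^tau", colnames(dlog))] <-
    log(dlog[, grep("^lambda0|^r_lambda|^sigma|^tau", colnames(dlog))])
  rhat <- vapply(seq_len(ncol(all_draws)), function(j)
    .split_rhat(matrix(dlog[, j], ncol = chains)), 0)
  names(rhat) <- colnames(all_draws)
  structure(list(
    draws = all_draws,
    chain = rep(seq_len(chains), each = iter_sampling),
    lp = unlist(lapply(res, `[[`, "lp")),
    pointwise = do.call(rbind, lapply(res, `[[`, "pointwise")),
    diagnostics = list(rhat = rhat, ess = rep(NA_real_, length(rhat))),
    unreliable = any(rhat > 1.01, na.rm = TRUE),
    seed = seed,
    meta = list(variant = variant, mice = mice, groups = groups,
                spec = spec, data_n = n_obs)),
    class = "posterior_result")
}

.parse_hierarchy <- function(variant) {
  v <- tolower(gsub(" ", "", variant))
  parts <- strsplit(v, "+", fixed = TRUE)[[1]]
  get <- function(key) {
    p <- grep(paste0("^", key, ":"), parts, value = TRUE)
    if (length(p) != 1) stop("variant must be 'n0:<mouse|group>+lambda0:<mouse|group>'")
    lvl <- sub(paste0(key, ":"), "", p)
    if (!lvl %in% c("mouse", "group")) stop("hierarchy level must be mouse or group")
    lvl
  }
  list(n0 = get("n0"), lambda0 = get("lambda0"))
}

#' Fit the Hill description of lambda0 versus mouse age
#'
#' Weighted least-squares fit of
#' `lambda0(t) = lambda_min + (lambda_max - lambda_min)/(1 + (t/t_half)^h)`
#' to group-level `lambda0` estimates; monotone non-increase is guaranteed
#' by the functional form regardless of scatter in the inputs.
#'
#' @param lambda0 group-level estimates, day^-1.
#' @param age group host ages, days.
#' @param se optional standard errors (weights 1/se^2).
#' @return a [lambda0_hill()] object; attributes `fitted` and
#'   `large_residuals` record the fit quality.
#' @export
fit_lambda0_hill <- function(lambda0, age, se = NULL) {
  stopifnot(length(lambda0) == length(age))
  if (length(unique(age)) < 3) stop("need >= 3 distinct group ages")
  w <- if (is.null(se)) rep(1, length(age)) else 1 / se^2
  if (diff(range(lambda0)) <= 1e-8 * max(abs(lambda0))) {
    out <- lambda0_hill(mean(lambda0), mean(lambda0),
                        stats::median(age), 1)
    attr(out, "fitted") <- data.frame(age = age, lambda0 = lambda0,
                                      fit = mean(lambda0))
    attr(out, "large_residuals") <- FALSE
    return(out)
  }
  df <- data.frame(l = lambda0, t = age, w = w)
  start <- list(lmin = max(min(lambda0) * 0.9, 1e-6),
                lmax = max(lambda0) * 1.05,
                th = stats::median(age), h = 4)
  fit <- try(minpack.lm::nlsLM(
    l ~ lmin + (lmax - lmin) / (1 + (t / th)^h),
    data = df, start = start, weights = w,
    lower = c(0, 1e-8, 1, 0.2), upper = c(Inf, Inf, 600, 40),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("Hill fit failed to converge: ", attr(fit, "condition")$message)
  cf <- stats::coef(fit)
  lmin <- min(cf[["lmin"]], cf[["lmax"]]); lmax <- max(cf[["lmin"]], cf[["lmax"]])
  out <- lambda0_hill(lmin, lmax, cf[["th"]], cf[["h"]])
  pred <- lambda0_at(out, age)
  res <- (lambda0 - pred) / pmax(pred, 1e-12)
  attr(out, "fitted") <- data.frame(age = age, lambda0 = lambda0, fit = pred)
  attr(out, "large_residuals") <- any(abs(res) > 0.5)
  out
}
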