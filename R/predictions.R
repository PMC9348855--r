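#' GFP expression map for Rag-GFP reporters
#'
#' RTE lose GFP positivity with first-order kinetics after thymic export, so
#' a cell of post-thymic age `a` is GFP+ with probability `exp(-a/T_gfp)`.
#' The probability is 1 at export and integrates to `T_gfp` over cell age
#' (the mean duration of GFP expression).
#'
#' @param t_gfp mean duration of GFP positivity after export, days (> 0).
#' @export
gfp_map <- function(t_gfp) {
  stopifnot(is.numeric(t_gfp), t_gfp > 0)
  structure(list(t_gfp = t_gfp), class = "gfp_map")
}

.p_gfp <- function(a, gfp) exp(-a / gfp$t_gfp)

#' Co-transfer setup
#'
#' Describes the RTE/MN co-transfer experiment: GFP+ (RTE-enriched) cells
#' from young reporter donors co-transferred in equal numbers with GFP-
#' (mature naive) cells from older donors into adult congenic recipients.
#'
#' @param rte_donor_age_range mouse ages of RTE donors, days (default 5-9
#'   weeks).
#' @param mn_donor_age_range mouse ages of MN donors, days (default >= 14
#'   weeks, capped at 20).
#' @param horizon follow-up time after transfer, days.
#' @export
cotransfer_setup <- function(rte_donor_age_range = c(35, 63),
                             mn_donor_age_range = c(98, 140),
                             horizon = 84) {
  stopifnot(horizon > 0)
  structure(list(rte_donor_age_range = rte_donor_age_range,
                 mn_donor_age_range = mn_donor_age_range,
                 initial_ratio = 1, horizon = horizon),
            class = "cotransfer_setup")
}

## donor-age-averaged cell-age distribution, weighted by GFP+ or GFP- prob
.transfer_pool <- function(p, influx, donor_ages, gfp, positive, a_step) {
  a_grid <- seq(0, max(donor_ages) - 1, by = a_step)
  kern <- .age_kernel(p, a_grid)
  w <- numeric(length(a_grid))
  for (td in donor_ages) {
    ii <- which(a_grid <= td - 1)
    t0 <- td - a_grid[ii]
    cs <- .modifier_scale(p$neonatal_modifier, t0)
    u <- p$psi * sp_count_curve(t0, influx) *
      exp(kern$P[ii] - cs * kern$D[ii])
    w[ii] <- w[ii] + u
  }
  pg <- .p_gfp(a_grid, gfp)
  w <- w * if (positive) pg else (1 - pg)
  if (sum(w) <= 0) stop("degenerate transfer pool (empty age support)")
  list(a = a_grid, w = w / sum(w))
}

#' Simulate the RTE/MN co-transfer experiment
#'
#' Transferred pools are built from the model's cell-age distributions in
#' the donor mice: the RTE pool weights ages by the GFP+ probability and the
#' MN pool by its complement (a probabilistic version of the GFP gate; set
#' `hard_cutoff_age` for a sharp age threshold instead). Both pools then
#' evolve in the adult recipient without influx under the model's loss and
#' division rates; the reported RTE:MN ratio is normalised to 1 at transfer
#' and is independent of the (equal) number of cells transferred.
#'
#' @param p a [kinetic_params()] object (point estimate).
#' @param influx an [influx_descriptor()].
#' @param setup a [cotransfer_setup()].
#' @param gfp a [gfp_map()].
#' @param draws optional matrix of posterior draws (columns named like
#'   kinetic parameters); when supplied the 2.5/50/97.5 percentile envelope
#'   over draws is returned.
#' @param hard_cutoff_age optional sharp RTE definition: cells younger than
#'   this age count as RTE, older as MN.
#' @param a_step age-grid resolution, days.
#' @return data frame `t_days`, `ratio` (and `lo`, `hi` when `draws` given).
#' @export
simulate_cotransfer <- function(p, influx, setup = cotransfer_setup(),
                                gfp = gfp_map(11), draws = NULL,
                                hard_cutoff_age = NULL, a_step = 0.5) {
  tau <- seq(0, setup$horizon, by = 1)
  one_run <- function(p) {
    rte_ages <- seq(setup$rte_donor_age_range[1], setup$rte_donor_age_range[2],
                    by = 7)
    mn_ages <- seq(setup$mn_donor_age_range[1], setup$mn_donor_age_range[2],
                   by = 7)
    if (is.null(hard_cutoff_age)) {
      pool_r <- .transfer_pool(p, influx, rte_ages, gfp, TRUE, a_step)
      pool_m <- .transfer_pool(p, influx, mn_ages, gfp, FALSE, a_step)
    } else {
      pool_r <- .transfer_pool(p, influx, rte_ages, gfp_map(1e9), TRUE, a_step)
      pool_m <- .transfer_pool(p, influx, mn_ages, gfp_map(1e9), TRUE, a_step)
      pool_r$w <- pool_r$w * (pool_r$a < hard_cutoff_age)
      pool_m$w <- pool_m$w * (pool_m$a >= hard_cutoff_age)
      if (sum(pool_r$w) <= 0 || sum(pool_m$w) <= 0)
        stop("degenerate transfer pool (empty age support)")
      pool_r$w <- pool_r$w / sum(pool_r$w)
      pool_m$w <- pool_m$w / sum(pool_m$w)
    }
    surv_frac <- function(pool) {
      ## survival of a cell of age a over tau: exp((P-D)(a+tau) - (P-D)(a))
      amax <- max(pool$a) + max(tau)
      kern <- .age_kernel(p, seq(0, amax, by = a_step))
      G <- kern$P - kern$D
      gi <- stats::approxfun(kern$a, G)
      vapply(tau, function(s) sum(pool$w * exp(gi(pool$a + s) - gi(pool$a))), 0)
    }
    surv_frac(pool_r) / surv_frac(pool_m)
  }
  if (is.null(draws)) return(data.frame(t_days = tau, ratio = one_run(p)))
  runs <- apply(draws, 1, function(v) {
    pp <- p
    for (nm in intersect(colnames(draws), names(pp))) pp[[nm]] <- v[[nm]]
    class(pp) <- "kinetic_params"
    one_run(pp)
  })
  qs <- apply(runs, 1, stats::quantile, probs = c(0.025, 0.5, 0.975))
  data.frame(t_days = tau, ratio = qs[2, ], lo = qs[1, ], hi = qs[3, ])
}

#' Predicted GFP+ reporter fractions from an age-resolved trajectory
#'
#' Integrates the Ki67-split age densities against the GFP+ probability to
#' predict the total GFP+ count and the percentages of the naive pool that
#' are GFP+Ki67+ and GFP+Ki67-.
#'
#' @param traj an age-resolved `population_trajectory`.
#' @param gfp a [gfp_map()].
#' @return data frame `t_days`, `gfp_count`, `pct_gfp_ki67pos`,
#'   `pct_gfp_ki67neg` (percentages of the total naive pool).
#' @export
predict_reporter_fractions <- function(traj, gfp) {
  if (!isTRUE(traj$age_resolved))
    stop("reporter mapping needs an age-resolved trajectory")
  pg <- .p_gfp(traj$a, gfp)
  out <- data.frame(t_days = traj$t, gfp_count = NA_real_,
                    pct_gfp_ki67pos = NA_real_, pct_gfp_ki67neg = NA_real_)
  for (j in seq_along(traj$t)) {
    front <- traj$t[j] - traj$influx_from
    up <- traj$u_pos[, j]; un <- traj$u_neg[, j]
    if (traj$has_init) { up <- up + traj$u_pos0[, j]; un <- un + traj$u_neg0[, j] }
    tot <- .trapz_front(traj$a, up + un, front)
    gp <- .trapz_front(traj$a, up * pg, front)
    gn <- .trapz_front(traj$a, un * pg, front)
    out$gfp_count[j] <- gp + gn
    if (tot > 0) {
      out$pct_gfp_ki67pos[j] <- 100 * gp / tot
      out$pct_gfp_ki67neg[j] <- 100 * gn / tot
    }
  }
  out
}

#' Estimate the mean duration of GFP expression
#'
#' With the kinetic parameters held fixed at their fitted values, the only
#' new parameter linking the model to Rag-GFP reporter data is `T_gfp`. It
#' is estimated from the GFP+ count timecourse by a one-dimensional grid
#' posterior on `log T_gfp` (lognormal count error with its scale
#' marginalised under a Jeffreys prior), which is deterministic and robust.
#'
#' @param reporter data frame in the `reporter` schema (needs
#'   `mouse_age_days` and `gfp_count`).
#' @param p fixed [kinetic_params()].
#' @param influx an [influx_descriptor()].
#' @param t_gfp_grid grid of candidate durations, days.
#' @param prior_meanlog,prior_sdlog lognormal prior on `T_gfp` (default:
#'   broad around 10 days).
#' @param a_step age-grid resolution for the trajectory.
#' @return list with `median`, `q2.5`, `q97.5`, the grid `posterior`, and
#'   `flat_likelihood` flag (wide-interval warning).
#' @export
estimate_gfp_duration <- function(reporter, p, influx,
                                  t_gfp_grid = exp(seq(log(2), log(60),
                                                       length.out = 121)),
                                  prior_meanlog = log(10), prior_sdlog = 1,
                                  a_step = 0.5) {
  ages <- sort(unique(reporter$mouse_age_days))
  traj <- solve_age_structured(p, influx, t_span = c(1, max(ages)),
                               t_out = ages, a_step = a_step)
  y <- log(reporter$gfp_count)
  n <- length(y)
  loglik <- vapply(t_gfp_grid, function(tg) {
    pr <- predict_reporter_fractions(traj, gfp_map(tg))
    mu <- log(pr$gfp_count[match(reporter$mouse_age_days, pr$t_days)])
    rss <- sum((y - mu)^2)
    -n / 2 * log(rss)        # sigma marginalised, Jeffreys prior
  }, 0)
  logpost <- loglik + stats::dnorm(log(t_gfp_grid), prior_meanlog,
                                   prior_sdlog, log = TRUE)
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  cdf <- cumsum(w)
  qv <- function(q) t_gfp_grid[which.max(cdf >= q)]
  flat <- diff(range(logpost)) < 2
  if (flat) warning("GFP duration weakly identified (flat likelihood)")
  list(median = qv(0.5), q2.5 = qv(0.025), q97.5 = qv(0.975),
       posterior = data.frame(t_gfp = t_gfp_grid, weight = w),
       flat_likelihood = flat)
}

#' Extrapolate a fitted model back to birth
#'
#' Runs the age-structured model from a near-empty pool at mouse age 1 day,
#' so the neonatal trajectory is generated entirely by thymic influx and the
#' adult-fitted kinetics. For CD8, a [lambda0_hill()] modifier raises the
#' baseline loss rate inherited by cohorts exported early in life; supplying
#' a modifier for CD4 is rejected (no neonatal effect is supported) unless
#' `force = TRUE`.
#'
#' @param p a [kinetic_params()] object.
#' @param influx an [influx_descriptor()] valid from t = 1 d.
#' @param subset `"CD4"` or `"CD8"`.
#' @param neonatal_modifier optional [lambda0_hill()].
#' @param t_end end of the run, days.
#' @param force allow a CD4 modifier.
#' @param ... passed to [solve_age_structured()].
#' @return an age-resolved `population_trajectory` starting at t = 1 d.
#' @export
extrapolate_to_birth <- function(p, influx, subset = c("CD4", "CD8"),
                                 neonatal_modifier = NULL, t_end = 300,
                                 force = FALSE, ...) {
  subset <- match.arg(subset)
  if (!is.null(neonatal_modifier)) {
    if (subset == "CD4" && !force)
      stop("no neonatal modifier for CD4 (no neonatal effect); use force = TRUE to override")
    p$neonatal_modifier <- neonatal_modifier
  }
  solve_age_structured(p, influx, t_span = c(1, t_end), ...)
}

#' Mean residence time of mature naive cells
#'
#' Averages a per-cell residence-time measure over the model's cell-age
#' distribution at host age `t`, restricted to cells older than `a_min`
#' (mature naive cells). Two definitions are available:
#' \describe{
#'   \item{`"expected"` (default)}{the expected remaining residence time of
#'     a cell of age `a`, `int_0^H exp(-int_0^s delta(a+x) dx) ds`, with the
#'     integral capped at `horizon` days (default 3 years, the maximal
#'     attainable mouse lifespan). Because the loss rate declines with cell
#'     age, the uncapped integral does not converge; the cap bounds
#'     residence by the remaining attainable lifespan.}
#'   \item{`"instantaneous"`}{the inverse instantaneous loss rate
#'     `1/delta(a)`. For a constant loss rate both definitions reduce to
#'     `1/delta`.}
#' }
#' Cohorts inherit their entry-time baseline when a neonatal modifier is
#' present in `p`.
#'
#' @param p a [kinetic_params()] object (age-structured family or neutral).
#' @param influx an [influx_descriptor()].
#' @param t host age, days.
#' @param a_min minimum cell age included, days (must be < `t`).
#' @param definition `"expected"` or `"instantaneous"`.
#' @param horizon cap on the remaining-lifetime integral, days.
#' @param a_step age-grid resolution, days.
#' @return mean residence time in days.
#' @export
mean_mn_residence_time <- function(p, influx, t, a_min = 21,
                                   definition = c("expected", "instantaneous"),
                                   horizon = 3 * 365, a_step = 0.25) {
  definition <- match.arg(definition)
  if (a_min >= t - 1) stop("empty age window: a_min must be < t - 1")
  a <- seq(a_min, t - 1, by = a_step)
  t0 <- t - a
  cs <- .modifier_scale(p$neonatal_modifier, t0)
  kern <- .age_kernel(p, a)
  ## age distribution of the pool (total over Ki67 states)
  u <- p$psi * sp_count_curve(t0, influx) * exp(kern$P - cs * kern$D)
  delta_a <- p$delta0 * cs * exp(-p$r_delta * a)
  if (definition == "instantaneous") {
    res <- 1 / delta_a
  } else if (p$r_delta == 0) {
    res <- (1 - exp(-delta_a * horizon)) / delta_a
  } else {
    s <- seq(0, horizon, by = min(1, horizon / 400))
    ws <- .trapz_weights(s)
    decay <- (1 - exp(-p$r_delta * s)) / p$r_delta
    ## E(a) = int exp(-delta(a) * (1 - e^{-r s})/r) ds, vectorised over a
    res <- as.numeric(exp(-outer(delta_a, decay)) %*% ws)
  }
  sum(u * res) / sum(u)
}

#' Simulate thymic lobe transplantation
#'
#' Hyperthymic mice carry `n_lobes` extra transplanted thymic lobes (2 lobes
#' = 1 extra thymus), scaling thymic export by `1 + n_lobes/2` from
#' `graft_age` onward. Returns the naive pool size relative to an
#' unperturbed control, plus the excess expressed as days of normal export
#' (the basis of the "accumulated export of the previous ~3 weeks"
#' interpretation).
#'
#' @param p a [kinetic_params()] object.
#' @param influx an [influx_descriptor()].
#' @param n_lobes number of transplanted lobes (>= 0).
#' @param graft_age host age at transplantation, days.
#' @param horizon follow-up, days.
#' @param a_step age-grid resolution, days.
#' @return data frame `t_days`, `fold_change`, `excess_cells`,
#'   `export_equiv_days` (excess cells per extra daily export).
#' @export
simulate_thymus_grafts <- function(p, influx, n_lobes, graft_age = 56,
                                   horizon = 56, a_step = 0.5) {
  stopifnot(n_lobes >= 0)
  boost <- n_lobes / 2
  t_out <- seq(graft_age, graft_age + horizon, by = 1)
  a_grid <- seq(0, max(t_out) - 1, by = a_step)
  kern <- .age_kernel(p, a_grid)
  fold <- excess <- eqd <- numeric(length(t_out))
  for (j in seq_along(t_out)) {
    t <- t_out[j]
    ii <- which(a_grid <= t - 1)
    a <- a_grid[ii]; t0 <- t - a
    cs <- .modifier_scale(p$neonatal_modifier, t0)
    u <- p$psi * sp_count_curve(t0, influx) * exp(kern$P[ii] - cs * kern$D[ii])
    base <- .trapz_front(a, u, t - 1)
    extra <- .trapz_front(a, u * (t0 >= graft_age) * boost, t - 1)
    fold[j] <- (base + extra) / base
    excess[j] <- extra
    eqd[j] <- if (boost > 0)
      extra / (boost * p$psi * sp_count_curve(t, influx)) else 0
  }
  data.frame(t_days = t_out, fold_change = fold, excess_cells = excess,
             export_equiv_days = eqd)
}
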