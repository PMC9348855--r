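#' Solve a compartmental model variant
#'
#' Integrates the Ki67-structured ODE system for the homogeneous (`neutral`),
#' density-dependent (`dd_loss`, `dd_division`) and RTE/mature-naive
#' (`rte_mn`) variants, with host/donor lineage bookkeeping after BMT.
#' Division bookkeeping follows the binary Ki67 model: a dividing Ki67- cell
#' contributes +2 Ki67+ and -1 Ki67-, a dividing Ki67+ cell net +1 Ki67+.
#' Density-dependent variants modulate the loss rate as
#' `delta0 (N/n_ref)^gamma` or the division rate as `rho0 (n_ref/N)^gamma`
#' where `N` is the whole naive pool.
#'
#' @inheritParams solve_age_structured
#' @param atol,rtol integrator tolerances passed to [deSolve::ode()].
#' @return A `population_trajectory` with `age_resolved = FALSE`, holding
#'   per-compartment counts (`counts`: columns split by lineage, Ki67 state
#'   and, for `rte_mn`, maturation stage).
#' @export
solve_compartmental <- function(p, influx, t_span, t_out = NULL,
                                t_bmt = NULL, bmt_delay = 0, init = NULL,
                                atol = 1e-4, rtol = 1e-8) {
  if (p$variant %in% c("age_loss", "age_division"))
    stop("age-structured variants require solve_age_structured()")
  if (is.null(t_out)) t_out <- seq(t_span[1], t_span[2], length.out = 201)
  t_out <- sort(unique(t_out))
  rte <- p$variant == "rte_mn"
  ## state: host/donor x Ki67 +/- (x RTE/MN for rte_mn)
  nm <- if (rte)
    c("rp_h", "rn_h", "mp_h", "mn_h", "rp_d", "rn_d", "mp_d", "mn_d")
  else c("p_h", "n_h", "p_d", "n_d")
  y0 <- stats::setNames(numeric(length(nm)), nm)
  if (!is.null(init) && init$N0 > 0) {
    if (rte) {
      y0["mp_h"] <- init$N0 * init$ki67; y0["mn_h"] <- init$N0 * (1 - init$ki67)
    } else {
      y0["p_h"] <- init$N0 * init$ki67; y0["n_h"] <- init$N0 * (1 - init$ki67)
    }
  }
  t_switch <- if (is.null(t_bmt)) Inf else t_bmt + bmt_delay

  deriv <- function(t, y, parms) {
    th <- p$psi * sp_count_curve(max(t, 1), influx)
    kap <- sp_ki67_curve(max(t, 1), influx)
    phi_p <- th * kap
    phi_n <- th * (1 - kap)
    donor_in <- t >= t_switch
    N <- sum(y)
    if (p$variant == "dd_loss") {
      delta <- p$delta0 * (max(N, 1) / p$n_ref)^p$gamma; rho <- p$rho0
    } else if (p$variant == "dd_division") {
      delta <- p$delta0; rho <- p$rho0 * (p$n_ref / max(N, 1))^p$gamma
    } else {
      delta <- p$delta0; rho <- p$rho0
    }
    b <- p$beta
    if (!rte) {
      dy <- c(
        p_h = (if (donor_in) 0 else phi_p) + rho * (y[["p_h"]] + 2 * y[["n_h"]]) -
          (b + delta) * y[["p_h"]],
        n_h = (if (donor_in) 0 else phi_n) + b * y[["p_h"]] -
          (rho + delta) * y[["n_h"]],
        p_d = (if (donor_in) phi_p else 0) + rho * (y[["p_d"]] + 2 * y[["n_d"]]) -
          (b + delta) * y[["p_d"]],
        n_d = (if (donor_in) phi_n else 0) + b * y[["p_d"]] -
          (rho + delta) * y[["n_d"]])
    } else {
      dr <- p$delta0; rr <- p$rho0          # RTE rates
      dm <- p$delta_mn; rm <- p$rho_mn      # MN rates
      mu <- p$mu
      f <- function(pin, nin, rp, rn, mp, mnn) c(
        rp = pin + rr * (rp + 2 * rn) - (b + dr + mu) * rp,
        rn = nin + b * rp - (rr + dr + mu) * rn,
        mp = mu * rp + rm * (mp + 2 * mnn) - (b + dm) * mp,
        mn = mu * rn + b * mp - (rm + dm) * mnn)
      dh <- f(if (donor_in) 0 else phi_p, if (donor_in) 0 else phi_n,
              y[["rp_h"]], y[["rn_h"]], y[["mp_h"]], y[["mn_h"]])
      dd <- f(if (donor_in) phi_p else 0, if (donor_in) phi_n else 0,
              y[["rp_d"]], y[["rn_d"]], y[["mp_d"]], y[["mn_d"]])
      dy <- c(dh, dd)
    }
    list(unname(dy))
  }

  times <- sort(unique(c(t_span[1], t_out,
                         if (is.finite(t_switch)) t_switch)))
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", atol = atol, rtol = rtol)
  if (attr(sol, "istate")[1] < 0)
    stop("stiff integration failure in solve_compartmental; ",
         "istate = ", attr(sol, "istate")[1])
  sol <- as.data.frame(sol)
  sol <- sol[match(t_out, sol$time), ]
  counts <- as.matrix(sol[, nm, drop = FALSE])
  if (any(counts < -1e-6 * max(abs(counts))))
    stop("negative compartment counts beyond tolerance")
  counts[counts < 0] <- 0
  structure(list(t = t_out, counts = counts, state_names = nm,
                 t_start = t_span[1], t_bmt = t_bmt, bmt_delay = bmt_delay,
                 params = p, influx = influx, age_resolved = FALSE),
            class = "population_trajectory")
}

#' Observables from a compartmental trajectory
#'
#' Counterpart of [observables_from_trajectory()] for non-age-resolved
#' solutions.
#'
#' @inheritParams observables_from_trajectory
#' @export
compartmental_observables <- function(traj, reference_chimerism = 1) {
  chi <- reference_chimerism
  if (chi <= 0 || chi > 1) stop("reference_chimerism must lie in (0, 1]")
  cn <- colnames(traj$counts)
  pos <- grepl("^(p_|rp_|mp_)", cn)
  don <- grepl("_d$", cn)
  tot <- rowSums(traj$counts)
  n_post <- rowSums(traj$counts[, don, drop = FALSE])
  n_pre <- tot - n_post
  kp_post <- rowSums(traj$counts[, pos & don, drop = FALSE])
  kp_pre <- rowSums(traj$counts[, pos & !don, drop = FALSE])
  host_n <- (1 - chi) * n_post + n_pre
  data.frame(
    t_days = traj$t,
    total_count = tot,
    fd = ifelse(is.null(traj$t_bmt), NA_real_, n_post / pmax(tot, 1e-300)),
    ki67_host = ifelse(host_n > 0,
                       ((1 - chi) * kp_post + kp_pre) / host_n, NA_real_),
    ki67_donor = ifelse(n_post > 0, kp_post / n_post, NA_real_))
}
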