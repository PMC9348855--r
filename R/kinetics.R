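#' Kinetic parameters for a naive T cell model variant
#'
#' Bundles the per-subset rate constants for any of the six candidate models:
#' \describe{
#'   \item{neutral}{constant loss rate `delta0` and division rate `rho0`.}
#'   \item{dd_loss}{loss rate scales with pool size, `delta0 * (N/n_ref)^gamma`.}
#'   \item{dd_division}{division rate rises when the pool shrinks (LIP),
#'     `rho0 * (n_ref/N)^gamma`.}
#'   \item{rte_mn}{recent thymic emigrants and mature naive cells with
#'     distinct constant rates and maturation RTE -> MN at rate `mu`.}
#'   \item{age_loss}{loss rate declines exponentially with post-thymic cell
#'     age, `delta(a) = delta0 * exp(-r_delta * a)`.}
#'   \item{age_division}{division rate grows exponentially with cell age,
#'     `rho(a) = rho0 * exp(r_rho * a)`.}
#' }
#' Ki67 is modelled as a binary state: division yields two Ki67+ daughters and
#' Ki67+ reverts to Ki67- at rate `beta` (default 1/3.5 per day, the ~3-4 day
#' detection window of Ki67).
#'
#' Derived quantities: the residence time of a cell of age `a` is
#' `1/delta(a)`; the interdivision time is `1/rho(a)`.
#'
#' @param variant model variant, one of `"neutral"`, `"dd_loss"`,
#'   `"dd_division"`, `"rte_mn"`, `"age_loss"`, `"age_division"`.
#' @param delta0 loss rate of cells of age 0 (day^-1); for `rte_mn`, the RTE
#'   loss rate.
#' @param r_delta exponential decline rate of loss with cell age (day^-1,
#'   `age_loss` only).
#' @param rho0 division rate of cells of age 0 (day^-1); for `rte_mn`, the RTE
#'   division rate.
#' @param r_rho exponential increase rate of division with cell age (day^-1,
#'   `age_division` only).
#' @param beta Ki67+ -> Ki67- transition rate (day^-1).
#' @param mu RTE -> MN maturation rate (day^-1, `rte_mn` only).
#' @param delta_mn,rho_mn mature-naive loss/division rates (`rte_mn` only).
#' @param psi thymic export rate per SP thymocyte (day^-1); scales the influx
#'   descriptor's shape function.
#' @param gamma density-dependence strength (dimensionless, `dd_*` only).
#' @param n_ref reference pool size for density dependence (cells).
#' @param neonatal_modifier optional [lambda0_hill()] object; cohorts exported
#'   at mouse age `t0` inherit baseline loss `delta0 * lambda0(t0)/lambda_min`.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(variant = c("neutral", "dd_loss", "dd_division",
                                       "rte_mn", "age_loss", "age_division"),
                           delta0, r_delta = 0, rho0 = 0, r_rho = 0,
                           beta = 1 / 3.5, mu = 0, delta_mn = NA, rho_mn = NA,
                           psi = 0.3, gamma = 0, n_ref = 1e7,
                           neonatal_modifier = NULL) {
  variant <- match.arg(variant)
  rates <- c(delta0 = delta0, r_delta = r_delta, rho0 = rho0, r_rho = r_rho,
             beta = beta, mu = mu, psi = psi, gamma = gamma)
  if (any(rates < 0, na.rm = TRUE)) stop("all rates must be non-negative")
  if (variant != "age_loss" && r_delta != 0)
    stop("r_delta is only active in the age_loss variant")
  if (variant != "age_division" && r_rho != 0)
    stop("r_rho is only active in the age_division variant")
  if (variant %in% c("dd_loss", "dd_division") && gamma < 0)
    stop("gamma must be non-negative")
  if (variant == "rte_mn" && (is.na(delta_mn) || is.na(rho_mn) || mu <= 0))
    stop("rte_mn requires delta_mn, rho_mn and mu > 0")
  if (!is.null(neonatal_modifier) &&
      !inherits(neonatal_modifier, "lambda0_hill"))
    stop("neonatal_modifier must be a lambda0_hill object or NULL")
  structure(list(variant = variant, delta0 = delta0, r_delta = r_delta,
                 rho0 = rho0, r_rho = r_rho, beta = beta, mu = mu,
                 delta_mn = delta_mn, rho_mn = rho_mn, psi = psi,
                 gamma = gamma, n_ref = n_ref,
                 neonatal_modifier = neonatal_modifier),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (", x$variant, ")\n", sep = "")
  act <- .variant_parnames(x$variant)
  for (nm in act)
    cat(" ", nm, "=", signif(x[[nm]], 4), "\n")
  cat("  beta =", signif(x$beta, 4), "(Ki67 decay)\n")
  if (!is.null(x$neonatal_modifier)) cat("  with neonatal Hill modifier\n")
  invisible(x)
}

## active kinetic parameters per variant (psi last; sigmas appended elsewhere)
.variant_parnames <- function(variant) {
  switch(variant,
    neutral      = c("delta0", "rho0", "psi"),
    age_loss     = c("delta0", "r_delta", "rho0", "psi"),
    age_division = c("delta0", "rho0", "r_rho", "psi"),
    dd_loss      = c("delta0", "rho0", "gamma", "psi"),
    dd_division  = c("delta0", "rho0", "gamma", "psi"),
    rte_mn       = c("delta0", "rho0", "delta_mn", "rho_mn", "mu", "psi"),
    stop("unknown variant ", variant))
}

#' Instantaneous loss rate delta(a)
#'
#' @param a post-thymic cell age, days (>= 0).
#' @param p a [kinetic_params()] object.
#' @param entry_time optional mouse age at thymic export of the cohort
#'   (days); used by the neonatal modifier, which scales the baseline loss
#'   rate each cohort inherits.
#' @return loss rate in day^-1.
#' @export
loss_rate <- function(a, p, entry_time = NULL) {
  if (any(a < 0)) stop("cell age a must be non-negative")
  scale <- if (is.null(entry_time)) 1 else
    .modifier_scale(p$neonatal_modifier, entry_time)
  if (p$variant == "age_loss") p$delta0 * scale * exp(-p$r_delta * a)
  else p$delta0 * scale * rep(1, length(a))
}

#' Instantaneous division rate rho(a)
#'
#' @inheritParams loss_rate
#' @return division rate in day^-1.
#' @export
division_rate <- function(a, p) {
  if (any(a < 0)) stop("cell age a must be non-negative")
  if (p$variant == "age_division") p$rho0 * exp(p$r_rho * a)
  else p$rho0 * rep(1, length(a))
}

#' Published point estimates for the age-dependent loss model
#'
#' Convenience constructor carrying the adult busulfan-chimera point
#' estimates for the cell-age-dependent loss model: residence time of cells
#' of age 0 of 22 d (CD4) / 40 d (CD8), loss-rate halving time 92 d / 146 d,
#' and mean interdivision times of 18 / 14 months (months converted at
#' 30.44 d/month).
#'
#' @param subset `"CD4"` or `"CD8"`.
#' @param neonatal_modifier optional [lambda0_hill()] modifier (CD8 only).
#' @param psi export rate per SP thymocyte (day^-1).
#' @return A [kinetic_params()] object with `variant = "age_loss"`.
#' @export
reference_params <- function(subset = c("CD4", "CD8"),
                             neonatal_modifier = NULL, psi = 0.3) {
  subset <- match.arg(subset)
  if (subset == "CD4") {
    if (!is.null(neonatal_modifier))
      stop("no neonatal modifier is supported for CD4 (no neonatal effect)")
    kinetic_params("age_loss", delta0 = 1 / 22, r_delta = log(2) / 92,
                   rho0 = 1 / (18 * 30.44), psi = psi)
  } else {
    kinetic_params("age_loss", delta0 = 1 / 40, r_delta = log(2) / 146,
                   rho0 = 1 / (14 * 30.44), psi = psi,
                   neonatal_modifier = neonatal_modifier)
  }
}

## ---- cohort kernel -------------------------------------------------------
## Along a characteristic (fixed entry time t0), with n = u+ + u- and
## k = u+/n:
##   dn/da = (rho(a) - delta(a)) n
##   dk/da = 2 rho(a) (1 - k) - beta k        (independent of delta)
## so n(a, t0) = theta(t0) exp(P(a) - c(t0) D(a)) with P = int rho,
## D = int delta0 e^{-r_delta x} dx, c(t0) the modifier scale, and
## k(a) = khom(a) k0 + kpart(a), khom = exp(-B), B = 2P + beta a.
## The kernel tabulates P, D, khom, kpart on an age grid once per parameter
## set; every cohort evaluation is then closed-form.
.age_kernel <- function(p, a_grid) {
  a <- a_grid
  P <- if (p$r_rho > 0) p$rho0 * (exp(p$r_rho * a) - 1) / p$r_rho
       else p$rho0 * a
  D <- if (p$r_delta > 0) p$delta0 * (1 - exp(-p$r_delta * a)) / p$r_delta
       else p$delta0 * a
  B <- 2 * P + p$beta * a
  khom <- exp(-B)
  if (p$r_rho == 0) {
    denom <- 2 * p$rho0 + p$beta
    kinf <- if (denom > 0) 2 * p$rho0 / denom else 0
    kpart <- kinf * (1 - exp(-denom * a))
  } else {
    ## particular solution with k0 = 0 by stable one-pass recursion
    n <- length(a)
    kpart <- numeric(n)
    if (n > 1) {
      rho <- p$rho0 * exp(p$r_rho * a)
      dB <- diff(B)
      h <- diff(a)
      for (i in seq_len(n - 1)) {
        dec <- exp(-dB[i])
        kpart[i + 1] <- kpart[i] * dec +
          0.5 * h[i] * (2 * rho[i + 1] + 2 * rho[i] * dec)
      }
      kpart <- pmin(kpart, 1)
    }
  }
  list(a = a, P = P, D = D, khom = khom, kpart = kpart)
}
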