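#' Thymic influx: empirical description of SP thymocyte export
#'
#' Naive T cells are seeded by export of late-stage single-positive (SP4/SP8)
#' thymocytes. The export rate at mouse age `t` is taken to be proportional to
#' the SP pool size, `theta(t) = psi * S(t)`, and is split into Ki67+ and
#' Ki67- streams by the SP Ki67+ fraction `kappa(t)`. `S(t)` and `kappa(t)`
#' are smooth empirical curves fitted to SP thymocyte timecourses; `psi`
#' (export per SP cell per day) is left free and is estimated downstream.
#'
#' Registered families:
#' * counts, `"biexp"`: `S(t) = A * (exp(-l1*t) - exp(-l2*t))`, `l2 > l1 >= 0`,
#'   a flexible positive curve that rises over the first weeks of life and
#'   declines slowly with thymic involution.
#' * Ki67 fraction, `"logage_logistic"`:
#'   `kappa(t) = k_min + (1 - k_min) / (1 + (t/t_half)^slope)`, a decreasing
#'   logistic in log mouse age: close to 1 in neonates, falling to its adult
#'   floor `k_min` over the first months of life.
#'
#' @param count_params named numeric vector, parameters of `S(t)`.
#' @param ki67_params named numeric vector, parameters of `kappa(t)`.
#' @param psi export rate per SP thymocyte per day (>= 0).
#' @param count_family,ki67_family family tags (see Details).
#' @param diagnostics optional list of fit diagnostics.
#' @return An object of class `influx_descriptor`.
#' @export
influx_descriptor <- function(count_params, ki67_params, psi = 1,
                              count_family = "biexp",
                              ki67_family = "logage_logistic",
                              diagnostics = NULL) {
  stopifnot(is.numeric(psi), length(psi) == 1L, psi >= 0)
  d <- structure(
    list(count_params = count_params, ki67_params = ki67_params, psi = psi,
         count_family = count_family, ki67_family = ki67_family,
         diagnostics = diagnostics),
    class = "influx_descriptor")
  tt <- c(1, 2, 5, 10, 30, 60, 120, 300, 600)
  s <- sp_count_curve(tt, d)
  k <- sp_ki67_curve(tt, d)
  if (any(!is.finite(s)) || any(s <= 0))
    stop("S(t) must be strictly positive on [1, 600] days")
  if (any(k < 0 | k > 1)) stop("kappa(t) must lie in [0, 1] on [1, 600] days")
  d
}

#' @export
print.influx_descriptor <- function(x, ...) {
  cat("Thymic influx descriptor\n")
  cat("  S(t) family:", x$count_family, " params:",
      paste(names(x$count_params), signif(x$count_params, 4),
            sep = "=", collapse = ", "), "\n")
  cat("  kappa(t) family:", x$ki67_family, " params:",
      paste(names(x$ki67_params), signif(x$ki67_params, 4),
            sep = "=", collapse = ", "), "\n")
  cat("  psi:", signif(x$psi, 4), "per SP cell per day\n")
  invisible(x)
}

#' SP thymocyte count curve S(t)
#'
#' @param t mouse age in days.
#' @param d an `influx_descriptor`.
#' @return SP thymocyte numbers at each `t`.
#' @export
sp_count_curve <- function(t, d) {
  p <- d$count_params
  switch(d$count_family,
    biexp = p[["A"]] * (exp(-p[["l1"]] * t) - exp(-p[["l2"]] * t)),
    constant = rep(p[["A"]], length(t)),
    stop("unknown count family: ", d$count_family))
}

#' SP thymocyte Ki67+ fraction kappa(t)
#'
#' @inheritParams sp_count_curve
#' @return Ki67+ fraction within SP thymocytes at each `t`, in \[0, 1\].
#' @export
sp_ki67_curve <- function(t, d) {
  p <- d$ki67_params
  switch(d$ki67_family,
    logage_logistic =
      p[["k_min"]] + (1 - p[["k_min"]]) / (1 + (t / p[["t_half"]])^p[["slope"]]),
    constant = rep(p[["k"]], length(t)),
    stop("unknown ki67 family: ", d$ki67_family))
}

#' Default influx descriptors
#'
#' Registered default curves emulating the reported behaviour of late-stage SP
#' thymocytes: pool size peaking at a few million cells around 6-8 weeks of
#' age then declining slowly with involution, and a Ki67+ fraction near 100%
#' in neonates declining to roughly 20% by 3 months.
#'
#' @param subset `"CD4"` or `"CD8"`.
#' @param psi export rate per SP thymocyte (day^-1).
#' @return An `influx_descriptor`.
#' @export
default_influx <- function(subset = c("CD4", "CD8"), psi = 0.3) {
  subset <- match.arg(subset)
  A <- if (subset == "CD4") 4e6 else 1.4e6
  influx_descriptor(
    count_params = c(A = A, l1 = 0.004, l2 = 0.05),
    ki67_params = c(k_min = 0.15, t_half = 35, slope = 3),
    psi = psi)
}

#' Ki67-split thymic influx rate
#'
#' Total export is `psi * S(t)`; the Ki67+ stream is `psi * S(t) * kappa(t)`
#' and the Ki67- stream `psi * S(t) * (1 - kappa(t))`, so the two always sum
#' to total export.
#'
#' @param t mouse age, days; must be >= 1.
#' @param ki67_state `"pos"`, `"neg"` or `"total"`.
#' @param d an `influx_descriptor`.
#' @return influx in cells/day.
#' @export
influx_rate <- function(t, ki67_state = c("total", "pos", "neg"), d) {
  ki67_state <- match.arg(ki67_state)
  if (any(t < 1)) stop("influx is defined for mouse age t >= 1 day")
  tot <- d$psi * sp_count_curve(t, d)
  switch(ki67_state,
    total = tot,
    pos = tot * sp_ki67_curve(t, d),
    neg = tot * (1 - sp_ki67_curve(t, d)))
}

#' Fit an influx descriptor to SP thymocyte timecourses
#'
#' `S(t)` is fitted by least squares on the log scale and `kappa(t)` on the
#' logit scale, reflecting the multiplicative count noise and bounded-fraction
#' noise the observation model assumes. `psi` is not estimable from thymic
#' data alone and is carried through as supplied.
#'
#' @param data data frame with columns `mouse_age_days`, `subset`, `sp_count`,
#'   `sp_ki67_frac` (the `sp` CSV schema, see [read_dataset()]).
#' @param subset `"CD4"` or `"CD8"`; rows for other subsets are ignored.
#' @param psi pass-through export rate (default 1; estimated downstream).
#' @return An `influx_descriptor` with fit diagnostics (residual SDs,
#'   convergence flags, n used/rejected).
#' @export
fit_sp_descriptor <- function(data, subset = c("CD4", "CD8"), psi = 1) {
  subset <- match.arg(subset)
  data <- data[data$subset == subset, , drop = FALSE]
  bad <- data$mouse_age_days < 1 | data$mouse_age_days > 600
  if (any(bad)) {
    warning(sum(bad), " rows with mouse age outside [1, 600] days rejected")
    data <- data[!bad, , drop = FALSE]
  }
  if (nrow(data) < 8)
    stop("need at least 8 SP observations to fit an influx descriptor")
  if (!any(data$mouse_age_days < 21) || !any(data$mouse_age_days > 90))
    stop("SP data must span neonatal (<21 d) and adult (>90 d) ages")

  t <- data$mouse_age_days

  ## S(t): biexponential, fitted on log counts; parameters kept positive with
  ## l2 = l1 + gap so the curve stays positive.
  y <- log(data$sp_count)
  obj_s <- function(par) {
    A <- exp(par[1]); l1 <- exp(par[2]); l2 <- l1 + exp(par[3])
    sum((y - log(A * (exp(-l1 * t) - exp(-l2 * t))))^2)
  }
  start_s <- c(log(max(data$sp_count) * 1.3), log(0.004), log(0.05))
  fit_s <- stats::optim(start_s, obj_s, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
  fit_s <- stats::optim(fit_s$par, obj_s, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
  A <- exp(fit_s$par[1]); l1 <- exp(fit_s$par[2]); l2 <- l1 + exp(fit_s$par[3])

  ## kappa(t): decreasing log-age logistic, fitted on the logit scale.
  k_obs <- pmin(pmax(data$sp_ki67_frac, 1e-4), 1 - 1e-4)
  z <- stats::qlogis(k_obs)
  obj_k <- function(par) {
    km <- stats::plogis(par[1]); th <- exp(par[2]); sl <- exp(par[3])
    kk <- km + (1 - km) / (1 + (t / th)^sl)
    sum((z - stats::qlogis(pmin(pmax(kk, 1e-6), 1 - 1e-6)))^2)
  }
  start_k <- c(stats::qlogis(max(min(k_obs) * 0.8, 1e-3)), log(40), log(2))
  fit_k <- stats::optim(start_k, obj_k, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
  fit_k <- stats::optim(fit_k$par, obj_k, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
  km <- stats::plogis(fit_k$par[1]); th <- exp(fit_k$par[2]); sl <- exp(fit_k$par[3])

  if (!is.finite(fit_s$value) || !is.finite(fit_k$value))
    stop("influx descriptor fit failed to converge; inspect the input data")

  influx_descriptor(
    count_params = c(A = A, l1 = l1, l2 = l2),
    ki67_params = c(k_min = km, t_half = th, slope = sl),
    psi = psi,
    diagnostics = list(
      rss_log_count = fit_s$value, rss_logit_ki67 = fit_k$value,
      sd_log_count = sqrt(fit_s$value / nrow(data)),
      sd_logit_ki67 = sqrt(fit_k$value / nrow(data)),
      n_obs = nrow(data), n_rejected = sum(bad),
      converged = fit_s$convergence == 0 && fit_k$convergence == 0))
}

#' Serialise an influx descriptor to JSON
#'
#' @param d an `influx_descriptor`.
#' @param path file to write.
#' @export
write_influx_json <- function(d, path) {
  jsonlite::write_json(
    list(count_family = d$count_family, count_params = as.list(d$count_params),
         ki67_family = d$ki67_family, ki67_params = as.list(d$ki67_params),
         psi = d$psi, diagnostics = d$diagnostics),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an influx descriptor from JSON
#'
#' @param path file written by [write_influx_json()].
#' @return An `influx_descriptor`.
#' @export
read_influx_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  influx_descriptor(count_params = unlist(x$count_params),
                    ki67_params = unlist(x$ki67_params),
                    psi = x$psi, count_family = x$count_family,
                    ki67_family = x$ki67_family, diagnostics = x$diagnostics)
}
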